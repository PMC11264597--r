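# In-silico extraction of 16S sub-regions: locate degenerate primer pairs on
# each full-length read with a bounded mismatch tolerance, slice the region
# between them, then verify capture efficiency and audit fidelity.

#' Locate a degenerate primer on a read
#'
#' Scans every window of `seq` for the primer and returns the qualifying hit
#' with the fewest mismatches. Reverse primers are scanned as their
#' IUPAC-aware reverse complement, so coordinates always refer to the plus
#' strand of `seq`. Ties on mismatch count go to the leftmost window for
#' forward primers and the rightmost for reverse primers (a primer pair
#' should bracket the widest region).
#'
#' @param seq Plus-strand DNA string.
#' @param primer A [primer].
#' @param max_mm Mismatch budget.
#' @return A list `(start, end, mismatches)` with 0-based half-open
#'   coordinates, or `NULL` when no window qualifies.
#' @export
find_primer <- function(seq, primer, max_mm = 4L) {
  stopifnot(inherits(primer, "primer"))
  pat <- if (primer$orientation == "reverse") revcomp(primer$sequence)
         else primer$sequence
  if (nchar(seq) < nchar(pat)) return(NULL)
  hit <- .scan_primer_cpp(seq, pat, as.integer(max_mm),
                          leftmost = primer$orientation == "forward")
  if (hit$start < 0) return(NULL)
  list(start = hit$start, end = hit$start + nchar(pat),
       mismatches = hit$mismatches)
}

#' Orient a read using a forward anchor primer
#'
#' Returns the orientation (the read or its reverse complement) whose best
#' anchor-primer hit has fewer mismatches; an exact tie (including
#' anchor-not-found on both strands) leaves the read unflipped.
#'
#' @param seq DNA string in unknown orientation.
#' @param anchor A forward [primer] (default 27F).
#' @param max_mm Mismatch budget used for the anchor search.
#' @return List `(sequence, strand_flipped)`.
#' @export
orient_read <- function(seq, anchor = default_primers()$`27F`, max_mm = 4L) {
  stopifnot(anchor$orientation == "forward")
  rc <- revcomp(seq)
  mm_fwd <- find_primer(seq, anchor, max_mm)
  mm_rev <- find_primer(rc, anchor, max_mm)
  a <- if (is.null(mm_fwd)) Inf else mm_fwd$mismatches
  b <- if (is.null(mm_rev)) Inf else mm_rev$mismatches
  if (b < a) list(sequence = rc, strand_flipped = TRUE)
  else list(sequence = seq, strand_flipped = FALSE)
}

#' Extract one sub-region from one read
#'
#' Locates the region's forward and reverse primer on the (optionally
#' auto-oriented) read and returns the sequence strictly between them,
#' primers removed. Failures are encoded as statuses, never errors:
#' `fwd_missing`, `rev_missing`, `both_missing`, or `malformed_order` when
#' the reverse hit precedes the forward hit.
#'
#' @param seq DNA string.
#' @param region A [region_def].
#' @param orient Auto-orient using the region's forward primer (default
#'   TRUE).
#' @param include_primers Include the primer-matched bases in the returned
#'   sequence (default FALSE, matching the primer-trimmed convention of CCS
#'   pre-processing).
#' @return List `(read_id-less) status, sequence, fwd_hit, rev_hit,
#'   strand_flipped`; `sequence` is `NA` unless `status == "extracted"`.
#' @export
extract_region <- function(seq, region, orient = TRUE,
                           include_primers = FALSE) {
  stopifnot(inherits(region, "region_def"))
  flipped <- FALSE
  if (orient) {
    o <- orient_read(seq, region$forward, region$max_mismatches)
    seq <- o$sequence
    flipped <- o$strand_flipped
  }
  fwd <- find_primer(seq, region$forward, region$max_mismatches)
  rev <- find_primer(seq, region$reverse, region$max_mismatches)
  status <- if (is.null(fwd) && is.null(rev)) "both_missing"
    else if (is.null(fwd)) "fwd_missing"
    else if (is.null(rev)) "rev_missing"
    else if (rev$start < fwd$end) "malformed_order"
    else "extracted"
  sequence <- NA_character_
  if (status == "extracted") {
    sequence <- if (include_primers) substr(seq, fwd$start + 1L, rev$end)
                else substr(seq, fwd$end + 1L, rev$start)
  }
  list(status = status, sequence = sequence, fwd_hit = fwd, rev_hit = rev,
       strand_flipped = flipped)
}

#' Extract a region from every read of a set
#'
#' @param reads Named character vector of reads (names = read ids).
#' @param region A [region_def].
#' @param orient,include_primers See [extract_region()].
#' @return data.frame with one row per read: read_id, region, status,
#'   sequence, primer-hit coordinates (1-based closed, as reported to users)
#'   and mismatch counts.
#' @export
extract_read_set <- function(reads, region, orient = TRUE,
                             include_primers = FALSE) {
  res <- lapply(reads, extract_region, region = region, orient = orient,
                include_primers = include_primers)
  data.frame(
    read_id = names(reads),
    region = region$name,
    status = vapply(res, `[[`, character(1), "status"),
    sequence = vapply(res, `[[`, character(1), "sequence"),
    fwd_start = vapply(res, function(r)
      if (is.null(r$fwd_hit)) NA_integer_ else r$fwd_hit$start + 1L,
      integer(1)),
    fwd_mm = vapply(res, function(r)
      if (is.null(r$fwd_hit)) NA_integer_ else r$fwd_hit$mismatches,
      integer(1)),
    rev_start = vapply(res, function(r)
      if (is.null(r$rev_hit)) NA_integer_ else r$rev_hit$start + 1L,
      integer(1)),
    rev_mm = vapply(res, function(r)
      if (is.null(r$rev_hit)) NA_integer_ else r$rev_hit$mismatches,
      integer(1)),
    strand_flipped = vapply(res, `[[`, logical(1), "strand_flipped"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Capture-efficiency report with fidelity audit
#'
#' Computes the fraction of input reads from which the region was extracted,
#' flags whether it clears the 98% capture threshold, and audits fidelity by
#' drawing a seeded random subset of extracted sequences and verifying each
#' is an exact substring of its (possibly reverse-complemented) parent read.
#'
#' @param results data.frame from [extract_read_set()] for a single region.
#' @param reads The original reads the results came from.
#' @param audit_size Number of extracted sequences to audit (default 100).
#' @param seed Seed for the audit draw.
#' @param threshold Capture-efficiency threshold (default 0.98).
#' @return List: region, n_input, n_extracted, efficiency, passes_threshold,
#'   fidelity_pass_fraction.
#' @export
capture_report <- function(results, reads, audit_size = 100L, seed = 1L,
                           threshold = 0.98) {
  if (nrow(results) == 0) stop("empty extraction results")
  if (length(unique(results$region)) != 1) {
    stop("capture_report expects results for a single region, got: ",
         paste(unique(results$region), collapse = ", "))
  }
  n_input <- nrow(results)
  ext <- results[results$status == "extracted", ]
  n_extracted <- nrow(ext)
  efficiency <- n_extracted / n_input
  fidelity <- NA_real_
  if (n_extracted > 0) {
    n_audit <- min(audit_size, n_extracted)
    idx <- withr::with_seed(seed, sample(n_extracted, n_audit))
    ok <- vapply(idx, function(i) {
      parent <- reads[[ext$read_id[i]]]
      grepl(ext$sequence[i], parent, fixed = TRUE) ||
        grepl(ext$sequence[i], revcomp(parent), fixed = TRUE)
    }, logical(1))
    fidelity <- mean(ok)
  }
  list(region = results$region[1], n_input = n_input,
       n_extracted = n_extracted, efficiency = efficiency,
       passes_threshold = efficiency >= threshold,
       fidelity_pass_fraction = fidelity)
}
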