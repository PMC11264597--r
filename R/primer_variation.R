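# Cataloging sequence variation at primer-binding sites across deduplicated
# full-length reads: abundance filters, consensus dot-masking,
# degenerate-coverage flags and taxon association.

#' Deduplicate full-length reads
#'
#' Exact-string deduplication; counts are conserved.
#'
#' @param reads Named character vector (read id -> sequence).
#' @return List: `uniques` (data.frame uid, sequence, count, ordered by
#'   count descending then sequence), `members` (named list uid -> read
#'   ids).
#' @export
dedupe_fulllength <- function(reads) {
  stopifnot(length(reads) > 0)
  grp <- split(names(reads), reads)
  cnt <- lengths(grp)
  ord <- order(-cnt, names(grp))
  grp <- grp[ord]
  uids <- sprintf("u%05d", seq_along(grp))
  list(uniques = data.frame(uid = uids, sequence = names(grp),
                            count = as.integer(cnt[ord]),
                            row.names = NULL, stringsAsFactors = FALSE),
       members = stats::setNames(grp, uids))
}

# dot-mask a site sequence against the consensus
.mask_site <- function(seq, consensus) {
  sc <- strsplit(seq, "")[[1]]
  cc <- strsplit(consensus, "")[[1]]
  paste(ifelse(sc == cc, ".", sc), collapse = "")
}

#' Catalog variation at one primer-binding site
#'
#' Locates the primer's binding site on every deduplicated full-length
#' sequence (mismatch budget `max_mm`, so sites mutated beyond the budget
#' are invisible, mirroring the detection bias of primer-based extraction),
#' tallies the distinct site sequences weighted by read counts, and applies
#' the abundance filters: variants backed by fewer than `min_reads` reads or
#' less than `min_frac` of the located total are dropped. The consensus (the
#' most frequent site sequence) is always retained and rendered in full; all
#' other variants are shown with dots at consensus-identical positions.
#' Positions whose base falls outside the primer's IUPAC expansion are
#' flagged.
#'
#' @param dedup Result of [dedupe_fulllength()].
#' @param primer A [primer].
#' @param max_mm Site-location mismatch budget (default 4); set to
#'   `nchar(primer$sequence)` for the unlimited-budget sensitivity mode.
#' @param min_reads Minimum backing reads (default 5).
#' @param min_frac Minimum fraction of located, count-weighted reads
#'   (default 0.001). The denominator is the weighted total of sequences
#'   with a located site for this primer.
#' @return A `site_catalog`: list with `variants` (data.frame primer,
#'   sequence, masked, count, fraction, is_consensus,
#'   outside_degenerate as comma-joined 1-based positions), `members`
#'   (named list site sequence -> uids), `consensus`, `n_located`,
#'   `low_recovery` (TRUE when the primer was absent from more than half of
#'   the unique sequences).
#' @export
site_catalog <- function(dedup, primer, max_mm = 4L, min_reads = 5L,
                         min_frac = 0.001) {
  stopifnot(inherits(primer, "primer"), min_reads >= 1)
  u <- dedup$uniques
  pat <- if (primer$orientation == "reverse") revcomp(primer$sequence)
         else primer$sequence
  pch <- strsplit(pat, "")[[1]]
  hits <- lapply(u$sequence, find_primer, primer = primer, max_mm = max_mm)
  located <- !vapply(hits, is.null, logical(1))
  low_recovery <- mean(located) < 0.5
  if (low_recovery) {
    warning("primer ", primer$name, " located in only ",
            sum(located), "/", length(located), " unique sequences")
  }
  site_seq <- rep(NA_character_, nrow(u))
  site_seq[located] <- substr(u$sequence[located],
                              vapply(hits[located], function(h)
                                h$start + 1L, integer(1)),
                              vapply(hits[located], function(h)
                                h$end, integer(1)))
  keep <- located
  tot <- sum(u$count[keep])
  agg <- rowsum(u$count[keep], site_seq[keep])
  cnt <- stats::setNames(as.integer(agg), rownames(agg))
  ord <- order(-cnt, names(cnt))
  cnt <- cnt[ord]
  consensus <- names(cnt)[1]
  frac <- cnt / tot
  retain <- (cnt >= min_reads & frac >= min_frac) |
    names(cnt) == consensus
  cnt <- cnt[retain]
  frac <- frac[retain]
  variants <- do.call(rbind, lapply(names(cnt), function(s) {
    sc <- strsplit(s, "")[[1]]
    outside <- which(!vapply(seq_along(pch), function(i)
      sc[i] %in% IUPAC_CODES[[pch[i]]], logical(1)))
    data.frame(
      primer = primer$name, sequence = s,
      masked = if (s == consensus) s else .mask_site(s, consensus),
      count = unname(cnt[s]), fraction = unname(frac[s]),
      is_consensus = s == consensus,
      outside_degenerate = paste(outside, collapse = ","),
      stringsAsFactors = FALSE)
  }))
  members <- lapply(names(cnt), function(s)
    u$uid[keep & !is.na(site_seq) & site_seq == s])
  names(members) <- names(cnt)
  structure(list(variants = variants, members = members,
                 consensus = consensus, n_located = tot,
                 low_recovery = low_recovery),
            class = "site_catalog")
}

#' Deepest confident label of each assignment
#'
#' @param assignments data.frame from [classify_variants()].
#' @return Named vector variant_id -> deepest non-missing rank label
#'   (`"unclassified"` when no rank was kept).
#' @export
deepest_labels <- function(assignments) {
  lab <- apply(assignments[, .RANKS], 1, function(r) {
    nn <- r[!is.na(r)]
    if (length(nn)) nn[[length(nn)]] else "unclassified"
  })
  stats::setNames(lab, assignments$variant_id)
}

#' Taxa associated with a primer-site variant
#'
#' Groups the reads backing one cataloged site variant by their taxonomic
#' label and ranks the groups by descending read count (ties broken
#' lexicographically), identifying the bacterial groups that carry the
#' variation.
#'
#' @param catalog A `site_catalog`.
#' @param site_sequence One of the cataloged site sequences.
#' @param dedup The [dedupe_fulllength()] result the catalog came from.
#' @param read_labels Named vector read id -> taxonomic label (e.g. the
#'   deepest confident lineage label, or ground-truth taxa).
#' @return data.frame: taxon, count (descending).
#' @export
taxon_association <- function(catalog, site_sequence, dedup, read_labels) {
  stopifnot(inherits(catalog, "site_catalog"),
            site_sequence %in% names(catalog$members))
  uids <- catalog$members[[site_sequence]]
  reads <- unlist(dedup$members[uids], use.names = FALSE)
  missing <- setdiff(reads, names(read_labels))
  if (length(missing)) {
    stop("reads without a taxonomic label: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  tb <- table(read_labels[reads])
  df <- data.frame(taxon = names(tb), count = as.integer(tb),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$taxon), , drop = FALSE]
}
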