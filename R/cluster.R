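# Feature building: exact-variant dereplication (the ASV stand-in) and
# greedy abundance-ordered OTU clustering at 97/98/99% identity.

#' Dereplicate sequences into exact variants
#'
#' Groups identical sequences into variants and tabulates per-sample counts.
#' Variants are ordered by total count (descending), ties broken by sequence
#' (ascending), and named `var00001, ...` in that order.
#'
#' @param records data.frame with columns `sample_id` and `sequence`.
#' @param min_count Drop variants with total count below this (default 1,
#'   i.e. keep singletons).
#' @return A `variant_set`: list with `variants` (data.frame variant_id,
#'   sequence, total) and `counts` (variants x samples integer matrix).
#' @export
dereplicate <- function(records, min_count = 1L) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "sequence") %in% colnames(records)))
  samples <- unique(records$sample_id)
  if (nrow(records) == 0) {
    return(structure(list(
      variants = data.frame(variant_id = character(0),
                            sequence = character(0), total = integer(0)),
      counts = matrix(0L, 0, length(samples),
                      dimnames = list(NULL, samples))),
      class = "variant_set"))
  }
  stopifnot(all(grepl("^[ACGT]+$", records$sequence)))
  tab <- table(records$sequence, factor(records$sample_id, levels = samples))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  total <- rowSums(counts)
  ord <- order(-total, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  total <- total[ord]
  keep <- total >= min_count
  counts <- counts[keep, , drop = FALSE]
  total <- total[keep]
  ids <- sprintf("var%05d", seq_len(nrow(counts)))
  variants <- data.frame(variant_id = ids, sequence = rownames(counts),
                         total = as.integer(total),
                         stringsAsFactors = FALSE)
  rownames(counts) <- ids
  structure(list(variants = variants, counts = counts),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set: %d variants over %d samples, %d reads>\n",
              nrow(x$variants), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Pairwise sequence identity
#'
#' Global alignment with free terminal gaps (match +1, mismatch -1, gap -2);
#' identity is matching columns over alignment columns, terminal-gap columns
#' excluded. Among maximum-score alignments the one maximising matches (then
#' minimising columns) defines the identity, making the value deterministic.
#'
#' @param a,b Non-empty DNA strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  .overlap_align_cpp(a, b)$identity
}

#' Greedy identity-threshold OTU clustering
#'
#' Single greedy centroid pass over variants in (abundance descending,
#' sequence ascending) order: each variant joins the existing centroid of
#' highest identity among those with identity >= `threshold` (ties -> the
#' earliest-founded centroid), otherwise founds a new cluster. Centroids are
#' therefore always the most abundant member of their cluster.
#'
#' @param variants A `variant_set` from [dereplicate()].
#' @param threshold Identity threshold in (0, 1], typically 0.97/0.98/0.99.
#' @return An `otu_set`: list with `otus` (data.frame otu_id,
#'   centroid_variant, centroid_sequence, n_members, total), `assignment`
#'   (named vector variant_id -> otu_id), `threshold`.
#' @export
cluster_otus <- function(variants, threshold) {
  stopifnot(inherits(variants, "variant_set"),
            threshold > 0, threshold <= 1)
  v <- variants$variants
  ord <- order(-v$total, v$sequence)   # defensive; dereplicate() pre-orders
  v <- v[ord, ]
  centroids <- integer(0)              # row indices into v
  assign <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    best_otu <- 0L
    best_id <- -1
    for (k in seq_along(centroids)) {
      id <- pairwise_identity(v$sequence[i], v$sequence[centroids[k]])
      if (id >= threshold && id > best_id) {
        best_id <- id
        best_otu <- k
      }
    }
    if (best_otu == 0L) {
      centroids <- c(centroids, i)
      assign[i] <- length(centroids)
    } else {
      assign[i] <- best_otu
    }
  }
  otu_ids <- sprintf("otu%04d", seq_along(centroids))
  totals <- vapply(seq_along(centroids), function(k)
    sum(v$total[assign == k]), numeric(1))
  otus <- data.frame(
    otu_id = otu_ids,
    centroid_variant = v$variant_id[centroids],
    centroid_sequence = v$sequence[centroids],
    n_members = as.integer(table(factor(assign,
                                        levels = seq_along(centroids)))),
    total = as.integer(totals),
    stringsAsFactors = FALSE)
  structure(list(otus = otus,
                 assignment = stats::setNames(otu_ids[assign], v$variant_id),
                 threshold = threshold),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("<otu_set: %d OTUs at %.0f%% identity>\n",
              nrow(x$otus), 100 * x$threshold))
  invisible(x)
}
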