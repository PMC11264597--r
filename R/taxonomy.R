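# Taxonomy: a naive k-mer bootstrap voter in the spirit of amplicon
# classifiers (k-mer profile vote with bootstrap confidence, assignments
# truncated below a confidence threshold), plus the species-level
# concordance rule that scores sub-region calls against the full-length
# call of the same read population.

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")

#' Prebuild a k-mer classifier from a reference
#'
#' Builds the inverted k-mer index once so that many variants can be
#' classified cheaply.
#'
#' @param reference A `reference_set`.
#' @param k Word size (default 8, minimum 4).
#' @return A `kmer_classifier` object.
#' @export
kmer_classifier <- function(reference, k = 8L) {
  stopifnot(inherits(reference, "reference_set"), k >= 4)
  taxa <- reference$taxa
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(taxa))) {
    s <- taxa$sequence[i]
    W <- nchar(s) - k + 1L
    kms <- unique(substring(s, 1:W, k:(W + k - 1L)))
    for (km in kms) {
      idx[[km]] <- c(idx[[km]], i)
    }
  }
  structure(list(k = as.integer(k), index = idx,
                 taxon_ids = taxa$taxon_id,
                 lineage = as.matrix(taxa[, .RANKS])),
            class = "kmer_classifier")
}

#' Assign a ranked lineage to a sequence variant
#'
#' Bootstrap k-mer vote: each bootstrap draws `ceiling(W/8)` of the
#' variant's `W` k-mers with replacement, scores every reference species by
#' the number of drawn k-mers it shares, and votes for the top-scoring
#' species (ties -> lexicographically smallest taxon id). Per-rank
#' confidence is the fraction of votes whose lineage agrees with the winning
#' species down to that rank; the lineage is truncated at the deepest rank
#' with confidence >= `conf_threshold`.
#'
#' @param variant DNA string to classify.
#' @param classifier A `kmer_classifier` (or a `reference_set`, from which
#'   one is built).
#' @param n_bootstrap Number of bootstrap votes (default 100).
#' @param conf_threshold Confidence needed to keep a rank (default 0.8).
#' @param seed Seed for the bootstrap draws.
#' @return A list: `lineage` (named character, `NA` below the truncation
#'   rank), `confidence` (named numeric over the 7 ranks),
#'   `deepest_confident_rank` (`NA` when unclassified), `best_taxon`.
#' @export
assign_taxonomy <- function(variant, classifier, n_bootstrap = 100L,
                            conf_threshold = 0.8, seed = 1L) {
  if (inherits(classifier, "reference_set")) {
    classifier <- kmer_classifier(classifier)
  }
  stopifnot(inherits(classifier, "kmer_classifier"), n_bootstrap >= 1)
  k <- classifier$k
  empty <- list(
    lineage = stats::setNames(rep(NA_character_, 7), .RANKS),
    confidence = stats::setNames(rep(0, 7), .RANKS),
    deepest_confident_rank = NA_character_, best_taxon = NA_character_)
  W <- nchar(variant) - k + 1L
  if (W < 1L) return(empty)
  kms <- substring(variant, 1:W, k:(W + k - 1L))
  posting <- lapply(kms, function(km) {
    p <- classifier$index[[km]]
    if (is.null(p)) integer(0) else p
  })
  lens <- lengths(posting)
  flat <- unlist(posting, use.names = FALSE)
  cum <- cumsum(c(0L, lens))
  n_ref <- length(classifier$taxon_ids)
  m <- ceiling(W / 8)
  votes <- withr::with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(W, m, replace = TRUE)
      use <- idx[lens[idx] > 0L]
      if (!length(use)) return(NA_integer_)
      tallies <- tabulate(flat[sequence(lens[use], from = cum[use] + 1L)],
                          nbins = n_ref)
      which.max(tallies)  # ties -> smallest index = smallest taxon_id
    }, integer(1))
  })
  if (all(is.na(votes))) return(empty)
  # winning species: modal vote, ties -> smallest taxon id
  tal <- tabulate(votes[!is.na(votes)], nbins = n_ref)
  win <- which.max(tal)
  win_lin <- classifier$lineage[win, ]
  vote_lin <- classifier$lineage[votes, , drop = FALSE]
  agree <- !is.na(votes)
  conf <- numeric(7)
  for (r in seq_len(7)) {
    agree <- agree & vote_lin[, r] == win_lin[[r]]
    agree[is.na(agree)] <- FALSE
    conf[r] <- sum(agree) / n_bootstrap
  }
  names(conf) <- .RANKS
  deep <- if (conf[1] >= conf_threshold) max(which(conf >= conf_threshold))
          else 0L
  lineage <- stats::setNames(rep(NA_character_, 7), .RANKS)
  if (deep > 0) lineage[seq_len(deep)] <- win_lin[seq_len(deep)]
  list(lineage = lineage, confidence = conf,
       deepest_confident_rank = if (deep > 0) .RANKS[deep] else NA_character_,
       best_taxon = classifier$taxon_ids[win])
}

#' Classify every variant of a variant set
#'
#' @param variants A `variant_set` (or data.frame with `variant_id` and
#'   `sequence`).
#' @param classifier A `kmer_classifier` or `reference_set`.
#' @param n_bootstrap,conf_threshold,seed See [assign_taxonomy()]. Each
#'   variant gets its own derived seed so results do not depend on call
#'   order.
#' @return data.frame: variant_id, the seven rank columns (NA below the
#'   truncation rank), `conf_<rank>` columns, and `deepest_rank`.
#' @export
classify_variants <- function(variants, classifier, n_bootstrap = 100L,
                              conf_threshold = 0.8, seed = 1L) {
  v <- if (inherits(variants, "variant_set")) variants$variants else variants
  if (inherits(classifier, "reference_set")) {
    classifier <- kmer_classifier(classifier)
  }
  rows <- lapply(seq_len(nrow(v)), function(i) {
    a <- assign_taxonomy(v$sequence[i], classifier,
                         n_bootstrap = n_bootstrap,
                         conf_threshold = conf_threshold,
                         seed = seed + i)
    cbind(data.frame(variant_id = v$variant_id[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(a$lineage), stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(as.list(a$confidence)),
                          paste0("conf_", .RANKS)),
          data.frame(deepest_rank = a$deepest_confident_rank,
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Species-level annotation rate
#'
#' @param assignments data.frame from [classify_variants()].
#' @return Fraction of variants whose assignment reaches species level.
#' @export
annotation_rate <- function(assignments) {
  stopifnot(nrow(assignments) > 0)
  mean(!is.na(assignments$species))
}

#' Majority parent map from sub-region variants to full-length variants
#'
#' Each sub-region variant is mapped to the full-length variant contributing
#' the most of its reads (ties -> lexicographically smallest full-length
#' variant id).
#'
#' @param region_records data.frame (read_id, sequence) of the extracted
#'   region sequences per read.
#' @param region_variants `variant_set` built from those records.
#' @param full_records data.frame (read_id, sequence) of the full-length
#'   sequences of the same reads.
#' @param full_variants `variant_set` built from the full-length records.
#' @return Named character vector: region variant_id -> full-length
#'   variant_id.
#' @export
derive_parent_map <- function(region_records, region_variants,
                              full_records, full_variants) {
  rv <- region_variants$variants
  fv <- full_variants$variants
  r_of_read <- stats::setNames(
    rv$variant_id[match(region_records$sequence, rv$sequence)],
    region_records$read_id)
  f_of_read <- stats::setNames(
    fv$variant_id[match(full_records$sequence, fv$sequence)],
    full_records$read_id)
  common <- intersect(names(r_of_read)[!is.na(r_of_read)],
                      names(f_of_read)[!is.na(f_of_read)])
  tab <- table(r_of_read[common], f_of_read[common])
  vapply(rownames(tab), function(r) {
    w <- tab[r, ]
    names(w)[which.max(w)]   # which.max ties -> first = smallest name
  }, character(1))
}

#' Species concordance of a sub-region against full-length assignments
#'
#' A sub-region variant is *eligible* when both it and its parent
#' full-length variant are assigned at species level; it is *concordant*
#' only when the two species labels are identical (a species-level call that
#' contradicts the full-length call does not count, even though it reaches
#' species rank).
#'
#' @param region_assignments data.frame from [classify_variants()] for the
#'   sub-region variants.
#' @param fulllength_assignments Same for the full-length variants.
#' @param parent_map Named vector region variant_id -> full-length
#'   variant_id (see [derive_parent_map()]).
#' @param region Region name carried through to the result.
#' @return List: region, n_species_eligible, n_concordant,
#'   concordant_species (unique species labels).
#' @export
species_concordance <- function(region_assignments, fulllength_assignments,
                                parent_map, region = NA_character_) {
  unmapped <- setdiff(region_assignments$variant_id, names(parent_map))
  if (length(unmapped)) {
    stop("variants without a parent mapping: ",
         paste(unmapped, collapse = ", "))
  }
  fsp <- stats::setNames(fulllength_assignments$species,
                         fulllength_assignments$variant_id)
  rsp <- region_assignments$species
  psp <- fsp[parent_map[region_assignments$variant_id]]
  eligible <- !is.na(rsp) & !is.na(psp)
  concordant <- eligible & rsp == psp
  list(region = region,
       n_species_eligible = sum(eligible),
       n_concordant = sum(concordant),
       concordant_species = sort(unique(rsp[concordant])))
}
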