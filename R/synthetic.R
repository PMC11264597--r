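# Synthetic full-length 16S communities with known ground truth.
#
# Templates follow the real gene's architecture: nine taxon-specific variable
# blocks separated by conserved stretches, with the canonical primer-binding
# sites embedded in the conserved blocks at their natural relative positions
# (338R/341F, 515F/534R and 799F/805R/806R each share one conserved stretch,
# as they do on the E. coli reference coordinates).

# Concrete conserved-block sequences. Each primer listed in default_primers()
# matches its block with zero mismatches (asserted by a unit test).
.CONSERVED <- list(
  C27   = "AGAGTTTGATCCTGGCTCAG",       # 27F site
  C338  = "ACTCCTACGGGAGGCAGCAGT",      # 338R site (0..18), 341F (3..19)
  C515  = "GTGCCAGCAGCCGCGGTAAT",       # 515F (0..18), 534R site (3..19)
  C799  = "AACAGGATTAGATACCCTGGTAGTCC", # 799F (0..18), 805R (4..24), 806R (6..25)
  S12   = "GGCGGACGGGTG",
  S56   = "CTGAGACACGGC",
  S67   = "GCACAAGCGGTG",
  S78   = "GGCTCGTGTCGT",
  S89   = "CGGATTGGAGTC"
)

#' Default synthetic 16S template layout
#'
#' Describes the block structure of the synthetic gene: nine variable blocks
#' (V1-V9) separated by conserved blocks, five of which carry the canonical
#' primer-binding sites. Coordinates are 0-based half-open on the plus
#' strand.
#'
#' @param variable_lengths Named integer vector of variable-block lengths.
#' @return An object of class `template_layout` with elements `blocks` (a
#'   data.frame of name/type/start/length/seq), `primer_sites` (primer name,
#'   start, end, site orientation) and `length`.
#' @export
default_layout <- function(variable_lengths = c(
    V1 = 140L, V2 = 160L, V3 = 140L, V4 = 230L, V5 = 120L,
    V6 = 100L, V7 = 100L, V8 = 110L, V9 = 90L)) {
  stopifnot(setequal(names(variable_lengths), paste0("V", 1:9)))
  vl <- variable_lengths
  c1492 <- revcomp(iupac_realize(default_primers()$`1492R`$sequence))
  spec <- list(
    list("C27",  "conserved", .CONSERVED$C27),
    list("V1",   "variable",  vl[["V1"]]),
    list("S12",  "spacer",    .CONSERVED$S12),
    list("V2",   "variable",  vl[["V2"]]),
    list("C338", "conserved", .CONSERVED$C338),
    list("V3",   "variable",  vl[["V3"]]),
    list("C515", "conserved", .CONSERVED$C515),
    list("V4",   "variable",  vl[["V4"]]),
    list("C799", "conserved", .CONSERVED$C799),
    list("V5",   "variable",  vl[["V5"]]),
    list("S56",  "spacer",    .CONSERVED$S56),
    list("V6",   "variable",  vl[["V6"]]),
    list("S67",  "spacer",    .CONSERVED$S67),
    list("V7",   "variable",  vl[["V7"]]),
    list("S78",  "spacer",    .CONSERVED$S78),
    list("V8",   "variable",  vl[["V8"]]),
    list("S89",  "spacer",    .CONSERVED$S89),
    list("V9",   "variable",  vl[["V9"]]),
    list("C1492","conserved", c1492)
  )
  blocks <- data.frame(
    name   = vapply(spec, `[[`, character(1), 1),
    type   = vapply(spec, `[[`, character(1), 2),
    length = vapply(spec, function(b)
      if (b[[2]] == "variable") as.integer(b[[3]]) else nchar(b[[3]]),
      integer(1)),
    seq    = vapply(spec, function(b)
      if (b[[2]] == "variable") NA_character_ else b[[3]], character(1)),
    stringsAsFactors = FALSE
  )
  blocks$start <- cumsum(c(0L, blocks$length[-nrow(blocks)]))
  bs <- function(bn) blocks$start[blocks$name == bn]
  # primer site coordinates on the plus strand (0-based half-open)
  primer_sites <- data.frame(
    primer = c("27F", "338R", "341F", "515F", "534R",
               "799F", "805R", "806R", "1492R"),
    start  = c(bs("C27"), bs("C338"), bs("C338") + 3L, bs("C515"),
               bs("C515") + 3L, bs("C799"), bs("C799") + 4L,
               bs("C799") + 6L, bs("C1492")),
    len    = c(20L, 19L, 17L, 19L, 17L, 19L, 21L, 20L, 22L),
    stringsAsFactors = FALSE
  )
  primer_sites$end <- primer_sites$start + primer_sites$len
  layout <- structure(
    list(blocks = blocks, primer_sites = primer_sites,
         length = sum(blocks$length)),
    class = "template_layout")
  validate_layout(layout)
  layout
}

#' Validate a template layout
#'
#' Blocks must tile the template contiguously and every primer site must fall
#' inside a conserved block; overlapping blocks or a primer site crossing a
#' variable block are rejected with a coordinate diagnostic.
#'
#' @param layout A `template_layout`.
#' @return The layout, invisibly.
#' @export
validate_layout <- function(layout) {
  b <- layout$blocks
  expected <- cumsum(c(0L, b$length[-nrow(b)]))
  if (!all(b$start == expected)) {
    bad <- which(b$start != expected)[1]
    stop("layout blocks overlap or leave gaps: block '", b$name[bad],
         "' starts at ", b$start[bad], ", expected ", expected[bad])
  }
  cons <- b[b$type != "variable", ]
  for (i in seq_len(nrow(layout$primer_sites))) {
    s <- layout$primer_sites[i, ]
    ok <- any(cons$start <= s$start & s$end <= cons$start + cons$length)
    if (!ok) {
      stop("primer site ", s$primer, " [", s$start, ",", s$end,
           ") overlaps a variable block")
    }
  }
  invisible(layout)
}

# uniform random DNA
.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_chars <- function(ch, pos) {
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  ch
}

#' Build a ground-truthed synthetic 16S reference
#'
#' Generates `n_species` full-length 16S-like reference sequences organised
#' into `n_genera` genera under a 7-rank taxonomy. Species within a genus
#' share the genus backbone and differ at a small set of
#' species-distinguishing substitutions; for a configurable fraction of
#' species those substitutions are confined to the V1-V3 variable blocks, so
#' the V4 slice cannot separate them from their siblings. A subset of genera
#' carries a taxon-linked single-base variant in one primer-binding site.
#'
#' @param n_species,n_genera Community size; `n_species >= n_genera >= 1`.
#'   Species are assigned to genera round-robin.
#' @param layout Template layout, see [default_layout()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @param n_species_snps Substitutions distinguishing a species from its
#'   genus backbone (default 8).
#' @param v13_only_fraction Fraction of non-backbone species whose
#'   distinguishing substitutions are restricted to the V1-V3 blocks
#'   (default 0.5).
#' @param n_site_variant_genera Number of genera carrying a taxon-linked
#'   primer-site variant (default ~10% of genera).
#' @return A `reference_set`: list with `taxa` (data.frame of taxon_id, the
#'   seven ranks kingdom..species, sequence), `layout`, `site_variants`
#'   (ground-truth table of injected primer-site variants) and `seed`.
#' @export
build_reference <- function(n_species, n_genera,
                            layout = default_layout(), seed = 1L,
                            n_species_snps = 8L,
                            v13_only_fraction = 0.5,
                            n_site_variant_genera =
                              max(0L, round(0.1 * n_genera))) {
  stopifnot(n_species >= n_genera, n_genera >= 1,
            n_site_variant_genera <= n_genera)
  validate_layout(layout)
  withr::with_seed(seed, {
    b <- layout$blocks
    vblocks <- which(b$type == "variable")
    v13 <- which(b$type == "variable" & b$name %in% c("V1", "V2", "V3"))
    genus_id <- ((seq_len(n_species) - 1L) %% n_genera) + 1L

    # genus backbones: fresh random variable blocks, shared conserved blocks
    backbones <- lapply(seq_len(n_genera), function(g) {
      blk <- b$seq
      blk[vblocks] <- vapply(b$length[vblocks], .rand_dna, character(1))
      blk
    })

    # taxon-linked primer-site variants: one substitution in one site of the
    # chosen genera, recorded as ground truth for the cataloging stage
    variant_genera <- if (n_site_variant_genera > 0)
      sort(sample(seq_len(n_genera), n_site_variant_genera)) else integer(0)
    sv <- list()
    for (g in variant_genera) {
      si <- sample(nrow(layout$primer_sites), 1)
      site <- layout$primer_sites[si, ]
      off <- sample(site$len, 1)                      # 1-based within site
      gpos <- site$start + off                        # 1-based template pos
      blk_i <- max(which(b$start < gpos))
      ch <- strsplit(backbones[[g]][blk_i], "")[[1]]
      in_blk <- gpos - b$start[blk_i]
      old <- ch[in_blk]
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      ch[in_blk] <- new
      backbones[[g]][blk_i] <- paste(ch, collapse = "")
      prim <- default_primers()[[site$primer]]
      pseq <- if (prim$orientation == "reverse")
        revcomp(prim$sequence) else prim$sequence
      pcode <- substr(pseq, off, off)
      sv[[length(sv) + 1]] <- data.frame(
        genus = sprintf("Genus%02d", g), primer = site$primer,
        site_pos = off, ref_base = old, var_base = new,
        within_degenerate = new %in% IUPAC_CODES[[pcode]],
        stringsAsFactors = FALSE)
    }
    site_variants <- if (length(sv)) do.call(rbind, sv) else
      data.frame(genus = character(0), primer = character(0),
                 site_pos = integer(0), ref_base = character(0),
                 var_base = character(0), within_degenerate = logical(0))

    # species = backbone plus distinguishing substitutions (first species of
    # each genus is the unmodified backbone)
    first_of_genus <- !duplicated(genus_id)
    seqs <- character(n_species)
    v13only <- logical(n_species)
    for (i in seq_len(n_species)) {
      blk <- backbones[[genus_id[i]]]
      if (!first_of_genus[i] && n_species_snps > 0) {
        v13only[i] <- stats::runif(1) < v13_only_fraction
        scope <- if (v13only[i]) v13 else vblocks
        repeat {
          cand <- blk
          lens <- b$length[scope]
          pick <- sample(rep(seq_along(scope), lens), n_species_snps)
          for (j in unique(pick)) {
            ch <- strsplit(cand[scope[j]], "")[[1]]
            ch <- .mutate_chars(ch, sample(length(ch), sum(pick == j)))
            cand[scope[j]] <- paste(ch, collapse = "")
          }
          if (!paste(cand, collapse = "") %in% seqs) break
        }
        blk <- cand
      }
      seqs[i] <- paste(blk, collapse = "")
    }
    stopifnot(!anyDuplicated(seqs))

    g <- genus_id
    taxa <- data.frame(
      taxon_id = sprintf("t%03d", seq_len(n_species)),
      kingdom  = "Bacteria",
      phylum   = sprintf("Phylum%02d", ((g - 1L) %/% 8L) + 1L),
      class    = sprintf("Class%02d",  ((g - 1L) %/% 4L) + 1L),
      order    = sprintf("Order%02d",  ((g - 1L) %/% 2L) + 1L),
      family   = sprintf("Family%02d", g),
      genus    = sprintf("Genus%02d", g),
      species  = sprintf("Genus%02d_sp%03d", g, stats::ave(
        seq_len(n_species), g, FUN = seq_along)),
      sequence = seqs,
      v13_only = v13only,
      stringsAsFactors = FALSE
    )
    stopifnot(!anyDuplicated(taxa$species))
    structure(list(taxa = taxa, layout = layout,
                   site_variants = site_variants, seed = seed),
              class = "reference_set")
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "<reference_set: %d species / %d genera, template %d nt, seed %d>\n",
    nrow(x$taxa), length(unique(x$taxa$genus)), x$layout$length, x$seed))
  invisible(x)
}

#' Reference sequences as a named vector
#' @param ref A `reference_set`.
#' @return Named character vector (names = taxon ids).
#' @export
ref_sequences <- function(ref) {
  stats::setNames(ref$taxa$sequence, ref$taxa$taxon_id)
}

#' Lineage strings for a reference
#' @param ref A `reference_set`.
#' @return Named character vector of semicolon-joined 7-rank lineages.
#' @export
ref_lineages <- function(ref) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  stats::setNames(
    apply(ref$taxa[, ranks], 1, paste, collapse = ";"), ref$taxa$taxon_id)
}

#' Site-specific community abundance profiles
#'
#' Draws one abundance profile per site over the reference species. The four
#' skin-like sites mix a shared Dirichlet "core" (weight `core_weight`) with
#' a site-specific Dirichlet draw over the same skin genera, giving
#' distinguishable but related compositions; the oral-analog site places
#' `oral_mass` of its probability on a disjoint set of genera (the last
#' `oral_genus_fraction` of genera), reproducing its strong divergence from
#' the skin sites.
#'
#' @param ref A `reference_set`.
#' @param sites Site labels; the last one is the oral analog by default.
#' @param oral_site Which label is the oral analog.
#' @param seed Integer seed.
#' @param oral_genus_fraction Fraction of genera reserved for the oral
#'   analog (default 0.25).
#' @param oral_mass Probability mass the oral profile puts on its reserved
#'   genera (default 0.95).
#' @param core_weight Weight of the shared core in skin-site profiles
#'   (default 0.5).
#' @return Named list of `community_profile` objects (`site_label`,
#'   `abundance`: named probability vector over all taxon ids).
#' @export
community_profiles <- function(ref,
                               sites = c("InaS", "CiraS", "PaS", "NaS", "OrE"),
                               oral_site = "OrE", seed = 1L,
                               oral_genus_fraction = 0.25,
                               oral_mass = 0.95, core_weight = 0.5) {
  stopifnot(oral_site %in% sites)
  taxa <- ref$taxa
  genera <- unique(taxa$genus)
  n_oral <- max(1L, round(oral_genus_fraction * length(genera)))
  oral_genera <- utils::tail(genera, n_oral)
  is_oral_taxon <- taxa$genus %in% oral_genera
  nt <- nrow(taxa)
  rdirich <- function(idx) {
    w <- numeric(nt)
    w[idx] <- stats::rgamma(length(idx), shape = 1)
    w / sum(w)
  }
  withr::with_seed(seed, {
    core <- rdirich(which(!is_oral_taxon))
    out <- lapply(sites, function(s) {
      p <- if (s == oral_site) {
        oral_mass * rdirich(which(is_oral_taxon)) + (1 - oral_mass) * core
      } else {
        core_weight * core + (1 - core_weight) * rdirich(which(!is_oral_taxon))
      }
      structure(list(site_label = s,
                     abundance = stats::setNames(p / sum(p), taxa$taxon_id)),
                class = "community_profile")
    })
    stats::setNames(out, sites)
  })
}

#' Sample error-bearing reads from a community profile
#'
#' Draws read templates i.i.d. from the profile and applies independent
#' per-base substitutions. Substitutions falling inside a primer-binding
#' site obey a separate rate and are capped at
#' `primer_site_mismatch_budget` per site, so the number of injected
#' primer-site mismatches is controlled exactly.
#'
#' @param profile A `community_profile`.
#' @param reference The `reference_set` the profile refers to.
#' @param n_reads Number of reads (>= 1).
#' @param substitution_rate Per-base substitution probability outside primer
#'   sites (must be < 0.05).
#' @param site_substitution_rate Per-base rate inside primer sites (defaults
#'   to `substitution_rate`).
#' @param primer_site_mismatch_budget Maximum injected substitutions per
#'   primer site per read (default 4).
#' @param revcomp_prob Probability a read is emitted on the minus strand
#'   (default 0).
#' @param sample_id Prefix for read ids.
#' @param seed Integer seed.
#' @return A `read_set`: list with `reads` (named character vector), `truth`
#'   (read id -> taxon id), `site_mismatches` (reads x primer-sites matrix of
#'   injected counts), `flipped` (logical) and `seed`.
#' @export
sample_reads <- function(profile, reference, n_reads,
                         substitution_rate = 0.001,
                         site_substitution_rate = substitution_rate,
                         primer_site_mismatch_budget = 4L,
                         revcomp_prob = 0, sample_id = "S1", seed = 1L) {
  stopifnot(inherits(profile, "community_profile"), n_reads >= 1,
            substitution_rate >= 0, substitution_rate < 0.05,
            primer_site_mismatch_budget >= 0)
  ab <- profile$abundance
  if (length(ab) == 0 || sum(ab) == 0) stop("empty community profile")
  if (abs(sum(ab) - 1) > 1e-9) stop("profile abundances must sum to 1")
  seqs <- ref_sequences(reference)
  if (!all(names(ab) %in% names(seqs))) {
    stop("profile refers to taxa absent from the reference")
  }
  sites <- reference$layout$primer_sites
  withr::with_seed(seed, {
    taxa <- sample(names(ab), n_reads, replace = TRUE, prob = ab)
    L <- nchar(seqs[[1]])
    rate <- rep(substitution_rate, L)
    for (i in seq_len(nrow(sites))) {
      rate[(sites$start[i] + 1):sites$end[i]] <- site_substitution_rate
    }
    site_mm <- matrix(0L, n_reads, nrow(sites),
                      dimnames = list(NULL, sites$primer))
    reads <- character(n_reads)
    flipped <- stats::runif(n_reads) < revcomp_prob
    for (r in seq_len(n_reads)) {
      ch <- strsplit(seqs[[taxa[r]]], "")[[1]]
      pos <- which(stats::runif(L) < rate)
      for (i in seq_len(nrow(sites))) {
        in_site <- pos[pos > sites$start[i] & pos <= sites$end[i]]
        if (length(in_site) > primer_site_mismatch_budget) {
          keep <- utils::head(in_site, primer_site_mismatch_budget)
          pos <- setdiff(pos, setdiff(in_site, keep))
          in_site <- keep
        }
        site_mm[r, i] <- length(in_site)
      }
      if (length(pos)) ch <- .mutate_chars(ch, pos)
      s <- paste(ch, collapse = "")
      reads[r] <- if (flipped[r]) revcomp(s) else s
    }
    ids <- sprintf("%s_read%05d", sample_id, seq_len(n_reads))
    structure(list(reads = stats::setNames(reads, ids),
                   truth = stats::setNames(taxa, ids),
                   site_mismatches = site_mm, flipped = flipped, seed = seed),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set: %d reads, seed %d>\n", length(x$reads), x$seed))
  invisible(x)
}

#' Generate a complete multi-sample synthetic dataset
#'
#' Convenience wrapper: builds the reference, draws the five site profiles,
#' jitters them per sample and samples reads, yielding the full ground-truth
#' dataset every downstream stage consumes.
#'
#' @param n_species,n_genera Reference size (defaults 120 species, 40
#'   genera).
#' @param samples_per_site Named integer vector of samples per site.
#' @param reads_per_sample Reads drawn per sample.
#' @param substitution_rate Per-base read error rate.
#' @param sample_jitter_shape Gamma shape controlling within-site
#'   compositional variation (larger = tighter; default 20).
#' @param seed Root seed; all stage seeds derive from it.
#' @param ... Passed on to [build_reference()].
#' @return A `synthetic_dataset`: list with `reference`, `profiles`,
#'   `read_sets` (one `read_set` per sample), `metadata` (sample_id, site)
#'   and `seed`.
#' @export
generate_dataset <- function(n_species = 120L, n_genera = 40L,
                             samples_per_site = c(InaS = 10L, CiraS = 10L,
                                                  PaS = 10L, NaS = 7L,
                                                  OrE = 10L),
                             reads_per_sample = 200L,
                             substitution_rate = 0.001,
                             sample_jitter_shape = 20, seed = 1L, ...) {
  ref <- build_reference(n_species, n_genera, seed = seed, ...)
  profiles <- community_profiles(ref, sites = names(samples_per_site),
                                 seed = seed + 1L)
  meta <- data.frame(
    sample_id = unlist(lapply(names(samples_per_site), function(s)
      sprintf("%s%02d", s, seq_len(samples_per_site[[s]])))),
    site = rep(names(samples_per_site), samples_per_site),
    stringsAsFactors = FALSE)
  read_sets <- vector("list", nrow(meta))
  names(read_sets) <- meta$sample_id
  for (i in seq_len(nrow(meta))) {
    prof <- profiles[[meta$site[i]]]
    jit <- withr::with_seed(seed + 100L + i, {
      w <- prof$abundance *
        stats::rgamma(length(prof$abundance), shape = sample_jitter_shape,
                      rate = sample_jitter_shape)
      w / sum(w)
    })
    sprof <- structure(list(site_label = prof$site_label, abundance = jit),
                       class = "community_profile")
    read_sets[[i]] <- sample_reads(
      sprof, ref, n_reads = reads_per_sample,
      substitution_rate = substitution_rate,
      sample_id = meta$sample_id[i], seed = seed + 1000L + i)
  }
  structure(list(reference = ref, profiles = profiles,
                 read_sets = read_sets, metadata = meta, seed = seed),
            class = "synthetic_dataset")
}

#' Ground-truth feature table of a synthetic dataset
#'
#' Tabulates the true source taxa of every read per sample, optionally
#' aggregated to a higher rank.
#'
#' @param ds A `synthetic_dataset`.
#' @param rank `"taxon"` (taxon ids) or one of the seven rank names.
#' @return Features x samples integer matrix.
#' @export
truth_feature_table <- function(ds, rank = "taxon") {
  taxa <- ds$reference$taxa
  lab <- if (rank == "taxon") {
    stats::setNames(taxa$taxon_id, taxa$taxon_id)
  } else {
    stopifnot(rank %in% colnames(taxa))
    stats::setNames(taxa[[rank]], taxa$taxon_id)
  }
  feats <- sort(unique(lab))
  m <- matrix(0L, length(feats), nrow(ds$metadata),
              dimnames = list(feats, ds$metadata$sample_id))
  for (s in ds$metadata$sample_id) {
    tb <- table(lab[ds$read_sets[[s]]$truth])
    m[names(tb), s] <- as.integer(tb)
  }
  m
}

#' True region slice of a reference sequence
#'
#' The sub-region a perfect extraction should return for a given reference
#' taxon: the sequence strictly between the forward-primer site end and the
#' reverse-primer site start of the template layout.
#'
#' @param ref A `reference_set`.
#' @param taxon_id Taxon id.
#' @param region A [region_def].
#' @return Character string.
#' @export
true_region_slice <- function(ref, taxon_id, region) {
  ps <- ref$layout$primer_sites
  f <- ps[ps$primer == region$forward$name, ]
  r <- ps[ps$primer == region$reverse$name, ]
  stopifnot(nrow(f) == 1, nrow(r) == 1)
  seqs <- ref_sequences(ref)
  substr(seqs[[taxon_id]], f$end + 1L, r$start)
}
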