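# End-to-end orchestration: synthetic data -> extraction -> clustering ->
# taxonomy -> diversity -> biomarkers -> primer variation, with every stage
# output written before the next starts and a machine-readable summary.

#' Build and validate a pipeline configuration
#'
#' Aggregates every tunable constant of the pipeline with the conventional
#' defaults: per-primer mismatch budget 4, capture threshold 0.98, OTU
#' identity thresholds 97/98/99%, taxonomy confidence 0.8, LDA-score
#' threshold 4 at Kruskal-Wallis alpha 0.05, and primer-site variant filters
#' of 5 reads / 0.1%.
#'
#' @param out_dir Run directory for stage outputs.
#' @param seed Root seed; each stage derives its own seed from it.
#' @param n_species,n_genera,samples_per_site,reads_per_sample,substitution_rate
#'   Synthetic-data scale (see [generate_dataset()]).
#' @param regions Named list of [region_def]s; must contain `"V1-V9"`.
#' @param max_mm Per-primer mismatch budget.
#' @param capture_threshold Capture-efficiency threshold in (0, 1].
#' @param audit_size Fidelity-audit subset size.
#' @param otu_thresholds Identity thresholds for OTU clustering.
#' @param min_count Dereplication minimum variant count.
#' @param k,n_bootstrap,conf_threshold Classifier parameters.
#' @param lda_threshold,kw_alpha Biomarker screen parameters.
#' @param min_reads,min_frac Primer-site variant filters.
#' @param train_fraction,ntree Site-origin classifier parameters.
#' @param run_classifier Fit the random-forest stage (default TRUE).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            n_species = 120L, n_genera = 40L,
                            samples_per_site = c(InaS = 10L, CiraS = 10L,
                                                 PaS = 10L, NaS = 7L,
                                                 OrE = 10L),
                            reads_per_sample = 200L,
                            substitution_rate = 0.001,
                            regions = NULL, max_mm = 4L,
                            capture_threshold = 0.98, audit_size = 100L,
                            otu_thresholds = c(0.97, 0.98, 0.99),
                            min_count = 1L,
                            k = 8L, n_bootstrap = 100L,
                            conf_threshold = 0.8,
                            lda_threshold = 4, kw_alpha = 0.05,
                            min_reads = 5L, min_frac = 0.001,
                            train_fraction = 0.7, ntree = 500L,
                            run_classifier = TRUE) {
  if (is.null(regions)) regions <- default_regions(max_mm)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_species = n_species, n_genera = n_genera,
              samples_per_site = samples_per_site,
              reads_per_sample = reads_per_sample,
              substitution_rate = substitution_rate,
              regions = regions, max_mm = max_mm,
              capture_threshold = capture_threshold,
              audit_size = audit_size, otu_thresholds = otu_thresholds,
              min_count = min_count, k = k, n_bootstrap = n_bootstrap,
              conf_threshold = conf_threshold,
              lda_threshold = lda_threshold, kw_alpha = kw_alpha,
              min_reads = min_reads, min_frac = min_frac,
              train_fraction = train_fraction, ntree = ntree,
              run_classifier = run_classifier)
  validate_config(cfg)
}

#' Validate a pipeline configuration
#' @param cfg A `pipeline_config` list.
#' @return The config (classed), or an error describing the offending field.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(cfg$capture_threshold > 0 && cfg$capture_threshold <= 1,
      "capture_threshold must lie in (0, 1]")
  chk(all(cfg$otu_thresholds > 0 & cfg$otu_thresholds <= 1),
      "otu_thresholds must lie in (0, 1]")
  chk(cfg$conf_threshold >= 0 && cfg$conf_threshold <= 1,
      "conf_threshold must lie in [0, 1]")
  chk(cfg$kw_alpha > 0 && cfg$kw_alpha < 1, "kw_alpha must lie in (0, 1)")
  chk(cfg$max_mm >= 0, "max_mm must be nonnegative")
  chk(cfg$min_reads >= 1, "min_reads must be >= 1")
  chk(cfg$min_frac >= 0 && cfg$min_frac < 1, "min_frac must lie in [0, 1)")
  chk(cfg$train_fraction > 0 && cfg$train_fraction < 1,
      "train_fraction must lie in (0, 1)")
  chk("V1-V9" %in% names(cfg$regions), "regions must include V1-V9")
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes synthetic-data generation, per-region extraction, dereplication
#' and OTU clustering, taxonomy with the species-concordance rule, diversity
#' and ordination, the biomarker screen plus the site-origin classifier, and
#' primer-binding-site cataloging. Every stage writes its outputs under
#' `cfg$out_dir` before the next stage starts; a run summary is returned and
#' written as `summary.json`.
#'
#' @param cfg A `pipeline_config`.
#' @param quiet Suppress progress messages (default FALSE).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[insilico16S] ", ...)
  summary <- list(seed = cfg$seed)

  say("stage synth")
  ds <- generate_dataset(
    n_species = cfg$n_species, n_genera = cfg$n_genera,
    samples_per_site = cfg$samples_per_site,
    reads_per_sample = cfg$reads_per_sample,
    substitution_rate = cfg$substitution_rate, seed = cfg$seed)
  write_dataset(ds, file.path(cfg$out_dir, "synthetic"))
  reads <- unlist(unname(lapply(ds$read_sets, `[[`, "reads")))
  sample_of_read <- rep(ds$metadata$sample_id,
                        vapply(ds$read_sets, function(r)
                          length(r$reads), integer(1)))
  names(sample_of_read) <- names(reads)
  sites <- stats::setNames(ds$metadata$site, ds$metadata$sample_id)

  say("stage extract/cluster/classify")
  clf <- kmer_classifier(ds$reference, k = cfg$k)
  region_data <- list()
  for (rn in names(cfg$regions)) {
    region <- cfg$regions[[rn]]
    ext <- extract_read_set(reads, region)
    cap <- capture_report(ext, reads, audit_size = cfg$audit_size,
                          seed = cfg$seed + 7L,
                          threshold = cfg$capture_threshold)
    ok <- ext[ext$status == "extracted", ]
    records <- data.frame(read_id = ok$read_id,
                          sample_id = sample_of_read[ok$read_id],
                          sequence = ok$sequence,
                          stringsAsFactors = FALSE)
    vs <- dereplicate(records, min_count = cfg$min_count)
    otus <- lapply(cfg$otu_thresholds, function(th) cluster_otus(vs, th))
    names(otus) <- sprintf("%.2f", cfg$otu_thresholds)
    assign <- classify_variants(vs, clf, n_bootstrap = cfg$n_bootstrap,
                                conf_threshold = cfg$conf_threshold,
                                seed = cfg$seed + 11L)
    safe <- gsub("[^A-Za-z0-9]", "", rn)
    write_fastq(stats::setNames(
      ok$sequence, paste0(ok$read_id, "|", rn)),
      file.path(cfg$out_dir, paste0("region_", safe, ".fastq")))
    write_tsv(cbind(vs$variants, as.data.frame(vs$counts)),
              file.path(cfg$out_dir, paste0("variants_", safe, ".tsv")))
    write_tsv(assign,
              file.path(cfg$out_dir, paste0("taxonomy_", safe, ".tsv")))
    region_data[[rn]] <- list(records = records, variants = vs,
                              otus = otus, assignments = assign,
                              capture = cap)
  }
  write_tsv(do.call(rbind, lapply(region_data, function(r)
    as.data.frame(r$capture[c("region", "n_input", "n_extracted",
                              "efficiency", "passes_threshold",
                              "fidelity_pass_fraction")]))),
    file.path(cfg$out_dir, "capture_report.tsv"))

  say("stage concordance")
  full <- region_data[["V1-V9"]]
  concord <- list()
  for (rn in setdiff(names(cfg$regions), "V1-V9")) {
    rd <- region_data[[rn]]
    pm <- derive_parent_map(rd$records, rd$variants,
                            full$records, full$variants)
    keep <- rd$assignments$variant_id %in% names(pm)
    concord[[rn]] <- species_concordance(
      rd$assignments[keep, ], full$assignments, pm, region = rn)
  }
  write_tsv(do.call(rbind, lapply(concord, function(cc)
    data.frame(region = cc$region,
               n_species_eligible = cc$n_species_eligible,
               n_concordant = cc$n_concordant))),
    file.path(cfg$out_dir, "concordance.tsv"))

  say("stage diversity/biomarkers")
  diversity <- list(); biomarkers <- list(); rf <- list()
  for (rn in names(cfg$regions)) {
    rd <- region_data[[rn]]
    genus_tab <- aggregate_by_rank(rd$variants$counts, rd$assignments,
                                   "genus")
    genus_tab <- genus_tab[, colSums(genus_tab) > 0, drop = FALSE]
    sh <- shannon_by_site(genus_tab, sites)
    D <- bray_curtis_matrix(genus_tab)
    pc <- pcoa(D, n_axes = min(3L, nrow(D) - 1L))
    tr <- upgma(D)
    safe <- gsub("[^A-Za-z0-9]", "", rn)
    write_tsv(data.frame(sample_id = names(sh$shannon),
                         shannon = unname(sh$shannon)),
              file.path(cfg$out_dir, paste0("shannon_", safe, ".tsv")))
    ape::write.tree(tr, file.path(cfg$out_dir,
                                  paste0("upgma_", safe, ".nwk")))
    bm <- lefse_screen(genus_tab, sites,
                       lda_threshold = cfg$lda_threshold,
                       alpha = cfg$kw_alpha)
    write_tsv(bm, file.path(cfg$out_dir, paste0("biomarkers_", safe,
                                                ".tsv")))
    diversity[[rn]] <- list(shannon = sh$shannon, pcoa = pc)
    biomarkers[[rn]] <- bm
    if (cfg$run_classifier) {
      fit <- fit_site_classifier(genus_tab, sites,
                                 train_fraction = cfg$train_fraction,
                                 ntree = cfg$ntree,
                                 seed = cfg$seed + 23L)
      write_tsv(fit$evaluation$per_class,
                file.path(cfg$out_dir, paste0("evaluation_", safe,
                                              ".tsv")))
      rf[[rn]] <- fit
    }
  }

  say("stage primer variation")
  oriented <- vapply(reads, function(s)
    orient_read(s)$sequence, character(1))
  dedup <- dedupe_fulllength(oriented)
  full_v <- full$variants$variants
  lab_of_var <- deepest_labels(full$assignments)
  var_of_read <- full_v$variant_id[match(
    full$records$sequence, full_v$sequence)]
  read_labels <- rep("unclassified", length(reads))
  names(read_labels) <- names(reads)
  got <- !is.na(var_of_read)
  read_labels[full$records$read_id[got]] <-
    lab_of_var[var_of_read[got]]
  primers <- unique(unlist(lapply(cfg$regions, function(r)
    list(r$forward, r$reverse)), recursive = FALSE))
  primers <- primers[!duplicated(vapply(primers, `[[`, character(1),
                                        "name"))]
  pv <- list()
  for (p in primers) {
    cat_p <- suppressWarnings(
      site_catalog(dedup, p, max_mm = cfg$max_mm,
                   min_reads = cfg$min_reads, min_frac = cfg$min_frac))
    v <- cat_p$variants
    v$top_taxa <- vapply(v$sequence, function(s) {
      ta <- taxon_association(cat_p, s, dedup, read_labels)
      paste(utils::head(sprintf("%s(%d)", ta$taxon, ta$count), 3),
            collapse = ";")
    }, character(1))
    pv[[p$name]] <- v
  }
  write_tsv(do.call(rbind, unname(pv)),
            file.path(cfg$out_dir, "primer_variants.tsv"))

  summary$regions <- lapply(region_data, function(rd) {
    list(n_variants = nrow(rd$variants$variants),
         otu_counts = vapply(rd$otus, function(o) nrow(o$otus),
                             integer(1)),
         capture = rd$capture[c("n_input", "n_extracted", "efficiency",
                                "passes_threshold",
                                "fidelity_pass_fraction")])
  })
  summary$concordance <- lapply(concord, function(cc)
    cc[c("n_species_eligible", "n_concordant")])
  summary$shannon <- lapply(diversity, `[[`, "shannon")
  summary$biomarker_hits <- lapply(biomarkers, function(b)
    sum(b$passes))
  if (cfg$run_classifier) {
    summary$classifier_accuracy <- lapply(rf, function(f)
      f$evaluation$overall_accuracy)
  }
  summary$primer_variants <- lapply(pv, nrow)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  say("done")
  invisible(summary)
}
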