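test_that("an exact reference sequence is classified to species with full
           confidence", {
  ref <- small_ref()
  clf <- kmer_classifier(ref)
  a <- assign_taxonomy(ref$taxa$sequence[4], clf, seed = 51)
  expect_equal(a$best_taxon, ref$taxa$taxon_id[4])
  expect_equal(unname(a$lineage["species"]), ref$taxa$species[4])
  expect_equal(unname(a$confidence), rep(1, 7))
  expect_equal(a$deepest_confident_rank, "species")
})

test_that("a variant equidistant between two sibling species stops at
           genus", {
  # two species of one genus differing at two loci; the query carries one
  # allele from each, so bootstrap votes split roughly 50/50
  withr::local_seed(52)
  ref <- build_reference(6, 3, seed = 52, n_species_snps = 2)
  sib <- ref$taxa[ref$taxa$genus == ref$taxa$genus[1], ]
  a <- strsplit(sib$sequence[1], "")[[1]]
  b <- strsplit(sib$sequence[2], "")[[1]]
  diff <- which(a != b)
  expect_gte(length(diff), 2)
  q <- a
  q[diff[1]] <- b[diff[1]]       # first allele from sibling 2
  query <- paste(q, collapse = "")
  clf <- kmer_classifier(ref)
  asg <- assign_taxonomy(query, clf, n_bootstrap = 200, seed = 53)
  expect_gte(unname(asg$confidence["genus"]), 0.8)
  expect_lt(unname(asg$confidence["species"]), 0.8)
  expect_true(is.na(asg$lineage[["species"]]))
  expect_equal(unname(asg$lineage[["genus"]]), sib$genus[1])
  # votes split: neither species dominates overwhelmingly
  expect_gt(unname(asg$confidence["species"]), 0.2)
})

test_that("raising the confidence threshold never deepens an assignment", {
  ref <- small_ref()
  clf <- kmer_classifier(ref)
  withr::local_seed(54)
  q <- mutate_seq(ref$taxa$sequence[2], 30)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  depth <- function(a) {
    if (is.na(a$deepest_confident_rank)) 0
    else match(a$deepest_confident_rank, ranks)
  }
  a08 <- assign_taxonomy(q, clf, conf_threshold = 0.8, seed = 55)
  a10 <- assign_taxonomy(q, clf, conf_threshold = 1.0, seed = 55)
  expect_lte(depth(a10), depth(a08))
  # confidences are non-increasing with depth
  expect_true(all(diff(a08$confidence) <= 1e-12))
})

test_that("sequences shorter than k are unclassified", {
  ref <- small_ref()
  clf <- kmer_classifier(ref)
  a <- assign_taxonomy("ACGTA", clf, seed = 56)
  expect_true(all(is.na(a$lineage)))
  expect_true(is.na(a$deepest_confident_rank))
})

test_that("annotation rate counts species-level assignments", {
  asg <- data.frame(variant_id = sprintf("v%d", 1:10),
                    species = c(rep("x", 8), NA, NA))
  expect_equal(annotation_rate(asg), 0.8)
  expect_equal(annotation_rate(transform(asg, species = "x")), 1.0)
  expect_equal(annotation_rate(transform(asg, species = NA)), 0.0)
})

test_that("the concordance rule only credits agreeing species calls", {
  reg <- data.frame(variant_id = c("r1", "r2", "r3", "r4"),
                    species = c("spA", "spB", NA, "spC"),
                    stringsAsFactors = FALSE)
  full <- data.frame(variant_id = c("f1", "f2", "f3", "f4"),
                     species = c("spA", "spA", "spA", NA),
                     stringsAsFactors = FALSE)
  pm <- c(r1 = "f1", r2 = "f2", r3 = "f3", r4 = "f4")
  cc <- species_concordance(reg, full, pm, region = "V4")
  # r1 concordant; r2 species-level but contradicts parent; r3 not at
  # species; r4's parent lacks a species label
  expect_equal(cc$n_species_eligible, 2)
  expect_equal(cc$n_concordant, 1)
  expect_equal(cc$concordant_species, "spA")
  expect_error(species_concordance(reg, full, pm[-2]), "r2")
})

test_that("majority vote maps region variants to their parents", {
  rr <- data.frame(read_id = c("a", "b", "c", "d"),
                   sequence = c("AAAA", "AAAA", "AAAA", "CCCC"))
  fr <- data.frame(read_id = c("a", "b", "c", "d"),
                   sequence = c("GGGGGGGG", "GGGGGGGG", "TTTTTTTT",
                                "TTTTTTTT"))
  rv <- dereplicate(cbind(rr, sample_id = "s"))
  fv <- dereplicate(cbind(fr, sample_id = "s"))
  pm <- derive_parent_map(rr, rv, fr, fv)
  f_of <- setNames(fv$variants$variant_id, fv$variants$sequence)
  r_of <- setNames(rv$variants$variant_id, rv$variants$sequence)
  expect_equal(unname(pm[r_of["AAAA"]]), unname(f_of["GGGGGGGG"]))
  expect_equal(unname(pm[r_of["CCCC"]]), unname(f_of["TTTTTTTT"]))
})

test_that("species recovery is perfect on clean data and degrades from
           full-length to V4", {
  ref <- build_reference(30, 10, seed = 57, v13_only_fraction = 1)
  rs <- sample_reads(uniform_profile(ref), ref, 400,
                     substitution_rate = 0, seed = 58)
  clf <- kmer_classifier(ref)
  regs <- default_regions()[c("V1-V9", "V1-V3", "V4")]
  out <- lapply(regs, function(reg) {
    ext <- extract_read_set(rs$reads, reg)
    ok <- ext[ext$status == "extracted", ]
    rec <- data.frame(read_id = ok$read_id, sample_id = "s",
                      sequence = ok$sequence)
    vs <- dereplicate(rec)
    list(rec = rec, vs = vs,
         asg = classify_variants(vs, clf, seed = 59))
  })
  full <- out$`V1-V9`
  # full-length recovers the truth for every observed species
  expect_equal(annotation_rate(full$asg), 1.0)
  truth_species <- sort(unique(
    ref$taxa$species[match(rs$truth, ref$taxa$taxon_id)]))
  expect_setequal(full$asg$species, truth_species)
  n_conc <- vapply(c("V1-V3", "V4"), function(rn) {
    pm <- derive_parent_map(out[[rn]]$rec, out[[rn]]$vs,
                            full$rec, full$vs)
    species_concordance(out[[rn]]$asg, full$asg, pm, rn)$n_concordant
  }, numeric(1))
  n_full <- sum(!is.na(full$asg$species))
  expect_gte(n_full, n_conc[["V1-V3"]])
  expect_gte(n_conc[["V1-V3"]], n_conc[["V4"]])
  expect_gt(n_conc[["V1-V3"]], n_conc[["V4"]])
})
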