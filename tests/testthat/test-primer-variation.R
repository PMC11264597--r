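test_that("full-length deduplication conserves counts", {
  r <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  d <- dedupe_fulllength(r)
  expect_equal(nrow(d$uniques), 1)
  expect_equal(d$uniques$count, 3L)
  expect_setequal(d$members[[d$uniques$uid]], c("a", "b", "c"))
  r2 <- c(a = "AAAA", b = "CCCC", c = "GGGG")
  expect_equal(nrow(dedupe_fulllength(r2)$uniques), 3)
  r3 <- c(r, d = "TTTT")
  expect_equal(sum(dedupe_fulllength(r3)$uniques$count), 4)
})

test_that("the site catalog applies the 5-read and 0.1% filters", {
  withr::local_seed(81)
  p <- default_primers()$`341F`
  site <- iupac_realize(p$sequence)
  mk <- function(site_seq, n, tag) {
    body <- plant(rand_dna(300), site_seq, 101)
    setNames(rep(body, n), sprintf("%s_%02d", tag, seq_len(n)))
  }
  varA <- mutate_seq(site, 1, pos = 3)   # planted, only 4 backing reads
  varB <- mutate_seq(site, 1, pos = 9)   # planted, 5 reads and >0.1%
  reads <- c(mk(site, 991, "c"), mk(varA, 4, "a"), mk(varB, 5, "b"))
  cat1 <- site_catalog(dedupe_fulllength(reads), p)
  expect_true(site %in% cat1$variants$sequence)
  expect_false(varA %in% cat1$variants$sequence)   # fewer than five reads
  expect_true(varB %in% cat1$variants$sequence)
  expect_equal(cat1$consensus, site)
  expect_lte(sum(cat1$variants$fraction), 1 + 1e-12)
  expect_true(cat1$variants$is_consensus[cat1$variants$sequence == site])
})

test_that("masking dots consensus-identical positions only", {
  withr::local_seed(82)
  p <- default_primers()$`341F`
  site <- iupac_realize(p$sequence)
  varB <- mutate_seq(site, 1, pos = 9)
  mk <- function(site_seq, n, tag) {
    body <- plant(rand_dna(300), site_seq, 101)
    setNames(rep(body, n), sprintf("%s_%02d", tag, seq_len(n)))
  }
  cat1 <- site_catalog(dedupe_fulllength(c(mk(site, 20, "c"),
                                           mk(varB, 6, "b"))), p)
  cons_row <- cat1$variants[cat1$variants$is_consensus, ]
  expect_equal(cons_row$masked, site)              # consensus shown in full
  var_row <- cat1$variants[!cat1$variants$is_consensus, ]
  expect_equal(nchar(var_row$masked), nchar(p$sequence))
  m <- strsplit(var_row$masked, "")[[1]]
  expect_equal(sum(m != "."), 1)
  expect_equal(which(m != "."), 9L)
})

test_that("bases outside the degenerate expansion are flagged", {
  withr::local_seed(83)
  p515 <- default_primers()$`515F`   # position 4 is Y = C/T
  site <- iupac_realize(p515$sequence)
  stopifnot(substr(p515$sequence, 4, 4) == "Y")
  varO <- site
  substr(varO, 4, 4) <- "A"          # A is outside {C,T}
  mk <- function(site_seq, n, tag) {
    body <- plant(rand_dna(260), site_seq, 51)
    setNames(rep(body, n), sprintf("%s_%02d", tag, seq_len(n)))
  }
  cat1 <- site_catalog(dedupe_fulllength(c(mk(site, 30, "c"),
                                           mk(varO, 8, "o"))), p515)
  v <- cat1$variants[cat1$variants$sequence == varO, ]
  expect_equal(v$outside_degenerate, "4")
  cons <- cat1$variants[cat1$variants$is_consensus, ]
  expect_equal(cons$outside_degenerate, "")
  # within-degeneracy alternative bases are not flagged
  varY <- site
  substr(varY, 4, 4) <- setdiff(c("C", "T"),
                                substr(site, 4, 4))
  cat2 <- site_catalog(dedupe_fulllength(c(mk(site, 30, "c"),
                                           mk(varY, 8, "y"))), p515)
  vy <- cat2$variants[cat2$variants$sequence == varY, ]
  expect_equal(vy$outside_degenerate, "")
})

test_that("a primer missing from most uniques raises the warning flag", {
  withr::local_seed(84)
  p <- default_primers()$`341F`
  site <- iupac_realize(p$sequence)
  with_site <- setNames(plant(rand_dna(300), site, 101), "w1")
  without <- setNames(replicate(5, rand_dna(300)), sprintf("n%d", 1:5))
  expect_warning(cat1 <- site_catalog(dedupe_fulllength(c(with_site,
                                                          without)), p),
                 "located in only")
  expect_true(cat1$low_recovery)
})

test_that("taxon association recovers the planted genus-linked variant", {
  ref <- build_reference(40, 10, seed = 85, n_site_variant_genera = 1)
  sv <- ref$site_variants
  expect_equal(nrow(sv), 1)
  rs <- sample_reads(uniform_profile(ref), ref, 600,
                     substitution_rate = 0, seed = 86)
  dedup <- dedupe_fulllength(rs$reads)
  p <- default_primers()[[sv$primer]]
  cat1 <- site_catalog(dedup, p, min_frac = 0)
  genus_of <- setNames(ref$taxa$genus, ref$taxa$taxon_id)
  labels <- setNames(genus_of[rs$truth], names(rs$truth))
  found <- FALSE
  for (s in cat1$variants$sequence[!cat1$variants$is_consensus]) {
    ta <- taxon_association(cat1, s, dedup, labels)
    if (ta$taxon[1] == sv$genus) found <- TRUE
  }
  expect_true(found)
  # a pure-consensus catalog associates with many genera
  ta_cons <- taxon_association(cat1, cat1$consensus, dedup, labels)
  expect_gt(nrow(ta_cons), 1)
  expect_true(all(diff(ta_cons$count) <= 0))
})

test_that("association ordering is by count then label", {
  reads <- setNames(rep(plant(strrep("A", 100),
                              iupac_realize(default_primers()$`341F`$sequence),
                              41), 10), sprintf("r%02d", 1:10))
  dedup <- dedupe_fulllength(reads)
  cat1 <- site_catalog(dedup, default_primers()$`341F`)
  labels <- setNames(c(rep("GenusX", 6), rep("GenusB", 4)), names(reads))
  ta <- taxon_association(cat1, cat1$consensus, dedup, labels)
  expect_equal(ta$taxon, c("GenusX", "GenusB"))
  expect_equal(ta$count, c(6L, 4L))
  expect_error(taxon_association(cat1, cat1$consensus, dedup,
                                 labels[1:5]), "without a taxonomic label")
})
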