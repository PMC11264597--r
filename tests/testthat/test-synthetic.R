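test_that("every configured primer sits in the template exactly once", {
  ref <- build_reference(1, 1, seed = 3)
  s <- ref_sequences(ref)[[1]]
  expect_equal(nchar(s), ref$layout$length)
  for (p in default_primers()) {
    pat <- if (p$orientation == "reverse") revcomp(p$sequence) else p$sequence
    L <- nchar(pat)
    mm <- vapply(seq_len(nchar(s) - L + 1), function(i)
      count_mismatches(pat, substr(s, i, i + L - 1)), numeric(1))
    expect_equal(sum(mm == 0), 1)
    site <- ref$layout$primer_sites
    site <- site[site$primer == p$name, ]
    expect_equal(which(mm == 0) - 1L, site$start)
  }
})

test_that("reference generation is deterministic and well-formed", {
  a <- build_reference(10, 5, seed = 7)
  b <- build_reference(10, 5, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, build_reference(10, 5, seed = 8)))
  expect_false(anyDuplicated(a$taxa$species) > 0)
  expect_false(anyDuplicated(a$taxa$sequence) > 0)
  expect_true(all(nchar(a$taxa$sequence) >= 1200 &
                    nchar(a$taxa$sequence) <= 1650))
  expect_equal(length(unique(a$taxa$genus)), 5)
  expect_error(build_reference(3, 5, seed = 1))
})

test_that("V1-V3-only species pairs are invisible to the V4 slice", {
  ref <- build_reference(10, 5, seed = 21, v13_only_fraction = 1)
  v4 <- default_regions()$`V4`
  sib <- ref$taxa[ref$taxa$genus == ref$taxa$genus[1], ]
  expect_gte(nrow(sib), 2)
  s4a <- true_region_slice(ref, sib$taxon_id[1], v4)
  s4b <- true_region_slice(ref, sib$taxon_id[2], v4)
  expect_equal(pairwise_identity(s4a, s4b), 1.0)
  expect_lt(pairwise_identity(sib$sequence[1], sib$sequence[2]), 1.0)
})

test_that("malformed layouts are rejected with coordinate diagnostics", {
  lay <- default_layout()
  lay$blocks$start[3] <- lay$blocks$start[3] - 5L   # overlap previous block
  expect_error(validate_layout(lay), "overlap")
  lay2 <- default_layout()
  lay2$primer_sites$start[1] <- 30L                 # push 27F into V1
  lay2$primer_sites$end[1] <- 50L
  expect_error(validate_layout(lay2), "variable block")
})

test_that("error-free reads equal their source references", {
  ref <- small_ref()
  rs <- sample_reads(uniform_profile(ref), ref, 50,
                     substitution_rate = 0, seed = 5)
  seqs <- ref_sequences(ref)
  expect_true(all(rs$reads == seqs[rs$truth]))
  expect_true(all(rs$site_mismatches == 0))
})

test_that("a zero mismatch budget keeps all primer sites at consensus", {
  ref <- small_ref()
  rs <- sample_reads(uniform_profile(ref), ref, 40,
                     substitution_rate = 0.01,
                     site_substitution_rate = 0.2,
                     primer_site_mismatch_budget = 0, seed = 6)
  expect_true(all(rs$site_mismatches == 0))
  sites <- ref$layout$primer_sites
  seqs <- ref_sequences(ref)
  for (r in seq_along(rs$reads)) {
    src <- seqs[[rs$truth[r]]]
    for (i in seq_len(nrow(sites))) {
      expect_identical(
        substr(rs$reads[[r]], sites$start[i] + 1, sites$end[i]),
        substr(src, sites$start[i] + 1, sites$end[i]))
    }
  }
})

test_that("taxon draws follow the profile within binomial noise", {
  ref <- small_ref()
  four <- ref$taxa$taxon_id[1:4]
  prof <- structure(list(site_label = "x",
                         abundance = stats::setNames(rep(0.25, 4), four)),
                    class = "community_profile")
  rs <- sample_reads(prof, ref, 1000, substitution_rate = 0, seed = 9)
  tab <- table(factor(rs$truth, levels = four))
  sd <- sqrt(1000 * 0.25 * 0.75)   # ~13.7
  expect_true(all(abs(tab - 250) <= 5 * sd))
  expect_equal(length(rs$truth), 1000)
  expect_true(all(rs$truth %in% ref$taxa$taxon_id))
  expect_false(anyDuplicated(names(rs$reads)) > 0)
})

test_that("read sampling rejects degenerate inputs", {
  ref <- small_ref()
  empty <- structure(list(site_label = "x", abundance = numeric(0)),
                     class = "community_profile")
  expect_error(sample_reads(empty, ref, 10, seed = 1), "empty")
  expect_error(sample_reads(uniform_profile(ref), ref, 10,
                            substitution_rate = 0.2, seed = 1))
})

test_that("site profiles are proper and the oral analog stands apart", {
  ref <- build_reference(120, 40, seed = 1)
  pr <- community_profiles(ref, seed = 2)
  for (p in pr) {
    expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
    expect_true(all(names(p$abundance) %in% ref$taxa$taxon_id))
  }
  ab <- sapply(pr, function(p) p$abundance)
  labs <- colnames(ab)
  D <- matrix(0, 5, 5, dimnames = list(labs, labs))
  for (i in 1:5) for (j in 1:5) D[i, j] <- bray_curtis(ab[, i], ab[, j])
  skin <- setdiff(labs, "OrE")
  expect_gt(min(D["OrE", skin]), max(D[skin, skin]))
  # top-10 genus overlap between the oral analog and each skin site < 20%
  genus_of <- stats::setNames(ref$taxa$genus, ref$taxa$taxon_id)
  top10 <- function(p) {
    g <- tapply(p$abundance, genus_of[names(p$abundance)], sum)
    names(sort(g, decreasing = TRUE))[1:10]
  }
  oral <- top10(pr$OrE)
  for (s in skin) {
    expect_lt(length(intersect(oral, top10(pr[[s]]))) / 10, 0.2)
  }
})

test_that("dataset writing is byte-identical under a fixed seed", {
  ds1 <- generate_dataset(n_species = 8, n_genera = 4,
                          samples_per_site = c(A = 1, B = 1, OrE = 1),
                          reads_per_sample = 10, seed = 42)
  ds2 <- generate_dataset(n_species = 8, n_genera = 4,
                          samples_per_site = c(A = 1, B = 1, OrE = 1),
                          reads_per_sample = 10, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(ds1, d1)
  write_dataset(ds2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # round trip through the declared readers
  reads <- read_sequences(file.path(d1, "reads.fastq"))
  expect_identical(reads,
                   unlist(unname(lapply(ds1$read_sets, `[[`, "reads"))))
  tax <- read_tsv(file.path(d1, "taxonomy.tsv"))
  expect_equal(nrow(tax), 8)
  expect_true(all(lengths(strsplit(tax$lineage, ";")) == 7))
})
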