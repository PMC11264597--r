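test_that("planted primers are located with the fewest-mismatch rule", {
  withr::local_seed(31)
  p27 <- default_primers()$`27F`
  site <- iupac_realize(p27$sequence)
  s <- plant(rand_dna(400), site, 11)        # 0-based start 10
  h <- find_primer(s, p27, 4)
  expect_equal(h$start, 10)
  expect_equal(h$mismatches, 0)
  # five substitutions exceed the four-mismatch tolerance
  s5 <- plant(rand_dna(400), mutate_seq(site, 5), 11)
  expect_null(find_primer(s5, p27, 4))
  # but a raised budget finds it again
  expect_false(is.null(find_primer(s5, p27, 5)))
})

test_that("ties break leftmost for forward and rightmost for reverse", {
  withr::local_seed(32)
  p27 <- default_primers()$`27F`
  site <- iupac_realize(p27$sequence)
  s <- plant(plant(rand_dna(2000), mutate_seq(site, 2), 901), site, 51)
  h <- find_primer(s, p27, 4)
  expect_equal(h$start, 50)                  # leftmost of best (0 mm)
  expect_equal(h$mismatches, 0)
  r338 <- default_primers()$`338R`
  rsite <- revcomp(iupac_realize(r338$sequence))
  s2 <- plant(plant(rand_dna(1200), rsite, 101), rsite, 901)
  h2 <- find_primer(s2, r338, 4)
  expect_equal(h2$start, 900)                # rightmost of equal-best
})

test_that("find_primer agrees with the exhaustive-window oracle", {
  withr::local_seed(33)
  prim <- default_primers()
  for (i in 1:100) {
    p <- prim[[sample(length(prim), 1)]]
    s <- rand_dna(sample(60:200, 1))
    if (runif(1) < 0.5) {
      pat <- if (p$orientation == "reverse") revcomp(p$sequence)
             else p$sequence
      s <- plant(s, mutate_seq(iupac_realize(pat), sample(0:5, 1)),
                 sample(nchar(s) - nchar(pat) + 1, 1))
    }
    mm <- sample(0:5, 1)
    got <- find_primer(s, p, mm)
    want <- oracle_scan(s, p, mm)
    expect_identical(got[c("start", "mismatches")],
                     want[c("start", "mismatches")])
  }
})

test_that("reads orient by the anchor primer and orientation is stable", {
  ref <- small_ref()
  s <- ref_sequences(ref)[[1]]
  o <- orient_read(s)
  expect_false(o$strand_flipped)
  expect_identical(o$sequence, s)
  o2 <- orient_read(revcomp(s))
  expect_true(o2$strand_flipped)
  expect_identical(o2$sequence, s)
  # no anchor on either strand: tie resolves to unflipped
  withr::local_seed(34)
  junk <- rand_dna(60)
  o3 <- orient_read(junk)
  expect_false(o3$strand_flipped)
  expect_identical(o3$sequence, junk)
})

test_that("extraction returns the exact region slice on clean reads", {
  ref <- small_ref()
  regs <- default_regions()
  for (i in c(1, 5)) {
    s <- ref$taxa$sequence[i]
    for (rn in names(regs)) {
      er <- extract_region(s, regs[[rn]])
      expect_equal(er$status, "extracted")
      expect_identical(er$sequence,
                       true_region_slice(ref, ref$taxa$taxon_id[i],
                                         regs[[rn]]))
    }
  }
})

test_that("failure modes are encoded as statuses", {
  ref <- small_ref()
  s <- ref_sequences(ref)[[1]]
  v4 <- default_regions()$`V4`
  sites <- ref$layout$primer_sites
  zap <- function(seq, pname) {
    st <- sites[sites$primer == pname, ]
    plant(seq, strrep("A", st$len), st$start + 1)
  }
  expect_equal(extract_region(zap(s, "515F"), v4, orient = FALSE)$status,
               "fwd_missing")
  expect_equal(extract_region(zap(s, "806R"), v4, orient = FALSE)$status,
               "rev_missing")
  expect_equal(
    extract_region(zap(zap(s, "515F"), "806R"), v4, orient = FALSE)$status,
    "both_missing")
  # reverse site planted upstream of the forward site
  withr::local_seed(35)
  fsite <- iupac_realize(v4$forward$sequence)
  rsite <- revcomp(iupac_realize(v4$reverse$sequence))
  bad <- plant(plant(rand_dna(300), fsite, 201), rsite, 50)
  expect_equal(extract_region(bad, v4, orient = FALSE)$status,
               "malformed_order")
})

test_that("extracted sequences are substrings and strand-invariant", {
  ref <- small_ref()
  rs <- sample_reads(uniform_profile(ref), ref, 100,
                     substitution_rate = 0.005,
                     site_substitution_rate = 0.05, seed = 36)
  v34 <- default_regions()$`V3-V4`
  ext <- extract_read_set(rs$reads, v34)
  ok <- ext[ext$status == "extracted", ]
  expect_gt(nrow(ok), 0)
  for (i in seq_len(nrow(ok))) {
    expect_true(grepl(ok$sequence[i], rs$reads[[ok$read_id[i]]],
                      fixed = TRUE))
  }
  flipped <- vapply(rs$reads, revcomp, character(1))
  ext2 <- extract_read_set(flipped, v34)
  expect_identical(ext$status, ext2$status)
  expect_identical(ext$sequence, ext2$sequence)
})

test_that("raising the mismatch budget never loses reads", {
  ref <- small_ref()
  rs <- sample_reads(uniform_profile(ref), ref, 80,
                     substitution_rate = 0.005,
                     site_substitution_rate = 0.08, seed = 37)
  p <- default_primers()
  counts <- vapply(0:4, function(mm) {
    reg <- region_def("V3-V4", p$`341F`, p$`805R`, mm)
    sum(extract_read_set(rs$reads, reg)$status == "extracted")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("region extractions nest according to the primer coordinates", {
  ref <- small_ref()
  regs <- default_regions()
  s <- ref_sequences(ref)[[3]]
  e <- lapply(regs, function(r) extract_region(s, r)$sequence)
  expect_true(grepl(e$`V1-V2`, e$`V1-V3`, fixed = TRUE))
  expect_true(grepl(e$`V1-V3`, e$`V1-V9`, fixed = TRUE))
  expect_true(grepl(e$`V3-V4`, e$`V1-V9`, fixed = TRUE))
  expect_true(grepl(e$`V5-V9`, e$`V1-V9`, fixed = TRUE))
  # the V4 amplicon overhangs the V3-V4 amplicon by the distance between
  # the 806R and 805R binding sites (2 nt on these canonical primers)
  ps <- ref$layout$primer_sites
  over <- ps$start[ps$primer == "806R"] - ps$start[ps$primer == "805R"]
  expect_true(grepl(substr(e$`V4`, 1, nchar(e$`V4`) - over), e$`V3-V4`,
                    fixed = TRUE))
})

test_that("capture reports apply the 98% threshold and audit fidelity", {
  ref <- small_ref()
  rs <- sample_reads(uniform_profile(ref), ref, 100,
                     substitution_rate = 0, seed = 38)
  v4 <- default_regions()$`V4`
  ext <- extract_read_set(rs$reads, v4)
  fail <- function(ext, k) {
    ext$status[seq_len(k)] <- "fwd_missing"
    ext$sequence[seq_len(k)] <- NA_character_
    ext
  }
  r99 <- capture_report(fail(ext, 1), rs$reads, seed = 1)
  expect_equal(r99$efficiency, 0.99)
  expect_true(r99$passes_threshold)
  r97 <- capture_report(fail(ext, 3), rs$reads, seed = 1)
  expect_equal(r97$efficiency, 0.97)
  expect_false(r97$passes_threshold)
  expect_equal(r99$fidelity_pass_fraction, 1.0)
  mixed <- rbind(ext, transform(ext[1, ], region = "V1-V3"))
  expect_error(capture_report(mixed, rs$reads, seed = 1), "single region")
})
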