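# Independent oracles and shared fixtures. The oracles deliberately avoid
# the package's compiled code paths: the primer-scan oracle enumerates every
# window through count_mismatches(), and the alignment oracle is a plain-R
# dynamic program with its own traceback-free bookkeeping.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant `what` into `seq` at 1-based position `at` (overwriting)
plant <- function(seq, what, at) {
  paste0(substr(seq, 1, at - 1), what,
         substr(seq, at + nchar(what), nchar(seq)))
}

# mutate `n` distinct positions of a sequence (1-based positions optional)
mutate_seq <- function(seq, n, pos = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(pos)) pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Exhaustive-window primer scan: fewest mismatches <= max_mm, ties to the
# leftmost (forward) or rightmost (reverse) window. Returns NULL or
# list(start (0-based), mismatches).
oracle_scan <- function(seq, primer, max_mm) {
  pat <- if (primer$orientation == "reverse") revcomp(primer$sequence)
         else primer$sequence
  L <- nchar(pat)
  n <- nchar(seq)
  if (n < L) return(NULL)
  mm <- vapply(seq_len(n - L + 1), function(i)
    count_mismatches(pat, substr(seq, i, i + L - 1)), numeric(1))
  best <- min(mm)
  if (best > max_mm) return(NULL)
  at <- if (primer$orientation == "forward") which(mm == best)[1]
        else max(which(mm == best))
  list(start = at - 1L, mismatches = as.integer(best))
}

# Plain-R overlap alignment (free terminal gaps, match +1 / mismatch -1 /
# gap -2). Cell objective is lexicographic (score, matches, -columns), the
# same optimum definition the package uses, computed independently.
oracle_overlap_identity <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  S <- matrix(0, n + 1, m + 1)
  M <- matrix(0, n + 1, m + 1)
  C <- matrix(0, n + 1, m + 1)
  gt <- function(s1, m1, c1, s2, m2, c2) {
    s1 > s2 || (s1 == s2 && (m1 > m2 || (m1 == m2 && c1 < c2)))
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      eq <- ac[i - 1] == bc[j - 1]
      s <- S[i - 1, j - 1] + if (eq) 1 else -1
      mm <- M[i - 1, j - 1] + eq
      cc <- C[i - 1, j - 1] + 1
      if (gt(S[i - 1, j] - 2, M[i - 1, j], C[i - 1, j] + 1, s, mm, cc)) {
        s <- S[i - 1, j] - 2; mm <- M[i - 1, j]; cc <- C[i - 1, j] + 1
      }
      if (gt(S[i, j - 1] - 2, M[i, j - 1], C[i, j - 1] + 1, s, mm, cc)) {
        s <- S[i, j - 1] - 2; mm <- M[i, j - 1]; cc <- C[i, j - 1] + 1
      }
      S[i, j] <- s; M[i, j] <- mm; C[i, j] <- cc
    }
  }
  bs <- S[n + 1, m + 1]; bm <- M[n + 1, m + 1]; bc2 <- C[n + 1, m + 1]
  for (j in 1:(m + 1)) {
    if (gt(S[n + 1, j], M[n + 1, j], C[n + 1, j], bs, bm, bc2)) {
      bs <- S[n + 1, j]; bm <- M[n + 1, j]; bc2 <- C[n + 1, j]
    }
  }
  for (i in 1:(n + 1)) {
    if (gt(S[i, m + 1], M[i, m + 1], C[i, m + 1], bs, bm, bc2)) {
      bs <- S[i, m + 1]; bm <- M[i, m + 1]; bc2 <- C[i, m + 1]
    }
  }
  if (bc2 == 0) 0 else bm / bc2
}

# small shared reference, built once per test run
small_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_reference(10, 5, seed = 7)
    cache
  }
})

# a uniform community profile over all taxa of a reference
uniform_profile <- function(ref, label = "pool") {
  n <- nrow(ref$taxa)
  structure(list(site_label = label,
                 abundance = stats::setNames(rep(1 / n, n),
                                             ref$taxa$taxon_id)),
            class = "community_profile")
}
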