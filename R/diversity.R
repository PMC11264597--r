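# Alpha/beta diversity and sample ordination: Shannon index, Bray-Curtis
# distances on relative abundances, principal-coordinate analysis and UPGMA.

#' Shannon diversity index
#'
#' `H = -sum p_i log(p_i)` over the nonzero proportions of a count vector.
#' Base-2 logarithm by default (bits), configurable.
#'
#' @param counts Nonnegative vector with positive sum.
#' @param base Logarithm base (default 2).
#' @return Nonnegative scalar.
#' @export
shannon <- function(counts, base = 2) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) <= 0) stop("all-zero count vector")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`, in `[0, 1]`.
#'
#' @param x,y Equal-length nonnegative vectors with positive sums.
#' @return Scalar in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  stopifnot(sum(x) > 0, sum(y) > 0)
  sum(abs(x - y)) / sum(x + y)
}

#' Per-sample relative abundances
#'
#' @param table Features x samples count matrix.
#' @return Matrix with each column scaled to sum 1.
#' @export
relative_abundance <- function(table) {
  cs <- colSums(table)
  stopifnot(all(cs > 0))
  sweep(table, 2, cs, "/")
}

#' Bray-Curtis distance matrix over samples
#'
#' Computes all pairwise Bray-Curtis distances between the samples (columns)
#' of a feature table. Counts are converted to relative abundances first so
#' unequal sequencing depths do not masquerade as community differences.
#'
#' @param table Features x samples count matrix.
#' @param relative Normalise columns to relative abundance first (default
#'   TRUE).
#' @return Symmetric zero-diagonal matrix with sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(table, relative = TRUE) {
  if (relative) table <- relative_abundance(table)
  d <- as.matrix(vegan::vegdist(t(table), method = "bray"))
  diag(d) <- 0
  d
}

.check_distance_matrix <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix has a nonzero diagonal")
  invisible(D)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: double-centering of `-D^2/2`, then
#' eigendecomposition. Axes are ordered by decreasing eigenvalue; negative
#' eigenvalues are clamped to zero for the proportion-explained
#' denominator. Sign convention: each axis is flipped so its
#' largest-magnitude coordinate is positive.
#'
#' @param D Symmetric zero-diagonal distance matrix.
#' @param n_axes Number of axes to return (default `n - 1`).
#' @return List: `coordinates` (samples x axes), `eigenvalues`,
#'   `proportion_explained`.
#' @export
pcoa <- function(D, n_axes = nrow(D) - 1L) {
  .check_distance_matrix(D)
  n <- nrow(D)
  stopifnot(n_axes <= n - 1L, n_axes >= 1L)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values[seq_len(n_axes)]
  coords <- e$vectors[, seq_len(n_axes), drop = FALSE] %*%
    diag(sqrt(pmax(ev, 0)), n_axes)
  for (a in seq_len(n_axes)) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  dimnames(coords) <- list(rownames(D), paste0("PCo", seq_len(n_axes)))
  pos <- pmax(e$values, 0)
  list(coordinates = coords, eigenvalues = ev,
       proportion_explained = pmax(ev, 0) / sum(pos))
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering (UPGMA): the closest pair of
#' groups is merged iteratively and inter-group distances are size-weighted
#' means. Node height is the merge distance divided by two, so the tree is
#' ultrametric.
#'
#' @param D Symmetric zero-diagonal distance matrix with sample ids as
#'   dimnames.
#' @return An [ape::as.phylo()] tree with branch lengths (class `phylo`).
#' @export
upgma <- function(D) {
  .check_distance_matrix(D)
  stopifnot(nrow(D) >= 2)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)
}

#' Leaf-to-root depths of an ultrametric tree
#'
#' @param tree A `phylo` tree.
#' @return Named vector of root-to-tip path lengths, one per tip.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Welch t-tests of Shannon diversity between sites
#'
#' Computes the per-sample Shannon index of a feature table and compares
#' every pair of site groups with a two-sided Welch two-sample t-test.
#'
#' @param table Features x samples count matrix.
#' @param sites Named character vector sample_id -> site label.
#' @param base Logarithm base for the Shannon index.
#' @return List: `shannon` (named per-sample values), `tests` (data.frame
#'   site_a, site_b, t, p).
#' @export
shannon_by_site <- function(table, sites, base = 2) {
  stopifnot(all(colnames(table) %in% names(sites)))
  h <- apply(table, 2, shannon, base = base)
  grp <- sites[colnames(table)]
  labs <- sort(unique(grp))
  pairs <- utils::combn(labs, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- h[grp == pairs[1, i]]
    b <- h[grp == pairs[2, i]]
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(site_a = pairs[1, i], site_b = pairs[2, i],
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(shannon = h, tests = tests)
}

#' Aggregate a variant feature table to a taxonomic rank
#'
#' Sums variant counts by their assigned label at the requested rank;
#' variants unassigned at that rank are pooled into `"unassigned"`.
#'
#' @param counts Variants x samples count matrix (rownames = variant ids).
#' @param assignments data.frame from [classify_variants()].
#' @param rank One of the seven rank names (default `"genus"`).
#' @return Labels x samples count matrix.
#' @export
aggregate_by_rank <- function(counts, assignments, rank = "genus") {
  stopifnot(rank %in% .RANKS)
  lab <- assignments[[rank]][match(rownames(counts),
                                   assignments$variant_id)]
  lab[is.na(lab)] <- "unassigned"
  m <- rowsum(counts, group = lab)
  m[order(rownames(m)), , drop = FALSE]
}
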