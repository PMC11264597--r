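# Biomarker screening in the LEfSe spirit (Kruskal-Wallis screen plus a
# log10 effect-size score thresholded at 4) and evaluation of a site-origin
# classifier (stratified split, per-class precision/recall/F1, overall
# accuracy, importance ranking).

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on `g - 1`
#' degrees of freedom.
#'
#' @param values Numeric vector of per-sample values.
#' @param groups Group labels, >= 2 distinct, each non-empty.
#' @return List `(H, p)`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    stop("kruskal_wallis needs at least two groups")
  }
  if (length(unique(values)) == 1) {
    # all observations tied: no rank variation, H = 0 by convention
    return(list(H = 0, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' One-vs-rest LDA-style effect size
#'
#' A reproducible surrogate for the LEfSe effect size: with abundances
#' scaled to parts-per-million, the score of group `g` is
#' `log10(max(|mean_g - mean_rest|, 1))`. The enriched label is the group
#' with the largest mean.
#'
#' @param values Nonnegative per-sample abundances already scaled so each
#'   sample totals 1e6 across features.
#' @param groups Group labels.
#' @return List: `scores` (named per-group), `lda_score` (score of the
#'   enriched group), `enriched` (label).
#' @export
lda_effect_size <- function(values, groups) {
  stopifnot(all(values >= 0))
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  means <- vapply(labs, function(g) mean(values[groups == g]), numeric(1))
  scores <- vapply(labs, function(g) {
    rest <- mean(values[groups != g])
    log10(max(abs(means[[g]] - rest), 1))
  }, numeric(1))
  enriched <- labs[which.max(means)]
  list(scores = scores, lda_score = unname(scores[enriched]),
       enriched = enriched)
}

#' LEfSe-style biomarker screen
#'
#' Scales each sample to one million, then for every feature runs the
#' Kruskal-Wallis test across sites and computes the one-vs-rest effect
#' size. A feature passes when `kw_p < alpha` and the effect size of its
#' enriched site reaches `lda_threshold`.
#'
#' @param table Features x samples count (or abundance) matrix.
#' @param sites Named vector sample_id -> site label.
#' @param lda_threshold Effect-size threshold (default 4).
#' @param alpha Kruskal-Wallis significance level (default 0.05), applied to
#'   raw p-values as is conventional for this screen.
#' @return data.frame: feature, site, kw_p, lda_score, passes.
#' @export
lefse_screen <- function(table, sites, lda_threshold = 4, alpha = 0.05) {
  stopifnot(all(colnames(table) %in% names(sites)))
  ppm <- relative_abundance(table) * 1e6
  grp <- sites[colnames(table)]
  rows <- lapply(rownames(ppm), function(f) {
    v <- ppm[f, ]
    kw <- kruskal_wallis(v, grp)
    ef <- lda_effect_size(v, grp)
    data.frame(feature = f, site = ef$enriched, kw_p = kw$p,
               lda_score = ef$lda_score,
               passes = kw$p < alpha && ef$lda_score >= lda_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' F1 score from precision and recall (percent scale)
#'
#' Harmonic mean `2PR/(P+R)` rounded to two decimals; 0 by convention when
#' both inputs are 0.
#'
#' @param precision,recall Percentages in `[0, 100]`.
#' @return Percentage rounded to 2 decimals.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 100, recall >= 0, recall <= 100)
  if (precision + recall == 0) return(0)
  round(2 * precision * recall / (precision + recall), 2)
}

#' Evaluate a site-origin classifier
#'
#' Per-class precision, recall and F1 plus overall accuracy, all on the
#' percent scale rounded to two decimals, from the truth/prediction label
#' vectors. Classes never seen in truth have precision computed with
#' `TP = 0`.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return List: `confusion` (truth x predicted counts over the union of
#'   classes), `per_class` (data.frame class, precision, recall, f1),
#'   `overall_accuracy`.
#' @export
evaluate_classifier <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 1)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- sort(union(truth, predicted))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    data.frame(class = cl, precision = round(p, 2), recall = round(r, 2),
               f1 = f1_score(round(p, 2), round(r, 2)),
               stringsAsFactors = FALSE)
  }))
  list(confusion = cm, per_class = per_class,
       overall_accuracy = round(100 * sum(diag(cm)) / length(truth), 2))
}

#' Stratified train/test split over sites
#'
#' Allocates samples to the training set per site proportionally
#' (`n - floor((1 - train_fraction) * n)` per site, i.e. remainders go to
#' train), deterministically for a given seed.
#'
#' @param sites Named vector sample_id -> site label; every site needs >= 2
#'   samples.
#' @param train_fraction In (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return List `(train, test)` of sample ids.
#' @export
stratified_split <- function(sites, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  tab <- table(sites)
  if (any(tab < 2)) {
    stop("sites with a single sample cannot be split: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  withr::with_seed(seed, {
    train <- character(0)
    for (s in sort(unique(sites))) {
      ids <- names(sites)[sites == s]
      n_test <- floor((1 - train_fraction) * length(ids))
      train <- c(train, sample(ids, length(ids) - n_test))
    }
    list(train = sort(train), test = sort(setdiff(names(sites), train)))
  })
}

#' Rank features by importance
#'
#' @param importances Named numeric vector (feature -> importance).
#' @param n_top Number of features to keep (default 30).
#' @return Character vector of feature names, descending importance, ties
#'   broken lexicographically.
#' @export
rank_importance <- function(importances, n_top = 30L) {
  stopifnot(n_top >= 1)
  ord <- order(-importances, names(importances))
  utils::head(names(importances)[ord], n_top)
}

#' Fit and evaluate a random-forest site-origin classifier
#'
#' Wires an off-the-shelf random forest (500 trees, seeded) into the owned
#' evaluation logic: stratified split, per-class metrics and mean decrease
#' Gini importance ranking.
#'
#' @param table Features x samples count matrix.
#' @param sites Named vector sample_id -> site label.
#' @param train_fraction Passed to [stratified_split()].
#' @param ntree Number of trees (default 500).
#' @param n_top Importance list length (default 30).
#' @param seed Integer seed (drives both the split and the forest).
#' @return List: `evaluation` (from [evaluate_classifier()] on the held-out
#'   set), `top_features`, `importance` (full named vector), `split`.
#' @export
fit_site_classifier <- function(table, sites, train_fraction = 0.7,
                                ntree = 500L, n_top = 30L, seed = 1L) {
  rel <- relative_abundance(table)
  x <- t(rel)
  colnames(x) <- make.names(colnames(x))
  sp <- stratified_split(sites, train_fraction, seed = seed)
  ytr <- factor(sites[sp$train])
  fit <- withr::with_seed(seed, randomForest::randomForest(
    x = x[sp$train, , drop = FALSE], y = ytr, ntree = ntree,
    importance = FALSE))
  pred <- as.character(predict(fit, x[sp$test, , drop = FALSE]))
  imp <- fit$importance[, "MeanDecreaseGini"]
  list(evaluation = evaluate_classifier(sites[sp$test], pred),
       top_features = rank_importance(imp, n_top),
       importance = imp, split = sp)
}

#' Bundled reference classifier metrics
#'
#' Published per-site precision/recall/F1 percentages (with overall
#' accuracies) of a random-forest site-origin classifier for each 16S
#' region, used to validate the F1 arithmetic of the evaluation stage.
#'
#' @return data.frame: region, site, precision, recall, f1,
#'   overall_accuracy.
#' @export
rf_reference_metrics <- function() {
  utils::read.delim(
    system.file("extdata", "rf_reference_metrics.tsv",
                package = "insilico16S"),
    stringsAsFactors = FALSE, check.names = FALSE)
}
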