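#' Recompute a PC loading on the selected probes only
#'
#' Restricts the matrix to the selected probes, re-runs the gene-embedded
#' decomposition, and returns the chosen PC's sample loading as a per-sample
#' scalar feature. If the reduced matrix has rank below `pc_index` the
#' surplus loading is a zero vector (with a warning from [decompose()]).
#'
#' @param m Normalized probe-by-sample matrix.
#' @param selection A `probe_selection` (or character vector of probe ids).
#' @param pc_index Which PC loading to return (default 2).
#' @return Named numeric vector: one scalar per sample.
#' @export
reduced_loading <- function(m, selection, pc_index = 2L) {
  probes <- if (inherits(selection, "probe_selection"))
    selection$table$probe_id[selection$table$selected]
  else as.character(selection)
  if (length(probes) < 2L) stop("need at least 2 selected probes")
  if (pc_index > ncol(m)) stop("pc_index exceeds the number of samples")
  sub <- m[rownames(m) %in% probes, , drop = FALSE]
  emb <- decompose(expression_matrix(sub), n_components = pc_index)
  emb$loadings[, pc_index]
}

# Closed-form two-class LDA on a 1-D feature: equal within-class variance.
# `prior` is a named numeric vector of class priors; NULL uses training-set
# frequencies. Returns the fitted pieces and the decision boundary.
fit_lda_1d <- function(x, y, prior = NULL) {
  labs <- sort(unique(y))
  stopifnot(length(labs) == 2L)
  n <- length(x)
  mu <- vapply(labs, function(g) mean(x[y == g]), numeric(1))
  ss <- sum(vapply(labs, function(g) sum((x[y == g] - mu[g])^2), numeric(1)))
  s2 <- ss / (n - 2L)  # pooled within-class variance
  if (s2 <= 0 && mu[1L] == mu[2L])
    stop("degenerate training fold: zero pooled within-class variance and equal class means")
  pri <- if (is.null(prior))
    vapply(labs, function(g) mean(y == g), numeric(1))
  else prior[labs]
  # The discriminant delta_g(x) = x mu_g / s2 - mu_g^2 / (2 s2) + log pi_g
  # reduces on one dimension to a threshold rule; the boundary is where the
  # prior-weighted class densities are equal. As s2 -> 0 the prior term
  # vanishes and the boundary collapses to the midpoint of the means.
  boundary <- if (mu[1L] == mu[2L]) NA_real_
  else if (s2 > 0)
    (mu[1L] + mu[2L]) / 2 + s2 * (log(pri[2L]) - log(pri[1L])) / (mu[1L] - mu[2L])
  else (mu[1L] + mu[2L]) / 2
  list(labels = labs, mu = mu, s2 = s2, prior = pri,
       boundary = unname(boundary))
}

predict_lda_1d <- function(fit, x) {
  if (is.na(fit$boundary)) {
    # equal class means: the feature carries no information, the prior decides
    g <- if (fit$prior[1L] != fit$prior[2L]) which.max(fit$prior) else 1L
    return(rep(fit$labels[g], length(x)))
  }
  hi <- which.max(fit$mu)  # class claiming the upper side of the boundary
  lo <- 3L - hi
  pick <- ifelse(x > fit$boundary, hi,
                 ifelse(x < fit$boundary, lo, {
                   # tie at the boundary: larger prior wins, then lexicographic
                   if (fit$prior[1L] != fit$prior[2L]) which.max(fit$prior) else 1L
                 }))
  fit$labels[pick]
}

#' Leave-one-out cross-validated LDA on a scalar feature
#'
#' For each sample in turn, fits a two-class equal-variance Gaussian linear
#' discriminant on the remaining samples' feature values and predicts the
#' held-out sample; assembles the confusion table (true group x predicted
#' group) and accuracy. Class priors default to the whole-cohort class
#' frequencies held constant across folds, which is what the standard LDA
#' cross-validation routine does; `prior = "fold"` recomputes them from each
#' training fold, `prior = "uniform"` uses 1/2 each. Ties at the decision
#' boundary resolve to the larger-prior group, then lexicographically.
#'
#' @param feature Named per-sample numeric vector (e.g. from
#'   [reduced_loading()]).
#' @param groups Named group assignment covering the same samples.
#' @param prior `"cohort"` (default), `"fold"` or `"uniform"`.
#' @return A `discrimination_result` list: `feature`, `predictions`, `truth`,
#'   `confusion` (2x2, rows = true), `accuracy`.
#' @export
lda_loocv <- function(feature, groups, prior = c("cohort", "fold", "uniform")) {
  prior <- match.arg(prior)
  groups <- sample_groups(groups[names(feature)])
  y <- as.character(groups)
  labs <- sort(unique(y))
  if (any(table(factor(y, levels = labs)) < 2L))
    stop("both groups need at least 2 samples for leave-one-out")
  x <- as.numeric(feature)
  n <- length(x)
  pri <- switch(prior,
    cohort = vapply(stats::setNames(labs, labs), function(g) mean(y == g),
                    numeric(1)),
    uniform = stats::setNames(c(0.5, 0.5), labs),
    fold = NULL)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fit_lda_1d(x[-i], y[-i], prior = pri)
    pred[i] <- predict_lda_1d(fit, x[i])
  }
  names(pred) <- names(feature)
  conf <- table(true = factor(y, levels = labs),
                predicted = factor(pred, levels = labs))
  acc <- sum(diag(conf)) / n
  structure(list(feature = stats::setNames(x, names(feature)),
                 predictions = pred,
                 truth = stats::setNames(y, names(feature)),
                 confusion = conf, accuracy = acc, prior = prior),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat("LDA leave-one-out cross-validation\n")
  print(x$confusion)
  cat(sprintf("accuracy: %d/%d = %.1f%%\n",
              sum(diag(x$confusion)), length(x$predictions), 100 * x$accuracy))
  invisible(x)
}

#' Strict LOOCV: redo probe selection inside every fold
#'
#' The default pipeline selects probes once on the full dataset and only
#' refits the LDA per fold, which leaks the held-out sample into selection.
#' This variant repeats the whole selection (decomposition, PC
#' identification, chi-squared selection, reduced loading) on each training
#' fold, then scores the held-out sample by projecting it onto the fold's
#' probe-score vector. Slower but leak-free.
#'
#' @inheritParams select_probes
#' @param pc Optional PC override passed through to each fold's selection.
#' @return A `discrimination_result`.
#' @export
lda_loocv_strict <- function(m, groups, threshold = 0.01, pc = NULL,
                             prior = c("cohort", "fold", "uniform")) {
  prior <- match.arg(prior)
  groups <- sample_groups(groups[colnames(m)])
  y <- as.character(groups)
  labs <- sort(unique(y))
  n <- ncol(m)
  pri <- switch(prior,
    cohort = vapply(stats::setNames(labs, labs), function(g) mean(y == g),
                    numeric(1)),
    uniform = stats::setNames(c(0.5, 0.5), labs),
    fold = NULL)
  pred <- character(n)
  feat_all <- numeric(n)
  for (i in seq_len(n)) {
    mtr <- expression_matrix(unclass(m)[, -i, drop = FALSE])
    sel <- select_probes(mtr, groups[-i], threshold = threshold, pc = pc)
    probes <- sel$table$probe_id[sel$table$selected]
    if (length(probes) < 2L) probes <- sel$table$probe_id  # fall back: no selection power in fold
    sub <- unclass(m)[rownames(m) %in% probes, , drop = FALSE]
    k <- min(sel$pc_index, ncol(mtr))
    emb <- decompose(expression_matrix(sub[, -i, drop = FALSE]), n_components = k)
    xtr <- emb$loadings[, k]
    xte <- drop(crossprod(sub[, i, drop = FALSE], emb$scores[, k]))
    fit <- fit_lda_1d(xtr, y[-i], prior = pri)
    pred[i] <- predict_lda_1d(fit, xte)
    feat_all[i] <- xte
  }
  names(pred) <- colnames(m)
  conf <- table(true = factor(y, levels = labs),
                predicted = factor(pred, levels = labs))
  structure(list(feature = stats::setNames(feat_all, colnames(m)),
                 predictions = pred, truth = stats::setNames(y, colnames(m)),
                 confusion = conf, accuracy = sum(diag(conf)) / n,
                 prior = prior),
            class = "discrimination_result")
}
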