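#' Gene-embedded principal component decomposition
#'
#' Embeds probes (not samples) into PC space: eigenvectors u_k of X X^T give
#' per-probe PC scores, eigenvalues lambda_k their variances, and the
#' sample-side loadings are v_k = X^T u_k, which are eigenvectors of X^T X by
#' duality. Computed via the singular value decomposition of X rather than by
#' forming X X^T, which is numerically stabler for tens of thousands of
#' probes and mathematically identical.
#'
#' No centering beyond the column z-normalization of [normalize_samples()] is
#' applied; the eigenproblem acts on the normalized matrix as-is. The sign of
#' each u_k is fixed so that its largest-magnitude component is positive
#' (signs are otherwise arbitrary and the downstream statistic is
#' sign-invariant).
#'
#' @param m Probe-by-sample numeric matrix (normally the output of
#'   [normalize_samples()]).
#' @param n_components Number of components to return; at most the number of
#'   samples. Components beyond the matrix rank come back with eigenvalue 0
#'   and a warning.
#' @return A `gene_embedding` list: `eigenvalues` (non-increasing), `scores`
#'   (probes x k matrix of u_k), `loadings` (samples x k matrix of v_k),
#'   `probe_ids`, `sample_ids`.
#' @export
decompose <- function(m, n_components = ncol(m)) {
  x <- unclass(as.matrix(m))
  n_samp <- ncol(x)
  if (n_components < 1L || n_components > n_samp)
    stop("n_components must be between 1 and the number of samples")
  sv <- svd(x, nu = n_components, nv = n_components)
  lambda <- sv$d[seq_len(n_components)]^2
  rk <- sum(sv$d > max(dim(x)) * max(sv$d) * .Machine$double.eps)
  if (n_components > rk) {
    warning("requested ", n_components, " components but matrix rank is ", rk,
            "; surplus eigenvalues set to 0")
    lambda[(rk + 1L):n_components] <- 0
  }
  u <- sv$u
  # sign convention: largest-magnitude score component positive
  for (k in seq_len(ncol(u))) {
    i <- which.max(abs(u[, k]))
    if (u[i, k] < 0) u[, k] <- -u[, k]
  }
  v <- crossprod(x, u)  # v_k = X^T u_k, carries the eigen scale sqrt(lambda_k)
  rownames(u) <- rownames(m)
  rownames(v) <- colnames(m)
  colnames(u) <- colnames(v) <- paste0("PC", seq_len(n_components))
  structure(list(eigenvalues = lambda, scores = u, loadings = v,
                 probe_ids = rownames(m), sample_ids = colnames(m)),
            class = "gene_embedding")
}

#' Identify the PC whose sample loadings separate the two groups
#'
#' Runs a two-group t-test (Welch by default, pooled-variance optionally) on
#' each PC's sample loadings and returns the PC with the smallest p-value,
#' unless an explicit override is given. Ties resolve to the smallest index.
#'
#' @param e A `gene_embedding`.
#' @param groups Named group assignment covering all samples (see
#'   [sample_groups()]).
#' @param max_pc Number of leading PCs to test (default: all returned).
#' @param var_equal Use the pooled-variance (classical Student) t-test instead
#'   of the Welch default.
#' @param override Manually fix the returned `pc_index` (p-values are still
#'   reported for all tested PCs).
#' @return A `pc_identification` list: `pc_index`, `pvalues` (per tested PC),
#'   `group_labels`, `var_equal`, `overridden`.
#' @export
identify_discriminative_pc <- function(e, groups, max_pc = length(e$eigenvalues),
                                       var_equal = FALSE, override = NULL) {
  groups <- sample_groups(groups[e$sample_ids])
  labs <- unique(groups)
  if (any(table(factor(groups, levels = labs)) < 2L))
    stop("each group needs at least 2 samples for the t-test")
  max_pc <- min(max_pc, ncol(e$loadings))
  pvals <- vapply(seq_len(max_pc), function(k) {
    v <- e$loadings[, k]
    if (stats::sd(v[groups == labs[1L]]) == 0 && stats::sd(v[groups == labs[2L]]) == 0)
      return(1)
    stats::t.test(v[groups == labs[1L]], v[groups == labs[2L]],
                  var.equal = var_equal)$p.value
  }, numeric(1))
  idx <- if (is.null(override)) which.min(pvals) else as.integer(override)
  if (idx < 1L || idx > ncol(e$loadings)) stop("pc override out of range")
  structure(list(pc_index = idx, pvalues = pvals, group_labels = labs,
                 var_equal = var_equal, overridden = !is.null(override)),
            class = "pc_identification")
}

#' Chi-squared p-values for probe PC scores
#'
#' Standardizes the chosen PC's probe scores by their standard deviation
#' sigma and refers the squared standardized score (u_i / sigma)^2 to a
#' chi-squared distribution with 1 degree of freedom (upper tail). sigma is
#' the mean-subtracted sample standard deviation of the score components by
#' default; `center_sigma = FALSE` uses the root mean square instead, for
#' sensitivity analysis.
#'
#' @param e A `gene_embedding`.
#' @param pc_index Which PC's scores to test.
#' @param df Degrees of freedom of the chi-squared reference (default 1).
#' @param center_sigma Subtract the mean before computing sigma (default TRUE).
#' @return A data.frame with columns `probe_id`, `statistic`, `pvalue`, and
#'   attribute `sigma`.
#' @export
chi2_pvalues <- function(e, pc_index, df = 1, center_sigma = TRUE) {
  if (pc_index < 1L || pc_index > ncol(e$scores)) stop("pc_index out of range")
  u <- e$scores[, pc_index]
  if (length(u) < 2L) stop("need at least 2 probes")
  sigma <- if (center_sigma) stats::sd(u) else sqrt(sum(u^2) / (length(u) - 1L))
  if (sigma == 0) stop("degenerate PC score vector (zero standard deviation)")
  stat <- (u / sigma)^2
  out <- data.frame(probe_id = e$probe_ids, statistic = stat,
                    pvalue = stats::pchisq(stat, df = df, lower.tail = FALSE),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "sigma") <- sigma
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Select discriminating probes by PCA-based unsupervised feature extraction
#'
#' The full selection pass: decompose the normalized matrix, find the PC whose
#' sample loadings separate the groups (or use the given override), attribute
#' chi-squared(1) p-values to the standardized probe scores on that PC,
#' BH-adjust, and flag probes whose adjusted p falls strictly below the
#' threshold.
#'
#' @param m Normalized probe-by-sample matrix.
#' @param groups Named group assignment (two labels).
#' @param threshold Adjusted-p cutoff, strict inequality (default 0.01).
#' @param pc Optional manual PC index override.
#' @param var_equal Pooled-variance t-test for PC identification.
#' @param df Chi-squared degrees of freedom (default 1).
#' @return A `probe_selection` list: `table` (data.frame probe_id, statistic,
#'   pvalue, adjusted_pvalue, selected), `pc_index`, `pc_pvalues`, `sigma`,
#'   `threshold`.
#' @export
select_probes <- function(m, groups, threshold = 0.01, pc = NULL,
                          var_equal = FALSE, df = 1) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  emb <- decompose(m)
  ident <- identify_discriminative_pc(emb, groups, var_equal = var_equal,
                                      override = pc)
  tab <- chi2_pvalues(emb, ident$pc_index, df = df)
  tab$adjusted_pvalue <- bh_adjust(tab$pvalue)
  tab$selected <- tab$adjusted_pvalue < threshold
  structure(list(table = tab, pc_index = ident$pc_index,
                 pc_pvalues = ident$pvalues, sigma = attr(tab, "sigma"),
                 threshold = threshold, embedding = emb),
            class = "probe_selection")
}

#' @export
print.probe_selection <- function(x, ...) {
  cat("PCA-FE probe selection\n")
  cat("  discriminative PC:", x$pc_index,
      sprintf("(t-test p = %.3g)", x$pc_pvalues[x$pc_index]), "\n")
  cat("  probes tested:", nrow(x$table), "\n")
  cat("  selected (BH adj p <", x$threshold, "):", sum(x$table$selected), "\n")
  invisible(x)
}
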