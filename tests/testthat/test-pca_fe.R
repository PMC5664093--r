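test_that("decompose recovers the eigenpairs of a diagonal matrix", {
  m <- expression_matrix(matrix(c(2, 0, 0, 1), 2, 2),
                         c("p1", "p2"), c("s1", "s2"))
  e <- decompose(m)
  expect_equal(e$eigenvalues, c(4, 1))
  expect_equal(unname(e$scores[, 1]), c(1, 0))
  expect_equal(unname(e$scores[, 2]), c(0, 1))
  # loadings carry the singular-value scale: v_k = X^T u_k
  expect_equal(unname(e$loadings[, 1]), c(2, 0))
})

test_that("loadings are eigenvectors of the sample-side Gram matrix (duality)", {
  set.seed(11)
  for (rep in 1:10) {
    x <- matrix(rnorm(6 * 4), 6, 4)
    m <- expression_matrix(x, paste0("p", 1:6), paste0("s", 1:4))
    e <- decompose(m)
    gram <- crossprod(x)          # X^T X, the independent dense route
    for (k in seq_along(e$eigenvalues)) {
      v <- e$loadings[, k]
      lhs <- gram %*% v
      expect_lt(max(abs(lhs - e$eigenvalues[k] * v)),
                1e-6 * max(1, e$eigenvalues[k]) * max(abs(v), 1))
    }
    # independent oracle: eigen() on X^T X gives the same eigenvalues
    ev <- eigen(gram, symmetric = TRUE)$values
    expect_equal(e$eigenvalues, ev, tolerance = 1e-8)
    expect_true(all(diff(e$eigenvalues) <= 1e-8))
    expect_lt(max(abs(crossprod(e$scores) - diag(4))), 1e-8)
  }
})

test_that("rank-deficient requests return zero eigenvalues with a warning", {
  x <- matrix(rnorm(6 * 4), 6, 4)
  x[, 4] <- x[, 1] + x[, 2]  # rank 3
  m <- expression_matrix(x, paste0("p", 1:6), paste0("s", 1:4))
  expect_warning(e <- decompose(m, n_components = 4), "rank is 3")
  expect_equal(e$eigenvalues[4], 0)
  expect_equal(sum(e$eigenvalues > 1e-10), 3)
})

test_that("the discriminative PC is found by minimal loading t-test p-value", {
  set.seed(21)
  groups <- sample_groups(setNames(rep(c("control", "case"), c(5, 5)),
                                   paste0("s", 1:10)))
  loadings <- matrix(rnorm(10 * 4), 10, 4,
                     dimnames = list(paste0("s", 1:10), paste0("PC", 1:4)))
  loadings[, 2] <- ifelse(groups == "case", 1, -1) + rnorm(10, sd = 1e-3)
  e <- structure(list(eigenvalues = c(4, 3, 2, 1),
                      scores = matrix(rnorm(40), 10, 4),
                      loadings = loadings,
                      probe_ids = paste0("p", 1:10),
                      sample_ids = paste0("s", 1:10)),
                 class = "gene_embedding")
  id <- identify_discriminative_pc(e, groups)
  expect_equal(id$pc_index, 2)
  expect_true(all(id$pvalues >= 0 & id$pvalues <= 1))

  # manual override wins but p-values are still reported
  id3 <- identify_discriminative_pc(e, groups, override = 3)
  expect_equal(id3$pc_index, 3)
  expect_true(id3$overridden)

  tiny <- sample_groups(setNames(c("a", "b", "b", "b", "b", "b", "b", "b", "b", "b"),
                                 paste0("s", 1:10)))
  expect_error(identify_discriminative_pc(e, tiny), "at least 2 samples")
})

test_that("chi-squared probe p-values match the 1-df survival function", {
  u <- c(0, 1, -1)  # mean 0, sd exactly 1
  e <- structure(list(eigenvalues = c(2, 1),
                      scores = cbind(PC1 = c(1, 0, 0), PC2 = u),
                      loadings = matrix(0, 2, 2),
                      probe_ids = paste0("p", 1:3),
                      sample_ids = c("s1", "s2")),
                 class = "gene_embedding")
  tab <- chi2_pvalues(e, 2)
  expect_equal(attr(tab, "sigma"), 1)
  expect_equal(tab$statistic, c(0, 1, 1))
  expect_equal(tab$pvalue[1], 1)
  expect_equal(tab$pvalue[2], 0.3173105, tolerance = 1e-6)

  # sign flip of the whole eigenvector leaves every p unchanged
  e2 <- e
  e2$scores[, 2] <- -e2$scores[, 2]
  expect_equal(chi2_pvalues(e2, 2)$pvalue, tab$pvalue)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(31)
  for (rep in 1:50) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # adjusted values never drop below raw ones
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("probe selection is deterministic, sign-stable, and threshold-monotone", {
  sim <- make_matrix(500, 10, 9, n_sig = 20, effect = 2.5, seed = 5)
  mz <- normalize_samples(sim$matrix)
  s1 <- select_probes(mz, sim$groups, threshold = 0.01)
  s2 <- select_probes(mz, sim$groups, threshold = 0.01)
  expect_identical(s1$table, s2$table)

  strict <- select_probes(mz, sim$groups, threshold = 0.005)
  sel_strict <- strict$table$probe_id[strict$table$selected]
  sel_loose <- s1$table$probe_id[s1$table$selected]
  expect_true(all(sel_strict %in% sel_loose))

  expect_true(all(s1$table$adjusted_pvalue >= s1$table$pvalue))
  expect_identical(s1$table$selected, s1$table$adjusted_pvalue < 0.01)
  expect_error(select_probes(mz, sim$groups, threshold = 1), "threshold")
})
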