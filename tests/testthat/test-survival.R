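make_cohort <- function(time, event, expr = seq_along(time)) {
  survival_cohort(time = time, event = event, expression = expr)
}

test_that("median split halves the cohort with ties falling low", {
  co <- make_cohort(1:4, rep(1, 4), expr = c(1, 2, 3, 4))
  sp <- median_split(co)
  expect_equal(sort(sp$low$expression), c(1, 2))
  expect_equal(sort(sp$high$expression), c(3, 4))

  co2 <- make_cohort(1:4, rep(1, 4), expr = c(1, 2, 2, 3))
  sp2 <- median_split(co2)
  expect_equal(sort(sp2$low$expression), c(1, 2, 2))
  expect_equal(sp2$high$expression, 3)

  set.seed(41)
  co3 <- make_cohort(rexp(360) + 0.1, rbinom(360, 1, 0.8), expr = rnorm(360))
  sp3 <- median_split(co3)
  expect_equal(nrow(sp3$low), 180)
  expect_equal(nrow(sp3$high), 180)

  expect_error(median_split(make_cohort(1:4, rep(1, 4), expr = rep(2, 4))),
               "degenerate")
})

test_that("Kaplan-Meier curve matches hand product-limit computation", {
  # no events: flat at 1
  flat <- km_curve(make_cohort(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(flat$surv == 1))

  # all events: empirical survival 2/3, 1/3, 0
  all_ev <- km_curve(make_cohort(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(all_ev$surv, c(2/3, 1/3, 0))

  # censoring shrinks the risk set: (1,event),(2,censored),(3,event)
  mix <- km_curve(make_cohort(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(mix$surv[mix$time == 1], 2/3)
  expect_equal(mix$surv[mix$time == 3], 0)

  # random cohorts agree with the brute-force tabulation oracle
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    tm <- sample(1:15, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    got <- km_curve(make_cohort(tm, ev))
    want <- km_brute(tm, ev)
    expect_equal(got$surv, want$surv[match(got$time, want$time)],
                 tolerance = 1e-12)
  }
})

test_that("KM curves are proper survival functions and reduce to the ECDF without censoring", {
  set.seed(47)
  tm <- rexp(40) + 0.01
  cur <- km_curve(make_cohort(tm, rep(1, 40)))
  expect_true(all(diff(cur$surv) <= 1e-12))
  expect_true(all(cur$surv >= 0 & cur$surv <= 1))
  # no censoring: S(t) = fraction of times strictly greater than t
  for (i in seq_len(nrow(cur)))
    expect_equal(cur$surv[i], mean(tm > cur$time[i]))
})

test_that("log-rank test matches manual O-E tabulation and is symmetric", {
  a <- make_cohort(c(1, 2), c(1, 1))
  b <- make_cohort(c(3, 4), c(1, 1))
  got <- logrank_test(a, b)
  want <- logrank_brute(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$pvalue, want$pvalue, tolerance = 1e-10)

  swap <- logrank_test(b, a)
  expect_equal(swap$statistic, got$statistic, tolerance = 1e-12)

  # identical groups: observed equals expected exactly
  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$pvalue, 1)

  set.seed(53)
  for (rep in 1:10) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    t1 <- sample(1:25, n1, TRUE); t2 <- sample(1:25, n2, TRUE)
    e1 <- rbinom(n1, 1, 0.8); e2 <- rbinom(n2, 1, 0.8)
    if (sum(e1) + sum(e2) == 0) e1[1] <- 1
    got <- logrank_test(make_cohort(t1, e1), make_cohort(t2, e2))
    want <- logrank_brute(t1, e1, t2, e2)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
  }
})

test_that("log-rank statistic is invariant to monotone time transforms", {
  set.seed(59)
  t1 <- rexp(15) + 0.1; t2 <- rexp(15) * 2 + 0.1
  e1 <- rbinom(15, 1, 0.8); e2 <- rbinom(15, 1, 0.8)
  base <- logrank_test(make_cohort(t1, e1), make_cohort(t2, e2))
  warp <- logrank_test(make_cohort(exp(t1), e1), make_cohort(exp(t2), e2))
  expect_equal(warp$statistic, base$statistic, tolerance = 1e-10)
})

test_that("the gene screen flags hazard-linked genes with the right direction", {
  hi <- gen_survival(n_patients = 360, hazard_ratio = 3, censor_fraction = 0.2,
                     seed = 61)
  null1 <- gen_survival(n_patients = 360, hazard_ratio = 1,
                        censor_fraction = 0.2, seed = 62)
  res <- screen_genes(list(RISKY = hi$cohort, INERT = null1$cohort),
                      alpha = 0.05)
  risky <- res[res$gene_symbol == "RISKY", ]
  expect_true(risky$significant)
  expect_equal(risky$direction, "low_survives_better")
  expect_equal(risky$n_low + risky$n_high, 360)
  expect_true(all(res$fdr >= res$pvalue, na.rm = TRUE))

  # single gene: FDR equals the raw p-value
  single <- screen_genes(list(ONLY = hi$cohort), alpha = 0.05)
  expect_equal(single$fdr, single$pvalue)

  # degenerate cohorts yield NA rows, not errors
  flat <- survival_cohort(1:6, rep(1, 6), rep(1, 6))
  mixed <- screen_genes(list(BAD = flat, GOOD = hi$cohort), alpha = 0.05)
  expect_true(is.na(mixed$pvalue[mixed$gene_symbol == "BAD"]))
  expect_false(is.na(mixed$pvalue[mixed$gene_symbol == "GOOD"]))
})

test_that("the Cox option agrees in direction with the log-rank screen on strong signal", {
  hi <- gen_survival(n_patients = 360, hazard_ratio = 3, censor_fraction = 0.2,
                     seed = 67)
  cox <- screen_genes(list(G = hi$cohort), alpha = 0.05, method = "cox")
  expect_true(cox$significant)
  expect_equal(cox$direction, "low_survives_better")
})
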