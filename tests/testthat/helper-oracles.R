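# Independent oracles used across tests. Each re-derives the quantity it
# checks from first principles, never through the package's own code path.

# Benjamini-Hochberg step-up by direct enumeration of the definition:
# sort ascending, adj_(i) = min over j >= i of m * p_(j) / j, capped at 1,
# returned in input order.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Hypergeometric upper-tail by summing point masses computed with choose():
# P(overlap >= k) drawing n from a universe of N with K marked.
hyper_tail_brute <- function(k, K, N, n) {
  if (k <= 0) return(1)
  kk <- k:min(K, n)
  if (length(kk) == 0 || min(kk) > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Kaplan-Meier product-limit by explicit tabulation over distinct times.
km_brute <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    if (at_risk > 0) s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Two-group log-rank by manual O-E / hypergeometric-variance tabulation.
logrank_brute <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  g1 <- c(rep(TRUE, length(t1)), rep(FALSE, length(t2)))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in ts) {
    n <- sum(time >= tt); n1 <- sum(time >= tt & g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- o_minus_e^2 / v
  list(statistic = stat, pvalue = pchisq(stat, 1, lower.tail = FALSE))
}

# Equal-variance two-class Gaussian decision boundary: the point where the
# prior-weighted class densities are equal, found numerically on the
# log-density difference (the raw densities underflow far from the means).
lda_boundary_numeric <- function(mu1, mu2, s2, p1, p2) {
  f <- function(x) log(p1) + dnorm(x, mu1, sqrt(s2), log = TRUE) -
    log(p2) - dnorm(x, mu2, sqrt(s2), log = TRUE)
  lo <- min(mu1, mu2) - 50 * sqrt(s2)
  hi <- max(mu1, mu2) + 50 * sqrt(s2)
  uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root
}

# Small two-group matrix fixture with an optional shifted block.
make_matrix <- function(n_probes, n_ctrl, n_case, n_sig = 0, effect = 0,
                        seed = 1) {
  sim <- gen_expression(n_probes = n_probes, n_controls = n_ctrl,
                        n_cases = n_case, n_signal_probes = n_sig,
                        effect = effect, seed = seed)
  sim
}
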