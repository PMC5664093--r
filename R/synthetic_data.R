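#' Simulate a two-group expression matrix with known signal probes
#'
#' Gaussian(0, noise_sd) background on every probe; the first
#' `n_signal_probes` probes additionally receive a group-mean shift of
#' `effect * noise_sd` in the case samples. Signal probes are named
#' `sig_0001, ...` and noise probes `probe_000001, ...` so ground truth is
#' trivially recoverable. The sample-size defaults mirror a 10-control /
#' 9-case muscle-biopsy study design. Deterministic for a fixed seed.
#'
#' @param n_probes Total number of probes.
#' @param n_controls,n_cases Group sizes (defaults 10 and 9).
#' @param n_signal_probes Number of shifted probes (<= n_probes).
#' @param effect Group-mean shift in units of `noise_sd` (>= 0).
#' @param noise_sd Baseline noise standard deviation.
#' @param seed Integer seed; recorded in the output.
#' @return List: `matrix` (an `expression_matrix`), `groups` (named vector,
#'   labels "control"/"case"), `truth` (signal probe ids), `config`.
#' @export
gen_expression <- function(n_probes = 10000L, n_controls = 10L, n_cases = 9L,
                           n_signal_probes = 100L, effect = 2, noise_sd = 1,
                           seed = 1L) {
  if (n_signal_probes > n_probes) stop("n_signal_probes exceeds n_probes")
  if (effect < 0) stop("effect must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (n_controls < 1L || n_cases < 1L) stop("both groups must be non-empty")
  n_samp <- n_controls + n_cases
  probe_ids <- c(sprintf("sig_%04d", seq_len(n_signal_probes)),
                 sprintf("probe_%06d", seq_len(n_probes - n_signal_probes)))[seq_len(n_probes)]
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(n_controls)),
                  sprintf("case_%02d", seq_len(n_cases)))
  groups <- stats::setNames(rep(c("control", "case"), c(n_controls, n_cases)),
                            sample_ids)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_probes * n_samp, sd = noise_sd),
                 nrow = n_probes, ncol = n_samp)
  if (n_signal_probes > 0L && effect > 0) {
    case_cols <- which(groups == "case")
    vals[seq_len(n_signal_probes), case_cols] <-
      vals[seq_len(n_signal_probes), case_cols] + effect * noise_sd
  }
  m <- expression_matrix(vals, probe_ids, sample_ids)
  list(matrix = m, groups = groups,
       truth = probe_ids[seq_len(n_signal_probes)],
       config = list(n_probes = n_probes, n_controls = n_controls,
                     n_cases = n_cases, n_signal_probes = n_signal_probes,
                     effect = effect, noise_sd = noise_sd, seed = seed))
}

#' Simulate a survival cohort with expression-dependent hazard
#'
#' Expression is standard normal; survival times are exponential with
#' baseline hazard for the lower expression half and hazard multiplied by
#' `hazard_ratio` for the upper half. Independent uniform censoring trims
#' follow-up to reach roughly the requested censored fraction. Deterministic
#' for a fixed seed.
#'
#' @param n_patients Cohort size.
#' @param hazard_ratio Hazard multiplier for the upper expression half (> 0).
#' @param baseline_hazard Events per day in the lower half.
#' @param censor_fraction Target censored fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return List: `cohort` (a `survival_cohort`), `upper_half` (logical,
#'   truth), `config`.
#' @export
gen_survival <- function(n_patients = 360L, hazard_ratio = 1,
                         baseline_hazard = 1 / 1000, censor_fraction = 0.2,
                         seed = 1L) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("censor_fraction must be in [0, 1)")
  if (n_patients < 4L) stop("need at least 4 patients")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr <- stats::rnorm(n_patients)
  upper <- expr > stats::median(expr)
  haz <- baseline_hazard * ifelse(upper, hazard_ratio, 1)
  t_event <- stats::rexp(n_patients, rate = haz)
  if (censor_fraction > 0) {
    # uniform censoring on (0, c): for Exp(h) event times,
    # P(censored) = (1 - exp(-h c)) / (h c); solve c so the cohort-average
    # censored probability hits the target fraction
    pcens <- function(cc) mean((1 - exp(-haz * cc)) / (haz * cc))
    cmax <- stats::uniroot(function(cc) pcens(cc) - censor_fraction,
                           lower = 1e-8 / baseline_hazard,
                           upper = 1e6 / baseline_hazard)$root
    t_cens <- stats::runif(n_patients, 0, cmax)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n_patients)
  }
  co <- survival_cohort(time = time, event = event, expression = expr)
  list(cohort = co, upper_half = upper,
       config = list(n_patients = n_patients, hazard_ratio = hazard_ratio,
                     baseline_hazard = baseline_hazard,
                     censor_fraction = censor_fraction, seed = seed))
}

# save/restore the global RNG state so generators are pure functions of seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
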