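#' Validate a per-gene survival cohort
#'
#' @param time Positive follow-up times (days).
#' @param event 1 = death observed, 0 = censored.
#' @param expression Real-valued expression of one gene per patient.
#' @param patient_id Optional identifiers (defaults to `p1, p2, ...`).
#' @return A `survival_cohort` data.frame with those four columns.
#' @export
survival_cohort <- function(time, event, expression,
                            patient_id = paste0("p", seq_along(time))) {
  if (length(time) != length(event) || length(time) != length(expression))
    stop("time, event, expression must have equal length")
  if (anyNA(time) || any(time <= 0)) stop("times must be positive and non-missing")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  structure(data.frame(patient_id = as.character(patient_id),
                       time = as.numeric(time), event = as.integer(event),
                       expression = as.numeric(expression),
                       stringsAsFactors = FALSE),
            class = c("survival_cohort", "data.frame"))
}

#' Split a cohort at its median expression
#'
#' Patients with expression less than or equal to the median form the low
#' group; the rest form the high group. Ties at the median fall low. Even
#' cohorts without ties split into equal halves.
#'
#' @param cohort A `survival_cohort`.
#' @return List with `low` and `high` cohort subsets.
#' @export
median_split <- function(cohort) {
  if (nrow(cohort) < 4L) stop("cohort must have at least 4 patients")
  med <- stats::median(cohort$expression)
  low <- cohort$expression <= med
  if (all(low) || !any(low))
    stop("degenerate split: all expression values on one side of the median")
  list(low = cohort[low, , drop = FALSE], high = cohort[!low, , drop = FALSE])
}

#' Kaplan-Meier product-limit curve
#'
#' At each distinct event time t with d events among n at risk, the survival
#' estimate multiplies by (1 - d/n); censored patients leave the risk set
#' after their time; S(0) = 1.
#'
#' @param group A `survival_cohort` subset (or data.frame with `time`,
#'   `event`).
#' @return Data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` — the step function's value from each time onward.
#' @export
km_curve <- function(group) {
  if (nrow(group) == 0L) stop("group is empty")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = group)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank: the sum over event times of observed-minus-expected
#' events in one group, squared, divided by the hypergeometric variance,
#' referred to chi-squared with 1 degree of freedom.
#'
#' @param a,b `survival_cohort` subsets.
#' @return List with `statistic`, `pvalue`, `obs` and `exp` (per-group
#'   observed/expected event counts, a first).
#' @export
logrank_test <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both groups must be non-empty")
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  if (sum(event) == 0L) stop("no events in either group")
  grp <- factor(rep(c("a", "b"), c(nrow(a), nrow(b))), levels = c("a", "b"))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  if (!is.finite(sd_$chisq)) stop("log-rank statistic undefined (zero variance)")
  list(statistic = unname(sd_$chisq),
       pvalue = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       obs = unname(sd_$obs), exp = unname(sd_$exp))
}

# direction of the effect: which half has the higher estimated survival,
# judged by observed vs expected events in the low group
split_direction <- function(obs_low, exp_low) {
  if (obs_low < exp_low) "low_survives_better"
  else if (obs_low > exp_low) "high_survives_better"
  else "none"
}

#' Screen genes for survival association
#'
#' Per gene: median-split the cohort, run a log-rank test between halves (or
#' a Cox proportional-hazards regression on continuous expression when
#' `method = "cox"`), then BH-adjust the p-values across all screened genes
#' and flag those with FDR below `alpha`. Per-gene failures (degenerate
#' splits, no events) are recorded as NA rows rather than aborting.
#'
#' @param cohorts Named list of `survival_cohort` objects, one per gene.
#' @param alpha FDR cutoff in (0, 1), default 0.05.
#' @param method `"logrank"` (median split, default) or `"cox"` (continuous
#'   expression, Wald test).
#' @param cancer_label Optional label copied to every row (BH is applied
#'   within one call, i.e. within one cancer).
#' @return Data.frame with one row per gene: `gene_symbol`, `cancer_label`,
#'   `method`, `statistic`, `pvalue`, `fdr`, `n_low`, `n_high`, `direction`,
#'   `significant`.
#' @export
screen_genes <- function(cohorts, alpha = 0.05,
                         method = c("logrank", "cox"), cancer_label = NA_character_) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    stop("cohorts must be a named list (gene symbols)")
  rows <- lapply(names(cohorts), function(g) {
    co <- cohorts[[g]]
    out <- data.frame(gene_symbol = g, cancer_label = cancer_label,
                      method = method, statistic = NA_real_, pvalue = NA_real_,
                      n_low = NA_integer_, n_high = NA_integer_,
                      direction = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      halves <- median_split(co)
      out$n_low <- nrow(halves$low)
      out$n_high <- nrow(halves$high)
      if (method == "logrank") {
        lr <- logrank_test(halves$low, halves$high)
        out$statistic <- lr$statistic
        out$pvalue <- lr$pvalue
        out$direction <- split_direction(lr$obs[1L], lr$exp[1L])
      } else {
        fit <- survival::coxph(survival::Surv(time, event) ~ expression, data = co)
        z <- summary(fit)$coefficients[1L, "z"]
        out$statistic <- z
        out$pvalue <- summary(fit)$coefficients[1L, "Pr(>|z|)"]
        out$direction <- if (z > 0) "low_survives_better"
                         else if (z < 0) "high_survives_better" else "none"
      }
      out
    }, error = function(e) out)
    res
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$pvalue)
  tab$fdr <- NA_real_
  tab$fdr[ok] <- bh_adjust(tab$pvalue[ok])
  tab$significant <- !is.na(tab$fdr) & tab$fdr < alpha
  tab
}
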