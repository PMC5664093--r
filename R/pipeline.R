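#' Build a pipeline configuration
#'
#' Collects file paths and tuning parameters for [run_pipeline()]. Referenced
#' input files must exist at construction time; survival, probe-map and GMT
#' inputs are optional and their stages are skipped when absent.
#'
#' @param matrix_path Expression TSV (see [read_expression()]). Required.
#' @param groups_path Sample metadata TSV (`sample_id`, `group`). Required.
#' @param probe_map_path Optional probe-to-gene TSV.
#' @param survival_path Optional long-format survival TSV with columns
#'   `gene`, `patient_id`, `time_days`, `event`, `expression`.
#' @param gmt_path Optional GMT gene-set collection.
#' @param threshold Adjusted-p probe-selection cutoff (default 0.01).
#' @param alpha Survival-screen FDR cutoff (default 0.05).
#' @param pc Optional PC index override (default: automatic identification).
#' @param var_equal Pooled-variance t-test for PC identification.
#' @param survival_method `"logrank"` or `"cox"`.
#' @param strict_loocv Redo probe selection inside each LOOCV fold.
#' @param enrich_mode `"fisher"` or `"ease"`.
#' @param out_dir Output directory (created if missing).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_path, groups_path, probe_map_path = NULL,
                            survival_path = NULL, gmt_path = NULL,
                            threshold = 0.01, alpha = 0.05, pc = NULL,
                            var_equal = FALSE,
                            survival_method = c("logrank", "cox"),
                            strict_loocv = FALSE,
                            enrich_mode = c("fisher", "ease"),
                            out_dir = "pcafe_out") {
  survival_method <- match.arg(survival_method)
  enrich_mode <- match.arg(enrich_mode)
  for (p in c(matrix_path, groups_path, probe_map_path, survival_path, gmt_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  if (threshold <= 0 || threshold >= 1 || alpha <= 0 || alpha >= 1)
    stop("threshold and alpha must be in (0, 1)")
  structure(list(matrix_path = matrix_path, groups_path = groups_path,
                 probe_map_path = probe_map_path,
                 survival_path = survival_path, gmt_path = gmt_path,
                 threshold = threshold, alpha = alpha, pc = pc,
                 var_equal = var_equal, survival_method = survival_method,
                 strict_loocv = strict_loocv, enrich_mode = enrich_mode,
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full selection / discrimination / screening pipeline
#'
#' Executes: read + normalize expression, PCA-FE probe selection, LDA with
#' leave-one-out cross-validation on the reduced PC loading, probe-to-gene
#' mapping (if a map is given), per-gene survival screen (if a cohort table
#' is given), and gene-set enrichment of the surviving genes (if a GMT is
#' given). Every intermediate table is written to `cfg$out_dir` as TSV; a
#' machine-readable `summary.tsv` (key/value) and a plain-text run log
#' recording versions, parameters and the defaults in force are written too.
#'
#' @param cfg A `pipeline_config`.
#' @return A `pipeline_report` list with the in-memory stage results and the
#'   summary key/value data.frame.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("pcafe pipeline run")
  logf("R version: %s", R.version.string)
  logf("package version: %s", as.character(utils::packageVersion("pcafe")))
  for (nm in setdiff(names(cfg), "out_dir"))
    logf("config %s = %s", nm,
         if (is.null(cfg[[nm]])) "auto/none" else paste(cfg[[nm]], collapse = ","))

  stage <- "expression_io"
  report <- tryCatch({
    m <- read_expression(cfg$matrix_path)
    groups <- read_sample_groups(cfg$groups_path)
    groups <- sample_groups(groups[colnames(m)])
    mz <- normalize_samples(m)
    logf("loaded %d probes x %d samples; groups: %s", nrow(mz), ncol(mz),
         paste(sprintf("%s=%d", names(table(groups)), table(groups)),
               collapse = ", "))

    stage <- "select"
    sel <- select_probes(mz, groups, threshold = cfg$threshold, pc = cfg$pc,
                         var_equal = cfg$var_equal)
    write_tsv(sel$table, file.path(cfg$out_dir, "selection.tsv"))
    logf("discriminative PC %d (t-test p = %.4g), %d probes selected at adj p < %g",
         sel$pc_index, sel$pc_pvalues[sel$pc_index], sum(sel$table$selected),
         cfg$threshold)

    stage <- "classify"
    disc <- NULL
    if (sum(sel$table$selected) >= 2L) {
      if (cfg$strict_loocv) {
        disc <- lda_loocv_strict(mz, groups, threshold = cfg$threshold,
                                 pc = cfg$pc)
      } else {
        feat <- reduced_loading(mz, sel, pc_index = min(sel$pc_index, ncol(mz)))
        disc <- lda_loocv(feat, groups)
      }
      write_tsv(data.frame(sample_id = names(disc$predictions),
                           feature = disc$feature,
                           predicted = disc$predictions, truth = disc$truth),
                file.path(cfg$out_dir, "loocv.tsv"))
      logf("LOOCV accuracy %.3f (strict = %s, prior = %s)", disc$accuracy,
           cfg$strict_loocv, disc$prior)
    } else {
      logf("fewer than 2 probes selected; discrimination skipped")
    }

    stage <- "map_genes"
    genes <- NULL
    if (!is.null(cfg$probe_map_path)) {
      pmap <- read_probe_map(cfg$probe_map_path)
      mp <- map_probes(sel$table$probe_id[sel$table$selected], pmap)
      genes <- mp$genes
      write_tsv(data.frame(gene_symbol = genes),
                file.path(cfg$out_dir, "genes.tsv"))
      logf("%d genes mapped from %d selected probes (%d unmapped probes)",
           length(genes), sum(sel$table$selected), length(mp$unmapped))
    }

    stage <- "survival"
    surv <- NULL
    if (!is.null(cfg$survival_path)) {
      long <- utils::read.delim(cfg$survival_path, stringsAsFactors = FALSE)
      need <- c("gene", "patient_id", "time_days", "event", "expression")
      if (!all(need %in% colnames(long)))
        stop("survival table needs columns: ", paste(need, collapse = ", "))
      keep <- if (is.null(genes)) unique(long$gene) else intersect(unique(long$gene), genes)
      cohorts <- lapply(stats::setNames(keep, keep), function(g) {
        d <- long[long$gene == g, , drop = FALSE]
        survival_cohort(d$time_days, d$event, d$expression, d$patient_id)
      })
      surv <- screen_genes(cohorts, alpha = cfg$alpha,
                           method = cfg$survival_method)
      write_tsv(surv, file.path(cfg$out_dir, "survival_screen.tsv"))
      logf("survival screen (%s): %d genes, %d significant at FDR < %g",
           cfg$survival_method, nrow(surv), sum(surv$significant), cfg$alpha)
    }

    stage <- "enrich"
    enr <- NULL
    if (!is.null(cfg$gmt_path)) {
      qgenes <- if (!is.null(surv)) {
        sig <- surv$gene_symbol[surv$significant]
        if (length(sig) > 0L) sig else genes
      } else genes
      if (!is.null(qgenes) && length(qgenes) > 0L) {
        coll <- read_gmt(cfg$gmt_path)
        enr <- enrich(qgenes, coll, mode = cfg$enrich_mode)
        write_tsv(enr, file.path(cfg$out_dir, "enrichment.tsv"))
        logf("enrichment (%s): %d sets, %d at FDR < %g", cfg$enrich_mode,
             nrow(enr), sum(enr$fdr < cfg$alpha), cfg$alpha)
      }
    }

    summary_df <- data.frame(
      key = c("n_probes", "n_samples", "pc_index", "pc_pvalue",
              "n_selected", "loocv_accuracy", "n_genes_mapped",
              "n_survival_significant", "n_enriched_sets"),
      value = c(nrow(mz), ncol(mz), sel$pc_index,
                signif(sel$pc_pvalues[sel$pc_index], 6),
                sum(sel$table$selected),
                if (is.null(disc)) NA else signif(disc$accuracy, 6),
                if (is.null(genes)) NA else length(genes),
                if (is.null(surv)) NA else sum(surv$significant),
                if (is.null(enr)) NA else sum(enr$fdr < cfg$alpha)),
      stringsAsFactors = FALSE)
    write_tsv(summary_df, file.path(cfg$out_dir, "summary.tsv"))

    structure(list(selection = sel, discrimination = disc, genes = genes,
                   survival = surv, enrichment = enr, summary = summary_df,
                   out_dir = cfg$out_dir),
              class = "pipeline_report")
  }, error = function(e) {
    logf("ERROR in stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pcafe pipeline report (outputs in ", x$out_dir, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
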