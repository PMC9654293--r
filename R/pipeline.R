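#' Configuration of an end-to-end synthetic study run
#'
#' Bundles the stage parameters of [run_pipeline()]: phantom validation
#' (recovery of known areas from segmented phantoms), cohort simulation,
#' measurement quantification (gate, averaging, deltas), and the cohort
#' statistical battery.
#'
#' @param cohort a [cohort_spec()].
#' @param phantom a [phantom_spec()] used for the validation stage.
#' @param n_phantom_seeds noisy phantom replicates to segment.
#' @param phantom_noise_sd HU noise of the validation replicates.
#' @param gate_threshold reliability-gate Spearman threshold.
#' @param alpha significance level of the coincidence network.
#' @param confounders adjusted-model confounder columns.
#' @param outcomes mortality outcomes to model.
#' @param run_phantom,run_network stage toggles.
#' @param out_dir directory for result files (`NULL`: return results only).
#' @param seed master seed; overrides the cohort spec seed and derives the
#'   phantom noise seeds, so one integer reproduces the whole run.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       phantom = phantom_spec(),
                       n_phantom_seeds = 3L,
                       phantom_noise_sd = 10,
                       gate_threshold = 0.85,
                       alpha = 0.05,
                       confounders = c("age", "metastasis", "ecog",
                                       "ldh", "albumin", "urea"),
                       outcomes = c("overall", "tumor"),
                       run_phantom = TRUE,
                       run_network = TRUE,
                       out_dir = NULL,
                       seed = 1L) {
  structure(list(cohort = cohort, phantom = phantom,
                 n_phantom_seeds = as.integer(n_phantom_seeds),
                 phantom_noise_sd = phantom_noise_sd,
                 gate_threshold = gate_threshold, alpha = alpha,
                 confounders = confounders, outcomes = outcomes,
                 run_phantom = run_phantom, run_network = run_network,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full synthetic study
#'
#' Executes the stages in order — phantom validation, cohort simulation,
#' quantification (height normalization, reliability gate, rater averaging,
#' follow-up deltas, missingness filter), and the statistical battery
#' (survivor/non-survivor comparisons, Spearman matrix, coincidence
#' network, adjusted odds ratios) — and returns a machine-readable run
#' report with stage counts (the recruitment-flowchart analogue), the gate
#' report and dropped variables. Identical config and seed reproduce the
#' report and all result files exactly.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  report <- list(seed = config$seed)

  ## stage 1: phantom validation -------------------------------------------
  if (config$run_phantom) {
    spec0 <- config$phantom
    spec0$tissue_hu_sd <- 0
    ph0 <- generate_phantom(spec0)
    rec0 <- measure_slice(ph0$slice)
    zero_err <- max(abs(rec0$area_cm2 - ph0$truth))
    noisy_err <- if (config$n_phantom_seeds > 0) {
      errs <- vapply(seq_len(config$n_phantom_seeds), function(i) {
        sp <- config$phantom
        sp$tissue_hu_sd <- config$phantom_noise_sd
        sp$seed <- config$seed + i
        rec <- measure_slice(generate_phantom(sp)$slice)
        max(abs(rec$area_cm2 - ph0$truth) / ph0$truth) * 100
      }, numeric(1))
      mean(errs)
    } else NA_real_
    report$phantom <- list(zero_noise_max_abs_err_cm2 = zero_err,
                           noisy_mean_max_rel_err_pct = noisy_err,
                           truth = ph0$truth)
  }

  ## stage 2: simulate cohort ----------------------------------------------
  cspec <- config$cohort
  cspec$seed <- config$seed
  cohort <- generate_cohort(cspec)
  report$counts <- list(
    patients = nrow(cohort$patients),
    with_followup = sum(cohort$patients$has_followup),
    deceased = sum(cohort$patients$deceased))

  ## stage 3: quantification -----------------------------------------------
  q <- quantify_cohort(cohort$measures, cohort$patients,
                       gate_threshold = config$gate_threshold)
  report$gate <- q$gate
  report$counts$delta_patients <- if (is.null(q$delta)) 0L else nrow(q$delta)
  report$counts$delta_excluded <- nrow(q$excluded)

  filt <- missingness_filter(cohort$patients)
  report$dropped_variables <- filt$dropped
  patients <- filt$table

  analysis <- merge(patients, q$baseline, by = "patient_id")
  if (!is.null(q$delta))
    analysis <- merge(analysis, q$delta, by = "patient_id", all.x = TRUE)

  ## stage 4: statistics ---------------------------------------------------
  retained <- q$gate$measure[q$gate$retained]
  clin_vars <- intersect(c("age", "sex", "bmi", "weight_kg", "ecog",
                           "grade", "metastasis", "albumin", "ldh", "urea",
                           "glucose", "fibrinogen"), names(analysis))
  comp_vars <- intersect(retained, names(analysis))
  group_table <- group_compare_table(
    analysis, c(clin_vars, comp_vars),
    group = "deceased")

  corr <- spearman_matrix(
    analysis[, intersect(c("age", "bmi", "albumin", "ldh", "urea",
                           "glucose", "fibrinogen", comp_vars),
                         names(analysis))])

  network <- NULL
  if (config$run_network) {
    dich_vars <- analysis[, intersect(c("age", "bmi", "albumin", "ldh",
                                        "urea", comp_vars),
                                      names(analysis))]
    dich <- dichotomize(dich_vars)
    ind <- dich$indicators
    ind[["deceased"]] <- analysis$deceased == 1
    ind[["survivor"]] <- analysis$deceased == 0
    network <- build_coincidence_network(ind, alpha = config$alpha)
  }

  ors <- list()
  delta_cols <- grep("^delta_", names(analysis), value = TRUE)
  delta_cols <- delta_cols[sub("^delta_", "", delta_cols) %in% retained]
  for (oc in config$outcomes) {
    for (m in comp_vars)
      ors[[paste(oc, m)]] <- suppressWarnings(
        adjusted_logistic(analysis, m, oc, config$confounders))
    for (m in delta_cols)
      ors[[paste(oc, m)]] <- suppressWarnings(
        adjusted_logistic(analysis, m, oc, config$confounders))
  }
  or_table <- do.call(rbind, c(ors, make.row.names = FALSE))

  report$results <- list(group_table = group_table, spearman = corr,
                         network = network, odds_ratios = or_table,
                         analysis_table = analysis)
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(config$out_dir)) .write_run_outputs(report, q, cohort, config)
  class(report) <- "run_report"
  report
}

.write_run_outputs <- function(report, q, cohort, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(config$out_dir, f),
                                       row.names = FALSE, na = "")
  write_cohort(cohort, file.path(config$out_dir, "cohort"))
  w(report$results$group_table, "group_tests.csv")
  w(report$gate, "gate_report.csv")
  w(report$results$odds_ratios, "adjusted_odds_ratios.csv")
  w(report$results$analysis_table, "analysis_table.csv")
  rho <- report$results$spearman$rho
  utils::write.csv(rho, file.path(config$out_dir, "spearman_rho.csv"))
  if (!is.null(report$results$network)) {
    w(report$results$network$edges, "network_edges.csv")
    igraph::write_graph(report$results$network$graph,
                        file.path(config$out_dir, "network.graphml"),
                        format = "graphml")
  }
  summary <- list(seed = report$seed, counts = report$counts,
                  dropped_variables = report$dropped_variables,
                  phantom = report$phantom[c("zero_noise_max_abs_err_cm2",
                                             "noisy_mean_max_rel_err_pct")])
  jsonlite::write_json(summary, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  patients %d | follow-up %d | deceased %d | deltas %d\n",
              x$counts$patients, x$counts$with_followup, x$counts$deceased,
              x$counts$delta_patients))
  if (!is.null(x$phantom))
    cat(sprintf("  phantom: zero-noise max err %.4g cm2, noisy mean max rel err %.2f%%\n",
                x$phantom$zero_noise_max_abs_err_cm2,
                x$phantom$noisy_mean_max_rel_err_pct))
  dropped <- x$gate$measure[!x$gate$retained]
  cat(sprintf("  gate: dropped %s\n",
              if (length(dropped)) paste(dropped, collapse = ", ") else "none"))
  invisible(x)
}
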