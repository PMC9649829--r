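# Pipeline driver: simulate (or read) -> sleep metrics -> derived FA ->
# covariate-adjusted univariate statistics with FDR -> group-wise PLS-C,
# with exclusion accounting, seeded determinism, and a machine-readable report.

sleep_measure_names <- function() c("dsi", "awi", "tst", "se", "sfi", "waso")

#' Pipeline configuration
#'
#' @param sim A [cohort_config()] describing the synthetic cohort to generate,
#'   or `NULL` when reading an existing cohort from `input_dir`.
#' @param input_dir Directory holding `covariates.csv`, `roi_fa.csv`,
#'   `ksq.csv`, `diary.csv`, `actigraphy.csv` (as written by [write_cohort()]);
#'   ignored when `sim` is given.
#' @param period Questionnaire recall period used for DSI/AWI
#'   (default `"last_4_weeks"`).
#' @param n_perm,n_boot PLS-C iteration counts.
#' @param B Bootstrap resamples for the univariate partial correlations.
#' @param seed Master integer seed for every stochastic stage.
#' @param confounder_sets Named list of character vectors; each entry is a set
#'   of extra covariate columns (beyond age, sex, motion) for which the partial
#'   correlations and PLS-C are rerun. The default runs the base model only.
#' @param antipsychotic_free If `TRUE`, run a sensitivity analysis excluding
#'   patients on antipsychotic medication.
#' @param out_dir Optional output directory for the report files.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = cohort_config(), input_dir = NULL,
                            period = c("last_4_weeks", "last_night"),
                            n_perm = 1000, n_boot = 1000, B = 1000,
                            seed = 1L, confounder_sets = list(none = character(0)),
                            antipsychotic_free = FALSE, out_dir = NULL) {
  period <- match.arg(period)
  if (is.null(sim) && is.null(input_dir))
    stop("either 'sim' or 'input_dir' must be given")
  if (!is.null(sim) && !inherits(sim, "cohort_config"))
    stop("'sim' must be a cohort_config")
  if (!is.null(input_dir) && is.null(sim) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  if (is.null(names(confounder_sets)))
    stop("'confounder_sets' must be a named list")
  structure(list(sim = sim, input_dir = input_dir, period = period,
                 n_perm = n_perm, n_boot = n_boot, B = B,
                 seed = as.integer(seed), confounder_sets = confounder_sets,
                 antipsychotic_free = antipsychotic_free, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a cohort from delimited-text files
#'
#' Reads the file layout written by [write_cohort()] and reassembles the
#' per-subject actigraphy recordings. Schema violations are reported with the
#' file and missing column names.
#'
#' @param dir Directory holding the cohort csv files.
#' @return A list with `covariates`, `roi_fa`, `ksq`, `diary`, `actigraphy`
#'   (named list of [actigraphy_recording()]s).
#' @export
read_cohort <- function(dir) {
  need_file <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input file: ", path)
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  need_cols <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0)
      stop(file, " is missing required column(s): ",
           paste(miss, collapse = ", "))
    df
  }
  covariates <- need_cols(need_file("covariates.csv"),
                          c("subject_id", "group", "age", "sex",
                            "abs_motion", "rel_motion"), "covariates.csv")
  roi_fa <- validate_roi_table(need_file("roi_fa.csv"))
  ksq <- need_cols(need_file("ksq.csv"),
                   c("subject_id", "period", ksq_item_names()), "ksq.csv")
  diary <- need_cols(need_file("diary.csv"),
                     c("subject_id", "bed_time", "rise_time"), "diary.csv")
  acti_long <- need_cols(need_file("actigraphy.csv"),
                         c("subject_id", "timestamp", "counts"),
                         "actigraphy.csv")
  actigraphy <- lapply(diary$subject_id, function(id) {
    rows <- acti_long[acti_long$subject_id == id, ]
    if (nrow(rows) == 0) stop("actigraphy.csv has no epochs for subject ", id)
    d <- diary[diary$subject_id == id, ]
    actigraphy_recording(as.POSIXct(rows$timestamp, tz = "UTC",
                                    format = "%Y-%m-%dT%H:%M:%SZ"),
                         rows$counts,
                         rest_interval(as.POSIXct(d$bed_time, tz = "UTC",
                                                  format = "%Y-%m-%dT%H:%M:%SZ"),
                                       as.POSIXct(d$rise_time, tz = "UTC",
                                                  format = "%Y-%m-%dT%H:%M:%SZ")))
  })
  names(actigraphy) <- diary$subject_id
  list(covariates = covariates, roi_fa = roi_fa, ksq = ksq, diary = diary,
       actigraphy = actigraphy)
}

# per-subject sleep table: questionnaire indices for the chosen period plus
# actigraphy summary measures
.sleep_table <- function(cohort, period) {
  idx <- sleep_indices(cohort$ksq)
  idx <- idx[idx$period == period, c("subject_id", "dsi", "awi")]
  acti <- do.call(rbind, lapply(names(cohort$actigraphy), function(id) {
    s <- actigraphy_summary(cohort$actigraphy[[id]])
    data.frame(subject_id = id, tst = s$tst, se = s$se,
               sfi = ifelse(is.na(s$sfi), NA_real_, s$sfi), waso = s$waso,
               no_sleep = s$no_sleep, stringsAsFactors = FALSE)
  }))
  merge(idx, acti, by = "subject_id", sort = TRUE)
}

# univariate partial-correlation family for one cohort subset:
# 2 FA summaries x 6 sleep measures, BH-corrected as one family
.univariate_family <- function(tab, analysis, covariate_cols, B, seed) {
  combos <- expand.grid(x = c("global_fa", "callosal_fa"),
                        y = sleep_measure_names(), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    pc <- partial_correlation(tab[[combos$x[i]]], tab[[combos$y[i]]],
                              covariates = tab[, covariate_cols, drop = FALSE],
                              B = B, seed = seed + i)
    data.frame(analysis = analysis, x = combos$x[i], y = combos$y[i],
               n = pc$n, r = pc$r, p = pc$p_value,
               ci_lower = pc$ci[1], ci_upper = pc$ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p)
  out
}

# slim JSON-friendly view of a plsc_result
.plsc_report <- function(res) {
  list(singular_values = res$singular_values,
       inertia = res$inertia,
       cov_explained = res$cov_explained,
       omnibus_p = res$omnibus_p,
       lv_p = res$lv_p,
       reportable = res$reportable,
       n = res$n,
       y_saliences = apply(res$y_saliences, 2, identity, simplify = FALSE),
       y_reliable = apply(res$boot$y_reliable, 2, identity, simplify = FALSE),
       x_reliable_labels = lapply(seq_len(ncol(res$x_saliences)), function(k)
         rownames(res$x_saliences)[res$boot$x_reliable[, k]]))
}

#' Run the full analysis pipeline
#'
#' Sequences cohort generation (or loading), sleep-metric computation, FA
#' aggregation, covariate-adjusted univariate statistics with FDR control,
#' and the group-wise PLS-C, with listwise exclusion accounting and one master
#' seed. Every excluded subject is attributed to a named rule, and subject
#' counts entering each analysis equal the cohort size minus its exclusions.
#'
#' @param cfg A [pipeline_config()].
#' @return Object of class `run_report`: list with `provenance`, `counts`,
#'   `exclusions`, `sleep_summary`, `derived_fa`, `group_tests`, `univariate`
#'   (per confounder set), `plsc` (per confounder set), and `tables_dir`
#'   (when files were written).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop("'cfg' must be a pipeline_config")
  cohort <- if (!is.null(cfg$sim)) generate_cohort(cfg$sim)
            else read_cohort(cfg$input_dir)
  covars <- cohort$covariates
  n_total <- nrow(covars)
  sleep <- .sleep_table(cohort, cfg$period)
  derived <- derive_fa(cohort$roi_fa)
  tab <- merge(merge(covars, derived, by = "subject_id"), sleep,
               by = "subject_id", sort = TRUE)
  # exclusion accounting (listwise, attributed to named rules)
  excl <- data.frame(subject_id = character(0), rule = character(0),
                     stringsAsFactors = FALSE)
  flag <- function(mask, rule) {
    ids <- setdiff(tab$subject_id[mask], excl$subject_id)
    if (length(ids) > 0)
      excl <<- rbind(excl, data.frame(subject_id = ids, rule = rule,
                                      stringsAsFactors = FALSE))
  }
  flag(is.na(tab$dsi) | is.na(tab$awi), "missing_questionnaire_item")
  flag(tab$no_sleep | is.na(tab$sfi), "no_scored_sleep")
  if (cfg$antipsychotic_free && "antipsychotics" %in% names(tab))
    flag(tab$group == "patient" & tab$antipsychotics == 1,
         "antipsychotic_sensitivity_filter")
  analysis_tab <- tab[!tab$subject_id %in% excl$subject_id, ]
  stopifnot(nrow(analysis_tab) == n_total - nrow(excl))
  base_cov <- c("age", "sex", "abs_motion", "rel_motion")
  # covariate-adjusted group tests on the FA summaries and sleep indices
  group_tests <- do.call(rbind, lapply(
    c("global_fa", "callosal_fa", "dsi", "awi"), function(v) {
      gt <- glm_group_test(analysis_tab[[v]], analysis_tab$group,
                           analysis_tab[, base_cov])
      data.frame(outcome = v, f_stat = gt$f_stat, df_num = gt$df_num,
                 df_den = gt$df_den, p = gt$p_value,
                 mean_control = gt$adjusted_means[["control"]],
                 mean_patient = gt$adjusted_means[["patient"]],
                 stringsAsFactors = FALSE)
    }))
  roi_cols <- setdiff(names(cohort$roi_fa), "subject_id")
  univariate <- list(); plsc_res <- list()
  for (set_name in names(cfg$confounder_sets)) {
    extra <- cfg$confounder_sets[[set_name]]
    miss <- setdiff(extra, names(analysis_tab))
    if (length(miss) > 0)
      stop("confounder set '", set_name, "' names unknown column(s): ",
           paste(miss, collapse = ", "))
    cov_cols <- c(base_cov, extra)
    fam <- rbind(
      .univariate_family(analysis_tab, "ALL", cov_cols, cfg$B, cfg$seed),
      .univariate_family(analysis_tab[analysis_tab$group == "patient", ],
                         "patient", cov_cols, cfg$B, cfg$seed + 100),
      .univariate_family(analysis_tab[analysis_tab$group == "control", ],
                         "control", cov_cols, cfg$B, cfg$seed + 200))
    fam$confounder_set <- set_name
    univariate[[set_name]] <- fam
    roi_match <- match(analysis_tab$subject_id, cohort$roi_fa$subject_id)
    gw <- groupwise_plsc(
      as.matrix(cohort$roi_fa[roi_match, roi_cols]),
      as.matrix(analysis_tab[, sleep_measure_names()]),
      groups = analysis_tab$group,
      covariates = analysis_tab[, cov_cols],
      n_perm = cfg$n_perm, n_boot = cfg$n_boot, seed = cfg$seed + 300)
    plsc_res[[set_name]] <- list(
      contrast_stat = gw$contrast_stat, contrast_p = gw$contrast_p,
      within = lapply(gw$within, .plsc_report))
  }
  report <- structure(list(
    provenance = list(
      package = "sleepwm",
      version = as.character(utils::packageVersion("sleepwm")),
      seed = cfg$seed, n_perm = cfg$n_perm, n_boot = cfg$n_boot, B = cfg$B,
      period = cfg$period,
      simulated = !is.null(cfg$sim),
      sim_seed = if (!is.null(cfg$sim)) cfg$sim$seed else NULL,
      confounder_sets = cfg$confounder_sets,
      antipsychotic_free = cfg$antipsychotic_free),
    counts = list(total = n_total, excluded = nrow(excl),
                  analyzed = nrow(analysis_tab),
                  by_group = as.list(table(analysis_tab$group))),
    exclusions = excl,
    sleep_summary = sleep,
    derived_fa = derived,
    group_tests = group_tests,
    univariate = do.call(rbind, univariate),
    plsc = plsc_res), class = "run_report")
  rownames(report$univariate) <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sleep, file.path(cfg$out_dir, "sleep_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(derived, file.path(cfg$out_dir, "derived_fa.csv"),
                     row.names = FALSE)
    utils::write.table(report$univariate,
                       file.path(cfg$out_dir, "univariate_results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(excl, file.path(cfg$out_dir, "exclusions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(plsc_res, file.path(cfg$out_dir, "plsc_result.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      lapply(report[c("provenance", "counts")], identity),
      file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    report$tables_dir <- cfg$out_dir
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline report (seed %d): %d subjects, %d excluded, %d analyzed\n",
              x$provenance$seed, x$counts$total, x$counts$excluded,
              x$counts$analyzed))
  cat("\nGroup tests (covariate-adjusted):\n")
  print(transform(x$group_tests, f_stat = round(f_stat, 2), p = signif(p, 3),
                  mean_control = round(mean_control, 3),
                  mean_patient = round(mean_patient, 3)), row.names = FALSE)
  sig <- x$univariate[x$univariate$p_adj < 0.05, ]
  cat(sprintf("\nPartial correlations: %d of %d pass BH FDR at 0.05\n",
              nrow(sig), nrow(x$univariate)))
  if (nrow(sig) > 0)
    print(data.frame(sig[, c("confounder_set", "analysis", "x", "y")],
                     r = round(sig$r, 3), p_adj = signif(sig$p_adj, 3)),
          row.names = FALSE)
  for (set_name in names(x$plsc)) {
    p <- x$plsc[[set_name]]
    cat(sprintf("\nPLS-C [%s]: group-contrast p = %.4g; omnibus p by group: %s\n",
                set_name, p$contrast_p,
                paste(sprintf("%s = %.4g", names(p$within),
                              vapply(p$within, `[[`, 0, "omnibus_p")),
                      collapse = ", ")))
  }
  invisible(x)
}
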