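# Synthetic two-group cohort generator.
#
# Emulates the measured quantities the analysis consumes: a patients/controls
# covariate table (age, sex, scanner motion, clinical scores, medication),
# a subjects x 48 ROI FA table, Karolinska questionnaire items for two recall
# periods, and a 24-h 1-min-epoch actigraphy recording per subject with a
# diary-defined rest interval. A single zero-mean latent "sleep disturbance"
# score z per subject couples a sparse subset of ROI FA columns
# (latent_loadings_x, FA units per latent SD) to the sleep measures
# (latent_loadings_y, natural units per latent SD): z enters the questionnaire
# through a latent-Gaussian ordinal (probit-style) item model and the
# actigraphy through the wake-bout propensity of a two-state Markov bout
# process. The patient group additionally shifts the questionnaire channel
# only (latent_group_shift), so the subjective indices separate by group while
# the objective actigraphy measures do not. Setting both loading vectors to
# zero yields a null cohort with no X-Y association beyond covariates.

# fixed per-ROI FA baselines in (0.4, 0.8); callosal segments pinned near
# the magnitudes typical of skeletonized callosal FA
.default_fa_baseline <- function(roi_labels) {
  # fixed internal stream: baselines are config constants, not draws, and the
  # caller's RNG state must not be disturbed
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(48151)
  base <- stats::setNames(stats::runif(length(roi_labels), 0.45, 0.75),
                          roi_labels)
  cc <- intersect(callosal_labels(), roi_labels)
  base[cc] <- c(0.755, 0.740, 0.750)[seq_along(cc)]
  base
}

.default_loadings_x <- function(roi_labels) {
  lx <- stats::setNames(rep(0, length(roi_labels)), roi_labels)
  up <- "Fornix (column and body of fornix)"
  down <- c("Corticospinal tract R", "Corticospinal tract L",
            "Cerebral peduncle L", "Medial lemniscus L",
            "Cingulum (hippocampus) L")
  lx[intersect(up, roi_labels)] <- 0.015
  lx[intersect(down, roi_labels)] <- -0.015
  lx
}

#' Synthetic cohort configuration
#'
#' Bundles every parameter of the synthetic-cohort generator. Defaults emulate
#' the study conditions the package targets: 64 patients vs 35 controls, a
#' 0.013 FA-unit global deficit in patients, covariate effects on FA, and a
#' planted latent dimension linking a sparse ventral ROI subset to the six
#' sleep measures (DSI, AWI, TST, SE, SFI, WASO).
#'
#' @param n_patients,n_controls Group sizes (each at least 2).
#' @param roi_labels Character vector of 48 unique atlas labels; must contain
#'   the three callosal segment labels.
#' @param group_fa_deficit Mean FA reduction applied to patient ROI means
#'   (FA units).
#' @param covariate_betas Named numeric vector of slopes of FA on the centered
#'   covariates `age`, `sex`, `abs_motion`, `rel_motion` (FA units per
#'   covariate unit).
#' @param latent_loadings_x Length-48 named vector, FA units per latent SD
#'   (sparse: nonzero on the planted ROI subset).
#' @param latent_loadings_y Length-6 named vector over
#'   `dsi, awi, tst, se, sfi, waso`, each on its measure's natural scale per
#'   latent SD. The questionnaire couples through `dsi`/`awi`; the actigraphy
#'   couples through `waso` (wake-bout propensity `z * waso / 20`), with the
#'   TST/SE/SFI loadings emergent from the same bout process.
#' @param latent_sd Standard deviation of the zero-mean latent score z.
#' @param latent_group_shift Additive patient shift on the subjective
#'   (questionnaire) disturbance channel, in latent-SD units; drives the
#'   DSI/AWI group difference without separating the actigraphy measures.
#' @param noise_sd_fa Per-ROI Gaussian FA noise SD (FA units).
#' @param subject_sd_fa SD of a per-subject global FA offset shared by all 48
#'   ROIs (FA units); reproduces the between-subject spread of global mean FA
#'   (about 0.012-0.016 in such cohorts) that per-ROI noise alone cannot.
#' @param fa_baseline Named per-ROI baseline FA (defaults fixed in (0.4, 0.8)).
#' @param item_thresholds Increasing vector of 4 ordinal cut-points shared by
#'   the questionnaire items.
#' @param prop_missing_items Probability that any single questionnaire item is
#'   missing (drives listwise exclusion downstream).
#' @param seed Master integer seed.
#' @return Object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_patients = 64, n_controls = 35,
                          roi_labels = jhu_labels(),
                          group_fa_deficit = 0.013,
                          covariate_betas = c(age = -0.0008, sex = 0.004,
                                              abs_motion = -0.004,
                                              rel_motion = -0.02),
                          latent_loadings_x = .default_loadings_x(roi_labels),
                          latent_loadings_y = c(dsi = 3, awi = 2.5, tst = -25,
                                                se = -4, sfi = 8, waso = 20),
                          latent_sd = 1, latent_group_shift = 1,
                          noise_sd_fa = 0.01, subject_sd_fa = 0.012,
                          fa_baseline = .default_fa_baseline(roi_labels),
                          item_thresholds = c(-0.7, 0.3, 1.3, 2.3),
                          prop_missing_items = 0.02,
                          seed = 1L) {
  if (n_patients < 2 || n_controls < 2)
    stop("n_patients and n_controls must each be at least 2")
  if (length(roi_labels) != 48 || anyDuplicated(roi_labels))
    stop("roi_labels must be 48 unique labels")
  if (!all(callosal_labels() %in% roi_labels))
    stop("roi_labels must contain the genu, body and splenium callosal labels")
  need <- c("age", "sex", "abs_motion", "rel_motion")
  if (!all(need %in% names(covariate_betas)))
    stop("covariate_betas must name ", paste(need, collapse = ", "))
  if (length(latent_loadings_x) != 48)
    stop("latent_loadings_x must have length 48")
  if (is.null(names(latent_loadings_x)))
    names(latent_loadings_x) <- roi_labels
  ymeas <- c("dsi", "awi", "tst", "se", "sfi", "waso")
  if (length(latent_loadings_y) != 6 ||
      !all(ymeas %in% names(latent_loadings_y)))
    stop("latent_loadings_y must be a length-6 vector named ",
         paste(ymeas, collapse = ", "))
  if (length(item_thresholds) != 4 || any(diff(item_thresholds) <= 0))
    stop("item_thresholds must be 4 strictly increasing cut-points")
  if (latent_sd < 0 || noise_sd_fa <= 0 || subject_sd_fa < 0)
    stop("latent_sd and subject_sd_fa must be >= 0 and noise_sd_fa > 0")
  if (!all(names(fa_baseline) == roi_labels))
    fa_baseline <- fa_baseline[roi_labels]
  if (anyNA(fa_baseline) || any(fa_baseline <= 0 | fa_baseline >= 1))
    stop("fa_baseline must give every ROI a value in (0, 1)")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    roi_labels = roi_labels, group_fa_deficit = group_fa_deficit,
    covariate_betas = covariate_betas,
    latent_loadings_x = latent_loadings_x[roi_labels],
    latent_loadings_y = latent_loadings_y[ymeas],
    latent_sd = latent_sd, latent_group_shift = latent_group_shift,
    noise_sd_fa = noise_sd_fa, subject_sd_fa = subject_sd_fa,
    fa_baseline = fa_baseline,
    item_thresholds = item_thresholds,
    prop_missing_items = prop_missing_items, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Generate one questionnaire response from a latent score
#'
#' Latent-Gaussian (probit-style) ordinal model: for each item, a latent
#' utility `slope * latent_score + N(0, 1)` is cut at the four thresholds to
#' give a response in 1-5. Expected item scores are monotone in the latent
#' score; as the latent score grows large every item saturates at 5 (and at 1
#' for large negative scores).
#'
#' @param latent_score Scalar latent sleep-disturbance score.
#' @param item_thresholds Increasing vector of 4 cut-points (shared across
#'   items) or a 7 x 4 matrix of per-item cut-points.
#' @param item_slopes Length-7 non-negative slopes of the items (a-g) on the
#'   latent score (default all 1).
#' @param seed Optional integer seed.
#' @return Named integer vector `item_a` ... `item_g`, each in 1..5.
#' @export
generate_questionnaire <- function(latent_score, item_thresholds,
                                   item_slopes = rep(1, 7), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(item_thresholds)) {
    if (!all(dim(item_thresholds) == c(7, 4)))
      stop("matrix item_thresholds must be 7 x 4")
    thr <- item_thresholds
  } else {
    if (length(item_thresholds) != 4)
      stop("item_thresholds must give 4 cut-points per item")
    thr <- matrix(item_thresholds, nrow = 7, ncol = 4, byrow = TRUE)
  }
  if (any(apply(thr, 1, function(r) any(diff(r) <= 0))))
    stop("item_thresholds must be strictly increasing")
  if (length(item_slopes) != 7 || any(item_slopes < 0))
    stop("item_slopes must be 7 non-negative values")
  u <- item_slopes * latent_score + stats::rnorm(7)
  items <- 1L + vapply(1:7, function(i) sum(u[i] > thr[i, ]), integer(1))
  stats::setNames(items, ksq_item_names())
}

#' Generate a 24-h actigraphy recording from a latent score
#'
#' Two-state (sleep/wake) first-order Markov bout process on the in-bed
#' 1-min epochs, modulating Poisson activity counts. The latent score raises
#' the wake-bout propensity: the sleep-to-wake hazard, the wake-to-sleep
#' persistence, the chance of starting the night awake, and the residual
#' movement rate during sleep all shift with it, so WASO and fragmentation
#' increase stochastically in the latent score. Out-of-bed epochs carry
#' daytime-level counts. The recording spans 24 h of 1-min epochs starting
#' 11 h before bed time.
#'
#' @param latent_score Scalar wake-propensity score (0 = typical night).
#' @param diary A [rest_interval()]; the rise time must be within 13 h of bed
#'   time so the recording covers the night.
#' @param seed Optional integer seed.
#' @return An [actigraphy_recording()].
#' @export
generate_actigraphy <- function(latent_score, diary, seed = NULL) {
  if (!inherits(diary, "rest_interval")) stop("'diary' must be a rest_interval")
  if (!is.null(seed)) set.seed(seed)
  tib <- floor((as.numeric(diary$rise_time) - as.numeric(diary$bed_time)) / 60)
  if (tib < 1) stop("empty rest interval")
  if (tib > 780) stop("rest interval longer than 13 h is not supported")
  w <- latent_score
  p_sw <- stats::plogis(-5.1 + 0.5 * w)      # sleep -> wake hazard per min
  p_ws <- stats::plogis(-2.44 - 0.25 * w)    # wake -> sleep hazard per min
  p_wake0 <- stats::plogis(1.0 + 0.5 * w)    # start the night awake (latency)
  lambda_wake <- 60                          # counts/min in nocturnal wake
  lambda_sleep <- stats::plogis(w)           # residual movement during sleep
  lambda_day <- 250                          # counts/min out of bed
  awake <- logical(tib)
  awake[1] <- stats::runif(1) < p_wake0
  flips <- stats::runif(tib)
  for (t in seq_len(tib - 1)) {
    awake[t + 1] <- if (awake[t]) flips[t] >= p_ws else flips[t] < p_sw
  }
  in_bed_counts <- ifelse(awake,
                          stats::rpois(tib, lambda_wake),
                          stats::rpois(tib, lambda_sleep))
  start <- diary$bed_time - 660 * 60          # 11 h before bed
  epoch_start <- start + 60 * (seq_len(1440) - 1)
  counts <- stats::rpois(1440, lambda_day)
  idx <- 660 + seq_len(tib)                   # epochs with start in [bed, rise)
  counts[idx] <- in_bed_counts
  # post-rise epochs of the same day revert to daytime counts (already drawn)
  actigraphy_recording(epoch_start, counts, diary)
}

#' Generate a complete synthetic cohort
#'
#' Draws, per subject, the covariates, a latent sleep-disturbance score z,
#' the 48-ROI FA row (baseline + group deficit + covariate effects +
#' `latent_loadings_x * z` + Gaussian noise, reject-and-resampled into (0, 1)),
#' questionnaire responses for both recall periods, a sleep diary, and a 24-h
#' actigraphy recording. Each subject has an independent seeded random stream
#' derived from the master seed, so regeneration with the same config is
#' bit-for-bit identical regardless of order.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `config`,
#'   `covariates` (incl. clinical scores and medication flags), `roi_fa`,
#'   `ksq` (two rows per subject), `diary`, `actigraphy` (named list of
#'   recordings), and `latent` (the true z per subject, for recovery tests).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("'config' must be a cohort_config")
  n <- config$n_patients + config$n_controls
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("S%03d", seq_len(n))
  is_pat <- c(rep(TRUE, config$n_patients), rep(FALSE, config$n_controls))
  Ly <- config$latent_loadings_y
  slopes <- c(rep(Ly[["dsi"]] / 4, 4), rep(Ly[["awi"]] / 3, 3))
  if (any(slopes < 0)) stop("dsi/awi loadings must be non-negative")
  base_date <- as.POSIXct("2014-06-02 00:00:00", tz = "UTC")
  cov_rows <- vector("list", n); fa_rows <- vector("list", n)
  ksq_rows <- vector("list", n); diary_rows <- vector("list", n)
  acti <- vector("list", n); z_all <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    pat <- is_pat[i]
    age <- round(stats::rnorm(1, ifelse(pat, 23.6, 23.7),
                              ifelse(pat, 3.9, 2.7)), 1)
    age <- max(age, 18)
    sex <- as.integer(stats::runif(1) < ifelse(pat, 0.578, 0.40))  # 1 = male
    abs_motion <- max(stats::rnorm(1, ifelse(pat, 1.26, 1.23), 0.35), 0.2)
    rel_motion <- max(stats::rnorm(1, ifelse(pat, 0.178, 0.159), 0.07), 0.02)
    z <- stats::rnorm(1, 0, config$latent_sd)
    z_all[i] <- z
    zq <- z + config$latent_group_shift * pat   # subjective channel
    madrs <- max(0, round(stats::rnorm(1, ifelse(pat, 14, 2) + 2 * zq, 3)))
    caarms <- if (pat) max(0, round(stats::rnorm(1, 50 + 3 * zq, 15))) else 0
    antipsychotics <- as.integer(pat && stats::runif(1) < 0.30)
    sleep_medication <- as.integer(stats::runif(1) < ifelse(pat, 0.11, 0.03))
    substance_use <- stats::rpois(1, ifelse(pat, 6, 3))
    # ROI FA row: reject-and-resample the noise until all values are in (0,1)
    mu <- config$fa_baseline -
      config$group_fa_deficit * pat +
      config$covariate_betas[["age"]] * (age - 24) +
      config$covariate_betas[["sex"]] * (sex - 0.5) +
      config$covariate_betas[["abs_motion"]] * (abs_motion - 1.24) +
      config$covariate_betas[["rel_motion"]] * (rel_motion - 0.17) +
      config$latent_loadings_x * z +
      stats::rnorm(1, 0, config$subject_sd_fa)   # shared global FA offset
    fa <- NULL
    for (try in 1:100) {
      cand <- mu + stats::rnorm(48, 0, config$noise_sd_fa)
      if (all(cand > 0 & cand < 1)) { fa <- cand; break }
    }
    if (is.null(fa))
      stop("could not draw an FA row inside (0, 1); check config scales")
    # questionnaire: 4-week latent is zq; last night adds night-to-night noise
    z_night <- zq + stats::rnorm(1, 0, 0.5)
    resp <- lapply(c(last_4_weeks = zq, last_night = z_night), function(zz)
      generate_questionnaire(zz, config$item_thresholds, item_slopes = slopes))
    if (config$prop_missing_items > 0) {
      for (pd in names(resp)) {
        drop <- stats::runif(7) < config$prop_missing_items
        resp[[pd]][drop] <- NA_integer_
      }
    }
    # diary and actigraphy
    bed <- base_date + 23 * 3600 + 60 * round(stats::rnorm(1, 0, 30))
    tib_min <- min(max(round(stats::rnorm(1, 480, 40)), 300), 700)
    diary <- rest_interval(bed, bed + 60 * tib_min)
    acti[[i]] <- generate_actigraphy(z * Ly[["waso"]] / 20, diary)
    cov_rows[[i]] <- data.frame(
      subject_id = ids[i], group = ifelse(pat, "patient", "control"),
      age = age, sex = sex, abs_motion = abs_motion, rel_motion = rel_motion,
      madrs = madrs, caarms = caarms, antipsychotics = antipsychotics,
      sleep_medication = sleep_medication, substance_use = substance_use,
      stringsAsFactors = FALSE)
    fa_rows[[i]] <- data.frame(subject_id = ids[i], t(fa),
                               check.names = FALSE, stringsAsFactors = FALSE)
    ksq_rows[[i]] <- do.call(rbind, lapply(names(resp), function(pd)
      data.frame(subject_id = ids[i], period = pd, t(resp[[pd]]),
                 check.names = FALSE, stringsAsFactors = FALSE)))
    diary_rows[[i]] <- data.frame(
      subject_id = ids[i],
      bed_time = format(diary$bed_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      rise_time = format(diary$rise_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      stringsAsFactors = FALSE)
  }
  roi_fa <- do.call(rbind, fa_rows)
  names(roi_fa) <- c("subject_id", config$roi_labels)
  names(acti) <- ids
  structure(list(
    config = config,
    covariates = do.call(rbind, cov_rows),
    roi_fa = roi_fa,
    ksq = do.call(rbind, ksq_rows),
    diary = do.call(rbind, diary_rows),
    actigraphy = acti,
    latent = data.frame(subject_id = ids, z = z_all,
                        stringsAsFactors = FALSE)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients + %d controls (seed %d)\n",
              x$config$n_patients, x$config$n_controls, x$config$seed))
  cat(sprintf("  planted X loadings on %d/48 ROIs; latent SD %.2f\n",
              sum(x$config$latent_loadings_x != 0), x$config$latent_sd))
  invisible(x)
}

#' Write a synthetic cohort to delimited-text files
#'
#' Writes `covariates.csv`, `roi_fa.csv`, `ksq.csv`, `diary.csv`,
#' `actigraphy.csv` (long: subject, timestamp, counts) and `truth.json`
#' (planted parameters and true latent scores) into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) stop("not a synthetic_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("covariates.csv", "roi_fa.csv", "ksq.csv",
                            "diary.csv", "actigraphy.csv", "truth.json"))
  utils::write.csv(cohort$covariates, paths[1], row.names = FALSE)
  utils::write.csv(cohort$roi_fa, paths[2], row.names = FALSE)
  utils::write.csv(cohort$ksq, paths[3], row.names = FALSE)
  utils::write.csv(cohort$diary, paths[4], row.names = FALSE)
  long <- do.call(rbind, lapply(names(cohort$actigraphy), function(id) {
    rec <- cohort$actigraphy[[id]]
    data.frame(subject_id = id,
               timestamp = format(rec$epoch_start, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               counts = rec$counts, stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, paths[5], row.names = FALSE)
  truth <- list(
    seed = cohort$config$seed,
    group_fa_deficit = cohort$config$group_fa_deficit,
    latent_loadings_x = as.list(cohort$config$latent_loadings_x),
    latent_loadings_y = as.list(cohort$config$latent_loadings_y),
    latent_sd = cohort$config$latent_sd,
    latent_group_shift = cohort$config$latent_group_shift,
    noise_sd_fa = cohort$config$noise_sd_fa,
    latent_scores = stats::setNames(as.list(cohort$latent$z),
                                    cohort$latent$subject_id))
  jsonlite::write_json(truth, paths[6], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
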