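# Actigraphy: 1-min epoch activity counts, Cole-Kripke sleep/wake scoring
# within a diary-defined rest interval, and summary sleep measures
# (TST, WASO, SE, MI, FI, SFI).
#
# Epoch convention: each epoch is the half-open minute [t, t + 60 s); an epoch
# belongs to the rest interval iff its start time lies in [bed_time, rise_time).

#' Diary-defined rest interval
#'
#' @param bed_time,rise_time `POSIXct` timestamps (or strings coercible via
#'   [as.POSIXct()], UTC); `rise_time` must be strictly after `bed_time`.
#' @return Object of class `rest_interval`.
#' @export
rest_interval <- function(bed_time, rise_time) {
  bed_time <- as.POSIXct(bed_time, tz = "UTC")
  rise_time <- as.POSIXct(rise_time, tz = "UTC")
  if (length(bed_time) != 1 || length(rise_time) != 1 ||
      is.na(bed_time) || is.na(rise_time))
    stop("bed_time and rise_time must be single non-missing timestamps")
  if (rise_time <= bed_time)
    stop("rise_time must be after bed_time (empty rest interval)")
  structure(list(bed_time = bed_time, rise_time = rise_time),
            class = "rest_interval")
}

#' Actigraphy recording
#'
#' A sequence of 1-min epoch activity counts with the accompanying
#' diary-defined rest interval.
#'
#' @param epoch_start `POSIXct` vector of epoch start times, strictly
#'   increasing with exact 60-s spacing.
#' @param counts Non-negative numeric activity counts, one per epoch.
#' @param rest A [rest_interval()].
#' @return Object of class `actigraphy_recording`.
#' @export
actigraphy_recording <- function(epoch_start, counts, rest) {
  epoch_start <- as.POSIXct(epoch_start, tz = "UTC")
  if (length(epoch_start) != length(counts))
    stop("'epoch_start' and 'counts' must have the same length")
  if (length(counts) < 1) stop("recording is empty")
  if (anyNA(epoch_start) || anyNA(counts)) stop("missing timestamps or counts")
  d <- diff(as.numeric(epoch_start))
  if (length(d) > 0 && any(abs(d - 60) > 1e-6))
    stop("epochs must be strictly increasing with exact 60-s spacing")
  if (any(counts < 0)) stop("activity counts must be non-negative")
  if (!inherits(rest, "rest_interval")) stop("'rest' must be a rest_interval")
  structure(list(epoch_start = epoch_start, counts = as.numeric(counts),
                 rest = rest),
            class = "actigraphy_recording")
}

# Cole-Kripke 1-min weighted-sum weights for lags -4..+2 around the scored
# epoch; epoch is scored sleep when
#   0.001 * (106 A[-4] + 54 A[-3] + 58 A[-2] + 76 A[-1]
#            + 230 A[0] + 74 A[+1] + 67 A[+2]) < 1.
cole_kripke_weights <- function() {
  c(106, 54, 58, 76, 230, 74, 67)
}

#' Score in-bed epochs as sleep or wake
#'
#' Applies the Cole-Kripke 1-min weighted-sum classifier to the activity
#' counts and returns one `"sleep"`/`"wake"` label per epoch of the rest
#' interval. The weighted sum for an epoch uses the four preceding and two
#' following epochs of the full recording (counts outside the recording are
#' taken as zero), so context just outside the rest interval is used where
#' available. Deterministic given the counts.
#'
#' @param rec An [actigraphy_recording()] covering the rest interval.
#' @param algorithm Scoring algorithm; only `"cole_kripke"` is implemented.
#' @return Character vector of `"sleep"`/`"wake"` labels, one per in-bed epoch,
#'   named by epoch start time.
#' @export
score_epochs <- function(rec, algorithm = c("cole_kripke")) {
  algorithm <- match.arg(algorithm)
  if (!inherits(rec, "actigraphy_recording"))
    stop("'rec' must be an actigraphy_recording")
  t0 <- as.numeric(rec$epoch_start)
  bed <- as.numeric(rec$rest$bed_time)
  rise <- as.numeric(rec$rest$rise_time)
  in_bed <- t0 >= bed & t0 < rise
  if (!any(in_bed))
    stop("recording contains no epochs inside the rest interval")
  # coverage: every minute of [bed, rise) must be recorded
  n_expected <- floor((rise - bed) / 60)
  if (t0[1] > bed || sum(in_bed) < n_expected)
    stop("recording does not cover the rest interval")
  w <- cole_kripke_weights()
  padded <- c(rep(0, 4), rec$counts, rep(0, 2))
  n <- length(rec$counts)
  score <- numeric(n)
  for (j in seq_along(w)) {   # lag j - 5 in -4..+2
    score <- score + w[j] * padded[seq_len(n) + (j - 1)]
  }
  score <- 0.001 * score
  labels <- ifelse(score < 1, "sleep", "wake")[in_bed]
  names(labels) <- format(rec$epoch_start[in_bed], "%Y-%m-%dT%H:%M:%SZ",
                          tz = "UTC")
  labels
}

#' Summarize scored sleep within the rest interval
#'
#' Computes the standard actigraphic summary measures from per-epoch
#' sleep/wake labels:
#' \describe{
#'   \item{tst}{total sleep time: number of sleep-scored minutes in bed.}
#'   \item{waso}{wake after sleep onset: wake minutes after the first
#'     sleep-scored epoch.}
#'   \item{se}{sleep efficiency: `100 * tst / time_in_bed` (percent).}
#'   \item{mi}{movement index: `100 * wake minutes / time_in_bed` (percent).}
#'   \item{fi}{fragmentation index: percentage of sleep bouts lasting exactly
#'     one minute among all sleep bouts.}
#'   \item{sfi}{sleep fragmentation index: `mi + fi`.}
#' }
#' When no epoch is scored sleep, `tst = se = waso = 0`, onset and latency are
#' missing and the summary is flagged (`no_sleep = TRUE`). Otherwise the epoch
#' accounting identity `latency + tst + waso = time_in_bed` holds exactly.
#'
#' @param labels Character vector of `"sleep"`/`"wake"` labels, one per in-bed
#'   minute (as from [score_epochs()]).
#' @param rest Optional [rest_interval()]; when supplied, its length in whole
#'   minutes must equal `length(labels)` and the sleep-onset timestamp is
#'   reported.
#' @return Object of class `sleep_summary` (a named list) with fields
#'   `time_in_bed`, `latency`, `tst`, `waso`, `se`, `mi`, `fi`, `sfi`,
#'   `sleep_onset`, `no_sleep`.
#' @export
summarize_sleep <- function(labels, rest = NULL) {
  if (length(labels) == 0) stop("empty label vector")
  if (!all(labels %in% c("sleep", "wake")))
    stop("labels must be 'sleep' or 'wake'")
  n <- length(labels)
  if (!is.null(rest)) {
    if (!inherits(rest, "rest_interval")) stop("'rest' must be a rest_interval")
    n_expected <- floor((as.numeric(rest$rise_time) -
                           as.numeric(rest$bed_time)) / 60)
    if (n != n_expected)
      stop("labels (", n, ") do not cover the rest interval (",
           n_expected, " min)")
  }
  is_sleep <- labels == "sleep"
  out <- list(time_in_bed = n)
  if (!any(is_sleep)) {
    out <- c(out, list(latency = NA_real_, tst = 0, waso = 0, se = 0,
                       mi = 100, fi = NA_real_, sfi = NA_real_,
                       sleep_onset = NULL, no_sleep = TRUE))
    class(out) <- "sleep_summary"
    return(out)
  }
  onset <- which(is_sleep)[1]
  tst <- sum(is_sleep)
  waso <- sum(!is_sleep[onset:n])
  latency <- onset - 1L
  # sleep bouts: maximal runs of consecutive sleep epochs
  runs <- rle(is_sleep)
  bout_lengths <- runs$lengths[runs$values]
  fi <- 100 * sum(bout_lengths == 1) / length(bout_lengths)
  mi <- 100 * sum(!is_sleep) / n
  out <- c(out, list(
    latency = latency, tst = tst, waso = waso,
    se = 100 * tst / n, mi = mi, fi = fi, sfi = mi + fi,
    sleep_onset = if (!is.null(rest)) rest$bed_time + 60 * (onset - 1) else NULL,
    no_sleep = FALSE))
  class(out) <- "sleep_summary"
  out
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat("Sleep summary (", x$time_in_bed, " min in bed)\n", sep = "")
  if (x$no_sleep) {
    cat("  no sleep scored (flagged)\n")
  } else {
    cat(sprintf("  latency %d min, TST %d min, WASO %d min\n",
                x$latency, x$tst, x$waso))
    cat(sprintf("  SE %.1f%%, MI %.1f, FI %.1f, SFI %.1f\n",
                x$se, x$mi, x$fi, x$sfi))
  }
  invisible(x)
}

#' One-call actigraphy summary
#'
#' Scores a recording with [score_epochs()] and summarizes the in-bed labels
#' with [summarize_sleep()].
#'
#' @inheritParams score_epochs
#' @return A `sleep_summary`.
#' @export
actigraphy_summary <- function(rec, algorithm = "cole_kripke") {
  summarize_sleep(score_epochs(rec, algorithm), rec$rest)
}
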