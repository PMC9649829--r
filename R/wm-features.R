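# Derived white-matter FA predictors: weighted global mean FA and callosal FA.

#' Weighted global mean FA
#'
#' Aggregates per-ROI mean FA values into a single global summary, as the
#' weighted average over the ROI set. With no weights supplied all ROIs weigh
#' equally, so the result is the plain arithmetic mean; weights are typically
#' per-ROI skeleton voxel counts.
#'
#' @param fa Named numeric vector of per-ROI FA values in (0, 1).
#' @param weights Optional numeric vector of positive weights, same length as
#'   `fa` (matched by name when named, by position otherwise).
#' @return Single numeric FA value.
#' @examples
#' global_mean_fa(c(a = 0.4, b = 0.8), weights = c(a = 1, b = 3))
#' @seealso [callosal_fa()], [derive_fa()]
#' @export
global_mean_fa <- function(fa, weights = NULL) {
  if (!is.numeric(fa) || length(fa) == 0)
    stop("'fa' must be a non-empty numeric vector")
  if (anyNA(fa)) {
    bad <- if (!is.null(names(fa))) names(fa)[is.na(fa)] else which(is.na(fa))
    stop("missing FA value for ROI(s): ", paste(bad, collapse = ", "))
  }
  if (any(fa <= 0 | fa >= 1))
    stop("FA values must lie strictly in (0, 1)")
  if (is.null(weights)) {
    weights <- rep(1, length(fa))
  } else {
    if (length(weights) != length(fa))
      stop("'weights' must have the same length as 'fa'")
    if (!is.null(names(weights)) && !is.null(names(fa))) {
      if (!setequal(names(weights), names(fa)))
        stop("weight names do not match FA names")
      weights <- weights[names(fa)]
    }
    if (anyNA(weights) || any(weights <= 0))
      stop("'weights' must be positive and non-missing")
  }
  sum(weights * fa) / sum(weights)
}

#' Callosal mean FA
#'
#' Mean FA over the three corpus callosum segments: the arithmetic mean of the
#' genu, body and splenium ROI values, `(genu + body + splenium) / 3`.
#'
#' @param fa Named numeric vector of per-ROI FA values; names must include the
#'   three callosal atlas labels (see [jhu_labels()]).
#' @return Single numeric FA value.
#' @export
callosal_fa <- function(fa) {
  if (is.null(names(fa))) stop("'fa' must be named by atlas label")
  names(fa) <- normalize_label(names(fa))
  cc <- callosal_labels()
  missing_cc <- setdiff(cc, names(fa))
  if (length(missing_cc) > 0)
    stop("missing callosal ROI(s): ", paste(missing_cc, collapse = ", "))
  vals <- fa[cc]
  if (anyNA(vals))
    stop("missing FA value for ROI(s): ",
         paste(cc[is.na(vals)], collapse = ", "))
  mean(vals)
}

# Validate a subjects x 48 ROI FA table against the canonical label set.
# Returns the table with label columns in canonical order.
validate_roi_table <- function(roi_fa) {
  if (!is.data.frame(roi_fa)) stop("'roi_fa' must be a data.frame")
  if (!"subject_id" %in% names(roi_fa))
    stop("'roi_fa' must contain a 'subject_id' column")
  labs <- jhu_labels()
  cols <- setdiff(names(roi_fa), "subject_id")
  norm <- normalize_label(cols)
  missing_lab <- setdiff(labs, norm)
  if (length(missing_lab) > 0)
    stop("ROI FA table is missing label(s): ",
         paste(missing_lab, collapse = "; "))
  extra <- setdiff(norm, labs)
  if (length(extra) > 0)
    stop("ROI FA table has unrecognized column(s): ",
         paste(extra, collapse = "; "))
  names(roi_fa)[match(cols, names(roi_fa))] <- norm
  out <- roi_fa[, c("subject_id", labs)]
  vals <- as.matrix(out[, labs])
  if (anyNA(vals) || any(vals <= 0) || any(vals >= 1))
    stop("all ROI FA values must lie strictly in (0, 1) with no missing entries")
  out
}

#' Derive global and callosal FA per subject
#'
#' Applies [global_mean_fa()] and [callosal_fa()] to every row of a
#' subjects-by-ROI FA table (48 JHU atlas columns plus `subject_id`).
#'
#' @param roi_fa Data frame with a `subject_id` column and one column per JHU
#'   atlas label holding mean FA in (0, 1).
#' @param weights Optional named numeric vector of per-ROI weights (e.g.
#'   skeleton voxel counts) used for the global mean.
#' @return Data frame with columns `subject_id`, `global_fa`, `callosal_fa`.
#' @export
derive_fa <- function(roi_fa, weights = NULL) {
  roi_fa <- validate_roi_table(roi_fa)
  labs <- jhu_labels()
  if (!is.null(weights) && !is.null(names(weights)))
    names(weights) <- normalize_label(names(weights))
  mat <- as.matrix(roi_fa[, labs])
  data.frame(
    subject_id = roi_fa$subject_id,
    global_fa = apply(mat, 1, function(r) global_mean_fa(stats::setNames(r, labs), weights)),
    callosal_fa = apply(mat, 1, function(r) callosal_fa(stats::setNames(r, labs))),
    stringsAsFactors = FALSE
  )
}
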