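# Karolinska Sleep Questionnaire indices: disturbed sleep (DSI) and
# disturbed awakening (AWI).
#
# Seven ordinal items, each scored 1-5 (1 = never ... 5 = always), per recall
# period (last night / last 4 weeks):
#   (a) difficulty falling asleep   (b) disturbed/restless sleep
#   (c) repeated awakenings         (d) premature awakening
#   (e) difficulty waking up        (f) non-refreshing sleep
#   (g) exhaustion at awakening
# DSI = a + b + c + d (range 4-20); AWI = e + f + g (range 3-15).
# A missing item makes the index missing; such subjects are excluded listwise
# from any analysis that uses the index.

ksq_item_names <- function() paste0("item_", letters[1:7])

#' Construct a Karolinska questionnaire response
#'
#' @param subject_id Subject identifier.
#' @param period Recall period, `"last_4_weeks"` or `"last_night"`.
#' @param items Numeric vector of length 7 (items a-g in order, or named
#'   `item_a` ... `item_g`), each in 1-5 or `NA`.
#' @return Object of class `karolinska_response` (a named list).
#' @examples
#' r <- karolinska_response("s01", "last_4_weeks", c(2, 3, 4, 1, 2, 2, 3))
#' compute_dsi(r)
#' @export
karolinska_response <- function(subject_id, period = c("last_4_weeks", "last_night"),
                                items) {
  period <- match.arg(period)
  nm <- ksq_item_names()
  if (length(items) != 7)
    stop("'items' must have length 7 (items a-g)")
  if (!is.null(names(items))) {
    if (!setequal(names(items), nm)) stop("item names must be item_a ... item_g")
    items <- items[nm]
  }
  items <- as.numeric(items)
  ok <- is.na(items) | (items %in% 1:5)
  if (!all(ok))
    stop("items must be integers in 1..5 or NA; offending item(s): ",
         paste(letters[1:7][!ok], collapse = ", "))
  structure(list(subject_id = subject_id, period = period,
                 items = stats::setNames(items, nm)),
            class = "karolinska_response")
}

.ksq_items <- function(resp) {
  if (inherits(resp, "karolinska_response")) return(resp$items)
  nm <- ksq_item_names()
  if (is.list(resp) || is.data.frame(resp)) {
    if (!all(nm %in% names(resp)))
      stop("response must contain columns ", paste(nm, collapse = ", "))
    items <- vapply(nm, function(k) as.numeric(resp[[k]][1]), numeric(1))
  } else if (is.numeric(resp) && length(resp) == 7) {
    items <- stats::setNames(as.numeric(resp), nm)
  } else {
    stop("cannot interpret 'resp' as a Karolinska response")
  }
  ok <- is.na(items) | (items %in% 1:5)
  if (!all(ok))
    stop("items must be integers in 1..5 or NA; offending item(s): ",
         paste(letters[1:7][!ok], collapse = ", "))
  items
}

#' Disturbed Sleep Index (DSI)
#'
#' Sum of the four sleep-continuity items (a) difficulty falling asleep,
#' (b) disturbed/restless sleep, (c) repeated awakenings and (d) premature
#' awakening; range 4-20. Returns `NA` if any contributing item is missing.
#'
#' @param resp A [karolinska_response()], a length-7 numeric vector (items a-g),
#'   or a list/one-row data frame with columns `item_a` ... `item_g`.
#' @return Integer DSI in 4..20, or `NA`.
#' @export
compute_dsi <- function(resp) {
  items <- .ksq_items(resp)[paste0("item_", c("a", "b", "c", "d"))]
  if (anyNA(items)) return(NA_integer_)
  as.integer(sum(items))
}

#' Disturbed Awakening Index (AWI)
#'
#' Sum of the three awakening items (e) difficulty waking up, (f) non-refreshing
#' sleep and (g) exhaustion at awakening; range 3-15. Returns `NA` if any
#' contributing item is missing.
#'
#' @inheritParams compute_dsi
#' @return Integer AWI in 3..15, or `NA`.
#' @export
compute_awi <- function(resp) {
  items <- .ksq_items(resp)[paste0("item_", c("e", "f", "g"))]
  if (anyNA(items)) return(NA_integer_)
  as.integer(sum(items))
}

#' Sleep indices for a questionnaire table
#'
#' Computes DSI and AWI for every row of a long questionnaire table.
#'
#' @param ksq Data frame with columns `subject_id`, `period` and
#'   `item_a` ... `item_g`.
#' @return Data frame with columns `subject_id`, `period`, `dsi`, `awi`.
#' @export
sleep_indices <- function(ksq) {
  need <- c("subject_id", "period", ksq_item_names())
  miss <- setdiff(need, names(ksq))
  if (length(miss) > 0)
    stop("questionnaire table is missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(subject_id = ksq$subject_id, period = ksq$period,
                    stringsAsFactors = FALSE)
  out$dsi <- vapply(seq_len(nrow(ksq)), function(i) {
    v <- compute_dsi(as.list(ksq[i, ])); if (is.na(v)) NA_integer_ else v
  }, integer(1))
  out$awi <- vapply(seq_len(nrow(ksq)), function(i) {
    v <- compute_awi(as.list(ksq[i, ])); if (is.na(v)) NA_integer_ else v
  }, integer(1))
  out
}
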