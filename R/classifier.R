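#' Hemispheric pair differences of a trial
#'
#' For each selected symmetric channel pair, subtracts the right-hemisphere
#' channel's series from its left partner's and averages the difference
#' over the motor-activity window, separately for HbO and HbR. During
#' right-hand activity the contralateral (left) hemisphere responds, so the
#' HbO difference is positive and the HbR difference negative; left-hand
#' activity mirrors the signs.
#'
#' @param trial an `fnirs_trial`, baseline-corrected.
#' @param pairs two-column matrix or data frame (`left`, `right`) of channel
#'   ids, e.g. from [selected_pairs()].
#' @param window averaging window in trial seconds, default `c(5, 20)`.
#' @return data frame with one row per pair: `left`, `right`, `d_hbo`,
#'   `d_hbr` (window-averaged left-minus-right differences).
#' @export
pair_differences <- function(trial, pairs, window = c(5, 20)) {
  stopifnot(inherits(trial, "fnirs_trial"))
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("left", "right")
  idx <- window_indices(window, trial$fs)
  want <- as.character(c(pairs$left, pairs$right))
  missing <- setdiff(want, colnames(trial$hbo))
  if (length(missing))
    stop("trial lacks channel(s): ", paste(missing, collapse = ", "))
  l <- as.character(pairs$left); r <- as.character(pairs$right)
  data.frame(
    left = pairs$left, right = pairs$right,
    d_hbo = colMeans(trial$hbo[idx, l, drop = FALSE]) -
            colMeans(trial$hbo[idx, r, drop = FALSE]),
    d_hbr = colMeans(trial$hbr[idx, l, drop = FALSE]) -
            colMeans(trial$hbr[idx, r, drop = FALSE]),
    row.names = NULL)
}

#' Classify one trial from its hemispheric pair differences
#'
#' The decision tree counts evidence across pairs: a pair with positive
#' HbO difference and negative HbR difference votes "right hand"
#' (`CR := CR + 1`); the mirrored sign pattern votes "left hand"
#' (`CL := CL + 1`); any other pattern votes for neither. The label is
#' `right` if `CR > CL`, `left` if `CR < CL`, and `uncertain` on a tie.
#' Inequalities are strict, so an exact zero average contributes no vote.
#' The rule has no trainable parameters and is invariant to positive
#' rescaling of the data.
#'
#' @param diffs data frame from [pair_differences()] (columns `d_hbo`,
#'   `d_hbr`).
#' @return list of class `fnirs_decision`: integers `CR`, `CL` and
#'   `label` in `{"right", "left", "uncertain"}`.
#' @export
classify_trial <- function(diffs) {
  if (!nrow(diffs)) stop("at least one pair difference is required")
  CR <- sum(diffs$d_hbo > 0 & diffs$d_hbr < 0)
  CL <- sum(diffs$d_hbo < 0 & diffs$d_hbr > 0)
  label <- if (CR > CL) "right" else if (CR < CL) "left" else "uncertain"
  structure(list(CR = as.integer(CR), CL = as.integer(CL), label = label),
            class = "fnirs_decision")
}

#' @export
print.fnirs_decision <- function(x, ...) {
  cat(sprintf("decision: %s (CR = %d, CL = %d)\n", x$label, x$CR, x$CL))
  invisible(x)
}

#' Classify every trial of a session
#'
#' Runs baseline correction, pair differencing and the decision tree on
#' each trial and pairs every decision with the trial's ground-truth
#' labels, ready for [confusion()].
#'
#' @param trials list of `fnirs_trial`.
#' @param pairs selected symmetric pairs (two-column matrix/data frame).
#' @param window averaging window in trial seconds.
#' @return data frame of class `fnirs_decisions` with one row per trial:
#'   `trial`, `true_hand`, `condition`, `CR`, `CL`, `label`.
#' @export
classify_session <- function(trials, pairs, window = c(5, 20)) {
  rows <- lapply(seq_along(trials), function(k) {
    tr <- baseline_correct(trials[[k]])
    d <- classify_trial(pair_differences(tr, pairs, window))
    data.frame(trial = k, true_hand = tr$hand, condition = tr$condition,
               CR = d$CR, CL = d$CL, label = d$label,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(), true_hand = character(),
               condition = character(), CR = integer(), CL = integer(),
               label = character(), stringsAsFactors = FALSE)
  class(out) <- c("fnirs_decisions", "data.frame")
  out
}
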