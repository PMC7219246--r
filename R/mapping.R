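#' Task-window averages of a trial
#'
#' The characteristic value of a channel is its HbO (or HbR) concentration
#' change averaged over the motor-activity window, by default `[5, 20)` s of
#' trial time (command at 5 s). The average is the time mean: the window
#' integral divided by the window length, which keeps values comparable
#' across window sizes.
#'
#' @param trial an `fnirs_trial` (baseline-corrected; see
#'   [baseline_correct()]).
#' @param window half-open window `c(a, b)` in trial seconds.
#' @return list of class `fnirs_window_avg`: named numeric vectors `hbo`
#'   and `hbr` (one value per channel) plus the trial's `hand` and
#'   `condition` labels.
#' @export
window_average <- function(trial, window = c(5, 20)) {
  stopifnot(inherits(trial, "fnirs_trial"))
  if (window[1] < 0 || window[2] > TRIAL_SECONDS)
    stop("window must lie within [0, 35) s of trial time")
  idx <- window_indices(window, trial$fs)
  structure(list(hbo = colMeans(trial$hbo[idx, , drop = FALSE]),
                 hbr = colMeans(trial$hbr[idx, , drop = FALSE]),
                 hand = trial$hand, condition = trial$condition),
            class = "fnirs_window_avg")
}

#' Pairwise difference matrix of channel averages
#'
#' `dH[i, j] = <H_i> - <H_j>` over all channel pairs for one chromophore:
#' an antisymmetric matrix whose large positive entries mark channels whose
#' hemodynamic response stands out above the rest.
#'
#' @param avgs an `fnirs_window_avg` (see [window_average()]), or a plain
#'   named numeric vector of per-channel averages.
#' @param chromophore `"HbO"` or `"HbR"`.
#' @return list of class `fnirs_diffmat`: antisymmetric matrix `d`
#'   (channels x channels) plus `chromophore`, `hand`, `condition`.
#' @export
difference_matrix <- function(avgs, chromophore = c("HbO", "HbR")) {
  chromophore <- match.arg(chromophore)
  if (inherits(avgs, "fnirs_window_avg")) {
    h <- if (chromophore == "HbO") avgs$hbo else avgs$hbr
    hand <- avgs$hand; condition <- avgs$condition
  } else {
    h <- avgs; hand <- NA_character_; condition <- NA_character_
  }
  d <- outer(h, h, "-")
  dimnames(d) <- list(names(h), names(h))
  structure(list(d = d, chromophore = chromophore,
                 hand = hand, condition = condition),
            class = "fnirs_diffmat")
}

#' Sign- and quartile-filtered connectivity matrix
#'
#' Builds the hemodynamic connectivity matrix from a difference matrix:
#' (1) keep only entries of the physiologically informative sign -- positive
#' differences for HbO (activation raises oxyhemoglobin), negative for HbR
#' (activation lowers deoxyhemoglobin); (2) take absolute values; (3) rank
#' the kept values by their empirical CDF `F(v) = rank(v) / n` and zero
#' every entry below the `q` quantile (default: keep the fourth quartile,
#' `F >= 0.75`). Ties at the threshold all survive. The CDF is computed per
#' matrix, never pooled across conditions or chromophores.
#'
#' @param dm an `fnirs_diffmat` from [difference_matrix()].
#' @param q quantile threshold in (0, 1); default 0.75.
#' @return list of class `fnirs_connectivity`: nonnegative sparse matrix
#'   `delta`, plus `chromophore`, `hand`, `condition`, `q`.
#' @export
quartile_filter <- function(dm, q = 0.75) {
  stopifnot(inherits(dm, "fnirs_diffmat"))
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)")
  d <- dm$d
  keep <- if (dm$chromophore == "HbO") d > 0 else d < 0
  vals <- abs(d[keep])
  delta <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  if (length(vals) == 0) {
    warning("no entries survive the sign filter; connectivity matrix is zero")
  } else {
    # empirical CDF over kept values: F(v) = #(kept <= v) / n
    Fv <- stats::ecdf(vals)(abs(d[keep]))
    kept_idx <- which(keep)
    survive <- kept_idx[Fv >= q]
    delta[survive] <- abs(d[survive])
  }
  structure(list(delta = delta, chromophore = dm$chromophore,
                 hand = dm$hand, condition = dm$condition, q = q),
            class = "fnirs_connectivity")
}

#' Connectivity matrices for every hand/condition/chromophore combination
#'
#' Convenience pipeline from labeled trials to the full set of connectivity
#' matrices: trials are baseline-corrected, optionally averaged within each
#' (hand, condition) group (the default, matching topographic mapping
#' practice), reduced to task-window averages, differenced and
#' quartile-filtered.
#'
#' @param trials list of `fnirs_trial`.
#' @param q quantile threshold, see [quartile_filter()].
#' @param window task window in seconds.
#' @param trial_average average trials within each (hand, condition) group
#'   before computing window averages (default `TRUE`).
#' @return list of `fnirs_connectivity`, one per present
#'   (hand, condition, chromophore) combination.
#' @export
build_connectivity <- function(trials, q = 0.75, window = c(5, 20),
                               trial_average = TRUE) {
  if (!length(trials)) stop("no trials supplied")
  trials <- lapply(trials, baseline_correct)
  key <- vapply(trials, function(tr) paste(tr$hand, tr$condition, sep = "."),
                character(1))
  out <- list()
  for (g in unique(key)) {
    grp <- trials[key == g]
    if (trial_average && length(grp) > 1) {
      avg_trial <- grp[[1]]
      avg_trial$hbo <- Reduce(`+`, lapply(grp, `[[`, "hbo")) / length(grp)
      avg_trial$hbr <- Reduce(`+`, lapply(grp, `[[`, "hbr")) / length(grp)
      grp <- list(avg_trial)
    }
    for (tr in grp) {
      wa <- window_average(tr, window)
      for (chrom in c("HbO", "HbR")) {
        cm <- quartile_filter(difference_matrix(wa, chrom), q)
        out[[length(out) + 1L]] <- cm
      }
    }
  }
  out
}

#' Rank symmetric channel pairs by connectivity strength
#'
#' Scores each symmetric pair of the montage by how strongly its
#' contralateral member participates in the supplied connectivity matrices:
#' for matrices from right-hand activity the left channel's row plus column
#' sums are added, for left-hand activity the right partner's. Any monotone
#' strength measure recovers the clearly lateralized channels; this row +
#' column rule is the package's choice and is isolated here so alternatives
#' can be swapped in.
#'
#' @param cms list of `fnirs_connectivity` (each must carry a `hand` label),
#'   e.g. from [build_connectivity()].
#' @param montage an `fnirs_montage` with a pair map.
#' @param top number of pairs to mark as selected (default 3).
#' @return data frame of class `fnirs_ranking` with columns `left`, `right`,
#'   `score`, `selected`, ordered by decreasing score (ties broken by
#'   ascending left channel id).
#' @export
rank_channels <- function(cms, montage = default_montage(), top = 3) {
  if (is.null(montage$pairs) || !nrow(montage$pairs))
    stop("montage has no symmetric pair map")
  if (!length(cms)) stop("no connectivity matrices supplied")
  pairs <- montage$pairs
  score <- numeric(nrow(pairs))
  for (cm in cms) {
    if (is.na(cm$hand))
      stop("connectivity matrix lacks a hand label; cannot attribute strength")
    strength <- rowSums(cm$delta) + colSums(cm$delta)
    ch <- if (cm$hand == "right") pairs$left else pairs$right
    score <- score + strength[as.character(ch)]
  }
  ord <- order(-score, pairs$left)
  out <- data.frame(left = pairs$left[ord], right = pairs$right[ord],
                    score = unname(score[ord]))
  out$selected <- seq_len(nrow(out)) <= top
  class(out) <- c("fnirs_ranking", "data.frame")
  out
}

#' Selected symmetric pairs from a ranking
#'
#' @param ranking an `fnirs_ranking` from [rank_channels()].
#' @return two-column matrix (`left`, `right`) of the selected pairs.
#' @export
selected_pairs <- function(ranking) {
  as.matrix(ranking[ranking$selected, c("left", "right")])
}
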