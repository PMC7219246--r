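#' Channel montage for a motor-cortex fNIRS layout
#'
#' A montage records the channel identifiers, the hemisphere each channel
#' sits over, and a bijective map between left-hemisphere channels and their
#' mirror-symmetric right-hemisphere partners. The symmetric pairing is what
#' the lateralization classifier operates on: each decision compares a left
#' channel against its right partner.
#'
#' @param channels integer vector of channel identifiers.
#' @param hemisphere character vector of `"L"`/`"R"`, one per channel,
#'   named by channel identifier.
#' @param pairs data frame with integer columns `left` and `right`: each row
#'   pairs one left-hemisphere channel with one right-hemisphere channel.
#'   Must be a bijection (no channel re-used).
#' @param optodes optional data frame of optode metadata (columns `channel`,
#'   `source`, `detector`, `separation_cm`). Carried through untouched.
#'
#' @return An object of class `fnirs_montage`.
#' @seealso [default_montage()]
#' @export
fnirs_montage <- function(channels, hemisphere, pairs, optodes = NULL) {
  channels <- as.integer(channels)
  if (anyDuplicated(channels)) stop("duplicate channel ids in montage")
  if (is.null(names(hemisphere))) {
    if (length(hemisphere) != length(channels))
      stop("hemisphere must be named by channel or match channels in length")
    names(hemisphere) <- as.character(channels)
  }
  hemisphere <- hemisphere[as.character(channels)]
  if (anyNA(hemisphere) || !all(hemisphere %in% c("L", "R")))
    stop("every channel needs a hemisphere label 'L' or 'R'")
  pairs <- data.frame(left = as.integer(pairs$left),
                      right = as.integer(pairs$right))
  if (anyDuplicated(pairs$left) || anyDuplicated(pairs$right) ||
      length(intersect(pairs$left, pairs$right)))
    stop("pair map must be a bijection between disjoint channel sets")
  if (!all(pairs$left %in% channels) || !all(pairs$right %in% channels))
    stop("pair map references channels absent from the montage")
  if (!all(hemisphere[as.character(pairs$left)] == "L") ||
      !all(hemisphere[as.character(pairs$right)] == "R"))
    stop("pair map must map left-hemisphere channels to right-hemisphere ones")
  structure(list(channels = channels, hemisphere = hemisphere,
                 pairs = pairs, optodes = optodes),
            class = "fnirs_montage")
}

#' Default 20-channel motor-cortex montage
#'
#' The stock layout of an 8-source/8-detector probe over primary motor
#' cortex (M1): 20 channels, channels 1--10 on the left hemisphere and
#' 11--20 on the right, with the mirror pairing `left k` <-> `right k + 10`.
#' This pairing reproduces every printed symmetric pair of the layout
#' ((2,12), (3,13), (7,17), (8,18)); the remaining pairs follow the same
#' offset and can be overridden by building a custom [fnirs_montage()].
#'
#' @return An `fnirs_montage` with 20 channels and a full 10-pair map.
#' @examples
#' m <- default_montage()
#' pair_of(m, 2)   # 12
#' @export
default_montage <- function() {
  ch <- 1:20
  hemi <- rep(c("L", "R"), each = 10)
  names(hemi) <- ch
  fnirs_montage(ch, hemi, data.frame(left = 1:10, right = 11:20))
}

#' Right-hemisphere partner of a left channel
#'
#' @param montage an `fnirs_montage`.
#' @param left integer vector of left-hemisphere channel ids.
#' @return integer vector of the paired right-hemisphere channel ids.
#' @export
pair_of <- function(montage, left) {
  idx <- match(as.integer(left), montage$pairs$left)
  if (anyNA(idx)) stop("channel(s) not in the montage pair map: ",
                       paste(left[is.na(idx)], collapse = ", "))
  montage$pairs$right[idx]
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat("fNIRS montage:", length(x$channels), "channels (",
      sum(x$hemisphere == "L"), "L /", sum(x$hemisphere == "R"), "R ),",
      nrow(x$pairs), "symmetric pairs\n")
  invisible(x)
}

#' Event log of motor commands
#'
#' Validates and normalizes a table of command markers: onset time of the
#' command in seconds from record start, which hand, and whether the trial
#' was real execution or motor imagery. Onsets must increase strictly and
#' leave at least 5 s before the first command for the pre-trial baseline
#' window.
#'
#' @param onset numeric vector of command onset times in seconds.
#' @param hand character vector, `"left"` or `"right"`.
#' @param condition character vector, `"execution"` or `"imagery"`.
#' @return A data frame of class `fnirs_events` with columns
#'   `onset`, `hand`, `condition`.
#' @export
event_log <- function(onset, hand, condition) {
  onset <- as.numeric(onset)
  hand <- match_choices(hand, c("left", "right"), "hand")
  condition <- match_choices(condition, c("execution", "imagery"), "condition")
  if (length(onset) && any(diff(onset) <= 0))
    stop("event onsets must be strictly increasing")
  if (length(onset) && any(onset < 5))
    stop("every event onset must be >= 5 s from record start (pre-window)")
  ev <- data.frame(onset = onset, hand = hand, condition = condition,
                   stringsAsFactors = FALSE)
  class(ev) <- c("fnirs_events", "data.frame")
  ev
}

# vectorised strict match against a set of choices
match_choices <- function(x, choices, what) {
  x <- as.character(x)
  if (!all(x %in% choices))
    stop(what, " must be one of: ", paste(choices, collapse = ", "))
  x
}

#' Continuous fNIRS recording
#'
#' Bundles per-channel HbO and HbR concentration-change series (one column
#' per channel, sampled at a common rate), the event log, and the montage.
#' Concentration values are micromolar unless `unit` says otherwise; the
#' downstream classifier is sign- and scale-invariant, so the unit is
#' metadata, never silently converted.
#'
#' @param hbo,hbr numeric matrices, samples x channels, identical dimensions;
#'   columns ordered as `montage$channels`.
#' @param fs sampling rate in Hz.
#' @param events an `fnirs_events` table (see [event_log()]); every event
#'   must fit a full 35-s trial inside the record.
#' @param montage an `fnirs_montage`.
#' @param unit concentration unit label (default `"uM"`).
#' @return An object of class `fnirs_recording`.
#' @export
fnirs_recording <- function(hbo, hbr, fs, events, montage = default_montage(),
                            unit = "uM") {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!all(dim(hbo) == dim(hbr)))
    stop("HbO and HbR series must share dimensions")
  if (ncol(hbo) != length(montage$channels))
    stop("series must have one column per montage channel")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  if (!all(is.finite(hbo)) || !all(is.finite(hbr)))
    stop("concentration series contain non-finite values")
  if (!inherits(events, "fnirs_events"))
    events <- event_log(events$onset, events$hand, events$condition)
  dur <- nrow(hbo) / fs
  if (nrow(events) && any(events$onset + 30 > dur))
    stop("event(s) at ", paste(round(events$onset[events$onset + 30 > dur], 1),
                               collapse = ", "),
         " s do not leave room for a full trial (record is ",
         round(dur, 1), " s)")
  colnames(hbo) <- colnames(hbr) <- as.character(montage$channels)
  structure(list(hbo = hbo, hbr = hbr, fs = fs, events = events,
                 montage = montage, unit = unit),
            class = "fnirs_recording")
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("fNIRS recording: %d channels x %d samples at %g Hz (%.1f s), %d events\n",
              ncol(x$hbo), nrow(x$hbo), x$fs, nrow(x$hbo) / x$fs,
              nrow(x$events)))
  invisible(x)
}

# ---- timing conventions ----------------------------------------------------
# Half-open windows [a, b) s; sample k (0-based) covers [k/fs, (k+1)/fs).
# A time t maps to 0-based sample floor(t * fs); trial length is
# round(35 * fs) under round-half-even.

TRIAL_SECONDS <- 35
PRE_SECONDS <- 5
TASK_SECONDS <- 15

#' Number of samples in one 35-s trial at sampling rate `fs`
#' @param fs sampling rate in Hz.
#' @return integer sample count (`round(35 * fs)`, round-half-even).
#' @export
trial_length <- function(fs) as.integer(round(TRIAL_SECONDS * fs))

#' 1-based sample indices covering a half-open time window
#'
#' Window `[a, b)` seconds maps to 0-based samples `floor(a*fs) ..
#' floor(b*fs) - 1`, returned 1-based for R indexing.
#'
#' @param window numeric length-2, `c(a, b)` in seconds, `a < b`.
#' @param fs sampling rate in Hz.
#' @return integer vector of 1-based sample indices.
#' @export
window_indices <- function(window, fs) {
  a <- window[1]; b <- window[2]
  if (!(b > a)) stop("empty window: [", a, ", ", b, ")")
  lo <- floor(a * fs); hi <- floor(b * fs) - 1
  if (hi < lo) stop("window [", a, ", ", b, ") contains no sample at fs = ", fs)
  as.integer(lo:hi + 1L)
}

#' Segment masks of a trial (pre / task / rest)
#'
#' The three segments `[0,5)`, `[5,20)`, `[20,35)` s partition the
#' `round(35*fs)` samples of a trial: the rest segment absorbs any final
#' rounding sample.
#'
#' @param fs sampling rate in Hz.
#' @return named list of three integer index vectors `pre`, `task`, `rest`.
#' @export
trial_segments <- function(fs) {
  n <- trial_length(fs)
  pre <- window_indices(c(0, PRE_SECONDS), fs)
  task <- window_indices(c(PRE_SECONDS, PRE_SECONDS + TASK_SECONDS), fs)
  rest_lo <- floor((PRE_SECONDS + TASK_SECONDS) * fs) + 1
  list(pre = pre, task = task, rest = as.integer(rest_lo:n))
}

#' One labeled 35-s trial
#'
#' @param hbo,hbr numeric matrices, `trial_length(fs)` x channels.
#' @param fs sampling rate in Hz.
#' @param hand `"left"` or `"right"`.
#' @param condition `"execution"` or `"imagery"`.
#' @param montage the parent montage.
#' @param onset command onset in the parent record (s), for provenance.
#' @return An object of class `fnirs_trial`. Trial time runs 0--35 s with
#'   the command at t = 5 s.
#' @export
fnirs_trial <- function(hbo, hbr, fs, hand, condition,
                        montage = default_montage(), onset = NA_real_) {
  n <- trial_length(fs)
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (nrow(hbo) != n || nrow(hbr) != n)
    stop("trial data must have ", n, " samples per channel at fs = ", fs)
  if (!all(dim(hbo) == dim(hbr))) stop("HbO/HbR dimension mismatch")
  if (is.null(colnames(hbo))) {
    cn <- if (ncol(hbo) == length(montage$channels))
      as.character(montage$channels) else as.character(seq_len(ncol(hbo)))
    colnames(hbo) <- colnames(hbr) <- cn
  }
  structure(list(hbo = hbo, hbr = hbr, fs = fs,
                 hand = match_choices(hand, c("left", "right"), "hand"),
                 condition = match_choices(condition,
                                           c("execution", "imagery"),
                                           "condition"),
                 montage = montage, onset = onset),
            class = "fnirs_trial")
}

#' @export
print.fnirs_trial <- function(x, ...) {
  cat(sprintf("fNIRS trial: %s %s, %d channels x %d samples at %g Hz\n",
              x$hand, x$condition, ncol(x$hbo), nrow(x$hbo), x$fs))
  invisible(x)
}

#' Cut a continuous recording into labeled 35-s trials
#'
#' Each event yields one trial starting 5 s before the command onset:
#' 5 s preparation, 15 s task, 15 s rest. Events whose trial would read
#' outside the record are dropped with a warning.
#'
#' @param recording an `fnirs_recording`.
#' @return list of `fnirs_trial`, one per usable event, labels copied from
#'   the event log.
#' @export
slice_trials <- function(recording) {
  stopifnot(inherits(recording, "fnirs_recording"))
  fs <- recording$fs
  n <- trial_length(fs)
  total <- nrow(recording$hbo)
  out <- vector("list", nrow(recording$events))
  keep <- logical(nrow(recording$events))
  for (k in seq_len(nrow(recording$events))) {
    ev <- recording$events[k, ]
    start <- floor((ev$onset - PRE_SECONDS) * fs)   # 0-based
    if (start < 0 || start + n > total) {
      warning("event at ", ev$onset, " s too close to record edge; skipped")
      next
    }
    idx <- (start + 1):(start + n)
    out[[k]] <- fnirs_trial(recording$hbo[idx, , drop = FALSE],
                            recording$hbr[idx, , drop = FALSE],
                            fs, ev$hand, ev$condition,
                            montage = recording$montage, onset = ev$onset)
    keep[k] <- TRUE
  }
  out[keep]
}
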