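#' Write a recording as long-format delimited text
#'
#' The series file is tab-separated with columns `time_s`, `channel`,
#' `chromophore`, `value` and a comment header recording the sampling rate
#' and unit; the event log goes to a companion tab-separated file with
#' columns `onset_s`, `hand`, `condition`. Both files are plain text and
#' round-trip losslessly (values written at full double precision).
#'
#' @param recording an `fnirs_recording`.
#' @param series_path path of the series file to write.
#' @param events_path path of the events file; default: `series_path` with
#'   an `.events` suffix inserted before the extension.
#' @return Invisibly, the two paths.
#' @export
write_recording_text <- function(recording, series_path,
                                 events_path = default_events_path(series_path)) {
  stopifnot(inherits(recording, "fnirs_recording"))
  n <- nrow(recording$hbo)
  ch <- colnames(recording$hbo)
  t <- (seq_len(n) - 1) / recording$fs
  long <- data.frame(
    time_s = rep(t, times = 2 * length(ch)),
    channel = rep(rep(as.integer(ch), each = n), times = 2),
    chromophore = rep(c("HbO", "HbR"), each = n * length(ch)),
    value = c(as.numeric(recording$hbo), as.numeric(recording$hbr)))
  long$time_s <- sprintf("%.12g", long$time_s)
  long$value <- sprintf("%.17g", long$value)
  con <- file(series_path, "w")
  writeLines(sprintf("# fs_hz %.10g", recording$fs), con)
  writeLines(sprintf("# unit %s", recording$unit), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  ev <- recording$events
  utils::write.table(data.frame(onset_s = ev$onset, hand = ev$hand,
                                condition = ev$condition),
                     events_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(series = series_path, events = events_path))
}

default_events_path <- function(series_path) {
  sub("(\\.[[:alnum:]]+)?$", ".events\\1", series_path)
}

#' Read a recording from long-format delimited text
#'
#' Inverse of [write_recording_text()]. The sampling rate is taken from the
#' `# fs_hz` header if present, otherwise inferred from the time column.
#' Every channel must carry both chromophores on an identical time grid.
#'
#' @param series_path path of the series file.
#' @param events_path path of the events file (may be absent: empty log).
#' @param montage montage to attach; default built from the channel ids
#'   found (20-channel default montage if they match it).
#' @return An `fnirs_recording`.
#' @export
read_recording_text <- function(series_path,
                                events_path = default_events_path(series_path),
                                montage = NULL) {
  header <- readLines(series_path, n = 5)
  fs <- NA_real_; unit <- "uM"
  for (h in grep("^#", header, value = TRUE)) {
    kv <- strsplit(sub("^#\\s*", "", h), "\\s+")[[1]]
    if (kv[1] == "fs_hz") fs <- as.numeric(kv[2])
    if (kv[1] == "unit") unit <- kv[2]
  }
  long <- utils::read.delim(series_path, comment.char = "#")
  need <- c("time_s", "channel", "chromophore", "value")
  if (!all(need %in% names(long)))
    stop("series file must have columns: ", paste(need, collapse = ", "))
  tgrid <- sort(unique(long$time_s))
  if (is.na(fs)) fs <- (length(tgrid) - 1) / (max(tgrid) - min(tgrid))
  channels <- sort(unique(long$channel))
  if (is.null(montage)) {
    montage <- if (identical(as.integer(channels), 1:20)) default_montage()
    else fnirs_montage(channels,
                       rep("L", length(channels)),
                       data.frame(left = integer(), right = integer()))
  }
  pivot <- function(chrom) {
    sub <- long[long$chromophore == chrom, ]
    if (!nrow(sub)) stop("series file lacks chromophore ", chrom)
    m <- matrix(NA_real_, length(tgrid), length(channels),
                dimnames = list(NULL, channels))
    for (ch in channels) {
      s <- sub[sub$channel == ch, ]
      if (nrow(s) != length(tgrid))
        stop("channel ", ch, "/", chrom, " does not cover the full time grid")
      m[, as.character(ch)] <- s$value[order(s$time_s)]
    }
    m
  }
  hbo <- pivot("HbO"); hbr <- pivot("HbR")
  ev <- if (file.exists(events_path)) {
    e <- utils::read.delim(events_path)
    event_log(e$onset_s, e$hand, e$condition)
  } else event_log(numeric(), character(), character())
  fnirs_recording(hbo, hbr, fs, ev, montage = montage, unit = unit)
}

#' Write session decisions as delimited text
#'
#' @param decisions an `fnirs_decisions` data frame.
#' @param path output path (tab-separated).
#' @return Invisibly, `path`.
#' @export
write_decisions <- function(decisions, path) {
  utils::write.table(as.data.frame(decisions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read session decisions written by [write_decisions()]
#' @param path input path.
#' @return An `fnirs_decisions` data frame.
#' @export
read_decisions <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(d) <- c("fnirs_decisions", "data.frame")
  d
}

#' Pipeline configuration with the method's printed defaults
#'
#' Collects every tunable of the pipeline in one list. The defaults are the
#' method's published operating point: 0.01--0.1 Hz band, task window
#' `[5, 20)` s, fourth-quartile threshold `q = 0.75`, 3 symmetric pairs,
#' 10-fold cross-validation with 20 trials per subsample, uncertain counted
#' as error.
#'
#' @param ... overrides of the default fields (unknown names are an error).
#' @return list of class `fnirs_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    band_low = 0.01, band_high = 0.1,
    window_start = 5, window_end = 20,
    quartile = 0.75, top_pairs = 3,
    uncertain_policy = "error",
    kfold_k = 10, kfold_subsample = 20,
    fs = 7.8125,
    condition = "execution",
    trials_per_condition = 10,
    snr = 3, imagery_scale = 0.4, imagery_onset_delay = 10,
    seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "fnirs_config"))
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(band_low > 0 && band_high > band_low)) stop("invalid filter band")
    if (!(window_start >= 0 && window_end > window_start && window_end <= 35))
      stop("invalid task window")
    if (!(quartile > 0 && quartile < 1)) stop("quartile must be in (0,1)")
    if (top_pairs < 1) stop("at least one symmetric pair is required")
    if (!uncertain_policy %in% c("error", "drop"))
      stop("uncertain_policy must be 'error' or 'drop'")
  })
  cfg
}

#' Read / write a plain-text key-value configuration file
#'
#' One `key value` pair per line, `#` comments allowed; keys are the fields
#' of [pipeline_config()].
#'
#' @param path file path.
#' @return For the reader, an `fnirs_config`.
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- strsplit(trimws(lines), "\\s+")
  args <- stats::setNames(
    lapply(kv, function(x) {
      v <- paste(x[-1], collapse = " ")
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }),
    vapply(kv, `[[`, character(1), 1))
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param config an `fnirs_config` to write.
#' @export
write_config <- function(config, path) {
  writeLines(vapply(names(config), function(k)
    sprintf("%s %s", k, format(config[[k]], digits = 15)), character(1)),
    path)
  invisible(path)
}
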