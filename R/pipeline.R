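#' Run the full classification pipeline
#'
#' One call from recording to report: band-pass filter the continuous
#' record, slice 35-s trials, baseline-correct, select informative
#' symmetric pairs from the quartile-thresholded connectivity matrices,
#' classify every trial with the lateralization decision tree, and
#' evaluate (confusion table, Eq.-style rates, two-segment ROC; optional
#' k-fold cross-validation). All stage parameters come from the config,
#' which is echoed in the report so the operating point is auditable.
#'
#' @param config an [pipeline_config()].
#' @param input an `fnirs_recording`, or a path to a series text file /
#'   SNIRF container; `NULL` (default) generates a synthetic session from
#'   the config's generator fields.
#' @param kfold also run k-fold cross-validation (default `FALSE`; needs
#'   `kfold_k * kfold_subsample` trials).
#' @return list of class `fnirs_report`: `config`, `ranking`, `pairs`,
#'   `decisions`, `confusion`, `rates`, `roc`, and optionally `cv`.
#' @export
run_pipeline <- function(config = pipeline_config(), input = NULL,
                         kfold = FALSE) {
  config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  rec <- stage("input", {
    if (is.null(input)) {
      p <- synth_params(fs = config$fs,
                        trials_per_condition = config$trials_per_condition,
                        snr = config$snr,
                        imagery_scale = config$imagery_scale,
                        imagery_onset_delay = config$imagery_onset_delay,
                        seed = config$seed)
      generate_session(p, config$condition)
    } else if (inherits(input, "fnirs_recording")) input
    else if (grepl("\\.snirf$", input)) read_snirf(input)
    else read_recording_text(input)
  })
  rec <- stage("bandpass",
               bandpass(rec, low = config$band_low, high = config$band_high))
  trials <- stage("slice", slice_trials(rec))
  if (!length(trials)) stop("pipeline stage 'slice': no usable trials")
  window <- c(config$window_start, config$window_end)
  ranking <- stage("mapping",
                   rank_channels(build_connectivity(trials,
                                                    q = config$quartile,
                                                    window = window),
                                 rec$montage, top = config$top_pairs))
  pairs <- selected_pairs(ranking)
  decisions <- stage("classify", classify_session(trials, pairs, window))
  ct <- stage("evaluate", confusion(decisions, config$uncertain_policy))
  rs <- stage("evaluate", rates(ct))
  report <- list(config = config, ranking = ranking, pairs = pairs,
                 decisions = decisions, confusion = ct, rates = rs,
                 roc = roc_curve(rs))
  if (kfold)
    report$cv <- stage("kfold",
                       kfold_evaluate(trials, k = config$kfold_k,
                                      subsample = config$kfold_subsample,
                                      seed = config$seed,
                                      q = config$quartile,
                                      top = config$top_pairs,
                                      window = window,
                                      policy = config$uncertain_policy))
  class(report) <- "fnirs_report"
  report
}

#' @export
print.fnirs_report <- function(x, ...) {
  cat("== fnirslat pipeline report ==\n")
  cat("pairs:", paste(x$pairs[, "left"], x$pairs[, "right"], sep = ":",
                      collapse = " "), "\n")
  print(x$confusion); print(x$rates)
  cat(sprintf("ROC AUC: %.3f\n", x$roc$auc))
  if (!is.null(x$cv)) print(x$cv)
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' @param report an `fnirs_report`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  out <- list(
    config = unclass(report$config),
    pairs = apply(report$pairs, 1, paste, collapse = ":"),
    ranking = as.data.frame(unclass(report$ranking)),
    decisions = as.data.frame(unclass(report$decisions)),
    confusion = unclass(report$confusion),
    rates = unclass(report$rates),
    roc = list(vertices = report$roc$vertices, auc = report$roc$auc))
  if (!is.null(report$cv))
    out$cv <- list(folds = report$cv$folds, mean = as.list(report$cv$mean),
                   sd = as.list(report$cv$sd))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
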