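#' Confusion table of session decisions
#'
#' Counts decisions against ground truth with right-hand trials as the
#' positive class: TP = right trials labeled right, TN = left trials
#' labeled left, FP = left trials labeled right, FN = right trials labeled
#' left. Uncertain decisions (tied evidence) are handled by `policy`:
#' `"error"` (default) charges them against their true class (truth right
#' -> FN, truth left -> FP), matching the convention of pooling incorrect
#' and uncertain events as failures; `"drop"` excludes them and reports
#' the count separately.
#'
#' @param decisions an `fnirs_decisions` data frame (see
#'   [classify_session()]) or any data frame with columns `true_hand` and
#'   `label`.
#' @param policy `"error"` or `"drop"`.
#' @return list of class `fnirs_confusion`: integers `TP`, `FP`, `TN`,
#'   `FN`, `uncertain`, and the `policy` applied.
#' @export
confusion <- function(decisions, policy = c("error", "drop")) {
  policy <- match.arg(policy)
  truth <- decisions$true_hand
  if (!all(truth %in% c("left", "right")))
    stop("unknown ground-truth hand label")
  lab <- decisions$label
  unc <- lab == "uncertain"
  TP <- sum(truth == "right" & lab == "right")
  TN <- sum(truth == "left" & lab == "left")
  FP <- sum(truth == "left" & lab == "right")
  FN <- sum(truth == "right" & lab == "left")
  if (policy == "error") {
    FN <- FN + sum(unc & truth == "right")
    FP <- FP + sum(unc & truth == "left")
  }
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 TN = as.integer(TN), FN = as.integer(FN),
                 uncertain = as.integer(sum(unc)), policy = policy),
            class = "fnirs_confusion")
}

#' @export
print.fnirs_confusion <- function(x, ...) {
  cat(sprintf("confusion (right = positive): TP %d  FP %d  TN %d  FN %d  (uncertain %d, policy %s)\n",
              x$TP, x$FP, x$TN, x$FN, x$uncertain, x$policy))
  invisible(x)
}

#' Sensitivity, specificity and false-positive fraction
#'
#' `TPF = TP / (TP + FN) x 100`, `TNF = TN / (TN + FP) x 100`,
#' `FPF = 100 - TNF`, all on the percent scale.
#'
#' @param ct an `fnirs_confusion` from [confusion()].
#' @return list of class `fnirs_rates` with `TPF`, `TNF`, `FPF` (percent)
#'   and `accuracy` (percent of all counted trials classified correctly).
#' @export
rates <- function(ct) {
  stopifnot(inherits(ct, "fnirs_confusion"))
  if (ct$TP + ct$FN == 0) stop("no positive-class (right-hand) trials: TPF undefined")
  if (ct$TN + ct$FP == 0) stop("no negative-class (left-hand) trials: TNF undefined")
  TPF <- ct$TP / (ct$TP + ct$FN) * 100
  TNF <- ct$TN / (ct$TN + ct$FP) * 100
  structure(list(TPF = TPF, TNF = TNF, FPF = 100 - TNF,
                 accuracy = (ct$TP + ct$TN) /
                   (ct$TP + ct$TN + ct$FP + ct$FN) * 100),
            class = "fnirs_rates")
}

#' @export
print.fnirs_rates <- function(x, ...) {
  cat(sprintf("TPF %.1f%%  TNF %.1f%%  FPF %.1f%%  accuracy %.1f%%\n",
              x$TPF, x$TNF, x$FPF, x$accuracy))
  invisible(x)
}

#' Two-segment ROC curve of a binary threshold-free classifier
#'
#' A decision-tree classifier emits hard labels, so its ROC curve is the
#' two-segment polyline `(0,0) - (FPF,TPF) - (100,100)` (percent axes).
#' The AUC is the trapezoid area under that polyline on the unit square:
#' `auc = tpf * fpf / 2 + (1 - fpf) * (tpf + 1) / 2` with `tpf = TPF/100`,
#' `fpf = FPF/100`.
#'
#' @param rs an `fnirs_rates` from [rates()].
#' @return list of class `fnirs_roc`: `vertices` (3 x 2 matrix, percent)
#'   and `auc` in `[0, 1]`.
#' @export
roc_curve <- function(rs) {
  stopifnot(inherits(rs, "fnirs_rates"))
  fpf <- rs$FPF / 100; tpf <- rs$TPF / 100
  vertices <- rbind(c(0, 0), c(rs$FPF, rs$TPF), c(100, 100))
  colnames(vertices) <- c("FPF", "TPF")
  auc <- fpf * tpf / 2 + (1 - fpf) * (tpf + 1) / 2
  structure(list(vertices = vertices, auc = auc), class = "fnirs_roc")
}

#' k-fold cross-validated evaluation of the full pipeline
#'
#' Partitions the trials into `k` held-out subsamples of `subsample` trials
#' each (balanced between left and right hands where possible), and for
#' each fold re-runs the only data-dependent stage -- informative-channel
#' selection on the training portion -- before classifying the held-out
#' trials and computing Eq.-style rates. The classifier itself has no
#' trainable parameters. Trials are canonically sorted (hand, condition,
#' onset) before seeding, so input order does not affect the folds.
#'
#' @param trials list of labeled `fnirs_trial` (at least `k * subsample`).
#' @param k number of folds (default 10).
#' @param subsample held-out trials per fold (default 20).
#' @param seed integer RNG seed for the fold assignment.
#' @param q quartile threshold for channel selection.
#' @param top number of symmetric pairs to select per fold.
#' @param window task window in seconds.
#' @param policy uncertain-handling policy, see [confusion()].
#' @return list of class `fnirs_cv`: `folds` (data frame of per-fold TPF,
#'   TNF, FPF, accuracy and selected pairs), `mean` and `sd` (named
#'   vectors over folds), `k`, `subsample`.
#' @export
kfold_evaluate <- function(trials, k = 10, subsample = 20, seed = 1,
                           q = 0.75, top = 3, window = c(5, 20),
                           policy = "error") {
  n <- length(trials)
  if (n < k * subsample)
    stop("need at least k * subsample = ", k * subsample,
         " trials for ", k, "-fold evaluation; got ", n)
  hands <- vapply(trials, `[[`, character(1), "hand")
  conds <- vapply(trials, `[[`, character(1), "condition")
  onsets <- vapply(trials, `[[`, numeric(1), "onset")
  canon <- order(hands, conds, onsets)
  trials <- trials[canon]; hands <- hands[canon]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  # deal shuffled trials of each hand round-robin into k folds, then trim
  # each fold to the stated subsample size
  fold_of <- integer(n)
  for (h in unique(hands)) {
    idx <- sample(which(hands == h))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    if (length(test_idx) > subsample) test_idx <- test_idx[seq_len(subsample)]
    train <- trials[setdiff(seq_len(n), test_idx)]
    sel <- selected_pairs(rank_channels(build_connectivity(train, q = q,
                                                           window = window),
                                        trials[[1]]$montage, top = top))
    dec <- classify_session(trials[test_idx], sel, window)
    r <- rates(confusion(dec, policy))
    rows[[f]] <- data.frame(fold = f, TPF = r$TPF, TNF = r$TNF,
                            FPF = r$FPF, accuracy = r$accuracy,
                            pairs = paste(sel[, "left"], sel[, "right"],
                                          sep = ":", collapse = ","))
  }
  folds <- do.call(rbind, rows)
  m <- colMeans(folds[, c("TPF", "TNF", "FPF", "accuracy")])
  s <- vapply(folds[, c("TPF", "TNF", "FPF", "accuracy")], stats::sd,
              numeric(1))
  structure(list(folds = folds, mean = m, sd = s, k = k,
                 subsample = subsample),
            class = "fnirs_cv")
}

#' @export
print.fnirs_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV (%d trials/fold):\n", x$k, x$subsample))
  for (nm in names(x$mean))
    cat(sprintf("  %-9s %.1f +/- %.1f %%\n", nm, x$mean[nm], x$sd[nm]))
  invisible(x)
}
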