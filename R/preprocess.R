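#' Modified Beer-Lambert law constants
#'
#' Molar extinction coefficients, differential pathlength factors and the
#' source-detector separation used to convert dual-wavelength optical
#' density changes into hemoglobin concentration changes. The shipped
#' defaults are the standard literature values for 785 nm and 850 nm
#' (extinction in cm^-1 M^-1, compiled tabulations as used by common fNIRS
#' toolboxes; adult-head differential pathlength factors) with a 3 cm
#' channel separation. Every value can be overridden.
#'
#' @param extinction 2x2 numeric matrix, rows = wavelengths (785, 850 nm),
#'   columns = chromophores (HbO, HbR), cm^-1 M^-1.
#' @param dpf named numeric, differential pathlength factor per wavelength.
#' @param separation_cm source-detector distance in cm.
#' @return A list of class `mbll_constants`.
#' @export
mbll_constants <- function(extinction = NULL,
                           dpf = c("785" = 6.3, "850" = 5.9),
                           separation_cm = 3) {
  if (is.null(extinction)) {
    extinction <- matrix(c(735, 1097,    # 785 nm: HbO, HbR
                           1058, 691),   # 850 nm: HbO, HbR
                         nrow = 2, byrow = TRUE,
                         dimnames = list(c("785", "850"), c("HbO", "HbR")))
  }
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2, 2)))
    stop("extinction must be a 2x2 matrix (wavelength x chromophore)")
  if (abs(det(extinction)) < .Machine$double.eps * max(abs(extinction))^2)
    stop("extinction matrix is singular; chromophores are not separable")
  if (separation_cm <= 0) stop("separation must be positive")
  structure(list(extinction = extinction, dpf = dpf,
                 separation_cm = separation_cm),
            class = "mbll_constants")
}

# wavelength x chromophore system matrix mapping uM concentrations to dOD
mbll_system_matrix <- function(constants) {
  E <- constants$extinction
  d <- constants$separation_cm
  # dOD(lambda) = eps(lambda, c) * dC[M] * d * DPF(lambda); dC in uM -> 1e-6
  A <- diag(as.numeric(constants$dpf[rownames(E)])) %*% E * d * 1e-6
  dimnames(A) <- dimnames(E)
  A
}

#' Convert optical-density changes to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law per sample: the 2x2 linear system
#' `dOD(lambda) = sum_c eps(c, lambda) dC_c * d * DPF(lambda)` is solved for
#' `(dC_HbO, dC_HbR)` at each time point and channel.
#'
#' @param od785,od850 numeric matrices (samples x channels) of dimensionless
#'   optical-density changes at 785 and 850 nm.
#' @param constants an [mbll_constants()] object.
#' @return list with components `hbo` and `hbr`, matrices of concentration
#'   changes in micromolar, same shape as the inputs.
#' @seealso [od_forward()] for the forward model.
#' @export
mbll_convert <- function(od785, od850, constants = mbll_constants()) {
  od785 <- as.matrix(od785); od850 <- as.matrix(od850)
  if (!all(dim(od785) == dim(od850)))
    stop("optical-density series at the two wavelengths differ in shape")
  A <- mbll_system_matrix(constants)
  Ainv <- solve(A)
  hbo <- Ainv[1, 1] * od785 + Ainv[1, 2] * od850
  hbr <- Ainv[2, 1] * od785 + Ainv[2, 2] * od850
  list(hbo = hbo, hbr = hbr)
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes (micromolar) to the dual-wavelength
#' optical-density changes a detector would report; the exact inverse of
#' [mbll_convert()] and the generator's raw-output path.
#'
#' @inheritParams mbll_convert
#' @param hbo,hbr matrices of concentration changes in micromolar.
#' @return list with components `od785` and `od850`.
#' @export
od_forward <- function(hbo, hbr, constants = mbll_constants()) {
  A <- mbll_system_matrix(constants)
  list(od785 = A[1, 1] * hbo + A[1, 2] * hbr,
       od850 = A[2, 1] * hbo + A[2, 2] * hbr)
}

# ---- Butterworth band-pass, zero phase -------------------------------------
# No DSP package is assumed: the 4th-order Butterworth band-pass (order-2
# analog low-pass prototype, LP->BP transform, bilinear mapping) is designed
# here and applied as cascaded biquads forward and backward (zero phase)
# with odd-reflection padding.

butter_bandpass_sos <- function(low, high, fs, order = 4) {
  if (order %% 2 != 0) stop("band-pass order must be even")
  n <- order / 2
  # prewarped analog edge frequencies
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  # analog low-pass prototype poles on the unit circle, Re < 0
  k <- seq_len(n)
  proto <- exp(1i * (pi / 2 + pi * (2 * k - 1) / (2 * n)))
  # LP -> BP: each prototype pole splits into two band-pass poles
  s_poles <- unlist(lapply(proto, function(p) {
    m <- p * bw / 2
    d <- sqrt(m^2 - w0^2)
    c(m + d, m - d)
  }))
  # bilinear transform to the z plane
  z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
  # group poles into conjugate pairs; each biquad gets zeros at z = +1, -1
  ord <- order(Im(z_poles))
  z_poles <- z_poles[ord]                      # conjugates symmetric in Im
  sections <- lapply(seq_len(n), function(j) {
    p <- z_poles[c(j, 2 * n + 1 - j)]          # a pole and its conjugate
    a <- c(1, -Re(p[1] + p[2]), Re(p[1] * p[2]))
    list(b = c(1, 0, -1), a = a)
  })
  # normalize overall gain to 1 at the geometric band center
  fc <- sqrt(low * high)
  g <- 1 / abs(sos_response(sections, fc, fs))
  sections[[1]]$b <- sections[[1]]$b * g
  sections
}

# complex frequency response of a biquad cascade at frequency f (Hz)
sos_response <- function(sections, f, fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)
  h <- 1 + 0i
  for (s in sections)
    h <- h * (s$b[1] + s$b[2] * z1 + s$b[3] * z1^2) /
             (s$a[1] + s$a[2] * z1 + s$a[3] * z1^2)
  h
}

# single forward pass of one biquad (direct form, zero initial conditions),
# built from stats::filter so the recursion runs in C
biquad_filter <- function(x, b, a) {
  xp <- c(0, 0, x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)[-(1:2)]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

filtfilt_sos <- function(x, sections, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1)
  # odd reflection about the end points reduces edge transients
  head_pad <- 2 * x[1] - x[seq(padlen + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  y <- c(head_pad, x, tail_pad)
  for (s in sections) y <- biquad_filter(y, s$b, s$a)
  y <- rev(y)
  for (s in sections) y <- biquad_filter(y, s$b, s$a)
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Removes slow drift and the dominant physiological nuisance components of
#' fNIRS signals -- Mayer waves (~0.1 Hz), respiration (~0.25 Hz) and
#' heartbeat (~1 Hz) -- with a recursive band-pass applied forward and
#' backward, so the slow hemodynamic response suffers no phase distortion.
#' The default band is 0.01--0.1 Hz. The effective (two-pass) magnitude
#' response attenuates 0.25 Hz and 1 Hz by more than 20 dB while passing
#' 0.05 Hz within 3 dB.
#'
#' Filter the continuous recording before slicing trials: edge transients
#' then fall outside every trial.
#'
#' @param x numeric vector, samples x channels matrix, or
#'   `fnirs_recording` (both chromophores filtered).
#' @param fs sampling rate in Hz (taken from the object for recordings).
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order recursive filter order (default 4, i.e. two biquads).
#' @return Object of the same class as `x`, filtered, same length.
#' @export
bandpass <- function(x, fs, low = 0.01, high = 0.1, order = 4) {
  UseMethod("bandpass")
}

#' @export
bandpass.numeric <- function(x, fs, low = 0.01, high = 0.1, order = 4) {
  check_band(low, high, fs)
  if (!all(is.finite(x))) stop("input contains non-finite values")
  min_len <- 3 * (order + 1)
  if (length(x) < min_len)
    stop("series too short to filter: need at least ", min_len, " samples")
  sos <- butter_bandpass_sos(low, high, fs, order)
  padlen <- max(min_len, min(length(x) - 1, ceiling(3 * fs / low)))
  filtfilt_sos(x, sos, padlen)
}

#' @export
bandpass.matrix <- function(x, fs, low = 0.01, high = 0.1, order = 4) {
  out <- apply(x, 2, bandpass.numeric, fs = fs, low = low, high = high,
               order = order)
  dimnames(out) <- dimnames(x)
  out
}

#' @export
bandpass.fnirs_recording <- function(x, fs, low = 0.01, high = 0.1,
                                     order = 4) {
  x$hbo <- bandpass.matrix(x$hbo, x$fs, low, high, order)
  x$hbr <- bandpass.matrix(x$hbr, x$fs, low, high, order)
  x
}

check_band <- function(low, high, fs) {
  if (!(low > 0 && high > low && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (got ",
         low, ", ", high, " at fs = ", fs, ")")
}

#' Baseline-correct a trial against its 5-s preparation window
#'
#' Subtracts, per channel and chromophore, the mean over the pre-command
#' segment `[0, 5)` s from the whole trial, so every trial is expressed as
#' a change from its own immediate baseline. Idempotent.
#'
#' @param trial an `fnirs_trial`.
#' @return The corrected `fnirs_trial`.
#' @export
baseline_correct <- function(trial) {
  stopifnot(inherits(trial, "fnirs_trial"))
  pre <- trial_segments(trial$fs)$pre
  trial$hbo <- sweep(trial$hbo, 2, colMeans(trial$hbo[pre, , drop = FALSE]))
  trial$hbr <- sweep(trial$hbr, 2, colMeans(trial$hbr[pre, , drop = FALSE]))
  trial
}
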