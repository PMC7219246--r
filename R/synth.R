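#' Double-gamma hemodynamic response kernel
#'
#' The canonical slow vascular response to a neural event: a gamma-shaped
#' rise peaking a few seconds after onset minus a scaled, later gamma
#' undershoot. Returned sampled at `fs` over `[0, duration]` s and
#' normalized to peak value 1. An `onset_delay` > 0 delays and slows the
#' rise by shifting both gamma shapes additively (peak moves from
#' `peak_delay - 1` to `peak_delay - 1 + onset_delay` s without stretching
#' the decay), which models the sluggish build-up of the motor-imagery
#' response.
#'
#' @param fs sampling rate in Hz.
#' @param peak_delay gamma shape of the positive lobe (peak near
#'   `peak_delay - 1` s at rate 1; default 6, peak ~5 s).
#' @param undershoot_delay gamma shape of the undershoot (default 16).
#' @param ratio undershoot amplitude relative to the peak (default 1/6).
#' @param duration kernel support in seconds (default `30 + 2 *
#'   onset_delay`).
#' @param onset_delay additional rise delay in seconds (default 0).
#' @return numeric vector of kernel samples, `max == 1`.
#' @export
hrf_kernel <- function(fs, peak_delay = 6, undershoot_delay = 16,
                       ratio = 1 / 6, duration = 30 + 2 * onset_delay,
                       onset_delay = 0) {
  if (peak_delay <= 0 || undershoot_delay <= 0 || onset_delay < 0)
    stop("HRF delays must be positive and onset_delay nonnegative")
  t <- seq(0, duration, by = 1 / fs)
  h <- stats::dgamma(t, shape = peak_delay + onset_delay, rate = 1) -
       ratio * stats::dgamma(t, shape = undershoot_delay + onset_delay,
                             rate = 1)
  h / max(h)
}

# peak-normalized response of a `task_s`-long activation convolved with the
# HRF kernel
task_response <- function(fs, task_s = TASK_SECONDS, onset_delay = 0, ...) {
  kern <- hrf_kernel(fs, onset_delay = onset_delay, ...)
  box <- rep(1, max(1L, round(task_s * fs)))
  r <- stats::convolve(c(box, numeric(length(kern))), rev(kern),
                       type = "open")
  r <- r[seq_len(length(box) + length(kern) - 1)]
  r / max(r)
}

#' Parameters of the synthetic fNIRS session generator
#'
#' The generator emulates a motor-cortex session: lateralized antiphase
#' HbO/HbR responses in a fixed "informative" channel set, the three
#' physiological nuisance oscillations (Mayer wave ~0.1 Hz, respiration
#' ~0.25 Hz, heartbeat ~1 Hz) with a session-random common phase and
#' per-channel amplitude jitter, white measurement noise, and slow linear
#' drift.
#'
#' `snr` is defined as (evoked HbO response peak of the generated
#' condition) / (HbO white-noise sigma); the HbR white-noise sigma scales
#' with `|hbr_ratio|`, mirroring the smaller amplitude and noise of the
#' deoxyhemoglobin signal. Motor imagery scales the response amplitude by
#' `imagery_scale` and delays/slows its rise: the HRF gamma shapes are
#' shifted additively by `imagery_onset_delay`, moving the kernel peak
#' from about `hrf_peak_delay - 1` to `hrf_peak_delay - 1 +
#' imagery_onset_delay` seconds without stretching the decay, so the
#' oxyhemoglobin increase becomes apparent roughly `imagery_onset_delay`
#' seconds after the command.
#'
#' @param fs sampling rate in Hz (default 7.8125).
#' @param montage an `fnirs_montage`.
#' @param trials_per_condition trials per hand per session (default 10).
#' @param hrf_peak_delay,hrf_undershoot_delay,hrf_ratio double-gamma HRF
#'   shape parameters, see [hrf_kernel()].
#' @param exec_amplitude HbO response peak for motor execution, uM.
#' @param hbr_ratio HbR amplitude as a (negative) fraction of HbO
#'   (default -1/3).
#' @param imagery_scale imagery HbO peak as a fraction of `exec_amplitude`
#'   (default 0.4).
#' @param imagery_onset_delay seconds by which the imagery response rise
#'   is delayed/slowed (default 10).
#' @param contralateral_gain,ipsilateral_gain response gain of the active
#'   hemisphere's informative channels and of their mirror partners.
#' @param informative_left left-hemisphere channels carrying the response
#'   (default `c(2, 7, 8)`; partners via the montage pair map).
#' @param mayer_amp,resp_amp,cardiac_amp nuisance oscillation amplitudes
#'   (uM) at 0.1, 0.25 and 1 Hz.
#' @param snr evoked-HbO-peak over white-noise-sigma ratio (default 3).
#' @param white_sd explicit HbO white-noise sigma; overrides `snr` if set.
#' @param drift maximal |linear drift| in uM per minute (per-channel slope
#'   drawn uniformly).
#' @param seed integer seed; the seed fully determines the session.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(fs = 7.8125, montage = default_montage(),
                         trials_per_condition = 10,
                         hrf_peak_delay = 6, hrf_undershoot_delay = 16,
                         hrf_ratio = 1 / 6,
                         exec_amplitude = 1.0, hbr_ratio = -1 / 3,
                         imagery_scale = 0.4, imagery_onset_delay = 10,
                         contralateral_gain = 1, ipsilateral_gain = 0.25,
                         informative_left = c(2, 7, 8),
                         mayer_amp = 0.1, resp_amp = 0.05,
                         cardiac_amp = 0.05,
                         snr = 3, white_sd = NULL, drift = 0.05,
                         seed = 1) {
  stopifnot(fs > 0, exec_amplitude >= 0, imagery_scale > 0,
            imagery_scale <= 1, imagery_onset_delay >= 0,
            mayer_amp >= 0, resp_amp >= 0, cardiac_amp >= 0,
            is.null(white_sd) || white_sd >= 0)
  structure(as.list(environment()), class = "synth_params")
}

# white-noise sigma implied by the SNR definition for a given condition
white_sigma <- function(params, condition) {
  if (!is.null(params$white_sd)) return(params$white_sd)
  peak <- params$exec_amplitude *
    if (condition == "imagery") params$imagery_scale else 1
  if (params$snr <= 0) stop("snr must be positive")
  peak / params$snr
}

#' Generate one labeled synthetic fNIRS session
#'
#' Builds a continuous recording with one 35-s trial per scheduled command:
#' 5 s lead-in before the first trial, contiguous trials, 5 s tail. The
#' contralateral hemisphere's informative channels receive the scaled HRF
#' response in HbO and `hbr_ratio` times it in HbR; the mirror channels
#' receive the same response at `ipsilateral_gain`; every channel receives
#' the nuisance oscillations, white noise and drift. Ground truth lives in
#' the returned recording's event log.
#'
#' @param params a [synth_params()] object.
#' @param condition `"execution"` or `"imagery"` (applies to all trials).
#' @param hands optional character vector of `"left"`/`"right"` commands,
#'   one per trial, in presentation order; default: a seeded random
#'   interleaving of `trials_per_condition` of each hand.
#' @return an `fnirs_recording`.
#' @export
generate_session <- function(params = synth_params(),
                             condition = c("execution", "imagery"),
                             hands = NULL) {
  stopifnot(inherits(params, "synth_params"))
  condition <- match.arg(condition)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  if (is.null(hands))
    hands <- sample(rep(c("left", "right"), params$trials_per_condition))
  hands <- match_choices(hands, c("left", "right"), "hand")
  n_tr <- length(hands)
  fs <- params$fs
  onsets <- 10 + 35 * (seq_len(n_tr) - 1)
  total_s <- 35 * n_tr + 10
  n <- ceiling(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  mont <- params$montage
  n_ch <- length(mont$channels)

  amp <- params$exec_amplitude *
    if (condition == "imagery") params$imagery_scale else 1
  # execution: sustained activation, HRF convolved with the 15-s task box;
  # imagery: weaker, delayed, transient response -- the shape-shifted HRF
  # bump itself, which rises ~imagery_onset_delay s after the command and
  # recovers within the trial's rest interval
  resp <- if (condition == "execution")
    task_response(fs, peak_delay = params$hrf_peak_delay,
                  undershoot_delay = params$hrf_undershoot_delay,
                  ratio = params$hrf_ratio)
  else
    hrf_kernel(fs, onset_delay = params$imagery_onset_delay,
               peak_delay = params$hrf_peak_delay,
               undershoot_delay = params$hrf_undershoot_delay,
               ratio = params$hrf_ratio)

  hbo <- matrix(0, n, n_ch); hbr <- matrix(0, n, n_ch)
  left_ch <- match(params$informative_left, mont$channels)
  right_ch <- match(pair_of(mont, params$informative_left), mont$channels)
  for (k in seq_len(n_tr)) {
    i0 <- floor(onsets[k] * fs)            # command sample, 0-based
    idx <- (i0 + 1):min(n, i0 + length(resp))
    seg <- amp * resp[seq_along(idx)]
    contra <- if (hands[k] == "right") left_ch else right_ch
    ipsi <- if (hands[k] == "right") right_ch else left_ch
    hbo[idx, contra] <- hbo[idx, contra] + params$contralateral_gain * seg
    hbo[idx, ipsi] <- hbo[idx, ipsi] + params$ipsilateral_gain * seg
  }
  hbr <- params$hbr_ratio * hbo

  # systemic oscillations: common phase, per-channel amplitude jitter
  freqs <- c(0.1, 0.25, 1.0)
  amps <- c(params$mayer_amp, params$resp_amp, params$cardiac_amp)
  phases <- stats::runif(3, 0, 2 * pi)
  for (j in seq_along(freqs)) {
    if (amps[j] == 0) next
    wave <- sin(2 * pi * freqs[j] * t + phases[j])
    jitter <- stats::runif(n_ch, 0.8, 1.2)
    hbo <- hbo + outer(wave, amps[j] * jitter)
    hbr <- hbr + outer(wave, abs(params$hbr_ratio) * amps[j] * jitter)
  }
  # linear drift, per-channel slope in uM/min
  slopes <- stats::runif(n_ch, -params$drift, params$drift)
  hbo <- hbo + outer(t / 60, slopes)
  hbr <- hbr + outer(t / 60, slopes * abs(params$hbr_ratio))
  # white measurement noise
  sd_o <- white_sigma(params, condition)
  if (sd_o > 0) {
    hbo <- hbo + matrix(stats::rnorm(n * n_ch, sd = sd_o), n, n_ch)
    hbr <- hbr + matrix(stats::rnorm(n * n_ch,
                                     sd = sd_o * abs(params$hbr_ratio)),
                        n, n_ch)
  }

  fnirs_recording(hbo, hbr, fs,
                  event_log(onsets, hands, rep(condition, n_tr)),
                  montage = mont)
}

#' Generate a reproducible benchmark suite of synthetic sessions
#'
#' One session per (SNR, condition) grid point, each with its own derived
#' seed, plus a manifest recording the exact settings and ground truth.
#'
#' @param params base [synth_params()]; `snr` and `seed` are overridden
#'   per grid point.
#' @param snr numeric vector of SNR values.
#' @param conditions character vector of conditions.
#' @param seed base seed; session `i` uses `seed + i`.
#' @return list with `sessions` (list of `fnirs_recording`) and `manifest`
#'   (data frame: id, condition, snr, imagery_scale, seed, n_trials).
#' @export
generate_benchmark <- function(params = synth_params(), snr = c(1, 2, 3),
                               conditions = c("execution", "imagery"),
                               seed = 1) {
  grid <- expand.grid(snr = snr, condition = conditions,
                      stringsAsFactors = FALSE)
  sessions <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$snr <- grid$snr[i]
    p$seed <- seed + i
    sessions[[i]] <- generate_session(p, grid$condition[i])
  }
  manifest <- data.frame(id = seq_len(nrow(grid)),
                         condition = grid$condition, snr = grid$snr,
                         imagery_scale = params$imagery_scale,
                         seed = seed + seq_len(nrow(grid)),
                         n_trials = 2 * params$trials_per_condition)
  list(sessions = sessions, manifest = manifest)
}
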