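# Synthetic polysomnographic EEG with ground-truth sleep-spindle annotations.
#
# The generator emulates the statistical structure of NREM sleep EEG needed to
# exercise a spindle detector: a 1/f^alpha colored-noise background and
# fusiform sigma-band (11-16 Hz) bursts of 0.5-3 s, with slow spindles
# (12-13 Hz) on frontal channels and fast spindles (14-15 Hz) elsewhere.

DEFAULT_CHANNELS <- c("F4-M1", "C4-M1", "O2-M1", "F3-M2", "C3-M2", "O1-M2")

#' Configuration for the synthetic EEG simulator
#'
#' Bundles every knob of [simulate_recording()] with validated defaults.
#' Spindle carrier frequencies are channel dependent: frontal channels
#' (labels starting with "F") draw from `slow_band`, centroparietal and
#' occipital channels from `fast_band`, mirroring the topography of slow
#' (~12-13 Hz) and fast (~14-15 Hz) spindles.
#'
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @param fs sampling rate in Hz (default 128).
#' @param duration_s recording length in seconds.
#' @param channels ordered channel label vector (default six referential
#'   EEG derivations F4-M1, C4-M1, O2-M1, F3-M2, C3-M2, O1-M2).
#' @param spindle_rate_per_min expected spindle events per minute per channel.
#' @param amp_sigma_ratio spindle peak envelope amplitude divided by
#'   background RMS.
#' @param background list with `noise_exponent` (alpha of the 1/f^alpha
#'   background, default 1) and `rms` (background RMS in microvolts,
#'   default 10).
#' @param slow_band,fast_band carrier frequency ranges in Hz for frontal and
#'   non-frontal channels; both must lie within the sigma band 11-16 Hz.
#' @param duration_band spindle duration range in seconds, within [0.5, 3].
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, duration_s = 60)
#' @export
sim_config <- function(seed = 1L,
                       fs = 128,
                       duration_s = 300,
                       channels = DEFAULT_CHANNELS,
                       spindle_rate_per_min = 3,
                       amp_sigma_ratio = 2,
                       background = list(noise_exponent = 1, rms = 10),
                       slow_band = c(12, 13),
                       fast_band = c(14, 15),
                       duration_band = c(0.5, 3)) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_number(spindle_rate_per_min, "spindle_rate_per_min")
  if (spindle_rate_per_min < 0) stop("`spindle_rate_per_min` must be >= 0", call. = FALSE)
  stopifnot_scalar_number(amp_sigma_ratio, "amp_sigma_ratio", positive = TRUE)
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  if (is.null(background$noise_exponent)) background$noise_exponent <- 1
  if (is.null(background$rms)) background$rms <- 10
  if (background$rms < 0) stop("background rms must be >= 0", call. = FALSE)
  check_band <- function(b, name, lo, hi) {
    if (length(b) != 2L || b[1] >= b[2] || b[1] < lo || b[2] > hi)
      stop(sprintf("`%s` must be an increasing pair within [%g, %g]", name, lo, hi),
           call. = FALSE)
  }
  check_band(slow_band, "slow_band", 11, 16)
  check_band(fast_band, "fast_band", 11, 16)
  check_band(duration_band, "duration_band", 0.5, 3)
  if (fs <= 2 * max(slow_band, fast_band))
    stop("`fs` must exceed twice the highest generated frequency", call. = FALSE)
  structure(list(seed = as.integer(seed), fs = fs, duration_s = duration_s,
                 channels = channels,
                 spindle_rate_per_min = spindle_rate_per_min,
                 amp_sigma_ratio = amp_sigma_ratio,
                 background = background,
                 slow_band = slow_band, fast_band = fast_band,
                 duration_band = duration_band),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic EEG configuration\n")
  cat(sprintf("  fs %g Hz, duration %g s, %d channels\n",
              x$fs, x$duration_s, length(x$channels)))
  cat(sprintf("  spindle rate %g/min, amplitude/background RMS ratio %g\n",
              x$spindle_rate_per_min, x$amp_sigma_ratio))
  cat(sprintf("  background: 1/f^%g, RMS %g uV; slow band %g-%g Hz, fast band %g-%g Hz\n",
              x$background$noise_exponent, x$background$rms,
              x$slow_band[1], x$slow_band[2], x$fast_band[1], x$fast_band[2]))
  invisible(x)
}

#' Colored-noise background EEG
#'
#' Gaussian 1/f^alpha noise generated by spectral shaping: white Gaussian
#' noise is transformed to the frequency domain, each Fourier amplitude is
#' scaled by f^(-alpha/2), and the result is transformed back, demeaned and
#' rescaled to the requested RMS (exactly, unless `rms = 0`).
#'
#' @param n_samples number of samples (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @param noise_exponent spectral exponent alpha (0 = white, 1 = pink).
#' @param rms target root-mean-square amplitude in microvolts.
#' @param seed optional integer seed; when given the output is reproducible
#'   and the caller's RNG state is untouched.
#' @return numeric vector of length `n_samples`, zero mean.
#' @examples
#' bg <- make_background(1024, fs = 128, noise_exponent = 1, rms = 10, seed = 1)
#' sqrt(mean(bg^2))
#' @export
make_background <- function(n_samples, fs, noise_exponent = 1, rms = 10,
                            seed = NULL) {
  stopifnot_scalar_number(n_samples, "n_samples", positive = TRUE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (rms < 0) stop("`rms` must be >= 0", call. = FALSE)
  n <- as.integer(n_samples)
  if (rms == 0) return(numeric(n))
  gen <- function() {
    w <- stats::rnorm(n)
    wf <- stats::fft(w)
    f <- seq_len(n) - 1
    f <- pmin(f, n - f) * fs / n        # folded frequency axis
    scale <- c(0, f[-1]^(-noise_exponent / 2))
    x <- Re(stats::fft(wf * scale, inverse = TRUE)) / n
    x <- x - mean(x)
    x * (rms / sqrt(mean(x^2)))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Fusiform spindle waveform
#'
#' A sigma-band sinusoid under a symmetric raised-cosine (Hann) envelope:
#' the canonical waxing-waning "fusiform" morphology of a sleep spindle.
#' The carrier phase is chosen so the absolute peak sits at the envelope
#' midpoint and equals `amp_uv` exactly; endpoints are (near) zero.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s spindle duration in seconds.
#' @param freq_hz carrier frequency in Hz; must be below `fs / 2`.
#' @param amp_uv peak envelope amplitude in microvolts.
#' @return numeric vector of `round(duration_s * fs)` samples.
#' @examples
#' w <- make_spindle_waveform(128, 1.0, 13, 20)
#' @export
make_spindle_waveform <- function(fs, duration_s, freq_hz, amp_uv) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_number(freq_hz, "freq_hz", positive = TRUE)
  stopifnot_scalar_number(amp_uv, "amp_uv", positive = TRUE)
  if (freq_hz >= fs / 2)
    stop(sprintf("carrier frequency %g Hz aliases at sampling rate %g Hz", freq_hz, fs),
         call. = FALSE)
  n <- round(duration_s * fs)
  if (n < 3) stop("spindle too short for the sampling rate", call. = FALSE)
  i <- seq_len(n) - 1
  env <- 0.5 * (1 - cos(2 * pi * i / (n - 1)))
  mid <- floor(n / 2)                       # 0-based midpoint index
  carrier <- cos(2 * pi * freq_hz * (i - mid) / fs)
  w <- env * carrier
  w * (amp_uv / max(abs(w)))
}

#' Create a spindle event table
#' @keywords internal
#' @noRd
spindle_events <- function(channel = character(), onset_s = numeric(),
                           duration_s = numeric(), freq_hz = numeric(),
                           amp_uv = numeric()) {
  data.frame(channel = as.character(channel), onset_s = onset_s,
             duration_s = duration_s, freq_hz = freq_hz, amp_uv = amp_uv,
             stringsAsFactors = FALSE)
}

#' Simulate a multi-channel EEG recording with ground-truth spindles
#'
#' Spindle events are placed per channel by a homogeneous Poisson process at
#' `spindle_rate_per_min`; a candidate overlapping an already-placed event on
#' the same channel is redrawn (up to 100 attempts, after which the channel is
#' declared saturated and an error is raised). Each event's carrier frequency
#' is drawn uniformly from the channel's band (slow for frontal channels,
#' fast otherwise), its duration uniformly from `duration_band`, and its peak
#' amplitude is `amp_sigma_ratio` times the background RMS.
#'
#' @param config a [sim_config()] object.
#' @return list with `recording` (an [eeg_recording()]) and `events`
#'   (data frame: channel, onset_s, duration_s, freq_hz, amp_uv, sorted by
#'   onset).
#' @examples
#' sim <- simulate_recording(sim_config(seed = 1, duration_s = 60))
#' nrow(sim$events)
#' @export
simulate_recording <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config", call. = FALSE)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  with_seed(config$seed, {
    samples <- matrix(0, nrow = length(config$channels), ncol = n,
                      dimnames = list(config$channels, NULL))
    ev <- spindle_events()
    for (ch in config$channels) {
      bg <- make_background(n, fs, config$background$noise_exponent,
                            config$background$rms)
      band <- if (grepl("^F", ch)) config$slow_band else config$fast_band
      n_ev <- stats::rpois(1, config$spindle_rate_per_min * config$duration_s / 60)
      placed_on <- numeric(0); placed_off <- numeric(0)
      sig <- bg
      if (n_ev > 0) {
        for (k in seq_len(n_ev)) {
          ok <- FALSE
          for (attempt in seq_len(100L)) {
            dur <- stats::runif(1, config$duration_band[1], config$duration_band[2])
            if (dur > config$duration_s)
              stop("recording shorter than the minimum spindle duration", call. = FALSE)
            onset <- stats::runif(1, 0, config$duration_s - dur)
            if (!any(onset < placed_off & onset + dur > placed_on)) { ok <- TRUE; break }
          }
          if (!ok)
            stop(sprintf("spindle placement saturated on channel %s: rate too high for overlap-free placement", ch),
                 call. = FALSE)
          freq <- stats::runif(1, band[1], band[2])
          amp <- config$amp_sigma_ratio * config$background$rms
          wf <- make_spindle_waveform(fs, dur, freq, amp)
          i0 <- round(onset * fs) + 1L
          idx <- i0:(i0 + length(wf) - 1L)
          idx <- idx[idx <= n]
          sig[idx] <- sig[idx] + wf[seq_along(idx)]
          placed_on <- c(placed_on, onset); placed_off <- c(placed_off, onset + dur)
          ev <- rbind(ev, spindle_events(ch, onset, dur, freq, amp))
        }
      }
      samples[ch, ] <- sig
    }
    ev <- ev[order(ev$onset_s), , drop = FALSE]
    rownames(ev) <- NULL
    list(recording = eeg_recording(samples, fs, config$channels),
         events = ev)
  })
}

#' Label 10-s frames by ground-truth spindle overlap
#'
#' A frame (half-open interval `[start, start + frame_s)`) on a channel is
#' labeled 1 if some event on that channel overlaps it by at least
#' `min_overlap_s` seconds, else 0. The result is invariant to the order of
#' the event table.
#'
#' @param events spindle event data frame (channel, onset_s, duration_s, ...).
#' @param duration_s recording length in seconds; frames tile
#'   `[0, duration_s)`.
#' @param channels channel labels defining the row order of the result.
#' @param frame_s frame length in seconds (default 10).
#' @param min_overlap_s minimum overlap in seconds to call a frame positive
#'   (default 0.25).
#' @return integer matrix, channels x frames, entries 0/1.
#' @examples
#' ev <- data.frame(channel = "C4-M1", onset_s = 9.9, duration_s = 1.5,
#'                  freq_hz = 14, amp_uv = 20)
#' label_segments(ev, duration_s = 30, channels = "C4-M1")
#' @export
label_segments <- function(events, duration_s, channels, frame_s = 10,
                           min_overlap_s = 0.25) {
  if (min_overlap_s < 0) stop("`min_overlap_s` must be >= 0", call. = FALSE)
  n_frames <- floor(duration_s / frame_s)
  lab <- matrix(0L, nrow = length(channels), ncol = n_frames,
                dimnames = list(channels, NULL))
  if (nrow(events) == 0) return(lab)
  if (any(events$onset_s < 0) ||
      any(events$onset_s + events$duration_s > duration_s + 1e-9))
    stop("event outside recording span", call. = FALSE)
  if (!all(events$channel %in% channels))
    stop("event on unknown channel: ",
         paste(setdiff(events$channel, channels), collapse = ", "), call. = FALSE)
  for (r in seq_len(nrow(events))) {
    a <- events$onset_s[r]; b <- a + events$duration_s[r]
    ch <- events$channel[r]
    for (fr in seq_len(n_frames)) {
      lo <- (fr - 1) * frame_s; hi <- fr * frame_s
      ov <- min(b, hi) - max(a, lo)
      if (ov >= min_overlap_s) lab[ch, fr] <- 1L
    }
  }
  lab
}
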