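# Per-frame feature families: power spectral density (band powers), Morlet
# continuous-wavelet features, the probability-plot Gaussianity score, and
# the bispectrum diagonal-slice band ratio.
#
# All features are computed on mean-removed signals, so they are invariant
# to a constant amplitude offset.

#' Biased autocorrelation sequence
#'
#' `A(xi) = (1/N) * sum_t x_t x_(t+xi)` on the mean-removed signal, for lags
#' `0 .. N-1`; `A(0)` is the population-style variance. Computed via FFT
#' (equivalent to the direct double sum to machine precision).
#'
#' @param x numeric sample vector, length >= 2.
#' @return numeric vector of length `N` (lags 0..N-1).
#' @export
autocorrelation <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  x <- x - mean(x)
  m <- next_pow2(2L * n)
  X <- stats::fft(c(x, numeric(m - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / m
  r[seq_len(n)] / n
}

#' Power spectral density of an EEG segment
#'
#' The PSD is the Fourier transform of the signal's autocorrelation
#' function. Three estimators are provided:
#' \describe{
#'   \item{`"welch"`}{(default) Welch average of Hann-windowed 2-s segments
#'     with 50% overlap — the production estimator, lower variance.}
#'   \item{`"periodogram"`}{the squared Fourier magnitude `|X|^2 / (N fs)`
#'     of the mean-removed signal, evaluated on a `2N-1`-point grid.}
#'   \item{`"acf"`}{the Fourier transform of the biased autocorrelation
#'     sequence on the same grid — identical to the periodogram by the
#'     Wiener-Khinchin theorem, retained as an algebraic cross-check.}
#' }
#' All estimators return a one-sided density: summing `power * delta_f`
#' rectangularly recovers the signal variance (exactly for the periodogram
#' and ACF routes).
#'
#' @param x numeric vector, length >= 16.
#' @param fs sampling rate in Hz.
#' @param method one of `"welch"`, `"periodogram"`, `"acf"`.
#' @param window_s Welch window length in seconds (default 2).
#' @param overlap Welch fractional overlap (default 0.5).
#' @return object of class `psd`: list with `freqs` (Hz, ascending from 0)
#'   and `power` (non-negative density per Hz).
#' @examples
#' x <- sin(2 * pi * 13 * (0:1279) / 128)
#' s <- power_spectral_density(x, 128)
#' s$freqs[which.max(s$power)]
#' @export
power_spectral_density <- function(x, fs,
                                   method = c("welch", "periodogram", "acf"),
                                   window_s = 2, overlap = 0.5) {
  method <- match.arg(method)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  n <- length(x)
  if (n < 16) stop("need at least 16 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  x <- x - mean(x)

  if (method == "welch") {
    L <- round(window_s * fs)
    if (L > n) L <- n
    hop <- max(1L, round(L * (1 - overlap)))
    starts <- seq(1L, n - L + 1L, by = hop)
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
    U <- sum(w^2)
    nk <- floor(L / 2) + 1L
    acc <- numeric(nk)
    for (s0 in starts) {
      seg <- x[s0:(s0 + L - 1L)]
      seg <- (seg - mean(seg)) * w
      S <- Mod(stats::fft(seg))^2
      acc <- acc + S[seq_len(nk)]
    }
    p <- acc / (length(starts) * U * fs)
    dbl <- rep(2, nk); dbl[1] <- 1
    if (L %% 2 == 0) dbl[nk] <- 1                       # Nyquist bin unpaired
    freqs <- (seq_len(nk) - 1) * fs / L
    power <- p * dbl
  } else {
    m <- 2L * n - 1L
    nk <- n
    if (method == "periodogram") {
      X <- stats::fft(c(x, numeric(m - n)))
      base <- Mod(X)^2 / (n * fs)
    } else {
      a <- autocorrelation(x) * n                      # unnormalized r(xi)
      s <- c(a, rev(a[-1]))                            # symmetric extension
      base <- Re(stats::fft(s)) / (n * fs)
      base <- pmax(base, 0)                            # clip FFT round-off
    }
    dbl <- rep(2, nk); dbl[1] <- 1
    freqs <- (seq_len(nk) - 1) * fs / m
    power <- base[seq_len(nk)] * dbl
  }
  structure(list(freqs = freqs, power = power, fs = fs, method = method),
            class = "psd")
}

#' Band power by rectangular integration
#'
#' Integrates the one-sided density over the half-open band `[lo_hz, hi_hz)`.
#'
#' @param spectrum a `psd` object.
#' @param lo_hz,hi_hz band edges in Hz, `lo_hz < hi_hz <= fs/2`.
#' @return power in the band (microvolts squared).
#' @export
band_power <- function(spectrum, lo_hz, hi_hz) {
  if (lo_hz >= hi_hz) stop("`lo_hz` must be below `hi_hz`", call. = FALSE)
  df <- spectrum$freqs[2] - spectrum$freqs[1]
  if (lo_hz < 0 || hi_hz > max(spectrum$freqs) + df)
    stop(sprintf("band [%g, %g) Hz outside the spectral grid [0, %g]",
                 lo_hz, hi_hz, max(spectrum$freqs)), call. = FALSE)
  sel <- spectrum$freqs >= lo_hz & spectrum$freqs < hi_hz
  sum(spectrum$power[sel]) * df
}

#' @param total_band reference band in Hz for the denominator
#'   (default 0.5-30 Hz, the conventional EEG range).
#' @rdname band_power
#' @export
relative_band_power <- function(spectrum, lo_hz, hi_hz, total_band = c(0.5, 30)) {
  tot <- band_power(spectrum, total_band[1], total_band[2])
  if (tot == 0) return(0)
  min(band_power(spectrum, lo_hz, hi_hz) / tot, 1)
}

#' Spectral peak frequency within a band
#' @param spectrum a `psd` object.
#' @param lo_hz,hi_hz search band in Hz (defaults 9-18, bracketing sigma).
#' @return frequency (Hz) of the maximum density inside the band.
#' @export
spectral_peak <- function(spectrum, lo_hz = 9, hi_hz = 18) {
  sel <- which(spectrum$freqs >= lo_hz & spectrum$freqs < hi_hz)
  if (!length(sel)) stop("band outside the spectral grid", call. = FALSE)
  spectrum$freqs[sel[which.max(spectrum$power[sel])]]
}

# kernel FFTs are reused across segments of identical length/rate/scales
.cwt_cache <- new.env(parent = emptyenv())

cwt_plan <- function(n, fs, freqs_hz, omega0) {
  key <- paste(n, fs, omega0, paste(signif(freqs_hz, 10), collapse = ","), sep = "|")
  plan <- .cwt_cache[[key]]
  if (!is.null(plan)) return(plan)
  scales <- omega0 * fs / (2 * pi * freqs_hz)          # scale in samples
  L <- ceiling(4 * max(scales))
  P <- next_pow2(n + 2L * L + 1L)
  kernels <- lapply(scales, function(a) {
    j <- -L:L
    u <- j / a
    # conjugate-reversed Morlet kernel: correlation becomes convolution
    k <- pi^(-0.25) * exp(1i * omega0 * u - u^2 / 2) / sqrt(a)
    stats::fft(c(k, complex(real = numeric(P - length(k)))))
  })
  plan <- list(scales = scales, L = L, P = P, kernels = kernels)
  .cwt_cache[[key]] <- plan
  plan
}

#' Continuous wavelet transform (Morlet) of an EEG segment
#'
#' Coefficients `C(b, a) = (1 / sqrt(a)) * sum_t x(t) psi((t - b) / a)` on a
#' log-spaced scale grid, with the analytic Morlet mother wavelet
#' `psi(u) = pi^(-1/4) exp(i omega0 u) exp(-u^2 / 2)` (omega0 = 6 cycles).
#' Scales are expressed through their equivalent frequencies
#' `f = omega0 * fs / (2 pi a)`.
#'
#' @param x numeric sample vector (mean-removed internally).
#' @param fs sampling rate in Hz.
#' @param freqs_hz equivalent-frequency grid; default 32 log-spaced points
#'   covering 2-30 Hz.
#' @param omega0 Morlet center frequency in radians (default 6).
#' @return object of class `scalogram`: list with `freqs_hz`, `scales`
#'   (samples), `coeffs` (complex matrix, scales x time) and `fs`.
#' @export
cwt <- function(x, fs, freqs_hz = NULL, omega0 = 6) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  n <- length(x)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  if (is.null(freqs_hz))
    freqs_hz <- exp(seq(log(2), log(30), length.out = 32))
  if (!length(freqs_hz) || any(freqs_hz <= 0))
    stop("`freqs_hz` must be positive and non-empty", call. = FALSE)
  x <- x - mean(x)
  plan <- cwt_plan(n, fs, freqs_hz, omega0)
  X <- stats::fft(c(x, numeric(plan$P - n)))
  coeffs <- matrix(0i, nrow = length(freqs_hz), ncol = n)
  for (s in seq_along(freqs_hz)) {
    z <- stats::fft(X * plan$kernels[[s]], inverse = TRUE) / plan$P
    coeffs[s, ] <- z[(plan$L + 1):(plan$L + n)]
  }
  structure(list(freqs_hz = freqs_hz, scales = plan$scales, coeffs = coeffs,
                 fs = fs, omega0 = omega0),
            class = "scalogram")
}

#' Scalar features from a scalogram
#'
#' Mean and maximum coefficient magnitude over sigma-equivalent scales, and
#' the sigma-scale share of total scalogram energy.
#'
#' @param scalogram a [cwt()] result.
#' @param sigma_band sigma band in Hz (default 11-16).
#' @return named numeric: `cwt_sigma_mean`, `cwt_sigma_max`,
#'   `cwt_sigma_ratio`.
#' @export
cwt_features <- function(scalogram, sigma_band = c(11, 16)) {
  m <- Mod(scalogram$coeffs)
  sel <- scalogram$freqs_hz >= sigma_band[1] & scalogram$freqs_hz <= sigma_band[2]
  if (!any(sel)) stop("scale grid does not cover the sigma band", call. = FALSE)
  tot <- sum(m^2)
  c(cwt_sigma_mean = mean(m[sel, ]),
    cwt_sigma_max = max(m[sel, ]),
    cwt_sigma_ratio = if (tot == 0) 0 else sum(m[sel, ]^2) / tot)
}

#' Normal probability-plot pair
#'
#' Sorted standardized sample values `q` against the reference normal
#' quantiles `p` at Blom plotting positions
#' `Phi^-1((j - 0.375) / (N + 0.25))`.
#'
#' @param x numeric vector, `N >= 20`, non-constant.
#' @return object of class `prob_plot_pair`: list with `q`, `p`, `N`.
#' @export
probability_plot_pair <- function(x) {
  n <- length(x)
  if (n < 20) stop("need at least 20 samples", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance input: standardization undefined", call. = FALSE)
  structure(list(q = sort((x - mean(x)) / s),
                 p = stats::qnorm((seq_len(n) - 0.375) / (n + 0.25)),
                 N = n),
            class = "prob_plot_pair")
}

#' Gaussianity score from a probability-plot pair
#'
#' `1 - sum((q_j - p_j)^2) / sum((q_j - mean(q))^2)`: equals 1 when the
#' sample quantiles coincide with the normal reference, and falls below 1 as
#' the segment's amplitude distribution departs from Gaussian — which is
#' exactly what a high-amplitude oscillatory burst inside a noise frame
#' produces. Always <= 1.
#'
#' @param pair a [probability_plot_pair()], or anything with `q` and `p`.
#' @return scalar score, at most 1.
#' @export
ngs_score <- function(pair) {
  q <- pair$q; p <- pair$p
  1 - sum((q - p)^2) / sum((q - mean(q))^2)
}

#' @param x numeric sample vector (convenience wrapper building the pair).
#' @rdname ngs_score
#' @export
ngs <- function(x) ngs_score(probability_plot_pair(x))

#' Bispectrum diagonal slice
#'
#' Direct estimator of the third-order spectrum restricted to the diagonal
#' `omega1 = omega2 = omega`: the signal is cut into `n_blocks`
#' Hann-windowed blocks, `X_k` is each block's DFT, and
#' `B(omega) = mean_k X_k(omega)^2 * conj(X_k(2 omega))`. The returned
#' magnitude `P(omega) = |B(omega, omega)|` runs up to `fs / 4` so that
#' `2 omega` stays on the grid. Unlike the (second-order) power spectrum the
#' bispectrum retains Fourier phase relations, so quadratic phase coupling
#' between frequency components stands out on the diagonal.
#'
#' @param x numeric vector; length must allow blocks of >= 64 samples.
#' @param fs sampling rate in Hz.
#' @param n_blocks number of averaging blocks (default 8).
#' @return object of class `bispec_slice`: list with `freqs` (Hz) and `P`
#'   (non-negative magnitude).
#' @export
bispectrum_diagonal <- function(x, fs, n_blocks = 8) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  n <- length(x)
  L <- floor(n / n_blocks)
  if (L < 64)
    stop(sprintf("block length %d < 64 samples: fewer blocks or more data needed", L),
         call. = FALSE)
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
  jmax <- floor(L / 4)
  acc <- complex(real = numeric(jmax + 1))
  for (k in seq_len(n_blocks)) {
    seg <- x[((k - 1) * L + 1):(k * L)]
    X <- stats::fft((seg - mean(seg)) * w)
    j <- 0:jmax
    acc <- acc + X[j + 1]^2 * Conj(X[2 * j + 1])
  }
  structure(list(freqs = (0:jmax) * fs / L, P = Mod(acc / n_blocks), fs = fs),
            class = "bispec_slice")
}

#' Bispectrum score: diagonal-slice band ratio
#'
#' Rectangular integral of the diagonal-slice magnitude `P(omega)` over the
#' numerator band divided by the integral over the denominator band. With
#' the sigma band on top of the broadband denominator, the score grows when
#' third-order structure concentrates at spindle frequencies.
#'
#' @param slice a [bispectrum_diagonal()] result.
#' @param numerator,denominator bands in Hz, within the slice grid.
#' @return non-negative ratio; equals 1 when the bands coincide.
#' @export
bgs <- function(slice, numerator = c(11, 16), denominator = c(0.5, 30)) {
  df <- slice$freqs[2] - slice$freqs[1]
  band_sum <- function(b, name) {
    if (b[1] >= b[2] || b[1] < 0 || b[2] > max(slice$freqs) + df)
      stop(sprintf("%s band [%g, %g) outside slice grid [0, %g]",
                   name, b[1], b[2], max(slice$freqs)), call. = FALSE)
    sum(slice$P[slice$freqs >= b[1] & slice$freqs < b[2]]) * df
  }
  num <- band_sum(numerator, "numerator")
  den <- band_sum(denominator, "denominator")
  if (den == 0) stop("denominator band integral is zero", call. = FALSE)
  num / den
}

FEATURE_NAMES <- c("bp_delta", "bp_theta", "bp_alpha", "bp_sigma", "bp_beta",
                   "rel_sigma", "peak_hz",
                   "cwt_sigma_mean", "cwt_sigma_max", "cwt_sigma_ratio",
                   "ngs", "bgs")

#' Assemble the 12-feature vector for one 10-s segment
#'
#' Fixed order: Welch band powers (delta 0.5-4, theta 4-8, alpha 8-11,
#' sigma 11-16, beta 16-30 Hz), relative sigma power, spectral peak in
#' 9-18 Hz; Morlet sigma-scale mean and max coefficient magnitude and
#' sigma/total energy ratio; Gaussianity score; bispectrum band ratio.
#'
#' @param values numeric vector of one segment (`frame_s * fs` samples).
#' @param fs sampling rate in Hz.
#' @param seg_id optional identifier used in error messages.
#' @return named numeric vector of length 12, finite.
#' @export
assemble_features <- function(values, fs, seg_id = NULL) {
  ctx <- if (is.null(seg_id)) "" else sprintf(" [segment %s]", seg_id)
  wrap <- function(feature, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("feature '%s'%s: %s", feature, ctx, conditionMessage(e)),
           call. = FALSE))
  }
  x <- values - mean(values)
  sp <- wrap("psd", power_spectral_density(x, fs, method = "welch"))
  out <- c(
    bp_delta = wrap("bp_delta", band_power(sp, 0.5, 4)),
    bp_theta = wrap("bp_theta", band_power(sp, 4, 8)),
    bp_alpha = wrap("bp_alpha", band_power(sp, 8, 11)),
    bp_sigma = wrap("bp_sigma", band_power(sp, 11, 16)),
    bp_beta = wrap("bp_beta", band_power(sp, 16, 30)),
    rel_sigma = wrap("rel_sigma", relative_band_power(sp, 11, 16)),
    peak_hz = wrap("peak_hz", spectral_peak(sp, 9, 18)))
  out <- c(out, wrap("cwt", cwt_features(cwt(x, fs))))
  out <- c(out, ngs = wrap("ngs", ngs(x)),
           bgs = wrap("bgs", bgs(bispectrum_diagonal(x, fs))))
  names(out) <- FEATURE_NAMES
  if (any(!is.finite(out)))
    stop(sprintf("non-finite feature(s)%s: %s", ctx,
                 paste(FEATURE_NAMES[!is.finite(out)], collapse = ", ")),
         call. = FALSE)
  out
}

#' Feature matrix for a segment set
#'
#' @param segments an [segment_recording()] result.
#' @return numeric matrix, one row per segment, 12 named columns.
#' @export
extract_features <- function(segments) {
  if (!inherits(segments, "eeg_segments"))
    stop("`segments` must come from segment_recording()", call. = FALSE)
  n <- nrow(segments$values)
  out <- matrix(0, nrow = n, ncol = length(FEATURE_NAMES),
                dimnames = list(NULL, FEATURE_NAMES))
  ids <- paste(segments$index$channel, segments$index$epoch_index,
               segments$index$frame_index, sep = "/")
  for (r in seq_len(n))
    out[r, ] <- assemble_features(segments$values[r, ], segments$fs, ids[r])
  out
}
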