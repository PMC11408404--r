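test_that("biased autocorrelation matches the O(N^2) double-loop oracle", {
  expect_equal(autocorrelation(rep(1, 4)), rep(0, 4))

  set.seed(3)
  x <- rnorm(64)
  a <- autocorrelation(x)
  expect_equal(a[1], mean((x - mean(x))^2), tolerance = 1e-12)
  xc <- x - mean(x)
  oracle <- vapply(0:(length(x) - 1), function(lag)
    sum(xc[1:(length(x) - lag)] * xc[(1 + lag):length(x)]) / length(x),
    numeric(1))
  expect_equal(a, oracle, tolerance = 1e-12)
})

test_that("PSD estimators locate peaks, conserve variance and agree via Wiener-Khinchin", {
  x <- sin(2 * pi * 13 * (0:1279) / 128)
  for (m in c("welch", "periodogram", "acf")) {
    s <- power_spectral_density(x, 128, method = m)
    expect_equal(s$freqs[which.max(s$power)], 13, tolerance = 0.51)
  }

  set.seed(4)
  y <- rnorm(512)
  p <- power_spectral_density(y, 128, method = "periodogram")
  df <- p$freqs[2] - p$freqs[1]
  expect_equal(sum(p$power) * df, mean((y - mean(y))^2), tolerance = 0.01)

  a <- power_spectral_density(y, 128, method = "acf")
  expect_lt(max(abs(a$power - p$power)) / max(p$power), 1e-8)
  expect_identical(a$freqs, p$freqs)
})

test_that("band powers integrate the density over half-open bands", {
  set.seed(5)
  x <- rnorm(1280)
  s <- power_spectral_density(x, 128, method = "periodogram")
  expect_equal(relative_band_power(s, 0.5, 30, total_band = c(0.5, 30)), 1)

  # white noise: sigma share of the 0.5-30 band approaches the flat-spectrum
  # band-width ratio (5 Hz of 29.5 Hz, computed exactly on the grid)
  rels <- vapply(1:200, function(i) {
    set.seed(i)
    relative_band_power(power_spectral_density(rnorm(1280), 128,
                                               method = "periodogram"),
                        11, 16)
  }, numeric(1))
  nbin <- function(b) sum(s$freqs >= b[1] & s$freqs < b[2])
  flat_ratio <- nbin(c(11, 16)) / nbin(c(0.5, 30))
  expect_equal(flat_ratio, 5 / 29.5, tolerance = 0.01)
  se <- sd(rels) / sqrt(length(rels))
  expect_lt(abs(mean(rels) - flat_ratio), 4 * se)

  sine <- power_spectral_density(sin(2 * pi * 13 * (0:1279) / 128), 128,
                                 method = "periodogram")
  expect_gt(relative_band_power(sine, 11, 16), 0.9)
  expect_error(band_power(s, 50, 80), "outside")
})

test_that("Morlet CWT matches the discretized-integral oracle and is linear", {
  z <- cwt(numeric(256), 128)
  expect_true(all(Mod(z$coeffs) == 0))

  x <- sin(2 * pi * 13 * (0:639) / 128)
  sc <- cwt(x, 128)
  peak <- sc$freqs_hz[which.max(rowMeans(Mod(sc$coeffs)))]
  step <- sc$freqs_hz[2] / sc$freqs_hz[1]
  expect_lt(abs(log(peak / 13)), log(step) + 1e-9)

  # direct discretized-integral oracle at one scale, a few positions
  omega0 <- 6
  a <- sc$scales[which.min(abs(sc$freqs_hz - 13))]
  s_idx <- which.min(abs(sc$freqs_hz - 13))
  for (b in c(100, 320, 500)) {
    t <- seq_along(x) - 1
    u <- (t - (b - 1)) / a
    oracle <- sum((x - mean(x)) * Conj(pi^(-0.25) * exp(1i * omega0 * u - u^2 / 2))) / sqrt(a)
    expect_equal(sc$coeffs[s_idx, b], oracle, tolerance = 1e-8)
  }

  sc2 <- cwt(2 * x, 128)
  expect_equal(Mod(sc2$coeffs), 2 * Mod(sc$coeffs), tolerance = 1e-10)
})

test_that("Gaussianity score is 1 at the reference fixed point and ranks non-Gaussian lower", {
  pair <- probability_plot_pair(rnorm(100))
  pair$q <- pair$p                     # quantiles equal the normal reference
  expect_equal(ngs_score(pair), 1)

  meds <- vapply(1:50, function(s) {
    set.seed(s); ngs(rnorm(2000))
  }, numeric(1))
  expect_gt(median(meds), 0.99)
  expect_true(all(meds <= 1))

  set.seed(60)
  gauss <- ngs(rnorm(1000))
  two_point <- ngs(rep(c(-1, 1), 500))
  expect_lt(two_point, gauss)
  expect_error(ngs(rep(2, 50)), "zero-variance")
})

test_that("bispectrum diagonal detects quadratic phase coupling", {
  z <- bispectrum_diagonal(numeric(640), 128)
  expect_true(all(z$P == 0))
  expect_error(bispectrum_diagonal(numeric(200), 128), "64")

  peak_stat <- function(x) {
    b <- bispectrum_diagonal(x, 128)
    max(b$P[b$freqs >= 3])
  }
  ratios <- vapply(1:11, function(s)
    peak_stat(make_coupled_triple(TRUE, s)) /
      peak_stat(make_coupled_triple(FALSE, 100 + s)), numeric(1))
  expect_gt(median(ratios), 2)

  # white noise: peak-to-mean concentration stays below the coupled signal's
  concentration <- function(x) {
    b <- bispectrum_diagonal(x, 128)
    max(b$P[b$freqs >= 3]) / mean(b$P[b$freqs >= 3])
  }
  set.seed(70)
  noise_conc <- median(vapply(1:11, function(i) concentration(rnorm(1280)),
                              numeric(1)))
  coupled_conc <- median(vapply(1:11, function(s)
    concentration(make_coupled_triple(TRUE, s)), numeric(1)))
  expect_lt(noise_conc, coupled_conc)
})

test_that("bispectrum band ratio behaves as a normalized rectangular integral", {
  x <- make_coupled_triple(TRUE, 1)
  slice <- bispectrum_diagonal(x, 128)
  expect_equal(bgs(slice, c(11, 16), c(11, 16)), 1)
  r <- bgs(slice, c(11, 16), c(0.5, 30))
  expect_gte(r, 0); expect_lte(r, 1)

  flat <- slice; flat$P <- rep(1, length(slice$P))
  # oracle: with flat P the ratio is the covered-bin count ratio
  df <- slice$freqs[2] - slice$freqs[1]
  nbin <- function(b) sum(slice$freqs >= b[1] & slice$freqs < b[2])
  expect_equal(bgs(flat, c(11, 16), c(0.5, 30)),
               nbin(c(11, 16)) / nbin(c(0.5, 30)))
  expect_equal(bgs(flat, c(11, 16), c(0.5, 30)), 5 / 29.5, tolerance = 0.05)
  zero <- slice; zero$P <- rep(0, length(slice$P))
  expect_error(bgs(zero), "zero")
})

test_that("the assembled 12-feature vector is stable, finite and offset invariant", {
  set.seed(8)
  x <- rnorm(1280, sd = 10)
  f1 <- assemble_features(x, 128)
  expect_length(f1, 12)
  expect_named(f1, c("bp_delta", "bp_theta", "bp_alpha", "bp_sigma", "bp_beta",
                     "rel_sigma", "peak_hz", "cwt_sigma_mean", "cwt_sigma_max",
                     "cwt_sigma_ratio", "ngs", "bgs"))
  expect_true(all(is.finite(f1)))
  expect_identical(f1, assemble_features(x, 128))
  # adding a constant offset changes nothing (mean removal first)
  expect_equal(assemble_features(x + 57.3, 128), f1, tolerance = 1e-9)

  expect_error(assemble_features(rep(1, 1280), 128, seg_id = "C4-M1/0/1"),
               "C4-M1/0/1")
})

test_that("spindle-bearing frames carry more relative sigma power than background", {
  sim <- sim_high_snr(seed = 21, duration_s = 120)
  lab <- label_segments(sim$events, 120, sim$recording$channel_labels)
  segs <- segment_recording(sim$recording)
  gframe <- segs$index$epoch_index * 3 + segs$index$frame_index
  y <- lab[cbind(match(segs$index$channel, rownames(lab)), gframe + 1L)]
  feats <- extract_features(segs)
  expect_true(min(table(y)) > 3)
  expect_gt(mean(feats[y == 1, "rel_sigma"]), mean(feats[y == 0, "rel_sigma"]))
})
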