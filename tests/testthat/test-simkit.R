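test_that("background noise has the requested RMS, determinism and spectral slope", {
  expect_identical(make_background(100, 128, rms = 0), numeric(100))
  a <- make_background(4096, 128, 1, 10, seed = 7)
  b <- make_background(4096, 128, 1, 10, seed = 7)
  expect_identical(a, b)
  expect_equal(mean(a), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(a^2)), 10, tolerance = 1e-9)
  expect_error(make_background(0, 128), "n_samples")

  # averaged periodogram of 1/f noise: log-log slope near -1 over 1-30 Hz,
  # fitted with an independent least-squares oracle
  bg <- make_background(2^15, 128, noise_exponent = 1, rms = 10, seed = 3)
  p <- power_spectral_density(bg, 128, method = "welch", window_s = 8)
  sel <- p$freqs >= 1 & p$freqs <= 30
  lx <- log(p$freqs[sel]); ly <- log(p$power[sel])
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  expect_lt(abs(slope - (-1)), 0.25)
})

test_that("spindle waveform is a Hann-windowed sigma sinusoid", {
  expect_length(make_spindle_waveform(200, 1.0, 13, 20), 200)

  w <- make_spindle_waveform(128, 1.5, 13, 20)
  n <- length(w)
  mid <- floor(n / 2) + 1L            # 1-based position of 0-based floor(N/2)
  expect_equal(max(abs(w)), 20)
  expect_equal(which.max(abs(w)), mid)
  expect_lt(abs(w[1]), 0.01 * 20)
  expect_lt(abs(w[n]), 0.01 * 20)

  # dominant DFT bin nearest the carrier, against a brute-force DFT oracle
  w2 <- make_spindle_waveform(128, 2, 13, 10)
  N <- length(w2)
  dft_mag <- vapply(0:(N %/% 2), function(k)
    Mod(sum(w2 * exp(-2i * pi * k * (0:(N - 1)) / N))), numeric(1))
  peak_hz <- (which.max(dft_mag) - 1) * 128 / N
  expect_equal(peak_hz, 13, tolerance = 128 / N + 1e-9)

  expect_error(make_spindle_waveform(128, 1, 70, 10), "alias")
})

test_that("simulated events respect invariants and channel band topography", {
  cfg <- sim_config(seed = 2, duration_s = 120)
  sim <- simulate_recording(cfg)
  ev <- sim$events
  expect_true(all(ev$onset_s >= 0))
  expect_true(all(ev$onset_s + ev$duration_s <= 120 + 1e-9))
  expect_true(all(ev$freq_hz >= 11 & ev$freq_hz <= 16))
  expect_true(all(ev$duration_s >= 0.5 & ev$duration_s <= 3))
  # frontal channels slow, others fast
  frontal <- grepl("^F", ev$channel)
  expect_true(all(ev$freq_hz[frontal] >= 12 & ev$freq_hz[frontal] <= 13))
  expect_true(all(ev$freq_hz[!frontal] >= 14 & ev$freq_hz[!frontal] <= 15))
  expect_false(is.unsorted(ev$onset_s))
  # no same-channel overlap
  for (ch in unique(ev$channel)) {
    e <- ev[ev$channel == ch, ]
    e <- e[order(e$onset_s), ]
    if (nrow(e) > 1)
      expect_true(all(e$onset_s[-1] >= (e$onset_s + e$duration_s)[-nrow(e)]))
  }
  # determinism: identical config => bit-identical recording and events
  sim2 <- simulate_recording(cfg)
  expect_identical(sim$recording$samples, sim2$recording$samples)
  expect_identical(sim$events, sim2$events)

  expect_identical(nrow(simulate_recording(
    sim_config(seed = 3, duration_s = 60, spindle_rate_per_min = 0))$events), 0L)
})

test_that("event counts match a Monte-Carlo re-simulation of the placement process", {
  # oracle: an independent implementation of Poisson placement with
  # same-channel overlap rejection, measuring the accepted-count mean
  oracle_counts <- function(seeds, rate = 3, duration = 600, dband = c(0.5, 3)) {
    vapply(seeds, function(s) {
      set.seed(s)
      n_ev <- rpois(1, rate * duration / 60)
      acc <- matrix(numeric(0), ncol = 2)
      for (k in seq_len(n_ev)) {
        for (a in 1:100) {
          d <- runif(1, dband[1], dband[2]); o <- runif(1, 0, duration - d)
          if (!any(o < acc[, 2] & o + d > acc[, 1])) {
            acc <- rbind(acc, c(o, o + d)); break
          }
        }
      }
      nrow(acc)
    }, numeric(1))
  }
  seeds <- 1:200
  pkg_counts <- vapply(seeds, function(s) {
    nrow(simulate_recording(sim_config(seed = s, duration_s = 600,
                                       channels = "C4-M1",
                                       spindle_rate_per_min = 3,
                                       background = list(rms = 0.001)))$events)
  }, numeric(1))
  orc <- oracle_counts(5000 + seeds)
  se <- sqrt(var(pkg_counts) / length(seeds) + var(orc) / length(orc))
  expect_lt(abs(mean(pkg_counts) - mean(orc)), 3 * se)
})

test_that("frame labeling follows the minimum-overlap rule on half-open frames", {
  chs <- "C4-M1"
  none <- label_segments(spindler:::spindle_events(), 30, chs)
  expect_identical(none, matrix(0L, 1, 3, dimnames = list(chs, NULL)))

  ev <- data.frame(channel = "C4-M1", onset_s = 12, duration_s = 1.5,
                   freq_hz = 13, amp_uv = 20)
  lab <- label_segments(ev, 30, chs)
  expect_identical(as.integer(lab), c(0L, 1L, 0L))

  # event at 9.9-11.4 s: overlap 0.1 s with [0,10) < 0.25, 1.4 s with [10,20)
  ev2 <- data.frame(channel = "C4-M1", onset_s = 9.9, duration_s = 1.5,
                    freq_hz = 13, amp_uv = 20)
  lab2 <- label_segments(ev2, 30, chs, min_overlap_s = 0.25)
  expect_identical(as.integer(lab2), c(0L, 1L, 0L))

  # idempotent and invariant to event order
  ev3 <- rbind(ev2, ev)
  expect_identical(label_segments(ev3, 30, chs), label_segments(ev3[2:1, ], 30, chs))
  expect_error(label_segments(data.frame(channel = "C4-M1", onset_s = 29,
                                         duration_s = 2, freq_hz = 13,
                                         amp_uv = 1), 30, chs),
               "outside")
})

test_that("sigma power is elevated in labeled frames of a high-SNR simulation", {
  sim <- sim_high_snr()
  lab <- label_segments(sim$events, 600, sim$recording$channel_labels)
  segs <- segment_recording(sim$recording)
  gframe <- segs$index$epoch_index * 3 + segs$index$frame_index
  y <- lab[cbind(match(segs$index$channel, rownames(lab)), gframe + 1L)]
  expect_gte(sum(y == 1), 100)
  sig <- apply(segs$values, 1, function(v)
    band_power(power_spectral_density(v, segs$fs), 11, 16))
  expect_gt(mean(sig[y == 1]), mean(sig[y == 0]))
  expect_lt(t.test(sig[y == 1], sig[y == 0], alternative = "greater")$p.value,
            1e-6)
})
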