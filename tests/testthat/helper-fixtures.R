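# Fixtures built in code: separable Gaussian blobs, tiny recordings, a
# hand-crafted EDF file, and per-block phase-coupled test signals.

# two well-separated 2-D Gaussian blobs, 3 sigma apart
make_blobs <- function(n = 200, sep = 3, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, 0, 1), ncol = 2),
             matrix(rnorm(n, sep, 1), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(0, 1), each = n / 2))
}

tiny_recording <- function(duration_s = 30, fs = 128, n_channels = 2,
                           seed = 5) {
  set.seed(seed)
  labs <- c("C4-M1", "F3-M2", "O2-M1")[seq_len(n_channels)]
  samples <- matrix(rnorm(n_channels * duration_s * fs, sd = 10),
                    nrow = n_channels, dimnames = list(labs, NULL))
  eeg_recording(samples, fs, labs)
}

# minimal single-channel EDF written byte-by-byte: an independent rendering
# of the format used to test read_edf against known header fields
write_manual_edf <- function(path, digital, fs = 4,
                             phys_min = -500, phys_max = 500,
                             dig_min = -32768, dig_max = 32767,
                             label = "C4-M1") {
  pad <- function(x, w) formatC(as.character(x), width = -w)
  n_rec <- length(digital) / fs
  hdr <- paste0(pad("0", 8), pad("X", 80), pad("X", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(512, 8), pad("EDF+C", 44), pad(n_rec, 8), pad(1, 8),
                pad(1, 4),
                pad(label, 16), pad("", 80), pad("uV", 8),
                pad(phys_min, 8), pad(phys_max, 8),
                pad(dig_min, 8), pad(dig_max, 8),
                pad("", 80), pad(fs, 8), pad("", 32))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(as.integer(digital), con, size = 2, endian = "little")
  invisible(path)
}

# signal whose blocks carry a quadratically phase-coupled (or randomized)
# (f, f, 2f) triple; phases are redrawn per block so randomization cancels
# under block averaging
make_coupled_triple <- function(coupled, seed, fs = 128, n = 1280,
                                n_blocks = 8, f1 = 6.4) {
  set.seed(seed)
  L <- n / n_blocks
  t <- (seq_len(L) - 1) / fs
  x <- numeric(0)
  for (k in seq_len(n_blocks)) {
    p1 <- runif(1, 0, 2 * pi)
    p3 <- if (coupled) 2 * p1 else runif(1, 0, 2 * pi)
    x <- c(x, cos(2 * pi * f1 * t + p1) + 0.8 * cos(2 * pi * 2 * f1 * t + p3))
  }
  x + rnorm(n, 0, 0.1)
}

# high-SNR simulated recording shared by feature-contrast tests
sim_high_snr <- function(seed = 11, duration_s = 600) {
  simulate_recording(sim_config(seed = seed, duration_s = duration_s,
                                spindle_rate_per_min = 2,
                                amp_sigma_ratio = 4))
}
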