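# Spike templates, recording simulation and the EEG-like epoch generator.

test_that("template waveform matches independent pointwise evaluation", {
  fs <- 20000
  for (p in default_spike_params()) {
    tpl <- make_spike_template(p, fs)
    n <- length(tpl$waveform)
    t <- (seq_len(n) - (n + 1) / 2) / fs
    # oracle: direct scalar evaluation of the cosine-times-Gaussian model
    expected <- vapply(t, function(ti)
      p$amplitude * cos(2 * pi * (ti - p$tau_ph) / p$tau1) *
        exp(-(2.3548 * ti / p$tau2)^2), numeric(1))
    expect_equal(tpl$waveform, expected, tolerance = 1e-12)
    expect_equal(n, 56L)
    # envelope peak lies mid-support
    expect_lt(abs(tpl$peak_index - n / 2), 8)
  }
  # at t = 0 with no phase offset the waveform equals the amplitude
  p0 <- spike_params(1.7, 1e-3, 1e-3, 0)
  expect_equal(eval_spike_waveform(0, p0), 1.7)
  # waveform is linear in A, so the zero-amplitude limit is the zero signal
  pa <- spike_params(0.5, 1e-3, 1e-3, 1e-4)
  pb <- spike_params(1.0, 1e-3, 1e-3, 1e-4)
  tt <- seq(-1e-3, 1e-3, by = 5e-5)
  expect_equal(2 * eval_spike_waveform(tt, pa), eval_spike_waveform(tt, pb))
})

test_that("invalid template parameters are rejected", {
  expect_error(spike_params(0, 1e-3, 1e-3), "amplitude")
  expect_error(spike_params(1, -1e-3, 1e-3), "tau1")
  expect_error(spike_params(1, 1e-3, 0), "tau2")
  expect_error(make_spike_template(spike_params(1, 1e-3, 1e-3), fs = -5),
               "fs")
})

test_that("default templates are pairwise dissimilar in shape", {
  tpls <- lapply(default_spike_params(), make_spike_template, fs = 20000)
  ncc <- function(a, b) {
    a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
    max(abs(convolve(a, rev(b), type = "open")))
  }
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(ncc(tpls[[i]]$waveform, tpls[[j]]$waveform), 0.9)
})

test_that("simulated recordings honor the Poisson firing rate", {
  cfg <- simulation_config(duration = 200, firing_rate = 3.3, snr = 1,
                           seed = 42)
  rec <- simulate_recording(cfg)
  expect_equal(length(rec$samples), 200 * 20000)
  mu <- 3.3 * 200
  for (k in 1:3) {
    nk <- sum(rec$annotations$class_id == k)
    expect_lt(abs(nk - mu), 3 * sqrt(mu))
  }
  expect_false(is.unsorted(rec$annotations$time_index))
})

test_that("zero-noise recordings superpose templates exactly at annotations", {
  cfg <- simulation_config(duration = 5, snr = Inf, seed = 3)
  rec <- simulate_recording(cfg)
  expect_equal(rec$noise_sd, 0)
  tpls <- lapply(cfg$templates, make_spike_template, fs = cfg$fs)
  for (i in seq_len(min(nrow(rec$annotations), 20))) {
    k <- rec$annotations$class_id[i]
    tpl <- tpls[[k]]
    s <- rec$annotations$time_index[i] - tpl$peak_index + 1L
    got <- rec$samples[s:(s + length(tpl$waveform) - 1L)]
    expect_equal(got, tpl$waveform)
  }
})

test_that("noise level matches the SNR definition", {
  cfg <- simulation_config(duration = 10, snr = 1.25, seed = 5)
  rec <- simulate_recording(cfg)
  # implied sd: mean peak template amplitude divided by snr
  tpls <- lapply(cfg$templates, make_spike_template, fs = cfg$fs)
  peaks <- vapply(tpls, function(tp) max(abs(tp$waveform)), numeric(1))
  expect_equal(rec$noise_sd, mean(peaks) / 1.25)
  # empirical sd of spike-free stretches within 5%
  mask <- rep(TRUE, length(rec$samples))
  half <- rec$support_len %/% 2
  for (t in rec$annotations$time_index)
    mask[max(1, t - half):min(length(mask), t + half)] <- FALSE
  expect_lt(abs(sd(rec$samples[mask]) - rec$noise_sd) / rec$noise_sd, 0.05)
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- simulation_config(duration = 2, snr = 1, seed = 99)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- simulate_recording(cfg, recording_id = 2)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("recordings round-trip through disk", {
  cfg <- simulation_config(duration = 1, snr = 2, seed = 8)
  rec <- simulate_recording(cfg)
  prefix <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, prefix)
  back <- read_recording(prefix)
  expect_identical(back$samples, rec$samples)
  expect_equal(back$annotations, rec$annotations)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$snr, rec$snr)
})

test_that("binary epoch generator meets its contract", {
  df <- simulate_binary_epochs(10, window_len = 178, seed = 21)
  expect_equal(dim(df), c(20L, 179L))
  expect_setequal(unique(df$y), c(0L, 1L))
  vals <- as.matrix(df[, 1:178])
  m_non <- mean(abs(vals[df$y == 0L, ]))
  m_sei <- mean(abs(vals[df$y == 1L, ]))
  expect_gt(m_sei, m_non)
  # identical bytes for a fixed seed
  td <- withr::local_tempdir()
  write_epochs_csv(simulate_binary_epochs(5, seed = 4),
                   file.path(td, "a.csv"))
  write_epochs_csv(simulate_binary_epochs(5, seed = 4),
                   file.path(td, "b.csv"))
  expect_identical(readBin(file.path(td, "a.csv"), "raw", 1e6),
                   readBin(file.path(td, "b.csv"), "raw", 1e6))
  expect_error(simulate_binary_epochs(0), "n_per_class")
})

test_that("epoch CSVs binarize five-class labels on read", {
  td <- withr::local_tempdir()
  df <- simulate_binary_epochs(3, window_len = 10, seed = 1)
  df$y <- c(2L, 3L, 5L, 1L, 1L, 4L)  # public five-class dialect
  write_epochs_csv(df, file.path(td, "uci.csv"))
  back <- read_uci_epochs(file.path(td, "uci.csv"))
  expect_equal(back$y, c(0L, 0L, 0L, 1L, 1L, 0L))
})
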