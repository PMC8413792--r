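test_that("wavelet transform reconstructs perfectly", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, stats::rnorm(256))
    dec <- nirsconn:::dwt_periodic(x, 4)
    expect_equal(nirsconn:::idwt_periodic(dec), x, tolerance = 1e-12)
    # orthonormality: energy preserved
    expect_equal(sum(x^2),
                 sum(dec$approx^2) + sum(unlist(dec$details)^2),
                 tolerance = 1e-10)
  }
})

test_that("artifact removal leaves smooth signals untouched", {
  x <- sin(2 * pi * 0.1 * seq(0, 100, by = 0.256))
  expect_equal(wavelet_artifact_removal(x), x, tolerance = 1e-8)
  expect_equal(wavelet_artifact_removal(rep(0, 100)), rep(0, 100))
  expect_error(wavelet_artifact_removal(rnorm(5)), "too short")
})

test_that("artifact removal suppresses spikes without disturbing the rest", {
  x <- sin(2 * pi * 0.1 * seq(0, 100, by = 0.256))
  spike_at <- 200
  xs <- x
  xs[spike_at] <- xs[spike_at] + 50 * stats::sd(x)
  ys <- wavelet_artifact_removal(xs)
  spike_before <- abs(xs[spike_at] - x[spike_at])
  spike_after <- abs(ys[spike_at] - x[spike_at])
  expect_lt(spike_after, 0.10 * spike_before) # >= 90% amplitude reduction
  clean <- setdiff(seq_along(x), (spike_at - 30):(spike_at + 30))
  rms_change <- sqrt(mean((ys[clean] - x[clean])^2)) / sqrt(mean(x[clean]^2))
  expect_lt(rms_change, 0.05)
})

test_that("zero-phase low-pass has the designed gains", {
  fs <- 3.9
  expect_equal(lowpass(rep(2, 100), fs), rep(2, 100), tolerance = 1e-9)
  t <- seq(0, 300, by = 1 / fs)
  mid <- seq(floor(length(t) / 3), floor(2 * length(t) / 3))
  # at the cutoff, two passes square the -3 dB point: amplitude ratio 0.5
  out <- lowpass(sin(2 * pi * 0.4 * t), fs)
  expect_equal(max(abs(out[mid])), 0.5, tolerance = 0.02)
  # a cardiac-band sinusoid is essentially eliminated
  out2 <- lowpass(sin(2 * pi * 1.1 * t), fs)
  expect_lt(max(abs(out2[mid])), 0.01)
  expect_error(lowpass(t, fs, fc_hz = 2.5), "Nyquist")
})

test_that("Beer-Lambert inversion recovers planted concentrations", {
  ev <- tibble::tibble(label = "Rest", onset_s = 0, duration_s = 10, hand = NA)
  m <- build_default_montage()
  hbo <- matrix(1.0, 50, 48)
  hbr <- matrix(-0.5, 50, 48)
  od <- forward_beer_lambert(hbo, hbr)
  rec <- new_recording(od, 3.9, m, ev)
  h <- od_to_hemoglobin(rec)
  expect_equal(h$hbo, hbo, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(h$hbr, hbr, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(h$hbt, hbo + hbr, tolerance = 1e-9, ignore_attr = TRUE)
  # zero OD maps to zero concentrations
  rec0 <- new_recording(array(0, c(50, 48, 2)), 3.9, m, ev)
  h0 <- od_to_hemoglobin(rec0)
  expect_equal(max(abs(h0$hbo)), 0)
  expect_equal(max(abs(h0$hbt)), 0)
  # doubling the pathlength factor halves recovered concentrations
  h2 <- od_to_hemoglobin(rec, dpf = c(12, 12))
  expect_equal(h2$hbo, hbo / 2, tolerance = 1e-9, ignore_attr = TRUE)
  # collinear extinction coefficients are rejected
  bad_ext <- tibble::tibble(wavelength_nm = c(760, 850),
                            eps_hbo = c(1, 2), eps_hbr = c(2, 4))
  expect_error(od_to_hemoglobin(rec, extinction = bad_ext), "singular")
})

test_that("CBSI enforces exact anticorrelation", {
  set.seed(31)
  a <- stats::rnorm(300)
  b <- -a + 0.4 * stats::rnorm(300)
  cc <- cbsi(a, b)
  expect_equal(stats::cor(cc$hbo, cc$hbr), -1)
  # already perfectly anticorrelated input with equal SD is a fixed point
  cc2 <- cbsi(a, -a)
  expect_equal(cc2$hbo, a)
  expect_equal(cc2$hbr, -a)
  expect_error(cbsi(a, rep(1, 300)), "variance")
})

test_that("CBSI variance follows the independence algebra", {
  # for hbr independent of hbo, var(hbo*) = (var(hbo) + alpha^2 var(hbr)) / 4
  # = var(hbo) / 2 since alpha^2 var(hbr) = var(hbo)
  set.seed(32)
  reps <- replicate(200, {
    a <- stats::rnorm(500)
    b <- stats::rnorm(500, sd = 2)
    stats::var(cbsi(a, b)$hbo) / stats::var(a)
  })
  expect_equal(mean(reps), 0.5, tolerance = 0.01)
})

test_that("hbt stays the sum of hbo and hbr through the chain", {
  rec <- tiny_recording(seed = 21)
  hemo <- preprocess_recording(rec, pipeline_config())
  expect_equal(hemo$hbt, hemo$hbo + hemo$hbr, tolerance = 1e-9)
  expect_true(hemo$cbsi_applied)
  expect_error(cbsi_signals(hemo), "already")
  # deterministic: same input, same output
  hemo2 <- preprocess_recording(rec, pipeline_config())
  expect_identical(hemo$hbt, hemo2$hbt)
})

test_that("subject QC applies the strict CV rule", {
  rec <- tiny_recording(seed = 22)
  n_ch <- dim(rec$intensity)[2]
  # clean recording passes
  rep0 <- subject_qc(rec)
  expect_false(rep0$excluded)
  expect_true(all(rep0$per_channel_cv$cv < 0.075))

  noisy <- function(rec, channels, sdlog = 0.2) {
    withr::with_seed(99, {
      for (ch in channels) {
        f <- exp(sdlog * stats::rnorm(dim(rec$intensity)[1]))
        rec$intensity[, ch, 1] <- rec$intensity[, ch, 1] * f
        rec$intensity[, ch, 2] <- rec$intensity[, ch, 2] * f
      }
    })
    rec
  }
  # 44/48 bad channels (91.7% > 80%) -> excluded
  rep1 <- subject_qc(noisy(rec, 1:44))
  expect_true(rep1$excluded)
  expect_gte(sum(rep1$per_channel_cv$cv > 0.075), 44)
  # a fraction exactly at the limit is NOT excluded (strict inequality);
  # 48 channels cannot hit 80% exactly, so probe the boundary at 50%
  rep2 <- subject_qc(noisy(rec, seq_len(n_ch / 2)),
                     channel_fraction_threshold = 0.50)
  expect_equal(rep2$fraction_bad, 0.5)
  expect_false(rep2$excluded)
  # non-positive mean intensity yields infinite CV
  rec$intensity[, 3, 1] <- 0
  expect_equal(subject_qc(rec)$per_channel_cv$cv[3], Inf)
})
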