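test_that("latent sampler hits the planted correlation targets", {
  # small plan, long sample: empirical within/between correlations converge
  plan <- connectivity_plan(n_channels = 10, n_blocks = 2,
                            r_within = 0.9, r_between = 0.0)
  r_target <- target_correlation(plan, task = FALSE)
  x <- withr::with_seed(101, {
    matrix(stats::rnorm(10000 * 10), 10000, 10) %*% chol(r_target)
  })
  emp <- stats::cor(x)
  same <- outer(plan$block_assignment, plan$block_assignment, "==")
  diag(same) <- NA
  within_r <- mean(emp[which(same)])
  between_r <- mean(emp[which(!same)])
  expect_gt(within_r, 0.85)
  expect_lt(within_r, 0.95)
  expect_lt(abs(between_r), 0.05)
})

test_that("plans with invalid correlations are rejected", {
  expect_error(connectivity_plan(r_within = 1.2), "in \\(-1, 1\\)")
  # an indefinite raw block matrix is repaired to a valid correlation
  plan <- connectivity_plan(n_channels = 12, r_within = -0.5,
                            r_between = 0.4)
  r <- target_correlation(plan)
  expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(r), rep(1, 12))
})

test_that("forward model and preprocessing are mutually consistent", {
  # response-only recording: no latent process, physio, noise or artifacts
  spec <- simulation_spec(
    n_subjects = 1, seed = 5, hb_sd = 0, noise_sd = 0, artifact_rate = 0,
    physio = list(amplitudes = c(0, 0, 0),
                  frequencies_hz = c(1.1, 0.25, 0.10))
  )
  rec <- generate_recording(spec, 1, "before_SD")
  h <- od_to_hemoglobin(rec)
  resp <- nirsconn:::responsive_channels(spec$montage)
  silent <- setdiff(seq_len(48), unlist(resp))
  expect_lt(max(abs(h$hbo[, silent])), 1e-9)
  # recovered HbO on responsive channels is the planted HRF response:
  # unit-peak kernel times the planted amplitude
  expect_equal(max(h$hbo[, resp$left[1]]), spec$response_amp_um,
               tolerance = 1e-6)
  expect_gte(min(h$hbo) + 1e-9, min(0, min(h$hbo))) # finite, defined
  # HbR is the planted -gamma * HbO exactly (no independent noise here)
  expect_equal(h$hbr, -spec$hbr_gamma * h$hbo, tolerance = 1e-6,
               ignore_attr = TRUE)
  # before stimulus onset nothing happens anywhere
  pre <- seq_len(floor(59 * spec$fs_hz))
  expect_lt(max(abs(h$hbo[pre, ])), 1e-9)
})

test_that("evoked HbO and HbR are anticorrelated in responsive channels", {
  spec <- simulation_spec(n_subjects = 1, seed = 6, artifact_rate = 0)
  rec <- generate_recording(spec, 1, "before_SD")
  h <- od_to_hemoglobin(rec)
  segs_o <- extract_segments(h, signal = "hbo")
  segs_r <- extract_segments(h, signal = "hbr")
  resp <- nirsconn:::responsive_channels(spec$montage)
  hands <- c(Stim1 = "left", Stim2 = "right", Stim3 = "left",
             Stim4 = "right", Stim5 = "left", Stim6 = "right")
  for (stim in names(hands)) {
    i <- which(segs_o$label == stim)
    for (ch in resp[[hands[[stim]]]]) {
      expect_lt(stats::cor(segs_o$data[[i]][, ch], segs_r$data[[i]][, ch]), 0)
    }
  }
})

test_that("generation is reproducible and subject counts are right", {
  spec <- simulation_spec(n_subjects = 10, seed = 17)
  r1 <- generate_recording(spec, 3, "after_SD")
  r2 <- generate_recording(spec, 3, "after_SD")
  expect_identical(r1$od, r2$od)
  expect_identical(r1$intensity, r2$intensity)
  # different subjects/states differ
  r3 <- generate_recording(spec, 4, "after_SD")
  expect_false(identical(r1$od, r3$od))

  spec_small <- simulation_spec(n_subjects = 10, seed = 17, artifact_rate = 0)
  cohort <- generate_cohort(spec_small)
  expect_length(cohort$recordings, 20)
  states <- vapply(cohort$recordings, function(r) r$sleep_state, "")
  subs <- vapply(cohort$recordings, function(r) r$subject_id, "")
  expect_equal(unname(table(subs)), rep(2L, 10), ignore_attr = TRUE)
  expect_equal(sum(states == "before_SD"), 10)
  expect_equal(nrow(cohort$cognitive_scores), 20)
})

test_that("score coupling drives the planted correlation", {
  # strong negative coupling, vanishing noise: correlation with the planted
  # connectivity change approaches -1
  spec <- simulation_spec(
    n_subjects = 30, seed = 23, artifact_rate = 0,
    score_coupling = list(PAL = -40, RTI = 0, RVPA = 0),
    score_noise_sd = list(PAL = 1e-9, RTI = 20, RVPA = 0.03)
  )
  cohort <- generate_cohort(spec)
  ch <- cohort$cognitive_scores
  d_pal <- ch$PAL[ch$visit == 2] - ch$PAL[ch$visit == 1]
  expect_equal(stats::cor(d_pal, cohort$ground_truth$planted_delta), -1,
               tolerance = 1e-6)
  # zero coupling: near-null correlation at n = 50
  spec0 <- simulation_spec(
    n_subjects = 50, seed = 24, artifact_rate = 0,
    score_coupling = list(PAL = 0, RTI = 0, RVPA = 0)
  )
  cohort0 <- generate_cohort(spec0)
  ch0 <- cohort0$cognitive_scores
  d0 <- ch0$PAL[ch0$visit == 2] - ch0$PAL[ch0$visit == 1]
  expect_lt(abs(stats::cor(d0, cohort0$ground_truth$planted_delta)), 0.2)
})

test_that("qc fixture separates clean and degraded subjects by design", {
  fx <- qc_mixed_fixture(seed = 42)
  reports <- lapply(fx$recordings, subject_qc)
  for (rep in reports) {
    if (rep$subject_id == "S10") {
      expect_true(rep$excluded)
      expect_gte(sum(rep$per_channel_cv$cv > 0.075), 39)
    } else {
      expect_false(rep$excluded)
      expect_true(all(rep$per_channel_cv$cv < 0.075))
    }
  }
  # the pass/fail pattern is seed-independent by construction
  fx2 <- qc_mixed_fixture(seed = 101)
  excl <- vapply(fx2$recordings,
                 function(r) subject_qc(r)$excluded, logical(1))
  subs <- vapply(fx2$recordings, function(r) r$subject_id, "")
  expect_equal(sort(unique(subs[excl])), "S10")
})

test_that("cohorts round-trip through the on-disk format", {
  spec <- simulation_spec(n_subjects = 2, seed = 31, artifact_rate = 0)
  dir <- withr::local_tempdir()
  simulate_cohort_to_dir(spec, dir)
  expect_length(list.files(dir, pattern = "\\.snirf$"), 4)
  expect_true(file.exists(file.path(dir, "scores.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  # same seed -> byte-identical scores file
  dir2 <- withr::local_tempdir()
  simulate_cohort_to_dir(spec, dir2)
  expect_identical(readLines(file.path(dir, "scores.csv")),
                   readLines(file.path(dir2, "scores.csv")))
  back <- read_cohort(dir)
  expect_length(back$recordings, 4)
  expect_equal(nrow(back$cognitive_scores), 4)
  # an invalid spec fails validation before anything is written
  dir3 <- file.path(withr::local_tempdir(), "out")
  spec_json <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_subjects = 0, seed = 1), spec_json,
                       auto_unbox = TRUE)
  expect_error(simulate_cohort_to_dir(spec_json, dir3), "n_subjects")
  expect_false(dir.exists(dir3))
})
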