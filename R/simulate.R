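#' Connectivity plan for the synthetic-cohort generator
#'
#' Specifies the latent inter-channel correlation structure the generator
#' plants: a block (community) structure at rest, an additive change of the
#' off-diagonal correlations during stimulus epochs, and a further additive
#' change of that task modulation in the sleep-deprived session. The default
#' plan encodes the pattern the analysis is designed to detect: connectivity
#' drops during task, and the drop is smaller after sleep deprivation.
#'
#' @param n_channels Number of channels (default 48).
#' @param n_blocks Number of equal communities channels are assigned to.
#' @param r_within,r_between Resting-state Pearson targets within/between
#'   communities.
#' @param task_modulation Additive change of all off-diagonal correlations
#'   during stimulus epochs (negative = task-related decoupling).
#' @param sd_modulation Additive change applied to the task modulation in the
#'   after-sleep-deprivation session (positive = smaller task-related drop).
#' @return List of class `connectivity_plan`.
#' @export
connectivity_plan <- function(n_channels = 48, n_blocks = 4,
                              r_within = 0.35, r_between = 0.10,
                              task_modulation = -0.12, sd_modulation = 0.08) {
  if (r_within <= -1 || r_within >= 1 || r_between <= -1 || r_between >= 1) {
    abort("plan correlations must lie in (-1, 1)")
  }
  block <- rep(seq_len(n_blocks), length.out = n_channels)
  block <- sort(block)
  plan <- structure(
    list(
      n_channels = n_channels,
      block_assignment = block,
      r_within = r_within, r_between = r_between,
      task_modulation = task_modulation, sd_modulation = sd_modulation
    ),
    class = "connectivity_plan"
  )
  # fail early if the implied matrices cannot be repaired to a correlation
  for (task in c(FALSE, TRUE)) {
    for (state in c("before_SD", "after_SD")) {
      target_correlation(plan, task = task, sleep_state = state)
    }
  }
  plan
}

#' Target correlation matrix implied by a plan
#'
#' @param plan A `connectivity_plan`.
#' @param task Whether the epoch is a stimulus epoch.
#' @param sleep_state `"before_SD"` or `"after_SD"`.
#' @param task_modulation,sd_modulation Optional per-subject overrides of the
#'   plan values (subject random effects).
#' @return A valid correlation matrix (positive semidefinite, unit diagonal);
#'   indefinite block designs are repaired by eigenvalue clipping at 1e-10.
#' @export
target_correlation <- function(plan, task = FALSE, sleep_state = "before_SD",
                               task_modulation = plan$task_modulation,
                               sd_modulation = plan$sd_modulation) {
  n <- plan$n_channels
  same <- outer(plan$block_assignment, plan$block_assignment, "==")
  r <- ifelse(same, plan$r_within, plan$r_between)
  if (task) {
    mod <- task_modulation + if (sleep_state == "after_SD") sd_modulation else 0
    r <- r + mod
  }
  r <- pmin(pmax(r, -0.99), 0.99)
  diag(r) <- 1
  nearest_correlation(r)
}

# Eigenvalue-clipping repair to the nearest (in the spectral sense)
# positive-semidefinite matrix, rescaled to unit diagonal.
nearest_correlation <- function(r, eps = 1e-10) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= eps) return(r)
  v <- pmax(e$values, eps)
  m <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m))
  m <- m / outer(d, d)
  diag(m) <- 1
  m
}

#' Canonical double-gamma hemodynamic response function
#'
#' @param t Time points in seconds.
#' @param peak Time-to-peak of the positive lobe (default 6 s).
#' @param undershoot Time-to-peak of the undershoot (default 16 s).
#' @param ratio Undershoot-to-peak amplitude ratio (default 1/6).
#' @return HRF values, scaled to unit peak.
#' @export
double_gamma_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  shape1 <- peak
  shape2 <- undershoot
  h <- stats::dgamma(t, shape = shape1, rate = 1) -
    ratio * stats::dgamma(t, shape = shape2, rate = 1)
  h / max(h)
}

#' Simulation specification for a synthetic fNIRS cohort
#'
#' Bundles every parameter of the generator. Defaults emulate the recording
#' protocol of the study design: the packaged 48-channel montage, 3.9 Hz
#' sampling, the rest + six-stimulus schedule, systemic oscillations at
#' cardiac (~1.1 Hz), respiratory (~0.25 Hz) and Mayer-wave (~0.1 Hz)
#' frequencies, HRF-shaped responses on contralateral motor channels, and the
#' connectivity plan's rest/task and before/after structure.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer master seed; every random stream is derived from it.
#' @param fs_hz Sampling frequency.
#' @param montage,schedule Measurement geometry and event schedule.
#' @param plan A `connectivity_plan`.
#' @param hb_sd Standard deviation (micromolar) of the latent HbO process.
#' @param hbr_gamma HbR = -gamma * HbO + independent noise.
#' @param response_amp_um Peak HbO amplitude of the evoked response
#'   (micromolar) on responsive channels.
#' @param physio List of `amplitudes` (micromolar) and `frequencies_hz` for
#'   the three systemic oscillations.
#' @param hrf List of double-gamma parameters (`peak`, `undershoot`, `ratio`).
#' @param artifact_rate Expected motion spikes per minute per recording.
#' @param noise_sd White-noise standard deviation (micromolar).
#' @param subject_jitter_sd SD of the per-subject random effect added to the
#'   task and sleep-deprivation modulations.
#' @param score_coupling Named list: linear slope of each cognitive-score
#'   change (PAL, RTI, RVPA) on the subject's planted connectivity change.
#' @param score_noise_sd Named list of score-change noise SDs.
#' @param baseline_intensity Baseline detector intensity (arbitrary units).
#' @param dpf Differential pathlength factors used by the forward model.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 10, seed = 1, fs_hz = 3.9,
                            montage = build_default_montage(),
                            schedule = build_default_schedule(),
                            plan = connectivity_plan(nrow(montage)),
                            hb_sd = 0.10, hbr_gamma = 1 / 3,
                            response_amp_um = 0.3,
                            physio = list(
                              amplitudes = c(cardiac = 0.04,
                                             respiratory = 0.03,
                                             mayer = 0.04),
                              frequencies_hz = c(cardiac = 1.1,
                                                 respiratory = 0.25,
                                                 mayer = 0.10)
                            ),
                            hrf = list(peak = 6, undershoot = 16, ratio = 1 / 6),
                            artifact_rate = 0.5, noise_sd = 0.02,
                            subject_jitter_sd = 0.02,
                            score_coupling = list(PAL = -40, RTI = 0, RVPA = 0),
                            score_noise_sd = list(PAL = 1.5, RTI = 20,
                                                  RVPA = 0.03),
                            baseline_intensity = 1, dpf = c(6, 6)) {
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  if (any(physio$amplitudes < 0)) abort("physiological amplitudes must be >= 0")
  if (plan$n_channels != nrow(montage)) {
    abort("plan channel count must match the montage")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      fs_hz = fs_hz, montage = montage, schedule = schedule, plan = plan,
      hb_sd = hb_sd, hbr_gamma = hbr_gamma,
      response_amp_um = response_amp_um, physio = physio, hrf = hrf,
      artifact_rate = artifact_rate, noise_sd = noise_sd,
      subject_jitter_sd = subject_jitter_sd,
      score_coupling = score_coupling, score_noise_sd = score_noise_sd,
      baseline_intensity = baseline_intensity, dpf = dpf
    ),
    class = "simulation_spec"
  )
}

# Deterministic per-(subject, purpose) seed below 2^31.
.stream_seed <- function(seed, subject, purpose) {
  p <- c(recording_before = 1L, recording_after = 2L, effects = 3L,
         scores = 4L, qc = 5L)[[purpose]]
  (abs(seed) %% 1000003L) * 2011L + subject * 17L + p
}

# Channels responsive to each hand: motor-area sources, contralateral side.
responsive_channels <- function(montage) {
  motor_sources <- c("C3", "C4", "FC1", "FC2", "FC5", "FC6", "CP1", "CP2")
  motor <- montage$source %in% motor_sources
  list(
    left = montage$channel[motor & montage$hemisphere == "right"],
    right = montage$channel[motor & montage$hemisphere == "left"]
  )
}

#' Generate one synthetic recording
#'
#' Draws latent per-channel HbO processes from a multivariate Gaussian whose
#' correlation follows the plan's rest/task (and before/after sleep
#' deprivation) targets, imposed exactly per epoch through the Cholesky factor
#' of the target matrix; sets HbR to `-gamma * HbO` plus independent noise;
#' adds HRF-convolved boxcar responses on contralateral motor channels during
#' stimuli (odd stimuli = left hand = right-hemisphere channels and vice
#' versa); adds systemic sinusoids with small frequency jitter and white
#' noise; converts to two-wavelength optical density via the forward
#' Beer-Lambert model; and finally plants Poisson-timed motion spikes with
#' exponentially decaying tails in the optical-density domain.
#'
#' @param spec A `simulation_spec`.
#' @param subject Subject index (1-based).
#' @param sleep_state `"before_SD"` or `"after_SD"`.
#' @param effects Optional per-subject random effects (list with
#'   `task_modulation`, `sd_modulation`); defaults to the plan values.
#' @return An `fnirs_recording` with both `od` and `intensity`.
#' @export
generate_recording <- function(spec, subject, sleep_state,
                               effects = NULL) {
  plan <- spec$plan
  if (is.null(effects)) {
    effects <- list(task_modulation = plan$task_modulation,
                    sd_modulation = plan$sd_modulation)
  }
  purpose <- if (sleep_state == "after_SD") "recording_after" else "recording_before"
  seed <- .stream_seed(spec$seed, subject, purpose)
  withr::with_seed(seed, {
    fs <- spec$fs_hz
    sched <- spec$schedule
    duration <- max(sched$onset_s + sched$duration_s) + 5
    n_t <- ceiling(duration * fs)
    n_ch <- plan$n_channels
    t_sec <- (seq_len(n_t) - 1) / fs

    stim <- sched[sched$label != "Rest", ]
    is_task <- rep(FALSE, n_t)
    for (i in seq_len(nrow(stim))) {
      is_task <- is_task | (t_sec >= stim$onset_s[i] &
                              t_sec < stim$onset_s[i] + stim$duration_s[i])
    }

    r_rest <- target_correlation(plan, task = FALSE, sleep_state = sleep_state,
                                 task_modulation = effects$task_modulation,
                                 sd_modulation = effects$sd_modulation)
    r_task <- target_correlation(plan, task = TRUE, sleep_state = sleep_state,
                                 task_modulation = effects$task_modulation,
                                 sd_modulation = effects$sd_modulation)
    z <- matrix(stats::rnorm(n_t * n_ch), n_t, n_ch)
    x <- matrix(0, n_t, n_ch)
    if (any(!is_task)) x[!is_task, ] <- z[!is_task, , drop = FALSE] %*% chol(r_rest)
    if (any(is_task)) x[is_task, ] <- z[is_task, , drop = FALSE] %*% chol(r_task)

    hbo <- spec$hb_sd * x
    hbr <- -spec$hbr_gamma * hbo +
      0.5 * spec$hbr_gamma * spec$hb_sd *
        matrix(stats::rnorm(n_t * n_ch), n_t, n_ch)

    # evoked responses on contralateral motor channels
    if (spec$response_amp_um > 0) {
      resp_ch <- responsive_channels(spec$montage)
      hrf_t <- seq(0, 30, by = 1 / fs)
      kern <- double_gamma_hrf(hrf_t, spec$hrf$peak, spec$hrf$undershoot,
                               spec$hrf$ratio)
      for (i in seq_len(nrow(stim))) {
        box <- as.numeric(t_sec >= stim$onset_s[i] &
                            t_sec < stim$onset_s[i] + stim$duration_s[i])
        r <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_t)]
        r <- r / max(r)
        chans <- resp_ch[[stim$hand[i]]]
        amp <- spec$response_amp_um
        hbo[, chans] <- hbo[, chans] + amp * r
        hbr[, chans] <- hbr[, chans] - spec$hbr_gamma * amp * r
      }
    }

    # systemic physiological oscillations
    for (k in seq_along(spec$physio$amplitudes)) {
      a <- spec$physio$amplitudes[k]
      if (a <= 0) next
      f <- spec$physio$frequencies_hz[k] * (1 + 0.02 * stats::rnorm(1))
      phase <- stats::runif(n_ch, 0, 2 * pi)
      wave <- sin(outer(2 * pi * f * t_sec, rep(1, n_ch)) +
                    matrix(phase, n_t, n_ch, byrow = TRUE))
      hbo <- hbo + a * wave
      hbr <- hbr + 0.3 * a * wave
    }

    if (spec$noise_sd > 0) {
      hbo <- hbo + spec$noise_sd * matrix(stats::rnorm(n_t * n_ch), n_t, n_ch)
      hbr <- hbr + spec$hbr_gamma * spec$noise_sd *
        matrix(stats::rnorm(n_t * n_ch), n_t, n_ch)
    }

    dist <- attr(spec$montage, "source_detector_distance_cm")
    od <- forward_beer_lambert(hbo, hbr, dist, spec$dpf)

    if (spec$artifact_rate > 0) {
      n_spk <- stats::rpois(1, spec$artifact_rate * duration / 60)
      if (n_spk > 0) {
        tau <- 0.5 # s, decay constant of the spike tail
        for (s in seq_len(n_spk)) {
          ch <- sample.int(n_ch, 1)
          t0 <- stats::runif(1, 0, duration - 2)
          mag <- stats::runif(1, 5, 20) * sample(c(-1, 1), 1)
          tail <- exp(-(t_sec - t0) / tau)
          tail[t_sec < t0] <- 0
          for (wl in 1:2) {
            od[, ch, wl] <- od[, ch, wl] + mag * stats::sd(od[, ch, wl]) * tail
          }
        }
      }
    }

    intensity <- spec$baseline_intensity * 10^(-od)
    new_recording(
      od = od, fs_hz = fs, montage = spec$montage, events = sched,
      subject_id = sprintf("S%02d", subject), sleep_state = sleep_state,
      intensity = intensity
    )
  })
}

#' Generate a synthetic cohort
#'
#' Produces `n_subjects` pairs of recordings (before and after sleep
#' deprivation), subject-level random effects on the planted connectivity
#' modulations, and cognitive-score changes (PAL, RTI, RVPA) linearly coupled
#' to each subject's planted connectivity change plus noise.
#'
#' @param spec A `simulation_spec`.
#' @return Object of class `synthetic_cohort`: list with `recordings` (list,
#'   two per subject), `cognitive_scores` (tibble: subject_id, visit, PAL,
#'   RTI, RVPA), and `ground_truth` (plan plus per-subject effects and planted
#'   deltas).
#' @export
generate_cohort <- function(spec) {
  subjects <- seq_len(spec$n_subjects)
  effects <- purrr::map(subjects, function(s) {
    withr::with_seed(.stream_seed(spec$seed, s, "effects"), {
      list(
        task_modulation = spec$plan$task_modulation +
          spec$subject_jitter_sd * stats::rnorm(1),
        sd_modulation = spec$plan$sd_modulation +
          spec$subject_jitter_sd * stats::rnorm(1)
      )
    })
  })
  recordings <- purrr::flatten(purrr::map(subjects, function(s) {
    list(
      generate_recording(spec, s, "before_SD", effects[[s]]),
      generate_recording(spec, s, "after_SD", effects[[s]])
    )
  }))

  # planted connectivity change: after-vs-before difference of the task
  # modulation, i.e. what the measured task-minus-rest contrast should track
  planted_delta <- purrr::map_dbl(effects, "sd_modulation")
  scores <- purrr::map_dfr(subjects, function(s) {
    withr::with_seed(.stream_seed(spec$seed, s, "scores"), {
      base <- c(PAL = 15 + 3 * stats::rnorm(1),
                RTI = 400 + 30 * stats::rnorm(1),
                RVPA = 0.90 + 0.05 * stats::rnorm(1))
      change <- purrr::imap_dbl(spec$score_coupling, function(slope, nm) {
        slope * planted_delta[s] + spec$score_noise_sd[[nm]] * stats::rnorm(1)
      })
      tibble(
        subject_id = rep(sprintf("S%02d", s), 2), visit = c(1L, 2L),
        PAL = c(base["PAL"], base["PAL"] + change["PAL"]),
        RTI = c(base["RTI"], base["RTI"] + change["RTI"]),
        RVPA = c(base["RVPA"], base["RVPA"] + change["RVPA"])
      )
    })
  })

  structure(
    list(
      recordings = recordings,
      cognitive_scores = scores,
      ground_truth = list(
        plan = spec$plan, effects = effects, planted_delta = planted_delta,
        target_rest_before = target_correlation(spec$plan, FALSE, "before_SD"),
        target_task_before = target_correlation(spec$plan, TRUE, "before_SD"),
        target_task_after = target_correlation(spec$plan, TRUE, "after_SD")
      ),
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d recordings\n",
              x$spec$n_subjects, length(x$recordings)))
  invisible(x)
}

#' Mixed-quality cohort fixture for the QC rule
#'
#' A 10-subject cohort in which subjects 1-9 are clean (per-channel intensity
#' CV well below 5%) and subject 10 carries multiplicative intensity noise on
#' 43 of 48 channels (~90%), pushing their CV above 10%. The pass/fail pattern
#' is by construction the same for every seed.
#'
#' @param seed Master seed (default 42).
#' @return A `synthetic_cohort`.
#' @export
qc_mixed_fixture <- function(seed = 42) {
  spec <- simulation_spec(n_subjects = 10, seed = seed, artifact_rate = 0)
  cohort <- generate_cohort(spec)
  n_ch <- nrow(spec$montage)
  n_bad <- floor(0.9 * n_ch) # 43 of 48
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    if (rec$subject_id != "S10") next
    withr::with_seed(.stream_seed(seed, 10L, "qc") + i, {
      bad <- sort(sample.int(n_ch, n_bad))
      for (ch in bad) {
        noise <- exp(0.2 * stats::rnorm(nrow(rec$intensity)))
        for (wl in 1:2) {
          rec$intensity[, ch, wl] <- rec$intensity[, ch, wl] * noise
        }
      }
      base <- apply(rec$intensity, c(2, 3), mean)
      for (wl in 1:2) {
        rec$od[, , wl] <- -log10(sweep(rec$intensity[, , wl], 2,
                                       base[, wl], "/"))
      }
    })
    cohort$recordings[[i]] <- rec
  }
  cohort
}

#' Write a cohort to disk
#'
#' One SNIRF file per recording (`sub-XX_<state>.snirf`), the cognitive scores
#' as `scores.csv` (subject_id, visit, PAL, RTI, RVPA), and the ground truth
#' (plan scalars and per-subject planted deltas) as `ground_truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    write_snirf(rec, file.path(dir, sprintf("sub-%s_%s.snirf",
                                            sub("^S", "", rec$subject_id),
                                            rec$sleep_state)))
  }
  utils::write.csv(cohort$cognitive_scores, file.path(dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(
      plan = gt$plan[c("n_channels", "r_within", "r_between",
                       "task_modulation", "sd_modulation")],
      planted_delta = gt$planted_delta
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Simulate a cohort and write it to disk
#'
#' @param spec A `simulation_spec`, or a path to a JSON file of spec
#'   parameters (any argument of [simulation_spec()]).
#' @param out_dir Output directory.
#' @return The output directory, invisibly.
#' @export
simulate_cohort_to_dir <- function(spec, out_dir) {
  if (is.character(spec)) {
    args <- jsonlite::read_json(spec, simplifyVector = TRUE)
    keep <- intersect(names(args), names(formals(simulation_spec)))
    spec <- do.call(simulation_spec, args[keep])
  }
  cohort <- generate_cohort(spec)
  write_cohort(cohort, out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `sub-*.snirf` files and `scores.csv`.
#' @return A list with `recordings` and `cognitive_scores`.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.snirf$", full.names = TRUE))
  if (length(files) == 0) abort(paste("no SNIRF files found in", dir))
  recordings <- purrr::map(files, read_snirf)
  scores_path <- file.path(dir, "scores.csv")
  scores <- if (file.exists(scores_path)) {
    as_tibble(utils::read.csv(scores_path, stringsAsFactors = FALSE))
  } else {
    NULL
  }
  list(recordings = recordings, cognitive_scores = scores)
}
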