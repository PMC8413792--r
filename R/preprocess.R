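#' Zero-phase Butterworth low-pass filter
#'
#' Applies a 5th-order Butterworth low-pass design forward and backward
#' (zero phase), so the effective magnitude response is the square of the
#' single-pass response: the amplitude gain at the cutoff is 0.5 rather than
#' the single-pass 1/sqrt(2). The series mean is removed before filtering and
#' restored afterwards, which keeps DC exactly and avoids start-up transients.
#'
#' @param x Numeric series.
#' @param fs_hz Sampling frequency (Hz).
#' @param order Filter order (default 5).
#' @param fc_hz Cutoff frequency (Hz, default 0.4); must be below Nyquist.
#' @return Filtered series, same length.
#' @export
lowpass <- function(x, fs_hz, order = 5, fc_hz = 0.4) {
  if (fc_hz <= 0 || fc_hz >= fs_hz / 2) {
    abort("cutoff frequency must lie strictly between 0 and Nyquist")
  }
  bf <- signal::butter(order, fc_hz / (fs_hz / 2), type = "low")
  mu <- mean(x)
  as.numeric(signal::filtfilt(bf, x - mu)) + mu
}

#' Extinction coefficients for HbO and HbR
#'
#' Molar extinction coefficients (cm^-1 per mol/L) of oxy- and
#' deoxyhemoglobin at the two operating wavelengths, from the standard
#' compiled hemoglobin absorption spectra used throughout CW-fNIRS.
#'
#' @param wavelengths_nm Wavelengths to tabulate (760 and/or 850).
#' @return Tibble with columns `wavelength_nm`, `eps_hbo`, `eps_hbr`.
#' @export
default_extinction <- function(wavelengths_nm = c(760, 850)) {
  tab <- tibble(
    wavelength_nm = c(760, 850),
    eps_hbo = c(1486.5865, 2526.391),
    eps_hbr = c(3843.707, 1798.643)
  )
  out <- tab[match(wavelengths_nm, tab$wavelength_nm), ]
  if (anyNA(out$eps_hbo)) {
    abort("extinction table only covers 760 and 850 nm")
  }
  out
}

# 2x2 coefficient matrix mapping (HbO, HbR) in mol/L to pathlength-normalized
# optical density, one row per wavelength.
.mbll_matrix <- function(extinction) {
  as.matrix(extinction[, c("eps_hbo", "eps_hbr")])
}

#' Forward modified Beer-Lambert model
#'
#' Converts hemoglobin concentration changes (micromolar) to optical-density
#' changes at each wavelength:
#' `dOD(lambda) = (eps_HbO(lambda) * dHbO + eps_HbR(lambda) * dHbR) * d * DPF(lambda)`.
#'
#' @param hbo,hbr Time x channel matrices of concentration change, micromolar.
#' @param distance_cm Source-detector separation.
#' @param dpf Differential pathlength factor per wavelength (recycled).
#' @param extinction Extinction table, see [default_extinction()].
#' @return Array time x channel x wavelength of optical-density change.
#' @export
forward_beer_lambert <- function(hbo, hbr, distance_cm = 3.0, dpf = c(6, 6),
                                 extinction = default_extinction()) {
  E <- .mbll_matrix(extinction)
  dpf <- rep_len(dpf, nrow(E))
  od <- array(0, c(nrow(hbo), ncol(hbo), nrow(E)))
  for (wl in seq_len(nrow(E))) {
    od[, , wl] <- (hbo * E[wl, 1] + hbr * E[wl, 2]) * 1e-6 *
      distance_cm * dpf[wl]
  }
  od
}

#' Convert optical densities to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law per channel and time point by solving
#' the 2x2 linear system across the two wavelengths, yielding oxy- (HbO) and
#' deoxyhemoglobin (HbR) concentration changes in micromolar; total hemoglobin
#' is their sum.
#'
#' @param recording An `fnirs_recording` (or a time x channel x 2 od array
#'   plus explicit `distance_cm`).
#' @param dpf Differential pathlength factor per wavelength (default 6.0 for
#'   both).
#' @param extinction Extinction table, see [default_extinction()].
#' @return An object of class `hemo_signals`: list with `hbo`, `hbr`, `hbt`
#'   (time x channel matrices, micromolar), `fs_hz`, `cbsi_applied`, plus the
#'   recording's montage, events and identifiers.
#' @export
od_to_hemoglobin <- function(recording, dpf = c(6, 6),
                             extinction = NULL) {
  if (is.null(extinction)) {
    extinction <- default_extinction(recording$wavelengths_nm)
  }
  E <- .mbll_matrix(extinction)
  if (abs(det(E)) < 1e-8 * prod(sqrt(rowSums(E^2)))) {
    abort("extinction matrix is singular: wavelength coefficients are collinear")
  }
  d <- attr(recording$montage, "source_detector_distance_cm")
  dpf <- rep_len(dpf, 2)
  if (any(dpf <= 0) || d <= 0) abort("DPF and distance must be positive")
  inv <- solve(E)
  od1 <- recording$od[, , 1] / (d * dpf[1])
  od2 <- recording$od[, , 2] / (d * dpf[2])
  hbo <- (inv[1, 1] * od1 + inv[1, 2] * od2) * 1e6
  hbr <- (inv[2, 1] * od1 + inv[2, 2] * od2) * 1e6
  new_hemo_signals(hbo, hbr, recording)
}

new_hemo_signals <- function(hbo, hbr, recording, cbsi_applied = FALSE) {
  structure(
    list(
      hbo = hbo, hbr = hbr, hbt = hbo + hbr,
      fs_hz = recording$fs_hz, cbsi_applied = cbsi_applied,
      montage = recording$montage, events = recording$events,
      subject_id = recording$subject_id, sleep_state = recording$sleep_state
    ),
    class = "hemo_signals"
  )
}

#' @export
print.hemo_signals <- function(x, ...) {
  cat(sprintf(
    "<hemo_signals> subject %s (%s): %d samples x %d channels%s\n",
    x$subject_id, x$sleep_state, nrow(x$hbo), ncol(x$hbo),
    if (x$cbsi_applied) ", CBSI applied" else ""
  ))
  invisible(x)
}

#' Correlation-based signal improvement (CBSI)
#'
#' Recombines an HbO/HbR channel pair into components that are exactly
#' anticorrelated, enhancing the evoked hemodynamic response which is
#' anticorrelated in the two species by neurovascular coupling:
#' `alpha = sd(hbo) / sd(hbr)`, `hbo* = (hbo - alpha * hbr) / 2`,
#' `hbr* = -hbo* / alpha`.
#'
#' @param hbo,hbr Numeric series with nonzero standard deviation.
#' @return List with `hbo` and `hbr` corrected series.
#' @export
cbsi <- function(hbo, hbr) {
  s_o <- stats::sd(hbo)
  s_r <- stats::sd(hbr)
  if (s_o == 0 || s_r == 0) {
    abort("CBSI requires nonzero variance in both HbO and HbR")
  }
  alpha <- s_o / s_r
  hbo_c <- (hbo - alpha * hbr) / 2
  list(hbo = hbo_c, hbr = -hbo_c / alpha)
}

#' Apply CBSI to every channel of a hemoglobin signal set
#'
#' @param hemo A `hemo_signals` object.
#' @return A `hemo_signals` object with `cbsi_applied = TRUE` and `hbt`
#'   recomputed from the corrected series.
#' @export
cbsi_signals <- function(hemo) {
  if (isTRUE(hemo$cbsi_applied)) abort("CBSI has already been applied")
  hbo <- hemo$hbo
  hbr <- hemo$hbr
  for (ch in seq_len(ncol(hbo))) {
    cc <- cbsi(hbo[, ch], hbr[, ch])
    hbo[, ch] <- cc$hbo
    hbr[, ch] <- cc$hbr
  }
  out <- hemo
  out$hbo <- hbo
  out$hbr <- hbr
  out$hbt <- hbo + hbr
  out$cbsi_applied <- TRUE
  out
}

#' Subject-level quality control on raw intensities
#'
#' Computes the coefficient of variation (sd/mean) of the raw intensity of
#' each channel (the worse of the two wavelengths) and flags the subject for
#' exclusion when strictly more than `channel_fraction_threshold` of channels
#' have CV strictly above `cv_threshold`. Channels with non-positive mean
#' intensity get CV = Inf.
#'
#' @param recording An `fnirs_recording` with raw intensities.
#' @param cv_threshold Per-channel CV limit (default 0.075, i.e. 7.5%).
#' @param channel_fraction_threshold Fraction of bad channels that triggers
#'   exclusion (default 0.80; the rule is a strict inequality).
#' @return Object of class `fnirs_qc`: list with `per_channel_cv` (tibble),
#'   `fraction_bad`, `excluded`, thresholds, subject and sleep state.
#' @export
subject_qc <- function(recording, cv_threshold = 0.075,
                       channel_fraction_threshold = 0.80) {
  if (is.null(recording$intensity)) {
    abort("quality control needs raw intensities; none stored in this recording")
  }
  n_ch <- dim(recording$intensity)[2]
  cv_wl <- apply(recording$intensity, c(2, 3), function(v) {
    m <- mean(v)
    if (m <= 0) Inf else stats::sd(v) / m
  })
  cv <- apply(cv_wl, 1, max)
  frac <- mean(cv > cv_threshold)
  structure(
    list(
      per_channel_cv = tibble(channel = seq_len(n_ch), cv = cv),
      fraction_bad = frac,
      excluded = frac > channel_fraction_threshold,
      cv_threshold = cv_threshold,
      channel_fraction_threshold = channel_fraction_threshold,
      subject_id = recording$subject_id,
      sleep_state = recording$sleep_state
    ),
    class = "fnirs_qc"
  )
}

#' @export
print.fnirs_qc <- function(x, ...) {
  cat(sprintf(
    "<fnirs_qc> subject %s (%s): %.1f%% of channels with CV > %.1f%% -> %s\n",
    x$subject_id, x$sleep_state, 100 * x$fraction_bad, 100 * x$cv_threshold,
    if (x$excluded) "EXCLUDED" else "retained"
  ))
  invisible(x)
}

#' Full preprocessing chain for one recording
#'
#' Runs, in order: wavelet-based artifact suppression per channel and
#' wavelength, zero-phase Butterworth low-pass, conversion to hemoglobin
#' concentration changes via the modified Beer-Lambert law, and (optionally)
#' correlation-based signal improvement.
#'
#' @param recording An `fnirs_recording`.
#' @param config Preprocessing options, see [pipeline_config()]; the relevant
#'   keys are `wavelet` (list: `enabled`, `iqr_factor`), `filter` (`enabled`,
#'   `order`, `fc_hz`), `beer_lambert` (`dpf`) and `cbsi` (logical).
#' @return A `hemo_signals` object.
#' @export
preprocess_recording <- function(recording, config = pipeline_config()) {
  od <- recording$od
  pp <- config$preprocess
  if (isTRUE(pp$wavelet$enabled)) {
    for (wl in seq_len(dim(od)[3])) {
      for (ch in seq_len(dim(od)[2])) {
        od[, ch, wl] <- wavelet_artifact_removal(od[, ch, wl],
                                                 iqr_factor = pp$wavelet$iqr_factor)
      }
    }
  }
  if (isTRUE(pp$filter$enabled)) {
    for (wl in seq_len(dim(od)[3])) {
      for (ch in seq_len(dim(od)[2])) {
        od[, ch, wl] <- lowpass(od[, ch, wl], recording$fs_hz,
                                order = pp$filter$order, fc_hz = pp$filter$fc_hz)
      }
    }
  }
  rec2 <- recording
  rec2$od <- od
  hemo <- od_to_hemoglobin(rec2, dpf = pp$beer_lambert$dpf)
  if (isTRUE(pp$cbsi)) hemo <- cbsi_signals(hemo)
  hemo
}
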