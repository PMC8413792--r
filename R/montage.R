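#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
NULL

# 10-10 labels of the 16 sources and 16 detectors of the packaged frontal/motor
# montage, in fixed order. Channel order is lexicographic by
# (source index, detector index), which fixes a deterministic channel
# numbering for all downstream tables.
.default_sources <- c(
  "F3", "AF7", "AF3", "Fz", "Fpz", "AF4", "F4", "AF8",
  "FC6", "C4", "FC2", "CP2", "FC1", "CP1", "C3", "FC5"
)
.default_detectors <- c(
  "F5", "F1", "Fp1", "AFz", "F2", "Fp2", "F6", "AFF6h",
  "C6", "CC4", "CP4", "C2", "C1", "FC3", "CP3", "C5"
)

# Each source is paired with three spatially adjacent detectors (by 10-10
# geometry), giving 16 x 3 = 48 channels. The pairing is package data: any
# montage supplied in a SNIRF file overrides it.
.default_pairing <- list(
  F3  = c("F5", "F1", "FC3"),
  AF7 = c("F5", "Fp1", "AFz"),
  AF3 = c("F1", "Fp1", "AFz"),
  Fz  = c("F1", "AFz", "F2"),
  Fpz = c("Fp1", "AFz", "Fp2"),
  AF4 = c("AFz", "F2", "Fp2"),
  F4  = c("F2", "F6", "AFF6h"),
  AF8 = c("Fp2", "F6", "AFF6h"),
  FC6 = c("F6", "AFF6h", "C6"),
  C4  = c("C6", "CC4", "C2"),
  FC2 = c("F2", "CC4", "C2"),
  CP2 = c("CP4", "C2", "C1"),
  FC1 = c("F1", "C1", "FC3"),
  CP1 = c("C2", "C1", "CP3"),
  C3  = c("C1", "CP3", "C5"),
  FC5 = c("F5", "FC3", "C5")
)

new_montage <- function(channels, source_labels, detector_labels,
                        source_detector_distance_cm = 3.0) {
  stopifnot(is.data.frame(channels))
  out <- as_tibble(channels)
  attr(out, "source_labels") <- source_labels
  attr(out, "detector_labels") <- detector_labels
  attr(out, "source_detector_distance_cm") <- source_detector_distance_cm
  class(out) <- c("fnirs_montage", class(out))
  validate_montage(out)
}

validate_montage <- function(montage) {
  src <- attr(montage, "source_labels")
  det <- attr(montage, "detector_labels")
  if (!all(montage$source %in% src)) {
    abort("montage channel references a source label that is not defined")
  }
  if (!all(montage$detector %in% det)) {
    abort("montage channel references a detector label that is not defined")
  }
  if (anyDuplicated(paste(montage$source, montage$detector))) {
    abort("montage channel list contains duplicate source-detector pairs")
  }
  if (attr(montage, "source_detector_distance_cm") <= 0) {
    abort("source-detector distance must be positive")
  }
  montage
}

#' Default frontal/motor fNIRS montage
#'
#' Builds the packaged measurement geometry: 16 sources and 16 detectors
#' placed over the prefrontal and motor cortices (10-10 system labels),
#' defining 48 measurement channels at an average source-detector separation
#' of 3 cm. Each source is paired with three adjacent detectors; channels are
#' ordered lexicographically by (source index, detector index) so that channel
#' numbering is deterministic.
#'
#' @return A tibble of class `fnirs_montage` with columns `channel`, `source`,
#'   `detector` and `hemisphere` (`"left"`, `"right"` or `"midline"`, derived
#'   from the source label), carrying the source/detector label vectors and
#'   the source-detector distance as attributes.
#' @export
#' @examples
#' m <- build_default_montage()
#' nrow(m) # 48 channels
build_default_montage <- function() {
  rows <- purrr::map_dfr(seq_along(.default_sources), function(si) {
    s <- .default_sources[si]
    dets <- .default_pairing[[s]]
    di <- match(dets, .default_detectors)
    ord <- order(di)
    tibble(source = s, detector = dets[ord])
  })
  rows$channel <- seq_len(nrow(rows))
  rows$hemisphere <- label_hemisphere(rows$source)
  new_montage(
    rows[, c("channel", "source", "detector", "hemisphere")],
    source_labels = .default_sources,
    detector_labels = .default_detectors,
    source_detector_distance_cm = 3.0
  )
}

# 10-10 convention: odd trailing digit = left hemisphere, even = right,
# letter-only/z suffix = midline.
label_hemisphere <- function(labels) {
  last_digit <- suppressWarnings(as.integer(sub(".*?(\\d)$", "\\1", labels)))
  out <- ifelse(is.na(last_digit), "midline",
    ifelse(last_digit %% 2 == 1, "left", "right")
  )
  out[grepl("z$", labels)] <- "midline"
  out
}

#' Default block-design event schedule
#'
#' One minute of rest followed by six 10-s finger-tapping stimuli separated by
#' 10-s inter-stimulus intervals. Odd-numbered stimuli are left-hand taps,
#' even-numbered right-hand, so the seven task states are
#' Rest, Stim1, ..., Stim6.
#'
#' @return A tibble of class `fnirs_schedule` with columns `label`, `onset_s`,
#'   `duration_s` and `hand` (`NA` for rest).
#' @export
build_default_schedule <- function() {
  onsets <- 60 + 20 * (0:5)
  sched <- tibble(
    label = c("Rest", paste0("Stim", 1:6)),
    onset_s = c(0, onsets),
    duration_s = c(60, rep(10, 6)),
    hand = c(NA, rep(c("left", "right"), 3))
  )
  new_schedule(sched)
}

new_schedule <- function(entries) {
  out <- as_tibble(entries)
  out <- out[order(out$onset_s), ]
  validate_schedule(out)
  class(out) <- unique(c("fnirs_schedule", class(out)))
  out
}

validate_schedule <- function(entries) {
  stopifnot(all(c("label", "onset_s", "duration_s") %in% names(entries)))
  if (any(entries$duration_s <= 0)) abort("event durations must be positive")
  ends <- entries$onset_s + entries$duration_s
  if (nrow(entries) > 1 &&
      any(entries$onset_s[-1] < ends[-nrow(entries)] - 1e-9)) {
    abort("event schedule entries overlap")
  }
  invisible(entries)
}

#' Read an event schedule from a tab-separated file
#'
#' Expects three columns: `label`, `onset_s`, `duration_s`.
#'
#' @param path Path to a TSV file.
#' @return An `fnirs_schedule` tibble.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("label", "onset_s", "duration_s") %in% names(df))) {
    abort("events TSV must have columns label, onset_s, duration_s")
  }
  if (!"hand" %in% names(df)) df$hand <- NA_character_
  new_schedule(df)
}

#' Construct an fNIRS recording object
#'
#' A recording bundles the per-channel, per-wavelength optical-density change
#' with the montage, sampling rate and event schedule. Raw intensities (used
#' by the coefficient-of-variation quality control) are kept alongside when
#' available.
#'
#' @param od Numeric array, time x channel x wavelength, of optical-density
#'   change.
#' @param fs_hz Sampling frequency in Hz.
#' @param montage An `fnirs_montage`.
#' @param events An `fnirs_schedule`.
#' @param wavelengths_nm Length-2 numeric, default `c(760, 850)`.
#' @param subject_id Subject identifier.
#' @param sleep_state `"before_SD"` or `"after_SD"`.
#' @param intensity Optional raw-intensity array matching `od`.
#' @return An object of class `fnirs_recording`.
#' @export
new_recording <- function(od, fs_hz, montage, events,
                          wavelengths_nm = c(760, 850),
                          subject_id = "S01", sleep_state = "before_SD",
                          intensity = NULL) {
  stopifnot(length(dim(od)) == 3)
  if (dim(od)[2] != nrow(montage)) {
    abort("od must have one column per montage channel")
  }
  if (dim(od)[3] != length(wavelengths_nm)) {
    abort("od must have one slice per wavelength")
  }
  if (fs_hz <= 0) abort("fs_hz must be positive")
  span <- max(events$onset_s + events$duration_s)
  if (dim(od)[1] / fs_hz < span - 1e-9) {
    abort("recording does not span the full event schedule")
  }
  if (!sleep_state %in% c("before_SD", "after_SD")) {
    abort("sleep_state must be 'before_SD' or 'after_SD'")
  }
  structure(
    list(
      od = od, fs_hz = fs_hz, montage = montage, events = events,
      wavelengths_nm = wavelengths_nm, subject_id = subject_id,
      sleep_state = sleep_state, intensity = intensity
    ),
    class = "fnirs_recording"
  )
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf(
    "<fnirs_recording> subject %s (%s): %d samples x %d channels x %d wavelengths @ %.2f Hz\n",
    x$subject_id, x$sleep_state, dim(x$od)[1], dim(x$od)[2], dim(x$od)[3],
    x$fs_hz
  ))
  invisible(x)
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat(sprintf(
    "<fnirs_montage> %d sources, %d detectors, %d channels (d = %.1f cm)\n",
    length(attr(x, "source_labels")), length(attr(x, "detector_labels")),
    nrow(x), attr(x, "source_detector_distance_cm")
  ))
  NextMethod()
}
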