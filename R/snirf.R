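#' Write a recording to a SNIRF (HDF5) file
#'
#' Stores raw continuous-wave intensities (dataType 1) in the standard SNIRF
#' layout: `/nirs/data1/dataTimeSeries` holds time x measurement columns in
#' wavelength-major blocks of montage channels, `/nirs/probe` carries the
#' optode labels and wavelengths, and each schedule entry becomes a
#' `/nirs/stim*` group. If the recording has no stored intensities they are
#' reconstructed as `10^(-od)` around a unit baseline.
#'
#' @param recording An `fnirs_recording`.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_snirf <- function(recording, path) {
  if (file.exists(path)) unlink(path)
  intensity <- recording$intensity
  if (is.null(intensity)) {
    intensity <- 10^(-recording$od)
  }
  n_t <- dim(intensity)[1]
  n_ch <- dim(intensity)[2]
  n_wl <- dim(intensity)[3]
  dts <- matrix(0, n_t, n_ch * n_wl)
  for (wl in seq_len(n_wl)) {
    dts[, (wl - 1) * n_ch + seq_len(n_ch)] <- intensity[, , wl]
  }

  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/metaDataTags")
  meta <- c(
    SubjectID = recording$subject_id,
    MeasurementDate = "unknown",
    MeasurementTime = "unknown",
    LengthUnit = "cm",
    TimeUnit = "s",
    FrequencyUnit = "Hz",
    SleepState = recording$sleep_state
  )
  for (k in names(meta)) {
    rhdf5::h5write(unname(meta[k]), path, paste0("nirs/metaDataTags/", k))
  }

  rhdf5::h5createGroup(path, "nirs/data1")
  rhdf5::h5write(dts, path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((seq_len(n_t) - 1) / recording$fs_hz, path, "nirs/data1/time")
  mg <- recording$montage
  src_idx <- match(mg$source, attr(mg, "source_labels"))
  det_idx <- match(mg$detector, attr(mg, "detector_labels"))
  m <- 0L
  for (wl in seq_len(n_wl)) {
    for (ch in seq_len(n_ch)) {
      m <- m + 1L
      g <- sprintf("nirs/data1/measurementList%d", m)
      rhdf5::h5createGroup(path, g)
      rhdf5::h5write(src_idx[ch], path, paste0(g, "/sourceIndex"))
      rhdf5::h5write(det_idx[ch], path, paste0(g, "/detectorIndex"))
      rhdf5::h5write(wl, path, paste0(g, "/wavelengthIndex"))
      rhdf5::h5write(1L, path, paste0(g, "/dataType"))
      rhdf5::h5write(1L, path, paste0(g, "/dataTypeIndex"))
    }
  }

  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write(recording$wavelengths_nm, path, "nirs/probe/wavelengths")
  rhdf5::h5write(attr(mg, "source_labels"), path, "nirs/probe/sourceLabels")
  rhdf5::h5write(attr(mg, "detector_labels"), path, "nirs/probe/detectorLabels")
  ns <- length(attr(mg, "source_labels"))
  nd <- length(attr(mg, "detector_labels"))
  rhdf5::h5write(cbind(seq_len(ns), rep(0, ns)), path, "nirs/probe/sourcePos2D")
  rhdf5::h5write(cbind(seq_len(nd), rep(1, nd)), path,
                 "nirs/probe/detectorPos2D")
  rhdf5::h5write(attr(mg, "source_detector_distance_cm"), path,
                 "nirs/probe/sourceDetectorDistanceCm")

  ev <- recording$events
  for (i in seq_len(nrow(ev))) {
    g <- sprintf("nirs/stim%d", i)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(ev$label[i], path, paste0(g, "/name"))
    rhdf5::h5write(matrix(c(ev$onset_s[i], ev$duration_s[i], 1), 1, 3),
                   path, paste0(g, "/data"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a continuous-wave SNIRF file
#'
#' Reads a SNIRF (HDF5) file with raw CW intensities, reconstructs the montage
#' from the probe labels and measurement list, converts intensities to
#' optical-density change relative to each channel's temporal mean
#' (`OD(t) = -log10(I(t) / mean(I))`), and collects the stimulus groups into
#' an event schedule.
#'
#' @param path Path to a SNIRF file.
#' @return An `fnirs_recording` with both `od` and `intensity` populated.
#' @export
read_snirf <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  wavelengths <- as.numeric(rhdf5::h5read(path, "nirs/probe/wavelengths"))
  if (length(wavelengths) < 2) {
    abort(sprintf(
      "SNIRF format error: need two wavelengths, found %d (%s)",
      length(wavelengths), paste(wavelengths, collapse = ", ")
    ))
  }
  src_labels <- as.character(rhdf5::h5read(path, "nirs/probe/sourceLabels"))
  det_labels <- as.character(rhdf5::h5read(path, "nirs/probe/detectorLabels"))

  ml_names <- ls$name[grepl("^measurementList\\d+$", ls$name)]
  ml_ids <- sort(as.integer(sub("measurementList", "", ml_names)))
  ml <- purrr::map_dfr(ml_ids, function(m) {
    g <- sprintf("nirs/data1/measurementList%d", m)
    dt <- as.integer(rhdf5::h5read(path, paste0(g, "/dataType")))
    if (dt != 1L) {
      abort(sprintf(
        "SNIRF format error: measurementList%d has dataType %d (only CW amplitude, dataType 1, is supported)",
        m, dt
      ))
    }
    tibble(
      m = m,
      source = as.integer(rhdf5::h5read(path, paste0(g, "/sourceIndex"))),
      detector = as.integer(rhdf5::h5read(path, paste0(g, "/detectorIndex"))),
      wavelength = as.integer(rhdf5::h5read(path, paste0(g, "/wavelengthIndex")))
    )
  })
  if (any(ml$source > length(src_labels)) ||
      any(ml$detector > length(det_labels))) {
    abort("SNIRF format error: measurement list references an optode beyond the probe label lists")
  }

  # Channel = unique (source, detector) pair, in first-wavelength order.
  ml1 <- ml[ml$wavelength == 1L, ]
  chan_key <- paste(ml1$source, ml1$detector, sep = "-")
  channels <- tibble(
    channel = seq_len(nrow(ml1)),
    source = src_labels[ml1$source],
    detector = det_labels[ml1$detector]
  )
  channels$hemisphere <- label_hemisphere(channels$source)
  dist <- tryCatch(
    as.numeric(rhdf5::h5read(path, "nirs/probe/sourceDetectorDistanceCm")),
    error = function(e) 3.0
  )
  montage <- new_montage(channels, src_labels, det_labels, dist)

  dts <- rhdf5::h5read(path, "nirs/data1/dataTimeSeries")
  time <- as.numeric(rhdf5::h5read(path, "nirs/data1/time"))
  fs <- 1 / stats::median(diff(time))
  n_ch <- nrow(channels)
  n_wl <- length(wavelengths)
  intensity <- array(NA_real_, c(nrow(dts), n_ch, n_wl))
  for (i in seq_len(nrow(ml))) {
    key <- paste(ml$source[i], ml$detector[i], sep = "-")
    ch <- match(key, chan_key)
    if (is.na(ch)) {
      abort(sprintf(
        "SNIRF format error: measurement %d (source %d, detector %d) has no wavelength-1 counterpart",
        ml$m[i], ml$source[i], ml$detector[i]
      ))
    }
    intensity[, ch, ml$wavelength[i]] <- dts[, ml$m[i]]
  }

  base <- apply(intensity, c(2, 3), mean)
  od <- array(0, dim(intensity))
  for (wl in seq_len(n_wl)) {
    od[, , wl] <- -log10(sweep(intensity[, , wl, drop = FALSE][, , 1],
                               2, base[, wl], "/"))
  }

  stim_names <- ls$name[grepl("^stim\\d+$", ls$name)]
  stim_ids <- sort(as.integer(sub("stim", "", stim_names)))
  events <- purrr::map_dfr(stim_ids, function(i) {
    g <- sprintf("nirs/stim%d", i)
    dat <- rhdf5::h5read(path, paste0(g, "/data"))
    dat <- matrix(as.numeric(dat), ncol = 3)
    tibble(
      label = as.character(rhdf5::h5read(path, paste0(g, "/name"))),
      onset_s = dat[, 1], duration_s = dat[, 2]
    )
  })
  events$hand <- ifelse(grepl("^Stim[135]$", events$label), "left",
                        ifelse(grepl("^Stim[246]$", events$label), "right",
                               NA_character_))
  meta_get <- function(tag, default) {
    tryCatch(as.character(rhdf5::h5read(path, paste0("nirs/metaDataTags/", tag))),
             error = function(e) default)
  }
  new_recording(
    od = od, fs_hz = fs, montage = montage, events = new_schedule(events),
    wavelengths_nm = wavelengths,
    subject_id = meta_get("SubjectID", "unknown"),
    sleep_state = meta_get("SleepState", "before_SD"),
    intensity = intensity
  )
}
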