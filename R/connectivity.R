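#' Extract equal-length state segments
#'
#' Cuts the seven analysis segments out of a session: the full 10-s epoch of
#' each of the six stimuli, and a 10-s window centered on the middle of the
#' 60-s rest period (samples covering 25-35 s). All segments have
#' `floor(10 * fs)` samples, so every connection matrix rests on the same
#' number of observations. Epochs are half-open `[onset, onset + duration)`.
#'
#' @param hemo A `hemo_signals` object.
#' @param events Event schedule; defaults to the one stored in `hemo`.
#' @param signal Which series to cut: `"hbt"` (default), `"hbo"` or `"hbr"`.
#' @return Tibble with columns `label`, `start_sample`, `n_samples` and a
#'   list-column `data` of time x channel matrices.
#' @export
extract_segments <- function(hemo, events = hemo$events, signal = "hbt") {
  fs <- hemo$fs_hz
  mat <- hemo[[signal]]
  need <- c("Rest", paste0("Stim", 1:6))
  missing <- setdiff(need, events$label)
  if (length(missing) > 0) {
    abort(paste("event schedule is missing:", paste(missing, collapse = ", ")))
  }
  n_seg <- floor(10 * fs + 1e-9)
  rows <- purrr::map_dfr(need, function(lab) {
    ev <- events[events$label == lab, ][1, ]
    if (lab == "Rest") {
      mid <- ev$onset_s + ev$duration_s / 2
      start <- floor((mid - 5) * fs + 1e-9) + 1L
    } else {
      start <- floor(ev$onset_s * fs + 1e-9) + 1L
    }
    if (start + n_seg - 1L > nrow(mat)) {
      abort(sprintf("event %s extends beyond the recording", lab))
    }
    tibble(
      label = lab, start_sample = start, n_samples = n_seg,
      data = list(mat[start:(start + n_seg - 1L), , drop = FALSE])
    )
  })
  rows$label <- factor(rows$label, levels = need)
  rows
}

#' Pearson connection matrix of one state segment
#'
#' Pairwise Pearson correlation of all channel pairs over a segment. The
#' diagonal is set to 0 (self-connections are never edges). Channels with
#' zero variance get zero correlations and are flagged.
#'
#' @param segment Time x channel matrix (>= 3 rows).
#' @param state Optional metadata list/tibble row (subject, sleep_state,
#'   task_state) carried through to the network stage.
#' @return Object of class `connection_matrix`: list with `r` (N x N),
#'   `n_samples`, `state`, `bad_channels`.
#' @export
pearson_matrix <- function(segment, state = NULL) {
  if (nrow(segment) < 3) abort("segment must have at least 3 samples")
  sds <- apply(segment, 2, stats::sd)
  bad <- which(sds == 0)
  r <- suppressWarnings(stats::cor(segment))
  if (length(bad) > 0) {
    r[bad, ] <- 0
    r[, bad] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 0
  structure(
    list(r = r, n_samples = nrow(segment), state = state,
         bad_channels = bad),
    class = "connection_matrix"
  )
}

new_thresholded_network <- function(weights, scheme, parameter, cm,
                                    binary = FALSE) {
  structure(
    list(weights = weights, scheme = scheme, parameter = parameter,
         binary = binary, n_samples = cm$n_samples, state = cm$state),
    class = "thresholded_network"
  )
}

#' Absolute thresholding
#'
#' Keeps coefficients greater than or equal to a fixed positive cutoff `tau`;
#' everything below (including all negative coefficients) becomes 0.
#'
#' @param cm A `connection_matrix`.
#' @param tau Cutoff in (0, 1).
#' @return A weighted `thresholded_network`.
#' @export
threshold_absolute <- function(cm, tau) {
  if (tau <= 0 || tau >= 1) abort("tau must lie in (0, 1)")
  w <- ifelse(cm$r >= tau, cm$r, 0)
  diag(w) <- 0
  new_thresholded_network(w, "absolute", tau, cm)
}

#' Cost (proportional) thresholding
#'
#' Retains the `round(cost * M)` largest positive coefficients among the
#' `M = N(N-1)/2` unique channel pairs (fewer if fewer positive coefficients
#' exist); ties are broken by (row, column) order so the edge set is
#' deterministic and nested across increasing cost.
#'
#' @param cm A `connection_matrix`.
#' @param cost Fraction of connections to preserve, in (0, 1].
#' @return A weighted `thresholded_network`.
#' @export
threshold_cost <- function(cm, cost) {
  if (cost <= 0 || cost > 1) abort("cost must lie in (0, 1]")
  n <- nrow(cm$r)
  ut <- which(upper.tri(cm$r), arr.ind = TRUE)
  vals <- cm$r[ut]
  m_tot <- nrow(ut)
  k <- round(cost * m_tot)
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(k, m_tot))]
  keep <- keep[vals[keep] > 0]
  w <- matrix(0, n, n)
  w[ut[keep, , drop = FALSE]] <- vals[keep]
  w <- w + t(w)
  new_thresholded_network(w, "cost", cost, cm)
}

#' Surrogate (significance) thresholding
#'
#' Retains positive coefficients whose two-sided correlation test is
#' significant: `t = c * sqrt((n - 2) / (1 - c^2))` against Student's t with
#' `n - 2` degrees of freedom, keeping the edge when `p < alpha`. A
#' coefficient of exactly 1 is treated as p = 0.
#'
#' @param cm A `connection_matrix` with `n_samples >= 4`.
#' @param alpha Per-edge significance level (default 0.05).
#' @return A weighted `thresholded_network`.
#' @export
threshold_surrogate <- function(cm, alpha = 0.05) {
  if (cm$n_samples < 4) abort("surrogate thresholding needs n_samples >= 4")
  p <- correlation_pvalue(cm$r, cm$n_samples)
  w <- ifelse(cm$r > 0 & p < alpha, cm$r, 0)
  diag(w) <- 0
  new_thresholded_network(w, "surrogate", alpha, cm)
}

# Two-sided p-value of a Pearson coefficient under the exact t transform.
correlation_pvalue <- function(r, n) {
  p <- matrix(0, nrow(as.matrix(r)), ncol(as.matrix(r)))
  r <- as.matrix(r)
  sat <- abs(r) >= 1
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[sat] <- 0
  p
}

#' Binarize a thresholded network
#'
#' Maps every surviving (positive) weight to 1. Idempotent.
#'
#' @param net A `thresholded_network`.
#' @return The network with binary weights and `binary = TRUE`.
#' @export
binarize <- function(net) {
  out <- net
  out$weights <- (net$weights > 0) * 1
  out$binary <- TRUE
  out
}

#' @export
print.connection_matrix <- function(x, ...) {
  cat(sprintf("<connection_matrix> %d channels, n = %d samples\n",
              nrow(x$r), x$n_samples))
  invisible(x)
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf(
    "<thresholded_network> %s (parameter %.3g), %s, %d edges\n",
    x$scheme, x$parameter, if (x$binary) "binary" else "weighted",
    sum(x$weights[upper.tri(x$weights)] > 0)
  ))
  invisible(x)
}
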