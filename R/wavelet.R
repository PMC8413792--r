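# Periodized orthogonal discrete wavelet transform with the 4-tap Daubechies
# filter. Implemented in-package: the interquartile-fence thresholding of
# detail coefficients (motion-artifact suppression) operates directly on this
# decomposition, and the transform must be exactly invertible so that clean
# signals pass through unchanged.

.db4_scaling <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
  (4 * sqrt(2))
.db4_wavelet <- rev(.db4_scaling) * c(1, -1, 1, -1)

# One analysis step on an even-length vector (periodic boundary).
.dwt_step <- function(x) {
  n <- length(x)
  idx <- outer(2 * seq_len(n / 2) - 1, 0:3, function(k, m) ((k + m - 1) %% n) + 1)
  xs <- matrix(x[idx], n / 2, 4)
  list(approx = as.numeric(xs %*% .db4_scaling),
       detail = as.numeric(xs %*% .db4_wavelet))
}

# Adjoint/inverse of .dwt_step (orthogonal filter bank).
.idwt_step <- function(approx, detail) {
  n <- 2 * length(approx)
  x <- numeric(n)
  for (m in 0:3) {
    pos <- ((2 * seq_along(approx) - 1 + m - 1) %% n) + 1
    x[pos] <- x[pos] + approx * .db4_scaling[m + 1] +
      detail * .db4_wavelet[m + 1]
  }
  x
}

# Full decomposition to `levels` scales; series length must be divisible by
# 2^levels. Returns list(approx, details = list(level1 finest .. coarsest)).
dwt_periodic <- function(x, levels) {
  stopifnot(length(x) %% 2^levels == 0)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- .dwt_step(a)
    details[[j]] <- st$detail
    a <- st$approx
  }
  list(approx = a, details = details)
}

idwt_periodic <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- .idwt_step(a, decomp$details[[j]])
  }
  a
}

#' Wavelet-based motion-artifact suppression
#'
#' Decomposes a single-channel optical-density series with a periodized
#' Daubechies-4 discrete wavelet transform, zeroes detail coefficients that
#' fall outside the interquartile fence
#' `[Q1 - f * IQR, Q3 + f * IQR]` of their own decomposition level, and
#' reconstructs. Sharp transients (motion spikes) concentrate in few large
#' detail coefficients and are removed; smooth oscillations pass unchanged.
#' The series is reflection-padded to a power-of-two length before the
#' transform and truncated after reconstruction, so any length >= 8 is
#' accepted and length is preserved.
#'
#' @param x Numeric series (length >= 8).
#' @param iqr_factor Fence width factor `f` (default 1.5).
#' @param max_levels Cap on decomposition depth; by default the depth is the
#'   maximum that keeps the coarsest subband at >= 8 coefficients.
#' @return Numeric series, same length as `x`.
#' @export
wavelet_artifact_removal <- function(x, iqr_factor = 1.5, max_levels = Inf) {
  n <- length(x)
  if (n < 8) abort("series too short for one wavelet decomposition level")
  if (iqr_factor <= 0) abort("iqr_factor must be positive")

  n_pad <- 2^ceiling(log2(n))
  if (n_pad < 16) n_pad <- 16
  pad <- n_pad - n
  # reflect the tail to fill up to the padded length
  xp <- c(x, rev(x)[seq_len(min(pad, n))])
  while (length(xp) < n_pad) {
    xp <- c(xp, rev(xp)[seq_len(min(n_pad - length(xp), length(xp)))])
  }

  levels <- min(floor(log2(n_pad)) - 5, max_levels)
  levels <- max(levels, 1)
  dec <- dwt_periodic(xp, levels)
  for (j in seq_along(dec$details)) {
    d <- dec$details[[j]]
    # Only coefficients whose support lies inside the original signal are
    # candidates: seam coefficients from the reflection padding would
    # otherwise look like (and be removed as) artifacts.
    len_j <- 3 * (2^j - 1) + 1 # equivalent filter length at level j
    interior <- which(2^j * (seq_along(d) - 1) + len_j <= n)
    if (length(interior) < 4) next
    q <- stats::quantile(d[interior], c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    lo <- q[1] - iqr_factor * iqr
    hi <- q[2] + iqr_factor * iqr
    kill <- interior[d[interior] < lo | d[interior] > hi]
    d[kill] <- 0
    dec$details[[j]] <- d
  }
  idwt_periodic(dec)[seq_len(n)]
}
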