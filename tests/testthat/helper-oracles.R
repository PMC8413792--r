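# Independent brute-force oracles used to cross-check the implementation.

# Textbook Pearson correlation: covariance over product of standard deviations.
brute_pearson <- function(x) {
  n <- ncol(x)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      xi <- x[, i] - mean(x[, i])
      xj <- x[, j] - mean(x[, j])
      out[i, j] <- sum(xi * xj) /
        sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# Global density by explicit edge counting.
brute_density <- function(a) {
  n <- nrow(a)
  sum(a[upper.tri(a)]) * 2 / (n * (n - 1))
}

# Clustering coefficient by exhaustive triple enumeration.
brute_clustering <- function(a) {
  n <- nrow(a)
  c_loc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (j in nb) for (h in nb) if (j != h && a[j, h] > 0) tri <- tri + 1
    c_loc[i] <- tri / (k * (k - 1))
  }
  mean(c_loc)
}

# Global efficiency from Floyd-Warshall all-pairs shortest paths.
brute_efficiency <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  mean(rowSums(inv) / (n - 1))
}

# Deterministic random binary adjacency.
random_adjacency <- function(n, p, seed) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
    a + t(a)
  })
}

# Wrap an adjacency/weight matrix as a thresholded network object.
as_network <- function(w, binary = any(w %in% c(0, 1)) && all(w %in% c(0, 1))) {
  structure(
    list(weights = w, scheme = "absolute", parameter = 0.5, binary = binary,
         n_samples = 39, state = NULL),
    class = "thresholded_network"
  )
}

# Wrap a correlation matrix as a connection matrix object.
as_connection <- function(r, n_samples = 39) {
  diag(r) <- 0
  structure(
    list(r = r, n_samples = n_samples, state = NULL, bad_channels = integer(0)),
    class = "connection_matrix"
  )
}

# Light processing path for simulation studies: clean generated signals need
# no artifact or low-pass stage, so conversion + CBSI + networks suffice.
lite_config <- function(seed = 1) {
  pipeline_config(seed = seed, preprocess = list(
    wavelet = list(enabled = FALSE), filter = list(enabled = FALSE)))
}

# Surrogate-thresholded global density table of a cohort via the lite path.
surrogate_density_table <- function(cohort, cfg = lite_config()) {
  purrr::map_dfr(cohort$recordings, function(rec) {
    hemo <- preprocess_recording(rec, cfg)
    segs <- extract_segments(hemo)
    purrr::map_dfr(seq_len(nrow(segs)), function(i) {
      cm <- pearson_matrix(segs$data[[i]])
      net <- threshold_surrogate(cm, 0.05)
      tibble::tibble(
        subject = rec$subject_id, sleep_state = rec$sleep_state,
        task_state = as.character(segs$label[i]),
        D = global_density(binarize(net)), WD = global_density(net)
      )
    })
  })
}

# A small clean recording for I/O tests.
tiny_recording <- function(seed = 11, n_subjects = 1) {
  spec <- simulation_spec(n_subjects = n_subjects, seed = seed,
                          artifact_rate = 0)
  generate_recording(spec, 1, "before_SD")
}
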