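#' Logarithmic transform of a metric table
#'
#' Replaces `value` by `log(value + epsilon)`. Network densities are bounded
#' and right-skewed, so downstream normality/sphericity checks and the
#' repeated-measures ANOVA operate on the log scale; `epsilon` guards exact
#' zeros (empty networks).
#'
#' @param results Tibble with a `value` column (all values >= 0).
#' @param epsilon Offset added before taking the log (default 1e-6).
#' @return The table with transformed values and a `log_transformed`
#'   attribute; transforming twice is an error.
#' @export
log_transform <- function(results, epsilon = 1e-6) {
  if (isTRUE(attr(results, "log_transformed"))) {
    abort("results are already log-transformed")
  }
  if (any(results$value < 0, na.rm = TRUE)) {
    abort("log transform requires non-negative values")
  }
  results$value <- log(results$value + epsilon)
  attr(results, "log_transformed") <- TRUE
  results
}

# Column-normalized Helmert contrasts: l x (l-1), orthonormal, orthogonal to
# the constant vector.
.orthonormal_contrasts <- function(l) {
  m <- stats::contr.helmert(l)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Fully-within repeated-measures ANOVA
#'
#' Balanced, fully-crossed within-subject analysis of variance for two or more
#' within factors (e.g. sleep state x task state, optionally with threshold as
#' a third repeated-measures factor). Each effect is evaluated on orthonormal
#' contrast scores: the effect sum of squares is `n * ||mean(Z)||^2` and its
#' error term is the subject-by-effect interaction, the deviation sum of
#' squares of the scores. The Greenhouse-Geisser epsilon and the Mauchly
#' sphericity test are computed from the covariance of the contrast scores;
#' the sphericity-corrected p-value is adopted whenever Mauchly's p < 0.05
#' (and the effect has more than one degree of freedom).
#'
#' @param data Long tibble with one row per subject x cell.
#' @param dv Name of the value column (default `"value"`).
#' @param subject Name of the subject column (default `"subject"`).
#' @param within Character vector of within-factor column names (>= 2).
#' @return Object of class `fnirs_anova` with a `table` tibble (effect,
#'   df_num, df_den, F, p, gg_epsilon, p_gg, mauchly_p, p_adj) and per-cell
#'   Shapiro-Wilk normality checks.
#' @export
rm_anova <- function(data, dv = "value", subject = "subject",
                     within = c("sleep_state", "task_state")) {
  if (length(within) < 2) abort("at least two within factors are required")
  data <- as_tibble(data)
  for (f in within) data[[f]] <- factor(data[[f]])
  levels_list <- purrr::map(within, ~ levels(data[[.x]]))
  names(levels_list) <- within
  subjects <- unique(data[[subject]])
  n <- length(subjects)
  if (n < 2) abort("at least two subjects are required")

  cells <- expand.grid(levels_list, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(cells)
  key <- function(df) do.call(paste, c(df[within], sep = "\r"))
  cell_keys <- key(cells)
  data_keys <- key(data)
  y <- matrix(NA_real_, n, nrow(cells))
  for (i in seq_len(n)) {
    rows <- data[[subject]] == subjects[i]
    idx <- match(cell_keys, data_keys[rows])
    if (anyNA(idx)) {
      miss <- cell_keys[is.na(idx)]
      abort(paste0("incomplete design: subject ", subjects[i],
                   " is missing cells: ",
                   paste(gsub("\r", ":", miss), collapse = ", ")))
    }
    y[i, ] <- data[[dv]][rows][idx]
  }

  # every non-empty subset of the within factors is an effect
  subsets <- purrr::map(seq_along(within), ~ utils::combn(within, .x,
                                                          simplify = FALSE))
  subsets <- purrr::flatten(subsets)

  table <- purrr::map_dfr(subsets, function(eff) {
    mats <- purrr::map(within, function(f) {
      l <- length(levels_list[[f]])
      if (f %in% eff) .orthonormal_contrasts(l) else
        matrix(1 / sqrt(l), l, 1)
    })
    m <- Reduce(kronecker, rev(mats))
    z <- y %*% m
    p_eff <- ncol(z)
    zbar <- colMeans(z)
    ss_eff <- n * sum(zbar^2)
    zc <- sweep(z, 2, zbar)
    ss_err <- sum(zc^2)
    df_num <- p_eff
    df_den <- (n - 1) * p_eff
    if (ss_err <= 0) {
      abort(paste0("degenerate within-subject variance for effect ",
                   paste(eff, collapse = ":")))
    }
    f_stat <- (ss_eff / df_num) / (ss_err / df_den)
    p_raw <- stats::pf(f_stat, df_num, df_den, lower.tail = FALSE)

    s <- stats::cov(z)
    if (p_eff >= 2) {
      eps <- sum(diag(s))^2 / (p_eff * sum(s^2))
      p_gg <- stats::pf(f_stat, df_num * eps, df_den * eps, lower.tail = FALSE)
      # Mauchly's W with the standard two-term chi-square approximation
      detS <- det(s)
      w <- if (detS <= 0) .Machine$double.xmin else
        detS / (sum(diag(s)) / p_eff)^p_eff
      n_df <- n - 1
      rho <- 1 - (2 * p_eff^2 + p_eff + 2) / (6 * p_eff * n_df)
      z <- -n_df * rho * log(w)
      mauchly_df <- p_eff * (p_eff + 1) / 2 - 1
      # second-order term as in stats::mauchly.test (its polynomial mixes the
      # contrast dimension with the number of response columns)
      w2 <- (p_eff + 2) * (p_eff - 1) * (p_eff - 2) *
        (2 * p_eff^3 + 6 * p_eff^2 + 3 * n_cells + 2) /
        (288 * (n_df * p_eff * rho)^2)
      pr1 <- stats::pchisq(z, mauchly_df, lower.tail = FALSE)
      pr2 <- stats::pchisq(z, mauchly_df + 4, lower.tail = FALSE)
      mauchly_p <- min(max(pr1 + w2 * (pr2 - pr1), 0), 1)
    } else {
      eps <- 1
      p_gg <- p_raw
      mauchly_p <- NA_real_
    }
    p_adj <- if (!is.na(mauchly_p) && mauchly_p < 0.05) p_gg else p_raw
    tibble(
      effect = paste(eff, collapse = ":"),
      df_num = df_num, df_den = df_den, statistic = f_stat,
      p = p_raw, gg_epsilon = eps, p_gg = p_gg,
      mauchly_p = mauchly_p, p_adj = p_adj
    )
  })

  shapiro <- if (n >= 3) {
    purrr::map_dfr(seq_len(nrow(cells)), function(j) {
      v <- y[, j]
      p <- if (stats::sd(v) == 0) NA_real_ else stats::shapiro.test(v)$p.value
      out <- as_tibble(cells[j, , drop = FALSE])
      out$shapiro_p <- p
      out
    })
  } else {
    NULL
  }

  structure(
    list(table = table, shapiro = shapiro, n_subjects = n,
         within = within, levels = levels_list),
    class = "fnirs_anova"
  )
}

#' @export
print.fnirs_anova <- function(x, ...) {
  cat(sprintf("<fnirs_anova> %d subjects, within factors: %s\n",
              x$n_subjects, paste(x$within, collapse = ", ")))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fnirs_anova <- function(x, ...) {
  x$table
}

#' @export
glance.fnirs_anova <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    n_effects = nrow(x$table),
    within = paste(x$within, collapse = ":"),
    any_sphericity_violation = any(x$table$mauchly_p < 0.05, na.rm = TRUE)
  )
}

#' Dunnett-style comparisons of task states against rest
#'
#' Within one sleep state, compares each stimulus level against the resting
#' state with paired contrasts, adjusting for multiplicity over the correlated
#' family of contrasts by Monte-Carlo evaluation of the maximum absolute
#' statistic of a multivariate t distribution (correlation estimated from the
#' subject-level difference vectors, `n - 1` degrees of freedom, fixed
#' internal seed). With a single contrast this reduces to the paired t-test.
#'
#' @param data Long tibble with columns `subject`, `sleep_state`,
#'   `task_state` and `value` (one metric slice).
#' @param sleep_state Which sleep state to analyze.
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param mc_seed Seed of the Monte-Carlo stream.
#' @return Tibble with one row per task state: mean difference, t, raw and
#'   adjusted p (adjusted >= raw by construction).
#' @export
dunnett_vs_rest <- function(data, sleep_state, n_mc = 1e5, mc_seed = 20210622) {
  d <- data[data$sleep_state == sleep_state, ]
  if (!"Rest" %in% d$task_state) abort("resting-state cell is missing")
  tasks <- setdiff(unique(as.character(d$task_state)), "Rest")
  tasks <- tasks[order(tasks)]
  subjects <- unique(d$subject)
  n <- length(subjects)
  if (n < 2) abort("at least two subjects are required")

  rest <- d$value[match(paste(subjects, "Rest"),
                        paste(d$subject, d$task_state))]
  diffs <- vapply(tasks, function(tk) {
    d$value[match(paste(subjects, tk), paste(d$subject, d$task_state))] - rest
  }, numeric(n))
  diffs <- matrix(diffs, nrow = n)

  means <- colMeans(diffs)
  sds <- apply(diffs, 2, stats::sd)
  t_obs <- ifelse(sds > 0, means / (sds / sqrt(n)), 0)
  p_raw <- ifelse(sds > 0, 2 * stats::pt(-abs(t_obs), df = n - 1), 1)

  k <- length(tasks)
  r <- suppressWarnings(stats::cor(diffs))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r <- nearest_correlation(r, eps = 1e-8)

  p_adj <- withr::with_seed(mc_seed, {
    z <- matrix(stats::rnorm(n_mc * k), n_mc, k) %*% chol(r)
    s <- sqrt(stats::rchisq(n_mc, df = n - 1) / (n - 1))
    maxabs <- apply(abs(z / s), 1, max)
    vapply(t_obs, function(t0) mean(maxabs >= abs(t0)), numeric(1))
  })
  p_adj <- pmax(p_adj, p_raw) # adjustment is monotone by contract

  tibble(
    task_state = tasks, estimate = means, statistic = t_obs,
    df = n - 1, p = p_raw, p_adj = p_adj, sleep_state = sleep_state
  )
}

#' Task-related connectivity change and its sleep-deprivation difference
#'
#' For each subject and sleep state, the task-related change of global
#' weighted density is the mean over the six stimulus states minus the resting
#' state; the sleep-deprivation effect is the difference of these changes,
#' `delta = after - before`.
#'
#' @param data Long tibble with columns `subject`, `sleep_state`,
#'   `task_state`, `value` (global weighted density of the
#'   surrogate-thresholded network, one row per cell).
#' @return Tibble with `subject`, `wd_bar_before`, `wd_bar_after`, `delta`.
#' @export
delta_wd <- function(data) {
  need <- c("Rest", paste0("Stim", 1:6))
  wd <- data |>
    dplyr::group_by(.data$subject, .data$sleep_state) |>
    dplyr::group_modify(function(g, key) {
      miss <- setdiff(need, as.character(g$task_state))
      if (length(miss) > 0) {
        abort(paste("missing cells:", paste(miss, collapse = ", ")))
      }
      rest <- g$value[g$task_state == "Rest"]
      tibble(wd_bar = mean(g$value[g$task_state != "Rest"]) - rest)
    }) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "sleep_state", values_from = "wd_bar",
                       names_prefix = "wd_bar_")
  if (!all(c("wd_bar_before_SD", "wd_bar_after_SD") %in% names(wd))) {
    abort("both sleep states are required")
  }
  wd$delta <- wd$wd_bar_after_SD - wd$wd_bar_before_SD
  dplyr::rename(wd, wd_bar_before = "wd_bar_before_SD",
                wd_bar_after = "wd_bar_after_SD")
}

#' Correlation of connectivity changes with cognitive-score changes
#'
#' Pearson correlation (two-sided, uncorrected) between each subject's
#' sleep-deprivation connectivity change and the change of each cognitive
#' score between visits. Subjects with a missing score are dropped pairwise.
#'
#' @param delta Output of [delta_wd()] (columns `subject`, `delta`).
#' @param scores Tibble with `subject_id`, `visit` (1 = before, 2 = after) and
#'   score columns (default `PAL`, `RTI`, `RVPA`); blanks are missing.
#' @param score_names Which score columns to test.
#' @return Tibble with `score`, `n`, `r`, `p`.
#' @export
brain_behavior_correlation <- function(delta, scores,
                                       score_names = c("PAL", "RTI", "RVPA")) {
  changes <- scores |>
    tidyr::pivot_longer(dplyr::all_of(score_names), names_to = "score") |>
    tidyr::pivot_wider(names_from = "visit", values_from = "value",
                       names_prefix = "v") |>
    dplyr::mutate(change = .data$v2 - .data$v1)
  joined <- dplyr::inner_join(changes,
                              dplyr::rename(delta, subject_id = "subject"),
                              by = "subject_id")
  purrr::map_dfr(score_names, function(sc) {
    g <- joined[joined$score == sc & !is.na(joined$change), ]
    if (nrow(g) < 3) {
      abort(paste0("fewer than 3 complete pairs for score ", sc))
    }
    ct <- stats::cor.test(g$delta, g$change, method = "pearson")
    tibble(score = sc, n = nrow(g), r = unname(ct$estimate), p = ct$p.value)
  })
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement among m raters (subjects) ranking the same N objects (channels),
#' with the standard tie correction:
#' `W = 12 S / (m^2 (N^3 - N) - m * sum(T_i))`, where `S` is the sum of
#' squared deviations of the rank sums and `T_i = sum(t^3 - t)` over the tie
#' groups of rater i.
#'
#' @param x Numeric matrix, raters x objects, of values to be ranked per
#'   rater (ties get average ranks) — or of ranks directly.
#' @return W in `[0, 1]`.
#' @export
kendalls_w <- function(x) {
  x <- as.matrix(x)
  m <- nrow(x)
  n_obj <- ncol(x)
  if (m < 2) abort("Kendall's W requires at least 2 raters")
  ranks <- t(apply(x, 1, rank))
  rank_sums <- colSums(ranks)
  s <- sum((rank_sums - m * (n_obj + 1) / 2)^2)
  tie_corr <- sum(apply(ranks, 1, function(rr) {
    tt <- table(rr)
    sum(tt^3 - tt)
  }))
  12 * s / (m^2 * (n_obj^3 - n_obj) - m * tie_corr)
}

#' Channel-wise contrast maps of local connection strength
#'
#' Per channel, the task-minus-rest change of local weighted density is
#' computed per subject within a sleep state (or its after-minus-before
#' difference), tested against zero with a one-sample t-test across subjects,
#' and corrected for the multiplicity over channels by the Benjamini-Hochberg
#' false-discovery-rate step-up.
#'
#' @param local Long tibble with columns `subject`, `sleep_state`,
#'   `task_state`, `channel`, `value` (local weighted density).
#' @param contrast One of `"task_minus_rest_before"`,
#'   `"task_minus_rest_after"`, `"sd_effect"` (after minus before of the
#'   task-minus-rest change).
#' @return Tibble with `channel`, `estimate`, `statistic`, `p`, `p_fdr`.
#' @export
channelwise_contrast_map <- function(local,
                                     contrast = c("task_minus_rest_before",
                                                  "task_minus_rest_after",
                                                  "sd_effect")) {
  contrast <- match.arg(contrast)
  tmr <- local |>
    dplyr::group_by(.data$subject, .data$sleep_state, .data$channel) |>
    dplyr::summarise(
      tmr = mean(.data$value[.data$task_state != "Rest"]) -
        .data$value[.data$task_state == "Rest"][1],
      .groups = "drop"
    )
  per_subject <- switch(contrast,
    task_minus_rest_before = tmr[tmr$sleep_state == "before_SD", ],
    task_minus_rest_after = tmr[tmr$sleep_state == "after_SD", ],
    sd_effect = tmr |>
      tidyr::pivot_wider(names_from = "sleep_state", values_from = "tmr") |>
      dplyr::mutate(tmr = .data$after_SD - .data$before_SD)
  )
  n_sub <- length(unique(per_subject$subject))
  if (n_sub < 2) abort("at least two subjects are required")
  out <- per_subject |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      estimate = mean(.data$tmr),
      sdv = stats::sd(.data$tmr),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      statistic = dplyr::case_when(
        .data$sdv > 0 ~ .data$estimate / (.data$sdv / sqrt(.data$n)),
        .data$estimate == 0 ~ 0,
        TRUE ~ Inf * sign(.data$estimate)
      ),
      p = dplyr::if_else(
        is.finite(.data$statistic),
        2 * stats::pt(-abs(.data$statistic), df = .data$n - 1),
        0
      ),
      p = dplyr::if_else(.data$sdv == 0 & .data$estimate == 0, 1, .data$p)
    )
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("channel", "estimate", "statistic", "p", "p_fdr")]
}
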