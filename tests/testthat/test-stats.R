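make_long <- function(y, cells, subjects) {
  out <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    df <- as.data.frame(cells)
    df$subject <- subjects[i]
    df$value <- y[i, ]
    df
  }))
  tibble::as_tibble(out)
}

test_that("log transform applies the epsilon convention once", {
  tab <- tibble::tibble(value = c(1, 0, 0.5))
  out <- log_transform(tab, epsilon = 0)
  expect_equal(out$value[1], 0)
  out2 <- log_transform(tab, epsilon = 1e-6)
  expect_equal(out2$value[2], log(1e-6))
  expect_error(log_transform(out2), "already")
  expect_error(log_transform(tibble::tibble(value = -1)), "non-negative")
})

test_that("repeated-measures ANOVA matches the car oracle to 1e-8", {
  skip_if_not_installed("car")
  for (seed in c(5, 6)) {
    n <- 8
    cells <- expand.grid(sleep_state = c("before_SD", "after_SD"),
                         task_state = paste0("t", 1:7),
                         stringsAsFactors = FALSE)
    y <- withr::with_seed(seed, {
      matrix(stats::rnorm(n * nrow(cells)), n) +
        rep(seq_len(nrow(cells)), each = n) * 0.2
    })
    fit <- rm_anova(make_long(y, cells, paste0("s", 1:n)))

    idata <- data.frame(sleep_state = factor(cells$sleep_state),
                        task_state = factor(cells$task_state))
    ca <- summary(car::Anova(stats::lm(y ~ 1), idata = idata,
                             idesign = ~ sleep_state * task_state, type = 3),
                  multivariate = FALSE)
    ut <- ca$univariate.tests
    for (eff in c("sleep_state", "task_state", "sleep_state:task_state")) {
      mine <- fit$table[fit$table$effect == eff, ]
      expect_equal(mine$statistic, ut[eff, "F value"], tolerance = 1e-8)
      expect_equal(mine$p, ut[eff, "Pr(>F)"], tolerance = 1e-8)
    }
    pa <- ca$pval.adjustments
    for (eff in rownames(pa)) {
      mine <- fit$table[fit$table$effect == eff, ]
      expect_equal(mine$gg_epsilon, pa[eff, "GG eps"], tolerance = 1e-8)
      expect_equal(mine$p_gg, pa[eff, "Pr(>F[GG])"], tolerance = 1e-8)
    }
    sp <- ca$sphericity.tests
    for (eff in rownames(sp)) {
      mine <- fit$table[fit$table$effect == eff, ]
      expect_equal(mine$mauchly_p, sp[eff, "p-value"], tolerance = 1e-8)
    }
  }
})

test_that("three-factor within designs match car as well", {
  skip_if_not_installed("car")
  n <- 6
  cells <- expand.grid(sleep = c("b", "a"), task = paste0("t", 1:3),
                       thr = paste0("h", 1:3), stringsAsFactors = FALSE)
  y <- withr::with_seed(8, matrix(stats::rnorm(n * nrow(cells)), n))
  fit <- rm_anova(make_long(y, cells, paste0("s", 1:n)),
                  within = c("sleep", "task", "thr"))
  expect_equal(nrow(fit$table), 7) # all non-empty factor subsets
  idata <- data.frame(lapply(cells, factor))
  ca <- summary(car::Anova(stats::lm(y ~ 1), idata = idata,
                           idesign = ~ sleep * task * thr, type = 3),
                multivariate = FALSE)
  ut <- ca$univariate.tests
  for (eff in setdiff(rownames(ut), "(Intercept)")) {
    mine <- fit$table[fit$table$effect == eff, ]
    expect_equal(mine$statistic, ut[eff, "F value"], tolerance = 1e-8)
    expect_equal(unname(mine$df_num), unname(ut[eff, "num Df"]))
    expect_equal(unname(mine$df_den), unname(ut[eff, "den Df"]))
  }
})

test_that("ANOVA rejects broken designs and degenerate data", {
  cells <- expand.grid(a = c("x", "y"), b = c("u", "v"),
                       stringsAsFactors = FALSE)
  y <- matrix(stats::rnorm(12), 3)
  long <- make_long(y, cells, paste0("s", 1:3))
  expect_error(rm_anova(long[-1, ], within = c("a", "b")), "missing cells")
  # identical values in all cells: no within-subject variance
  y0 <- matrix(rep(c(1, 2), each = 4), 2, 4, byrow = TRUE)
  long0 <- make_long(y0, cells, c("s1", "s2"))
  expect_error(rm_anova(long0, within = c("a", "b")), "degenerate")
  # tidiers
  fit <- rm_anova(long, within = c("a", "b"))
  expect_s3_class(generics::tidy(fit), "tbl_df")
  expect_equal(nrow(generics::glance(fit)), 1)
})

test_that("ANOVA interaction p-values are calibrated under the null", {
  # 500 null tables: values iid normal per subject and cell
  n_rep <- 500
  cells <- expand.grid(sleep_state = c("before_SD", "after_SD"),
                       task_state = paste0("t", 1:7),
                       stringsAsFactors = FALSE)
  rejections <- withr::with_seed(202, {
    vapply(seq_len(n_rep), function(r) {
      y <- matrix(stats::rnorm(10 * nrow(cells)), 10)
      fit <- rm_anova(make_long(y, cells, paste0("s", 1:10)))
      fit$table$p[fit$table$effect == "sleep_state:task_state"] < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.08)
})

test_that("Dunnett comparisons behave like the paired t in the base case", {
  set.seed(9)
  d <- tibble::tibble(
    subject = rep(1:10, 2), sleep_state = "before_SD",
    task_state = rep(c("Rest", "Stim1"), each = 10),
    value = c(stats::rnorm(10), stats::rnorm(10, 0.8))
  )
  dn <- dunnett_vs_rest(d, "before_SD", n_mc = 2e5)
  tt <- stats::t.test(d$value[d$task_state == "Stim1"] -
                        d$value[d$task_state == "Rest"])
  expect_equal(dn$p_adj, tt$p.value, tolerance = 0.01)
  expect_equal(dn$p, tt$p.value, tolerance = 1e-12)
})

test_that("Dunnett adjustment is monotone and null-safe", {
  # all task cells equal to rest: every adjusted p is ~1
  base <- withr::with_seed(10, stats::rnorm(8))
  d0 <- purrr::map_dfr(c("Rest", paste0("Stim", 1:6)), function(tk) {
    tibble::tibble(subject = 1:8, sleep_state = "after_SD",
                   task_state = tk, value = base)
  })
  dn0 <- dunnett_vs_rest(d0, "after_SD", n_mc = 1e4)
  expect_true(all(dn0$p_adj > 0.99))
  # adjusted >= raw for every contrast on noisy data
  d1 <- d0
  d1$value <- d1$value + withr::with_seed(11, stats::rnorm(nrow(d1), 0, 0.5))
  dn1 <- dunnett_vs_rest(d1, "after_SD", n_mc = 1e4)
  expect_true(all(dn1$p_adj >= dn1$p))
  expect_error(dunnett_vs_rest(d1[d1$task_state != "Rest", ], "after_SD"),
               "resting-state")
})

test_that("delta WD follows its definition and antisymmetry", {
  cells <- tidyr::expand_grid(
    subject = "S01",
    sleep_state = c("before_SD", "after_SD"),
    task_state = c("Rest", paste0("Stim", 1:6))
  )
  cells$value <- ifelse(cells$task_state == "Rest", 0.5,
                        ifelse(cells$sleep_state == "before_SD", 0.3, 0.5))
  d <- delta_wd(cells)
  expect_equal(d$wd_bar_before, -0.2)
  expect_equal(d$wd_bar_after, 0)
  expect_equal(d$delta, 0.2) # hand evaluation of the definition
  # identical states give zero
  cells0 <- cells
  cells0$value <- 0.4
  expect_equal(delta_wd(cells0)$delta, 0)
  # swapping the sleep labels negates delta
  swapped <- cells
  swapped$sleep_state <- ifelse(swapped$sleep_state == "before_SD",
                                "after_SD", "before_SD")
  expect_equal(delta_wd(swapped)$delta, -0.2)
  expect_error(delta_wd(cells[cells$task_state != "Stim3", ]), "missing")
})

test_that("brain-behavior correlations drop missing scores pairwise", {
  delta <- tibble::tibble(subject = sprintf("S%02d", 1:10),
                          delta = seq(-0.1, 0.08, length.out = 10))
  scores <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:10),
                               visit = 1:2)
  scores$PAL <- ifelse(scores$visit == 1, 15, 15 - 50 *
                         delta$delta[match(scores$subject_id, delta$subject)])
  scores$RTI <- stats::rnorm(20)
  scores$RVPA <- stats::rnorm(20)
  scores$PAL[scores$subject_id == "S03"] <- NA # one subject without PAL
  bb <- brain_behavior_correlation(delta, scores)
  expect_equal(bb$n[bb$score == "PAL"], 9)
  expect_equal(bb$n[bb$score == "RTI"], 10)
  expect_equal(bb$r[bb$score == "PAL"], -1, tolerance = 1e-9)
  expect_error(brain_behavior_correlation(delta[1:2, ], scores), "fewer than 3")
})

test_that("Kendall's W spans perfect agreement to perfect reversal", {
  expect_equal(kendalls_w(rbind(1:6, 1:6, 1:6)), 1)
  expect_equal(kendalls_w(rbind(1:6, 6:1)), 0)
  # 5 x 10 fixture against the direct formula computed by hand
  x <- withr::with_seed(12, matrix(stats::rnorm(50), 5, 10))
  ranks <- t(apply(x, 1, rank))
  s <- sum((colSums(ranks) - 5 * 11 / 2)^2)
  expect_equal(kendalls_w(x), 12 * s / (25 * (1000 - 10)))
  expect_error(kendalls_w(x[1, , drop = FALSE]), "2 raters")
})

test_that("Kendall's W agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  x <- withr::with_seed(13, matrix(stats::rnorm(80), 8, 10))
  # vegan arranges objects in rows and raters in columns
  vw <- vegan::kendall.global(t(x))$Concordance_analysis["W", 1]
  expect_equal(kendalls_w(x), unname(vw), tolerance = 1e-10)
})

test_that("channel-wise contrast maps handle nulls and planted effects", {
  channels <- 1:48
  grid <- tidyr::expand_grid(
    subject = sprintf("S%02d", 1:12),
    sleep_state = c("before_SD", "after_SD"),
    task_state = c("Rest", paste0("Stim", 1:6)),
    channel = channels
  )
  # constant zero differences: t = 0, p = 1 everywhere
  grid0 <- grid
  grid0$value <- 0.5
  map0 <- channelwise_contrast_map(grid0, "sd_effect")
  expect_equal(map0$statistic, rep(0, 48))
  expect_equal(map0$p, rep(1, 48))
  expect_equal(map0$p_fdr, rep(1, 48))

  # planted effect in 6 channels dominates the adjusted ranking
  grid1 <- grid
  grid1$value <- withr::with_seed(14, stats::rnorm(nrow(grid1), 0.5, 0.05))
  bump <- grid1$channel %in% 1:6 & grid1$task_state != "Rest" &
    grid1$sleep_state == "after_SD"
  grid1$value[bump] <- grid1$value[bump] + 0.5
  map1 <- channelwise_contrast_map(grid1, "sd_effect")
  expect_setequal(map1$channel[rank(map1$p_fdr, ties.method = "first") <= 6],
                  1:6)
  # FDR is the Benjamini-Hochberg step-up
  expect_equal(map1$p_fdr, stats::p.adjust(map1$p, "BH"))
})
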