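test_that("six all-positive distinct differences give W = 21, p = 2/64", {
  d <- c(1, 2, 3, 4, 5, 6)
  got <- wilcoxon_signed_rank(d)
  expect_equal(got$statistic, 21)
  expect_equal(got$p_value, 0.03125)
  expect_equal(got$method, "exact")
})

test_that("all-zero differences are degenerate, not a p-value", {
  got <- wilcoxon_signed_rank(rep(0, 5))
  expect_true(got$degenerate)
  expect_true(is.na(got$p_value))
})

test_that("exact p equals full sign-flip enumeration for every n up to 10", {
  for (n in 1:10) {
    for (seed in 1:3) {
      withr::with_seed(100 * n + seed, {
        d <- stats::rnorm(n)
        while (any(d == 0) || anyDuplicated(abs(d))) d <- stats::rnorm(n)
      })
      got <- wilcoxon_signed_rank(d, mode = "exact")
      want <- oracle_wilcoxon_exact(d)
      expect_equal(got$statistic, want$v)
      expect_equal(got$p_value, want$p, tolerance = 1e-12)
    }
  }
})

test_that("forced exact under ties enumerates over mid-ranks", {
  d <- c(1, 1, -2, 3, 3, -4)
  got <- wilcoxon_signed_rank(d, mode = "exact")
  expect_equal(got$method, "exact_enumeration")
  expect_equal(got$p_value, oracle_wilcoxon_exact(d)$p, tolerance = 1e-12)
  long <- rep(c(1, -1), 10)
  expect_error(wilcoxon_signed_rank(long, mode = "exact"), "m <= 16")
})

test_that("the p-value is invariant under a common positive rescaling", {
  withr::with_seed(31, d <- stats::rnorm(12))
  a <- wilcoxon_signed_rank(d)
  b <- wilcoxon_signed_rank(d * 37.5)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, b$statistic)
})

test_that("approximate mode applies tie and continuity corrections like wilcox.test", {
  withr::with_seed(32, d <- round(stats::rnorm(40), 1))
  d <- d[d != 0]
  got <- wilcoxon_signed_rank(d, mode = "approx")
  want <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                              correct = TRUE))
  expect_equal(got$p_value, want$p.value)
})

test_that("paired t handles the symmetric two-point case and degenerate input", {
  got <- paired_t(c(0, 0), c(1, -1))
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  expect_equal(got$df, 1)
  expect_error(paired_t(c(1, 2, 3), c(3, 4, 5)), "zero variance")
})

test_that("paired t matches the textbook formula on random pairs", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      x <- stats::rnorm(20, 100, 20)
      y <- x + stats::rnorm(20, 5, 10)
    })
    got <- paired_t(x, y)
    d <- y - x
    t_manual <- mean(d) / (stats::sd(d) / sqrt(20))
    p_manual <- 2 * stats::pt(-abs(t_manual), df = 19)
    expect_equal(got$statistic, t_manual, tolerance = 1e-12)
    expect_equal(got$p_value, p_manual, tolerance = 1e-12)
  }
})

test_that("perfect monotone association gives rho of exactly +/-1", {
  x <- c(3, 9, 27, 81, 243)
  expect_equal(rank_correlation(x, sqrt(x))$estimate, 1)
  expect_equal(rank_correlation(x, -log(x))$estimate, -1)
})

test_that("spearman is pearson on mid-ranks and monotone-transform invariant", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      x <- stats::rnorm(30)
      y <- 0.5 * x + stats::rnorm(30)
    })
    got <- rank_correlation(x, y, "spearman")
    want <- stats::cor(rank(x), rank(y))
    expect_equal(got$estimate, want, tolerance = 1e-12)
    # strictly monotone transforms change nothing
    again <- rank_correlation(exp(x), y^3 + 5 * y, "spearman")
    expect_equal(again$estimate, got$estimate, tolerance = 1e-12)
    expect_equal(again$p_value, got$p_value, tolerance = 1e-12)
  }
})

test_that("constant vectors and tiny samples are rejected", {
  expect_error(rank_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(rank_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("identical paired measures yield a degenerate, unflagged cell", {
  x <- c(100, 150, 200, 120)
  cell <- compare_cell(x, x)
  expect_equal(cell$discrepancy, 0)
  expect_true(is.na(cell$p_wilcoxon))
  expect_equal(cell$flag, "ns")
})

test_that("a constant +10 shift on 8 pairs is the all-positive extreme", {
  withr::with_seed(41, subj <- stats::runif(8, 60, 300))
  cell <- compare_cell(subj, subj + 10)
  expect_equal(cell$discrepancy, 10)
  expect_equal(cell$p_wilcoxon, 2 / 256)
  expect_equal(cell$flag, "significant")
  # paired t has zero variance here: reported as NA, not an error
  expect_true(is.na(cell$t_stat))
})

test_that("cell statistics match an independent straight-line recomputation", {
  withr::with_seed(50, {
    obj <- stats::rlnorm(50, 5, 0.5)
    subj <- 0.8 * obj + stats::rnorm(50, 0, 20)
  })
  cell <- compare_cell(subj, obj)
  expect_equal(cell$n, 50)
  expect_equal(cell$subj_mean, mean(subj), tolerance = 1e-12)
  expect_equal(cell$subj_sd, stats::sd(subj), tolerance = 1e-12)
  expect_equal(cell$obj_mean, mean(obj), tolerance = 1e-12)
  expect_equal(cell$discrepancy, mean(obj) - mean(subj), tolerance = 1e-12)
  d <- obj - subj
  t_manual <- mean(d) / (stats::sd(d) / sqrt(50))
  expect_equal(cell$t_stat, t_manual, tolerance = 1e-12)
  expect_equal(cell$spearman_rho, stats::cor(rank(subj), rank(obj)),
               tolerance = 1e-12)
  expect_equal(cell$pearson_r, stats::cor(subj, obj), tolerance = 1e-12)
  w <- suppressWarnings(stats::wilcox.test(obj, subj, paired = TRUE,
                                           exact = FALSE, correct = TRUE))
  expect_equal(cell$p_wilcoxon, w$p.value, tolerance = 1e-12)
})

test_that("the correlation panel has one row per cap level and day type", {
  cohort <- toy_cohort()
  g <- run_grid(cohort$sessions, cohort$subjective, zone = TEST_ZONE)
  panel <- correlation_panel(g, cutpoint_s = 20)
  expect_equal(nrow(panel), 7 * 2)
  expect_equal(sort(unique(panel$day_type)), c("weekday", "weekend"))
  expect_error(correlation_panel(g, cutpoint_s = 99), "no grid cells")
})

test_that("objective tied to subjective gives rho 1 in every panel row", {
  sim <- simulate_cohort(simulation_config(n_participants = 10, seed = 77))
  s <- sessionize(sim$events)
  frags <- split_at_day_boundaries(s, sim$config$zone)
  summ <- apply_inclusion_criteria(daily_totals(frags, sim$config$zone))
  # subjective defined as a strictly increasing transform of the
  # unfiltered objective mean; rank correlation must then be exactly 1
  # wherever the participant set and ordering are preserved
  subj <- tibble::tibble(
    participant_id = rep(summ$participant_id, 2),
    period = rep(c("weekday", "weekend"), each = nrow(summ)),
    subjective_min = c(sqrt(summ$mean_weekday_min),
                       sqrt(summ$mean_weekend_min)))
  g <- run_grid(s, subj, grid_spec(0, c(NA, 6), "include_all"),
                zone = sim$config$zone)
  free <- g[is.na(g$cap_h), ]
  expect_true(all(abs(free$spearman_rho - 1) < 1e-12))
})
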