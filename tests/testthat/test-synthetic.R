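test_that("scenario configs validate their fields", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(baseline = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(scenario_config(n_days = 0), "n_days")
  expect_error(scenario_config(volume_mean = -1), "volume_mean")
  expect_error(scenario_config(spikes = list(c(400, 10))), "spike")
  expect_error(scenario_config(events = list(c(1, 0, 0.1))), "event")
  expect_error(scenario_config(ooc_fraction = 1), "ooc_fraction")
  nullc <- null_scenario(n_days = 30)
  expect_equal(nullc$trend, c(0, 0, 0))
  expect_length(nullc$events, 0)
})

test_that("generation is deterministic in the seed, truth is seed-free", {
  cfg <- scenario_config(n_days = 40, volume_mean = 80)
  a <- generate_series(cfg, seed = 7)
  b <- generate_series(cfg, seed = 7)
  expect_identical(as.data.frame(a$series), as.data.frame(b$series))
  c2 <- generate_series(cfg, seed = 8)
  expect_false(identical(a$series$n_F, c2$series$n_F))
  # the truth trajectory depends only on the config
  expect_identical(a$truth$p, c2$truth$p)
})

test_that("the truth trajectory composes baseline, trend and events", {
  # no trend, no events: exactly constant at the baseline
  cfg0 <- null_scenario(n_days = 25)
  t0 <- generate_series(cfg0, seed = 1)$truth
  expect_true(all(abs(t0$p - matrix(cfg0$baseline, 25, 3, byrow = TRUE))
                  < 1e-12))

  # an event shifts p_F additively and rescales C and U proportionally
  cfg1 <- null_scenario(n_days = 25)
  cfg1$events <- list(c(10, 3, 0.1))
  t1 <- generate_series(cfg1, seed = 1)$truth
  expect_equal(unname(t1$p[10, 1]), 0.80, tolerance = 1e-12)
  expect_equal(unname(t1$p[10, 2] / t1$p[10, 3]), 0.164 / 0.136,
               tolerance = 1e-9)
  expect_equal(which(t1$event_day), 10:12)
  expect_equal(rowSums(t1$p), rep(1, 25), tolerance = 1e-12)

  # every realised truth vector stays on the simplex even when clipped
  cfg2 <- null_scenario(n_days = 10)
  cfg2$events <- list(c(2, 2, 0.5))
  expect_warning(t2 <- generate_series(cfg2, seed = 1)$truth, "clipped")
  expect_true(all(t2$p > 0 & t2$p < 1))
  expect_equal(t2$clipped_days, c(2L, 3L))
})

test_that("sampling matches the configured law", {
  # null config: pooled proportions within 3 standard errors of baseline
  cfg <- null_scenario(n_days = 120, volume_mean = 150)
  gs <- generate_series(cfg, seed = 11)
  pooled <- colSums(gs$series[, c("n_F", "n_C", "n_U")])
  n <- sum(pooled)
  for (j in 1:3) {
    se <- sqrt(cfg$baseline[j] * (1 - cfg$baseline[j]) / n)
    expect_lt(abs(pooled[j] / n - cfg$baseline[j]), 3 * se)
  }
  # empirical daily proportions approach the truth at large volumes
  cfg_big <- null_scenario(n_days = 8, volume_mean = 1e4,
                           volume_dispersion = 50)
  gb <- generate_series(cfg_big, seed = 3)
  expect_lt(max(abs(polarity_proportions(gb$series) - gb$truth$p)), 0.02)

  # a one-day multiplier-100 spike dominates the series volume
  cfg_sp <- null_scenario(n_days = 200, volume_mean = 150)
  cfg_sp$spikes <- list(c(150, 100))
  gsp <- generate_series(cfg_sp, seed = 4)
  expect_equal(which.max(gsp$series$volume), 150)
  expect_true(all(gsp$series$interactions >= gsp$series$volume))
})

test_that("post streams round-trip through ingestion", {
  cfg <- scenario_config(n_days = 30, volume_mean = 60,
                         duplicate_rate = 0.1)
  gp <- generate_posts(cfg, seed = 21)
  expect_false(any(duplicated(
    gp$posts$post_id[!duplicated(gp$posts$post_id)])))
  dd <- deduplicate(gp$posts)
  agg <- aggregate_daily(dd, min(gp$series$date), max(gp$series$date))
  expect_equal(as.data.frame(agg)[, names(gp$series)],
               as.data.frame(gp$series))

  # duplicate injection removes about the configured fraction
  frac_dup <- attr(dd, "n_duplicates") / nrow(gp$posts)
  expect_lt(abs(frac_dup - 0.1 / 1.1), 0.03)

  # out-of-context share close to its parameter
  retained <- mean(gp$posts$label[!duplicated(gp$posts$post_id)] != "OOC")
  expect_lt(abs(retained - (1 - cfg$ooc_fraction)), 0.03)
})

test_that("annotation simulation hits the agreement extremes", {
  ident <- diag(4)
  ann <- generate_annotations(50, 5, c(.6, .2, .1, .1), ident, seed = 5)
  expect_equal(fleiss_kappa(ann), 1)
  expect_true(all(rowSums(ann) == 5))
  expect_identical(ann, generate_annotations(50, 5, c(.6, .2, .1, .1),
                                             ident, seed = 5))
  expect_error(generate_annotations(10, 3, c(.6, .2, .1, .1),
                                    matrix(1, 4, 4)), "row-stochastic")
  expect_error(generate_annotations(10, 1, c(.6, .2, .1, .1), diag(4)),
               "raters")
})

test_that("calibration experiment summarises type-I behaviour", {
  cfg <- null_scenario(n_days = 50, volume_mean = 40)
  tab <- calibration_experiment(cfg, "basic", n_replicates = 4,
                                alphas = c(0.05, 0), seed = 31)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mean_rejected[tab$alpha == 0], 0)
  expect_equal(tab$mean_tested, rep(50, 2))
  expect_equal(tab$expected_days, c(0.05, 0) * 50)
  # variance flavour runs too
  tabv <- calibration_experiment(cfg, "variance", n_replicates = 2,
                                 alphas = 0.05, window = 10, seed = 31)
  expect_true(tabv$rejection_fraction >= 0 && tabv$rejection_fraction <= 1)
})
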