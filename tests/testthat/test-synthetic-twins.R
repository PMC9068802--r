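test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_mz = 80, n_dz = 80, seed = 99)
  t1 <- simulate_pairs(cfg)
  t2 <- simulate_pairs(cfg)
  expect_identical(t1, t2)
  t3 <- simulate_pairs(sim_config(n_mz = 80, n_dz = 80, seed = 100))
  expect_false(identical(t1$performance_1, t3$performance_1))
})

test_that("pure-E performance is uncorrelated across twins", {
  p <- moderated_paths(e_xx = 1, e_yy = 1)
  cfg <- univariate_config(0, 0, 1, 1500, 1500, seed = 21)
  tab <- simulate_pairs(cfg)
  for (z in c("MZ", "DZ")) {
    i <- tab$zygosity == z
    rho <- cor(tab$performance_1[i], tab$performance_2[i])
    expect_lt(abs(rho), 3 / sqrt(sum(i)))
  }
})

test_that("twin correlations recover the generating ACE shares (Falconer)", {
  tab <- simulate_pairs(univariate_config(0.5, 0.3, 0.2, 4000, 4000,
                                          seed = 31))
  tc <- twin_correlations(tab, "performance")
  rho_mz <- tc$rho[tc$zygosity == "MZ"]
  rho_dz <- tc$rho[tc$zygosity == "DZ"]
  expect_equal(rho_mz, 0.8, tolerance = 0.03)
  expect_equal(rho_dz, 0.55, tolerance = 0.04)
  expect_equal(2 * (rho_mz - rho_dz), 0.5, tolerance = 0.06)  # a2
  expect_equal(2 * rho_dz - rho_mz, 0.3, tolerance = 0.06)    # c2
})

test_that("MZ twins are identical when only A paths are non-zero", {
  p <- moderated_paths(a_xx = 2, a_yx = 0.5, a_yy = 1)
  cfg <- sim_config(n_mz = 50, n_dz = 0,
                    paths = list(immediate = p, delayed = p, missing = p),
                    means = list(immediate = list(mu_x = 0, mu_y = 0),
                                 delayed = list(mu_x = 0, mu_y = 0),
                                 missing = list(mu_x = 0, mu_y = 0)),
                    betas = list(), selection = list(p_delayed = 0.5),
                    p_track_missing = 0, missing_rates = list(),
                    performance_mean = 0, seed = 8)
  tab <- simulate_pairs(cfg)
  expect_equal(tab$performance_1, tab$performance_2, tolerance = 1e-12)
  expect_equal(tab$attainment_1, tab$attainment_2, tolerance = 1e-12)
})

test_that("simulated moments match the model-implied pair covariance", {
  paths <- trackace:::.default_paths()
  cfg <- sim_config(n_mz = 4000, n_dz = 4000, betas = list(),
                    selection = list(p_delayed = 0.5),
                    p_track_missing = 0, missing_rates = list(),
                    seed = 19)
  tab <- simulate_pairs(cfg)
  for (z in c("MZ", "DZ")) for (s in c("immediate", "delayed")) {
    i <- tab$zygosity == z & tab$tracking_1 == s & tab$tracking_2 == s
    n <- sum(i)
    expect_gt(n, 200)
    emp <- stats::cov(cbind(tab$performance_c_1, tab$attainment_1,
                            tab$performance_c_2, tab$attainment_2)[i, ])
    mod <- pair_covariance(paths[[s]], r = ifelse(z == "MZ", 1, 0.5))
    expect_lt(max(abs(emp - unclass(mod)) / pmax(abs(mod), 1)), 4 / sqrt(n))
  }
})

test_that("logistic tracking assignment hits its marginal rate and limits", {
  tab <- complete_bivariate_table(2500, 2500, seed = 13, p_track_missing = 0)
  t0 <- assign_tracking_by_performance(tab, intercept = stats::qlogis(0.27),
                                       slope = 0, seed = 2)
  share <- mean(c(t0$tracking_1, t0$tracking_2) == "delayed", na.rm = TRUE)
  expect_equal(share, 0.27, tolerance = 3 * sqrt(0.27 * 0.73 / 10000))
  # steep slope approaches a step function in performance
  t1 <- assign_tracking_by_performance(tab, intercept = 0, slope = 50,
                                       seed = 2)
  hi <- c(t1$performance_c_1, t1$performance_c_2) > 1
  lo <- c(t1$performance_c_1, t1$performance_c_2) < -1
  st <- c(t1$tracking_1, t1$tracking_2)
  expect_true(all(st[hi] == "delayed"))
  expect_true(all(st[lo] == "immediate"))
})

test_that("delayed share rises monotonically across performance bins under selection", {
  tab <- complete_bivariate_table(3000, 3000, seed = 17, p_track_missing = 0)
  tab <- assign_tracking_by_performance(tab, intercept = -1.1, slope = 0.08,
                                        seed = 3)
  ct <- tracking_crosstab(tab)
  pct_delayed <- ct$row_pct[, "delayed"]
  expect_true(all(diff(pct_delayed) > -3))   # monotone up to sampling noise
  expect_gt(stats::cor(seq_along(pct_delayed), pct_delayed), 0.9)
})

test_that("missingness is applied at the requested rates", {
  tab <- complete_bivariate_table(2500, 2500, seed = 5)
  same <- impose_missingness(tab, list(attainment = 0, performance = 0),
                             seed = 1)
  expect_identical(same$attainment_1, tab$attainment_1)
  m <- impose_missingness(tab, list(attainment = 0.3), seed = 1)
  frac <- mean(is.na(c(m$attainment_1, m$attainment_2)))
  expect_equal(frac, 0.3, tolerance = 3 * sqrt(0.3 * 0.7 / 10000))
  expect_error(impose_missingness(tab, list(attainment = 1.2)), "\\[0, 1\\]")
  expect_error(impose_missingness(tab, list(speed = 0.1)), "speed")
})

test_that("a fully missing moderator fails downstream with a clear message", {
  tab <- complete_bivariate_table(30, 30, seed = 6)
  gone <- impose_missingness(tab, list(performance = 1), seed = 1)
  expect_error(trackace:::.prepare_fit_data(gone), "empty")
})
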