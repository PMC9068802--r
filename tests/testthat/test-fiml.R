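test_that("FIML equals the direct multivariate-normal oracle", {
  tab <- complete_bivariate_table(60, 60, seed = 301)
  spec <- ace_model_spec("1b")
  theta <- trackace:::.falconer_start(spec, tab,
                                      trackace:::.prepare_fit_data(tab))
  expect_equal(neg2_loglik(theta, spec, tab), oracle_neg2ll(theta, spec, tab),
               tolerance = 1e-9)
  # with item missingness (FIML submatrices)
  miss <- impose_missingness(tab, list(attainment = 0.3, performance = 0.15),
                             seed = 4)
  expect_equal(neg2_loglik(theta, spec, miss),
               oracle_neg2ll(theta, spec, miss), tolerance = 1e-9)
})

test_that("single observed variables reduce to univariate normal densities", {
  tab <- complete_bivariate_table(40, 40, seed = 302)
  only_x1 <- impose_missingness(tab, list(attainment = 1), seed = 1)
  only_x1$performance_2 <- NA_real_
  only_x1 <- as_pair_table(as.data.frame(only_x1),
                           centering = attr(only_x1, "centering"))
  spec <- ace_model_spec("1a")
  theta <- trackace:::.falconer_start(spec, tab,
                                      trackace:::.prepare_fit_data(tab))
  ex <- trackace:::.expand_params(theta, spec)
  sd_x <- sqrt(sum(ex$paths["immediate", c("a_xx", "c_xx", "e_xx")]^2))
  mu <- trackace:::.mean_matrix(ex, trackace:::.prepare_fit_data(only_x1))
  direct <- -2 * sum(stats::dnorm(only_x1$performance_c_1,
                                  mean = mu[, 1], sd = sd_x, log = TRUE))
  expect_equal(neg2_loglik(theta, spec, only_x1), direct, tolerance = 1e-9)
})

test_that("duplicating every pair exactly doubles the -2 log-likelihood", {
  tab <- complete_bivariate_table(50, 50, seed = 303)
  dup <- as_pair_table(
    within(rbind(as.data.frame(tab), as.data.frame(tab)),
           pair_id <- sprintf("P%05d", seq_len(200))),
    centering = attr(tab, "centering"))
  spec <- ace_model_spec("1a")
  theta <- trackace:::.falconer_start(spec, tab,
                                      trackace:::.prepare_fit_data(tab))
  expect_equal(neg2_loglik(theta, spec, dup),
               2 * neg2_loglik(theta, spec, tab), tolerance = 1e-10)
})

test_that("freeing parameters never worsens the optimum and the fit is start-invariant", {
  tab <- complete_bivariate_table(400, 400, seed = 304)
  f1a <- ace_fit(tab, "1a", n_restarts = 2, seed = 1, se = FALSE)
  f1b <- ace_fit(tab, "1b", n_restarts = 1, seed = 1, se = FALSE,
                 starts = warm_start(f1a, ace_model_spec("1b")))
  expect_lte(f1b$neg2ll, f1a$neg2ll + 1e-3)
  # jittered restart reaches the same optimum
  f1a_b <- ace_fit(tab, "1a", n_restarts = 3, seed = 42, se = FALSE)
  expect_equal(f1a$neg2ll, f1a_b$neg2ll, tolerance = 1e-4)
  expect_equal(f1a$convergence, 0)
})

test_that("likelihood-ratio arithmetic and chi-square reference are correct", {
  lrt <- likelihood_ratio_test(73003.2, 72691.1, df = 22)
  expect_equal(lrt$statistic, 312.1, tolerance = 1e-9)
  expect_lt(lrt$p.value, 0.001)
  lrt2 <- likelihood_ratio_test(72691.1, 72386.9, df = 18)
  expect_equal(lrt2$statistic, 304.2, tolerance = 1e-9)
  same <- likelihood_ratio_test(1000, 1000, df = 3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(likelihood_ratio_test(100, 98, df = 4)$p.value,
               stats::pchisq(2, 4, lower.tail = FALSE))
  expect_error(likelihood_ratio_test(100, 99), "df")
  expect_warning(likelihood_ratio_test(99, 100.5, df = 2), "negative")
})

test_that("both AIC conventions follow their formulas", {
  fake <- list(neg2ll = 100, npar = 5, n_records = 60)
  a <- aic_conventions(fake)
  expect_equal(a[["standard"]], 110)
  expect_equal(a[["mx"]], 100 - 2 * (60 - 5))
  # Delta-AIC identity: dAIC = LRT - 2 * d(df) under the standard convention
  f1 <- list(neg2ll = 500, npar = 4, n_records = 100)
  f2 <- list(neg2ll = 490, npar = 10, n_records = 100)
  dAIC <- aic_conventions(f2)[["standard"]] - aic_conventions(f1)[["standard"]]
  lrt_stat <- f1$neg2ll - f2$neg2ll
  expect_equal(dAIC, -(lrt_stat - 2 * (f2$npar - f1$npar)))
})

test_that("delta-method intervals behave on identity and constant transforms", {
  tab <- complete_bivariate_table(300, 300, seed = 305)
  fit <- ace_fit(tab, "1a", n_restarts = 1, seed = 1)
  i <- which(names(coef(fit)) == "a_xx.all")
  ci <- delta_ci(fit, function(th) th[i])
  expect_equal(ci[["estimate"]], coef(fit)[[i]])
  expect_equal(ci[["se"]], fit$se[[i]], tolerance = 1e-6)
  expect_equal(ci[["upper"]] - ci[["lower"]],
               2 * stats::qnorm(0.975) * fit$se[[i]], tolerance = 1e-6)
  flat <- delta_ci(fit, function(th) 42)
  expect_equal(unname(flat), c(42, 0, 42, 42))
  # standardized-share interval is sensible and covers the point estimate
  share <- function(th) {
    ex <- trackace:::.expand_params(th, fit$spec)
    vc <- variance_components(trackace:::.paths_for_status(ex, "immediate"))
    standardize_components(vc)$attainment[["VA"]]
  }
  ci2 <- delta_ci(fit, share)
  expect_true(ci2[["lower"]] < ci2[["estimate"]] &&
                ci2[["estimate"]] < ci2[["upper"]])
  expect_true(ci2[["se"]] > 0 && ci2[["se"]] < 0.5)
})

test_that("fit objects expose the standard modelling interface", {
  tab <- complete_bivariate_table(250, 250, seed = 306)
  fit <- ace_fit(tab, "1a", n_restarts = 1, seed = 1)
  expect_s3_class(fit, "ace_fit")
  expect_length(coef(fit), 15)
  expect_equal(dim(vcov(fit)), c(15, 15))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -fit$neg2ll / 2)
  expect_equal(attr(ll, "df"), 15)
  expect_equal(stats::AIC(fit), aic_conventions(fit)[["standard"]])
  expect_output(print(fit), "free parameters: 15")
  expect_output(print(summary(fit)), "share")
  # canonical signs at convergence
  for (nm in c("a_xx.all", "c_xx.all", "e_xx.all", "a_yy.all"))
    expect_gte(coef(fit)[[nm]], 0)
  # simulate() round-trips a table of the same shape
  sim <- simulate(fit, seed = 9, n_mz = 40, n_dz = 40)
  expect_s3_class(sim, "pair_table")
  expect_equal(nrow(sim), 80)
})

test_that("anova on nested fits reports the LRT chain", {
  tab <- complete_bivariate_table(300, 300, seed = 307)
  f1a <- ace_fit(tab, "1a", n_restarts = 1, seed = 1, se = FALSE)
  f1b <- ace_fit(tab, "1b", n_restarts = 1, seed = 1, se = FALSE,
                 starts = warm_start(f1a, ace_model_spec("1b")))
  tab_an <- anova(f1a, f1b)
  expect_equal(tab_an$df[2], 22)
  expect_equal(tab_an$Chisq[2], f1a$neg2ll - f1b$neg2ll, tolerance = 1e-9)
})
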