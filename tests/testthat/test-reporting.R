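test_that("double-entry twin correlations are label-invariant and exact in edge cases", {
  df <- tiny_pair_df()
  df$attainment_2 <- df$attainment_1       # identical within pair
  tab <- as_pair_table(df)
  tc <- twin_correlations(tab, "attainment")
  expect_equal(tc$rho[tc$zygosity == "MZ"], 1)
  # swapping twin columns leaves the estimate unchanged
  tab2 <- complete_bivariate_table(400, 400, seed = 51)
  sw <- as.data.frame(tab2)
  for (col in c("attainment", "performance", "tracking", "male",
                "birth_year")) {
    tmp <- sw[[paste0(col, "_1")]]
    sw[[paste0(col, "_1")]] <- sw[[paste0(col, "_2")]]
    sw[[paste0(col, "_2")]] <- tmp
  }
  sw <- as_pair_table(sw, centering = attr(tab2, "centering"))
  expect_equal(twin_correlations(tab2, "attainment")$rho,
               twin_correlations(sw, "attainment")$rho)
  # insufficient pairs -> NA with count
  few <- as_pair_table(tiny_pair_df()[2, ])
  tc_few <- twin_correlations(few, "attainment")
  expect_true(all(is.na(tc_few$rho)))
})

test_that("simulated univariate shares reproduce the expected twin correlations", {
  tab <- simulate_pairs(univariate_config(0.6, 0.2, 0.2, 3000, 3000,
                                          seed = 52))
  tc <- twin_correlations(tab, "performance")
  expect_equal(tc$rho[tc$zygosity == "MZ"], 0.8, tolerance = 0.03)
  expect_equal(tc$rho[tc$zygosity == "DZ"], 0.5, tolerance = 0.04)
})

test_that("decomposition table reproduces printed-path arithmetic from a fit object", {
  # synthetic fit object carrying the printed overall path estimates
  spec <- ace_model_spec("1a", covariates = FALSE)
  theta <- setNames(numeric(11), spec$param_names)
  p <- unclass(paths_model1a())
  for (role in names(p)[1:9]) theta[[paste0(role, ".all")]] <- p[[role]]
  theta[["mu_x.all"]] <- -0.70; theta[["mu_y.all"]] <- 2.67
  fake <- structure(list(coefficients = theta,
                         se = setNames(rep(NA_real_, 11), names(theta)),
                         spec = spec, neg2ll = 0, npar = 11,
                         n_records = 0), class = "ace_fit")
  tab <- decomposition_table(fake)
  pick <- function(block, q, set = "all")
    tab$estimate[tab$set == set & tab$block == block & tab$quantity == q]
  expect_equal(pick("attainment", "VA"), 0.74, tolerance = 0.01)
  expect_equal(pick("attainment", "VT"), 1.27, tolerance = 0.02)
  expect_equal(pick("share_attainment", "VA"), 0.58, tolerance = 0.02)
  expect_equal(pick("performance", "VA"), 50.16, tolerance = 0.05)
  expect_equal(pick("intercepts", "mu_y"), 2.67)
  # shares sum to one and all-zero C rows stay exactly zero
  expect_equal(sum(tab$estimate[tab$set == "all" &
                                  tab$block == "share_attainment"]), 1)
  expect_equal(pick("unique", "VC"), 0)
  # pure function: identical output on re-run
  expect_identical(tab, decomposition_table(fake))
})

test_that("conditional variance curves evaluate moderated components on the grid", {
  spec <- ace_model_spec("2", covariates = FALSE)
  theta <- setNames(numeric(n_free_parameters(spec)), spec$param_names)
  t2_imm <- c(a_xx = 7.19, c_xx = 3.50, e_xx = 3.78,
              a_yx = 0.71, c_yx = 0.62, e_yx = 0.25,
              a_yy = 0.49, c_yy = -0.16, e_yy = 0.44,
              a_yx_mod = 0.01, a_yy_mod = 0, e_yy_mod = -0.01)
  t2_del <- c(a_xx = 5.39, c_xx = 1.10, e_xx = 3.24,
              a_yx = 0.56, c_yx = 0.08, e_yx = 0.19,
              a_yy = 0.67, c_yy = -0.10, e_yy = 0.46,
              a_yy_mod = -0.01, c_yx_mod = 0.01, e_yy_mod = -0.01)
  for (nm in names(t2_imm)) theta[[paste0(nm, ".immediate")]] <- t2_imm[[nm]]
  for (nm in names(t2_del)) theta[[paste0(nm, ".delayed")]] <- t2_del[[nm]]
  fake <- structure(list(coefficients = theta,
                         se = setNames(rep(NA_real_, length(theta)),
                                       names(theta)),
                         spec = spec, x_range = c(-38, 12)),
                    class = "ace_fit")
  cur <- conditional_variance_curves(fake, x_grid = c(-10, 0, 10))
  at <- function(status, X, part, comp)
    cur$raw[cur$status == status & cur$X == X & cur$part == part &
              cur$component == comp]
  expect_equal(at("delayed", 0, "unique", "A"), 0.67^2)
  expect_equal(at("immediate", 0, "unique", "A"), 0.49^2)
  expect_equal(at("delayed", 10, "unique", "A"), (0.67 - 0.1)^2)
  # standardized components sum to 1 at every grid point
  sums <- tapply(cur$standardized[cur$part != "total"],
                 list(cur$status[cur$part != "total"],
                      cur$X[cur$part != "total"]), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # flat when slopes are zero
  theta0 <- theta
  theta0[grep("_mod", names(theta0))] <- 0
  fake0 <- fake; fake0$coefficients <- theta0
  cur0 <- conditional_variance_curves(fake0, x_grid = c(-10, 0, 10))
  expect_equal(length(unique(round(cur0$raw[cur0$status == "immediate" &
                                              cur0$part == "unique" &
                                              cur0$component == "A"], 12))), 1)
  expect_warning(conditional_variance_curves(fake, x_grid = c(-50, 0)),
                 "range")
})

test_that("Rao-Scott correction is exact for singleton clusters", {
  set.seed(61)
  row <- sample(letters[1:4], 600, replace = TRUE)
  col <- sample(c("i", "d"), 600, replace = TRUE,
                prob = c(0.7, 0.3))
  ct <- crosstab_with_raoscott(row, col)
  pearson <- suppressWarnings(stats::chisq.test(table(row, col),
                                                correct = FALSE))
  expect_equal(ct$pearson, unname(pearson$statistic), tolerance = 1e-12)
  expect_lt(abs(ct$statistic - ct$pearson), 1e-10)
  expect_equal(ct$delta_bar, 1, tolerance = 1e-10)
  expect_equal(ct$df1, (4 - 1) * (2 - 1), tolerance = 1e-9)
})

test_that("Rao-Scott statistic is invariant under duplicating every cluster", {
  set.seed(62)
  n <- 400
  row <- sample(LETTERS[1:3], n, replace = TRUE)
  col <- sample(c("i", "d"), n, replace = TRUE, prob = c(0.6, 0.4))
  base <- crosstab_with_raoscott(row, col)
  dup <- crosstab_with_raoscott(rep(row, 2), rep(col, 2),
                                cluster = rep(seq_len(n), 2))
  expect_equal(dup$pearson, 2 * base$pearson, tolerance = 1e-10)
  expect_lt(abs(dup$statistic - base$statistic), 1e-8)
  # perfect within-cluster dependence halves the effective information:
  # the corrected statistic never exceeds Pearson
  expect_lte(dup$statistic, dup$pearson)
  expect_equal(dup$delta_bar, 2 * base$delta_bar, tolerance = 1e-8)
})

test_that("crosstab margins, percentages and clustering wiring are consistent", {
  tab <- complete_bivariate_table(800, 800, seed = 63)
  ct <- tracking_crosstab(tab)
  n_observed <- sum(!is.na(cito_bins(c(tab$performance_1,
                                       tab$performance_2))) &
                      c(tab$tracking_1, tab$tracking_2) %in%
                        c("immediate", "delayed"))
  expect_equal(ct$n, n_observed)
  expect_true(all(abs(rowSums(ct$row_pct) - 100) < 1e-9))
  expect_equal(ct$row_pct,
               100 * sweep(ct$counts, 1, rowSums(ct$counts), "/"))
  # twins cluster positively, so the correction shrinks the statistic
  expect_lte(ct$statistic, ct$pearson + 1e-9)
  expect_equal(ct$n_clusters, length(unique(rep(tab$pair_id, 2)[
    !is.na(cito_bins(c(tab$performance_1, tab$performance_2))) &
      c(tab$tracking_1, tab$tracking_2) %in% c("immediate", "delayed")])))
})

test_that("cito bins follow the conventional edges", {
  b <- cito_bins(c(501, 518, 519, 528, 533, 539, 544, 545, 550))
  expect_equal(as.character(b),
               c("500-518", "500-518", "519-525", "526-528", "533-536",
                 "537-539", "540-544", "545-550", "545-550"))
})

test_that("homogeneity checks accept homogeneous data and flag injected differences", {
  tab <- complete_bivariate_table(600, 600, seed = 64)
  hom <- homogeneity_checks(tab, "performance", by = "birth_order")
  expect_equal(hom$model,
               c("free", "equal variances", "equal variances + means"))
  expect_true(all(diff(hom$npar) < 0))
  expect_true(all(hom$Chisq[-1] >= 0))
  # generator is exchangeable in birth order: no step should reject strongly
  expect_true(all(hom$p.value[-1] > 0.01))
  # inject a large sex difference in means
  df <- as.data.frame(tab)
  df$attainment_1 <- df$attainment_1 + 1.5 * df$male_1
  df$attainment_2 <- df$attainment_2 + 1.5 * df$male_2
  sexed <- as_pair_table(df, centering = attr(tab, "centering"))
  het <- homogeneity_checks(sexed, "attainment", by = "sex")
  expect_lt(het$p.value[3], 1e-6)
})

test_that("fits export to JSON and a decomposition TSV", {
  tab <- complete_bivariate_table(150, 150, seed = 65)
  fit <- ace_fit(tab, "1a", n_restarts = 1, seed = 1, se = FALSE)
  fj <- withr::local_tempfile(fileext = ".json")
  export_fit_json(fit, fj)
  parsed <- jsonlite::read_json(fj)
  expect_equal(parsed$npar, 15)
  expect_equal(parsed$neg2ll, fit$neg2ll, tolerance = 1e-9)
  ft <- withr::local_tempfile(fileext = ".tsv")
  export_fit_tsv(fit, ft)
  tsv <- utils::read.delim(ft)
  expect_true(all(c("set", "block", "quantity", "estimate") %in% names(tsv)))
  expect_gt(nrow(tsv), 30)
})
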