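# Shared fixtures built in code.

# Minimal hand-built three-pair table exercising zygosity, tracking
# patterns and missingness.
tiny_pair_df <- function() {
  data.frame(
    pair_id = c("A1", "A2", "A3"),
    zygosity = c("MZ", "DZ", "MZ"),
    attainment_1 = c(4, 2, 3), attainment_2 = c(3.5, NA, 3),
    performance_1 = c(545, 530, 538), performance_2 = c(544, 531, NA),
    tracking_1 = c("immediate", "immediate", "delayed"),
    tracking_2 = c("immediate", "delayed", NA),
    male_1 = c(1, 0, 1), male_2 = c(1, 0, 1),
    birth_year_1 = c(1990, 1995, 1992), birth_year_2 = c(1990, 1995, 1992),
    stringsAsFactors = FALSE)
}

# Published path sets: overall (model 1a) and timing-specific (model 1b).
paths_model1a <- function() {
  moderated_paths(a_xx = 7.08, c_xx = 2.74, e_xx = 3.69,
                  a_yx = 0.65, c_yx = 0.53, e_yx = 0.20,
                  a_yy = 0.56, c_yy = 0.00, e_yy = 0.45)
}
paths_model1b_immediate <- function() {
  moderated_paths(a_xx = 7.11, c_xx = 3.64, e_xx = 3.81,
                  a_yx = 0.66, c_yx = 0.57, e_yx = 0.22,
                  a_yy = 0.53, c_yy = -0.16, e_yy = 0.44)
}
paths_model1b_delayed <- function() {
  moderated_paths(a_xx = 5.40, c_xx = 0.98, e_xx = 3.25,
                  a_yx = 0.53, c_yx = 0.04, e_yx = 0.19,
                  a_yy = 0.64, c_yy = -0.13, e_yy = 0.43)
}

# Univariate generating config on the standardized scale: performance has
# unit total variance split a2/c2/e2, attainment paths all zero except a
# pure E residual so each twin has a defined phenotype.
univariate_config <- function(a2, c2, e2, n_mz, n_dz, seed) {
  p <- moderated_paths(a_xx = sqrt(a2), c_xx = sqrt(c2), e_xx = sqrt(e2),
                       e_yy = 1)
  sim_config(n_mz = n_mz, n_dz = n_dz,
             paths = list(immediate = p, delayed = p, missing = p),
             means = list(immediate = list(mu_x = 0, mu_y = 0),
                          delayed = list(mu_x = 0, mu_y = 0),
                          missing = list(mu_x = 0, mu_y = 0)),
             betas = list(),
             selection = list(p_delayed = 0.3), p_track_missing = 0,
             missing_rates = list(), performance_mean = 0, seed = seed)
}

# A fully-observed bivariate table under the Model-1b-like generating
# values with random status assignment (statuses exactly follow the
# generating path sets).
complete_bivariate_table <- function(n_mz, n_dz, seed,
                                     p_track_missing = 0.2) {
  simulate_pairs(sim_config(
    n_mz = n_mz, n_dz = n_dz,
    selection = list(p_delayed = 0.3),
    p_track_missing = p_track_missing,
    missing_rates = list(), seed = seed))
}

# Direct multivariate-normal -2 log-likelihood oracle: per-pair Gaussian
# density of the observed subvector via base R linear algebra, means and
# covariances assembled from the R-side structural functions.
oracle_neg2ll <- function(theta, spec, pairs) {
  ex <- trackace:::.expand_params(theta, spec)
  statuses <- c("immediate", "delayed", "missing")
  tot <- 0
  for (i in seq_len(nrow(pairs))) {
    s1 <- pairs$tracking_1[i]; s2 <- pairs$tracking_2[i]
    if (is.na(s1)) s1 <- "missing"
    if (is.na(s2)) s2 <- "missing"
    x1 <- pairs$performance_c_1[i]; x2 <- pairs$performance_c_2[i]
    y <- c(x1, pairs$attainment_1[i], x2, pairs$attainment_2[i])
    obs <- c(!is.na(x1), !is.na(pairs$attainment_1[i]) & !is.na(x1),
             !is.na(x2), !is.na(pairs$attainment_2[i]) & !is.na(x2))
    if (!any(obs)) next
    X1 <- if (is.na(x1)) 0 else x1
    X2 <- if (is.na(x2)) 0 else x2
    S <- pair_covariance(trackace:::.paths_for_status(ex, s1),
                         trackace:::.paths_for_status(ex, s2),
                         r = ifelse(pairs$zygosity[i] == "MZ", 1, 0.5),
                         X1 = X1, X2 = X2)
    means <- list(mu_x = ex$mu[c(s1, s2), "mu_x"],
                  mu_y = ex$mu[c(s1, s2), "mu_y"],
                  beta_male_x = ex$beta[1], beta_male_y = ex$beta[2],
                  beta_yob_x = ex$beta[3], beta_yob_y = ex$beta[4])
    mu <- mean_vector(means,
                      male1 = pairs$male_1[i], male2 = pairs$male_2[i],
                      yob1 = pairs$birth_year_c_1[i],
                      yob2 = pairs$birth_year_c_2[i])
    mu <- mu + c(0, ex$bmod[match(s1, statuses)] * X1,
                 0, ex$bmod[match(s2, statuses)] * X2)
    So <- S[obs, obs, drop = FALSE]
    d <- y[obs] - mu[obs]
    tot <- tot + sum(obs) * log(2 * pi) +
      determinant(So, logarithm = TRUE)$modulus[1] +
      drop(t(d) %*% solve(So) %*% d)
  }
  tot
}
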