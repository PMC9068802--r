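# Generator for twin-pair tables drawn from the exact model the analysis
# assumes: correlated additive-genetic factors (r = 1 MZ, 0.5 DZ), shared
# C, independent E, bivariate Cholesky cross-loadings from performance to
# attainment, linear path moderation by the twin's own realized centered
# performance, covariate effects, performance-dependent tracking
# assignment, and item missingness.

# Default timing-specific path sets (immediate / delayed) mirroring
# published register-based estimates of this model family, with the
# overall single-set estimates standing in for the tracking-missing
# status, whose full path set is not published.
.default_paths <- function() {
  list(
    immediate = moderated_paths(a_xx = 7.11, c_xx = 3.64, e_xx = 3.81,
                                a_yx = 0.66, c_yx = 0.57, e_yx = 0.22,
                                a_yy = 0.53, c_yy = -0.16, e_yy = 0.44),
    delayed = moderated_paths(a_xx = 5.40, c_xx = 0.98, e_xx = 3.25,
                              a_yx = 0.53, c_yx = 0.04, e_yx = 0.19,
                              a_yy = 0.64, c_yy = -0.13, e_yy = 0.43),
    missing = moderated_paths(a_xx = 7.08, c_xx = 2.74, e_xx = 3.69,
                              a_yx = 0.65, c_yx = 0.53, e_yx = 0.20,
                              a_yy = 0.56, c_yy = 0.00, e_yy = 0.45))
}

.default_means <- function() {
  list(immediate = list(mu_x = -1.33, mu_y = 2.61),
       delayed = list(mu_x = 1.79, mu_y = 2.94),
       missing = list(mu_x = -0.70, mu_y = 2.67))
}

#' Build a generating configuration for synthetic twin pairs
#'
#' Defaults reproduce the study conditions the package's analyses assume: a
#' register-scale sample, immediate/delayed path sets and intercepts from
#' the multigroup decomposition, a tracking-missing status with the overall
#' path set, logistic performance-dependent selection into delayed tracking
#' calibrated to a ~27% marginal delayed share, and survey-style item
#' missingness.
#'
#' @param n_mz,n_dz Numbers of MZ and DZ pairs.
#' @param paths Named list of [moderated_paths()] for statuses
#'   `immediate`, `delayed`, `missing`.
#' @param means Named list per status with `mu_x`, `mu_y` (centered
#'   performance scale; raw attainment scale).
#' @param betas Covariate slopes `beta_male_x`, `beta_male_y`,
#'   `beta_yob_x`, `beta_yob_y`.
#' @param selection Tracking-selection model. `list(p_delayed =)` assigns
#'   the delayed status independently of performance;
#'   `list(intercept =, slope =)` draws each twin independently with
#'   `P(delayed | X) = plogis(intercept + slope * X)`; adding `sd_pair`,
#'   `sd_genetic`, `sd_twin` switches to a latent-threshold model
#'   `delayed = 1{intercept + slope * X + u_pair + g + e > 0}` with a
#'   pair-shared normal component (school choice is mostly a joint
#'   decision), a relatedness-correlated genetic component, and a small
#'   twin-specific residual — the default, calibrated once to a ~27%
#'   marginal delayed share with ~4% (MZ) / ~11% (DZ) pair discordance.
#' @param p_track_missing Per-twin probability of the tracking-missing
#'   status (a generative status with its own path set, mirroring the
#'   analysis model).
#' @param missing_rates Per-field blanking rates applied by
#'   [impose_missingness()] (names among `attainment`, `performance`,
#'   `tracking`).
#' @param p_male Probability a twin is male (MZ pairs are same-sex; DZ
#'   twins draw independently).
#' @param birth_years Integer range pairs are sampled from (uniform, shared
#'   within pair).
#' @param performance_mean Raw-scale constant added to centered simulated
#'   performance (CITO-like scale).
#' @param seed Integer seed; all randomness derives from it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_mz = 1700, n_dz = 3241,
                       paths = .default_paths(),
                       means = .default_means(),
                       betas = list(beta_male_x = 0.8, beta_male_y = 0.12,
                                    beta_yob_x = 0.05, beta_yob_y = 0.01),
                       selection = list(intercept = -1.7, slope = 0.08,
                                        sd_pair = 2.5, sd_genetic = 1.0,
                                        sd_twin = 0.2),
                       p_track_missing = 0.33,
                       missing_rates = list(attainment = 0.37,
                                            performance = 0.05),
                       p_male = 0.46,
                       birth_years = 1986:1999,
                       performance_mean = 538,
                       seed = 2026) {
  stopifnot(n_mz >= 0, n_dz >= 0,
            p_track_missing >= 0, p_track_missing <= 1,
            all(c("immediate", "delayed", "missing") %in% names(paths)))
  for (p in paths)
    if (!all(is.finite(unclass(p)))) stop("non-finite path set in config")
  structure(list(n_mz = n_mz, n_dz = n_dz, paths = paths, means = means,
                 betas = betas, selection = selection,
                 p_track_missing = p_track_missing,
                 missing_rates = missing_rates, p_male = p_male,
                 birth_years = birth_years,
                 performance_mean = performance_mean, seed = seed),
            class = "sim_config")
}

#' Generating configuration with performance-moderated paths
#'
#' As [sim_config()] but with the moderated (Model-2-style) path sets and
#' intercepts for the immediate and delayed statuses.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @export
config_moderated <- function(...) {
  paths <- .default_paths()
  paths$immediate <- moderated_paths(
    a_xx = 7.19, c_xx = 3.50, e_xx = 3.78,
    a_yx = 0.71, c_yx = 0.62, e_yx = 0.25,
    a_yy = 0.49, c_yy = -0.16, e_yy = 0.44,
    a_yx_mod = 0.01, c_yx_mod = 0.00, e_yx_mod = 0.00,
    a_yy_mod = 0.00, c_yy_mod = 0.00, e_yy_mod = -0.01)
  paths$delayed <- moderated_paths(
    a_xx = 5.39, c_xx = 1.10, e_xx = 3.24,
    a_yx = 0.56, c_yx = 0.08, e_yx = 0.19,
    a_yy = 0.67, c_yy = -0.10, e_yy = 0.46,
    a_yx_mod = 0.00, c_yx_mod = 0.01, e_yx_mod = 0.00,
    a_yy_mod = -0.01, c_yy_mod = 0.00, e_yy_mod = -0.01)
  means <- .default_means()
  means$immediate$mu_y <- 2.47
  means$delayed$mu_y <- 2.90
  sim_config(paths = paths, means = means, ...)
}

# Correlated pair factor: sqrt(r) * shared + sqrt(1 - r) * unique, so MZ
# and DZ differ only through r.
.pair_factor <- function(n, r) {
  shared <- stats::rnorm(n)
  list(t1 = sqrt(r) * shared + sqrt(1 - r) * stats::rnorm(n),
       t2 = sqrt(r) * shared + sqrt(1 - r) * stats::rnorm(n))
}

#' Simulate a twin-pair table from a generating configuration
#'
#' Draws pairwise A factors with correlation `r`, shared C and independent
#' E factors (all unit variance) for both the performance and the
#' attainment-unique Cholesky factors, assigns each twin a tracking status
#' (generatively missing with `p_track_missing`, otherwise by the
#' selection model applied to a provisional performance realisation), and
#' builds phenotypes from the status-specific moderated paths evaluated at
#' the twin's own centered performance. Item missingness is applied last.
#'
#' The returned table's centering attribute holds the generating constants,
#' so fitted parameters are directly comparable to the configuration.
#'
#' @param config A [sim_config()].
#' @return A `pair_table`.
#' @export
simulate_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_mz + config$n_dz
  if (n == 0) stop("config requests zero pairs")
  zyg <- rep(c("MZ", "DZ"), c(config$n_mz, config$n_dz))
  r <- .relatedness(zyg)

  Ax <- .pair_factor(n, r); Ay <- .pair_factor(n, r)
  Cx <- stats::rnorm(n); Cy <- stats::rnorm(n)
  Ex <- list(t1 = stats::rnorm(n), t2 = stats::rnorm(n))
  Ey <- list(t1 = stats::rnorm(n), t2 = stats::rnorm(n))

  male1 <- stats::rbinom(n, 1, config$p_male)
  male2 <- ifelse(zyg == "MZ", male1, stats::rbinom(n, 1, config$p_male))
  yob <- sample(config$birth_years, n, replace = TRUE)
  yob_ref <- mean(config$birth_years)
  yob_c <- yob - yob_ref

  # provisional performance from the reference (tracking-missing) set,
  # used only to let tracking selection depend on performance
  pref <- .as_pathvec(config$paths$missing)
  prov <- function(A, E) pref[["a_xx"]] * A + pref[["c_xx"]] * Cx +
    pref[["e_xx"]] * E
  xprov <- list(t1 = prov(Ax$t1, Ex$t1), t2 = prov(Ax$t2, Ex$t2))

  sel <- config$selection
  threshold_model <- any(c("sd_pair", "sd_genetic", "sd_twin") %in%
                           names(sel))
  delayed12 <- if (!is.null(sel$p_delayed)) {
    list(stats::runif(n) < sel$p_delayed, stats::runif(n) < sel$p_delayed)
  } else if (threshold_model) {
    u <- stats::rnorm(n, 0, sel$sd_pair %||% 0)
    Gsel <- .pair_factor(n, r)
    lin <- function(xp, g) sel$intercept + sel$slope * xp +
      u + (sel$sd_genetic %||% 0) * g +
      stats::rnorm(n, 0, sel$sd_twin %||% 0)
    list(lin(xprov$t1, Gsel$t1) > 0, lin(xprov$t2, Gsel$t2) > 0)
  } else {
    p <- function(xp) stats::plogis(sel$intercept + sel$slope * xp)
    list(stats::runif(n) < p(xprov$t1), stats::runif(n) < p(xprov$t2))
  }
  draw_status <- function(delayed) {
    ifelse(stats::runif(n) < config$p_track_missing, "missing",
           ifelse(delayed, "delayed", "immediate"))
  }
  st1 <- draw_status(delayed12[[1]])
  st2 <- draw_status(delayed12[[2]])

  pm <- do.call(rbind, lapply(config$paths[.statuses], .as_pathvec))
  mu_x <- vapply(config$means[.statuses], function(m) m$mu_x, numeric(1))
  mu_y <- vapply(config$means[.statuses], function(m) m$mu_y, numeric(1))
  b <- function(nm) if (is.null(config$betas[[nm]])) 0 else config$betas[[nm]]

  build_twin <- function(st, male, A_x, E_x, A_y, E_y) {
    s <- match(st, .statuses)
    x <- mu_x[s] + b("beta_male_x") * male + b("beta_yob_x") * yob_c +
      pm[s, "a_xx"] * A_x + pm[s, "c_xx"] * Cx + pm[s, "e_xx"] * E_x
    X <- x  # twin's own centered performance moderates its own y-paths
    eff <- function(role) pm[s, role] + pm[s, paste0(role, "_mod")] * X
    y <- mu_y[s] + b("beta_male_y") * male + b("beta_yob_y") * yob_c +
      eff("a_yx") * A_x + eff("c_yx") * Cx + eff("e_yx") * E_x +
      eff("a_yy") * A_y + eff("c_yy") * Cy + eff("e_yy") * E_y
    list(x = x, y = y)
  }
  t1 <- build_twin(st1, male1, Ax$t1, Ex$t1, Ay$t1, Ey$t1)
  t2 <- build_twin(st2, male2, Ax$t2, Ex$t2, Ay$t2, Ey$t2)

  df <- data.frame(
    pair_id = sprintf("P%05d", seq_len(n)), zygosity = zyg,
    attainment_1 = t1$y, attainment_2 = t2$y,
    performance_1 = config$performance_mean + t1$x,
    performance_2 = config$performance_mean + t2$x,
    tracking_1 = ifelse(st1 == "missing", NA_character_, st1),
    tracking_2 = ifelse(st2 == "missing", NA_character_, st2),
    male_1 = male1, male_2 = male2,
    birth_year_1 = yob, birth_year_2 = yob,
    stringsAsFactors = FALSE)
  tab <- as_pair_table(df, centering = list(
    performance_mean = config$performance_mean,
    birth_year_mean = yob_ref))
  if (length(config$missing_rates))
    tab <- impose_missingness(tab, config$missing_rates,
                              seed = config$seed + 1L)
  tab
}

#' Assign tracking status from performance through a logistic model
#'
#' Sets each twin's tracking status independently with
#' `P(delayed | X) = plogis(intercept + slope * X)`, `X` the twin's
#' centered performance. With `slope = 0` status is independent of
#' performance. Twins with missing performance keep their current status.
#'
#' @param pairs A pair table.
#' @param intercept,slope Logistic coefficients.
#' @param seed RNG seed.
#' @return The pair table with `tracking_1/_2` (and the group label)
#'   refreshed.
#' @export
assign_tracking_by_performance <- function(pairs, intercept, slope,
                                           seed = 1) {
  set.seed(seed)
  ctr <- attr(pairs, "centering")
  for (i in 1:2) {
    xc <- pairs[[paste0("performance_c_", i)]]
    ok <- !is.na(xc)
    p <- stats::plogis(intercept + slope * xc[ok])
    status <- ifelse(stats::runif(sum(ok)) < p, "delayed", "immediate")
    pairs[[paste0("tracking_", i)]][ok] <- status
  }
  as_pair_table(as.data.frame(pairs), centering = ctr)
}

#' Blank fields at given per-twin rates
#'
#' Each listed field is set to missing independently per twin with its
#' rate. Twins losing `performance` lose their moderator and are excluded
#' as individuals by the analysis while the co-twin is retained; blanked
#' `tracking` sends the twin to the tracking-missing parameter set.
#'
#' @param pairs A pair table.
#' @param rates Named list/vector with rates in `[0, 1]` for any of
#'   `attainment`, `performance`, `tracking`.
#' @param seed RNG seed.
#' @return The pair table with missingness applied and derived columns
#'   recomputed (centering constants kept).
#' @export
impose_missingness <- function(pairs, rates, seed = 1) {
  rates <- as.list(rates)
  bad <- vapply(rates, function(r) r < 0 || r > 1, logical(1))
  if (any(bad)) stop("missingness rates must lie in [0, 1]")
  set.seed(seed)
  ctr <- attr(pairs, "centering")
  df <- as.data.frame(pairs)
  for (field in names(rates)) {
    if (!field %in% c("attainment", "performance", "tracking"))
      stop("unknown field in missingness rates: ", field)
    for (i in 1:2) {
      col <- paste0(field, "_", i)
      hit <- stats::runif(nrow(df)) < rates[[field]]
      df[[col]][hit] <- if (is.character(df[[col]])) NA_character_ else NA_real_
    }
  }
  as_pair_table(df, centering = ctr)
}
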