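# Full-information maximum-likelihood estimation of multigroup moderated
# Cholesky ACE models, plus model comparison and delta-method intervals.

.status_index <- function(tracking) {
  i <- match(tracking, .statuses)
  i[is.na(i)] <- 3L
  i
}

# Assemble per-pair arrays for the likelihood kernel. Twins with a missing
# moderator (performance) are excluded as individuals: neither their
# performance nor their attainment contributes, but the co-twin is kept.
.prepare_fit_data <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  n <- nrow(pairs)
  x1 <- pairs$performance_c_1; x2 <- pairs$performance_c_2
  y1 <- pairs$attainment_1;    y2 <- pairs$attainment_2
  ox1 <- !is.na(x1); ox2 <- !is.na(x2)
  obs <- cbind(ox1, !is.na(y1) & ox1, ox2, !is.na(y2) & ox2)
  Y <- cbind(ifelse(obs[, 1], x1, 0), ifelse(obs[, 2], y1, 0),
             ifelse(obs[, 3], x2, 0), ifelse(obs[, 4], y2, 0))
  keep <- rowSums(obs) > 0
  zero_na <- function(v) ifelse(is.na(v), 0, v)
  dat <- list(Y = Y[keep, , drop = FALSE],
              obs = obs[keep, , drop = FALSE],
              r = .relatedness(pairs$zygosity)[keep],
              s1 = .status_index(pairs$tracking_1)[keep],
              s2 = .status_index(pairs$tracking_2)[keep],
              X1 = zero_na(x1)[keep], X2 = zero_na(x2)[keep],
              male1 = zero_na(pairs$male_1)[keep],
              male2 = zero_na(pairs$male_2)[keep],
              yob1 = zero_na(pairs$birth_year_c_1)[keep],
              yob2 = zero_na(pairs$birth_year_c_2)[keep])
  dat$n_pairs <- sum(keep)
  dat$n_records <- sum(obs[keep, ])
  if (dat$n_pairs == 0)
    stop("no pair contributes any observed value; analysis sample is empty")
  dat$group_n <- table(assign_pair_group(pairs$zygosity[keep],
                                         pairs$tracking_1[keep],
                                         pairs$tracking_2[keep]))
  dat
}

# Model-implied mean matrix (n x 4) for prepared data.
.mean_matrix <- function(ex, dat) {
  mu_x1 <- ex$mu[dat$s1, "mu_x"] + ex$beta[1] * dat$male1 +
    ex$beta[3] * dat$yob1
  mu_y1 <- ex$mu[dat$s1, "mu_y"] + ex$beta[2] * dat$male1 +
    ex$beta[4] * dat$yob1 + ex$bmod[dat$s1] * dat$X1
  mu_x2 <- ex$mu[dat$s2, "mu_x"] + ex$beta[1] * dat$male2 +
    ex$beta[3] * dat$yob2
  mu_y2 <- ex$mu[dat$s2, "mu_y"] + ex$beta[2] * dat$male2 +
    ex$beta[4] * dat$yob2 + ex$bmod[dat$s2] * dat$X2
  cbind(mu_x1, mu_y1, mu_x2, mu_y2)
}

.neg2ll_prepared <- function(theta, spec, dat, details = FALSE) {
  ex <- .expand_params(theta, spec)
  out <- .fiml_neg2ll_cpp(dat$Y, dat$obs, dat$r, dat$s1, dat$s2,
                          dat$X1, dat$X2, ex$paths, .mean_matrix(ex, dat))
  if (details) list(neg2ll = out[1], n_singular = out[2]) else out[1]
}

#' FIML -2 log-likelihood of a multigroup moderated ACE model
#'
#' Sums, over pairs, `k*log(2*pi) + log|S_obs| + (z-m)' S_obs^-1 (z-m)`
#' where `S_obs`/`m_obs` are the observed-variable submatrices of the
#' model-implied pair covariance and mean, evaluated with each twin's own
#' tracking status and moderator value. Pairs whose implied covariance is
#' numerically singular contribute a large finite penalty (with a warning)
#' instead of crashing the optimizer.
#'
#' @param params Free-parameter vector in the order of
#'   `spec$param_names`.
#' @param spec An [ace_model_spec()].
#' @param pairs A pair table (see [read_pair_table()]).
#' @return The scalar -2 log-likelihood.
#' @export
neg2_loglik <- function(params, spec, pairs) {
  dat <- .prepare_fit_data(pairs)
  res <- .neg2ll_prepared(params, spec, dat, details = TRUE)
  if (res$n_singular > 0)
    warning(res$n_singular,
            " pair(s) had a singular implied covariance; penalized")
  res$neg2ll
}

# Double-entry twin correlation of one variable over complete pairs.
.double_entry_cor <- function(v1, v2) {
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 2) return(NA_real_)
  stats::cor(c(v1[ok], v2[ok]), c(v2[ok], v1[ok]))
}

# Falconer-style method-of-moments starting values. Twin-level ACE shares
# from double-entry MZ/DZ correlations (clipped away from the boundary),
# a common/unique split of the attainment paths from the x-y regression
# slope, and per-status variance scaling.
.falconer_start <- function(spec, pairs, dat) {
  mz <- pairs$zygosity == "MZ"
  shares <- function(v1, v2) {
    rmz <- .double_entry_cor(v1[mz], v2[mz])
    rdz <- .double_entry_cor(v1[!mz], v2[!mz])
    if (is.na(rmz) || is.na(rdz)) { rmz <- 0.7; rdz <- 0.45 }
    a2 <- min(max(2 * (rmz - rdz), 0.15), 0.85)
    c2 <- min(max(2 * rdz - rmz, 0.05), 0.9 - a2)
    c(a2 = a2, c2 = c2, e2 = max(1 - a2 - c2, 0.05))
  }
  sx <- shares(pairs$performance_c_1, pairs$performance_c_2)
  sy <- shares(pairs$attainment_1, pairs$attainment_2)
  xs <- c(pairs$performance_c_1, pairs$performance_c_2)
  ys <- c(pairs$attainment_1, pairs$attainment_2)
  st <- c(.status_index(pairs$tracking_1), .status_index(pairs$tracking_2))
  okxy <- !is.na(xs) & !is.na(ys)
  b <- if (sum(okxy) > 2)
    stats::cov(xs[okxy], ys[okxy]) / stats::var(xs[okxy]) else 0.02
  vx_all <- stats::var(xs, na.rm = TRUE)
  vy_all <- stats::var(ys, na.rm = TRUE)
  w <- min(max(b^2 * vx_all / vy_all, 0.1), 0.9)  # common share of Vy

  theta <- numeric(n_free_parameters(spec))
  for (s in seq_along(.statuses)) {
    in_s <- st == s
    vx <- stats::var(xs[in_s], na.rm = TRUE)
    vy <- stats::var(ys[in_s], na.rm = TRUE)
    if (!is.finite(vx) || sum(in_s & !is.na(xs)) < 20) vx <- vx_all
    if (!is.finite(vy) || sum(in_s & !is.na(ys)) < 20) vy <- vy_all
    put <- function(role, value) {
      i <- spec$idx[s, role]
      if (i > 0L) theta[i] <<- value
    }
    put("a_xx", sqrt(sx["a2"] * vx))
    put("c_xx", sqrt(sx["c2"] * vx))
    put("e_xx", sqrt(sx["e2"] * vx))
    put("a_yx", sign(b) * sqrt(sy["a2"] * vy * w))
    put("c_yx", sign(b) * sqrt(sy["c2"] * vy * w))
    put("e_yx", sign(b) * sqrt(sy["e2"] * vy * w))
    put("a_yy", sqrt(sy["a2"] * vy * (1 - w)))
    put("c_yy", sqrt(sy["c2"] * vy * (1 - w)))
    put("e_yy", sqrt(sy["e2"] * vy * (1 - w)))
    put("mu_x", mean(xs[in_s], na.rm = TRUE))
    put("mu_y", mean(ys[in_s], na.rm = TRUE))
    if (spec$idx[s, "mu_x"] > 0L && !is.finite(theta[spec$idx[s, "mu_x"]]))
      theta[spec$idx[s, "mu_x"]] <- 0
    if (spec$idx[s, "mu_y"] > 0L && !is.finite(theta[spec$idx[s, "mu_y"]]))
      theta[spec$idx[s, "mu_y"]] <- mean(ys, na.rm = TRUE)
  }
  names(theta) <- spec$param_names
  theta
}

# Flip latent-factor signs towards the canonical orientation (a_xx, c_xx,
# e_xx, a_yy >= 0), carrying each factor's other loadings and moderation
# slopes along. A- and C-family loadings enter cross-twin products between
# different status sets (the latent factors are shared), so their flips
# must be applied to all status sets at once, anchored on the immediate
# set; E-family loadings have no cross-twin terms and can be oriented per
# status. All flips leave the likelihood unchanged.
.canonicalize_signs <- function(theta, spec) {
  flip <- function(idx_vec) {
    js <- unique(idx_vec[idx_vec > 0L])
    theta[js] <<- -theta[js]
  }
  global_families <- list(a_xx = c("a_xx", "a_yx", "a_yx_mod"),
                          c_xx = c("c_xx", "c_yx", "c_yx_mod"),
                          a_yy = c("a_yy", "a_yy_mod"))
  for (lead in names(global_families)) {
    i <- spec$idx["immediate", lead]
    if (i > 0L && theta[i] < 0)
      flip(spec$idx[, global_families[[lead]]])
  }
  per_status <- list(e_xx = c("e_xx", "e_yx", "e_yx_mod"),
                     e_yy = c("e_yy", "e_yy_mod"))
  for (s in seq_along(.statuses)) {
    for (lead in names(per_status)) {
      i <- spec$idx[s, lead]
      if (i > 0L && theta[i] < 0)
        flip(spec$idx[s, per_status[[lead]]])
    }
  }
  theta
}

# Central-difference Hessian of f at theta; step per the package's
# numerical-SE convention.
.num_hessian <- function(f, theta, h_rel = 1e-4) {
  p <- length(theta)
  h <- h_rel * pmax(1, abs(theta))
  H <- matrix(NA_real_, p, p)
  f0 <- f(theta)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
           f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

.num_gradient <- function(f, theta, h_rel = 1e-6) {
  h <- h_rel * pmax(1, abs(theta))
  vapply(seq_along(theta), function(i) {
    ei <- replace(numeric(length(theta)), i, h[i])
    (f(theta + ei) - f(theta - ei)) / (2 * h[i])
  }, numeric(1))
}

#' Fit a multigroup moderated Cholesky ACE model by FIML
#'
#' Minimizes the FIML -2 log-likelihood by quasi-Newton iteration
#' ([stats::nlminb()]) from a Falconer-style method-of-moments start plus
#' `n_restarts - 1` jittered restarts; the best converged optimum is kept.
#' Standard errors come from the inverse of a central-difference Hessian at
#' the optimum, and reported paths are sign-canonicalized (a_xx, c_xx,
#' e_xx, a_yy >= 0 per status set).
#'
#' @param pairs A pair table.
#' @param model Model label passed to [ace_model_spec()], or an
#'   `ace_model_spec` object.
#' @param covariates,moderator_mean Passed to [ace_model_spec()] when
#'   `model` is a label.
#' @param starts Optional numeric start vector (or matrix with one start
#'   per row) overriding the method-of-moments start.
#' @param n_restarts Total number of starts (first is unjittered).
#' @param seed Seed for the jitter; all randomness in the fit derives from
#'   it.
#' @param se Compute standard errors (can be skipped for speed in
#'   simulation studies)?
#' @param control Passed to [stats::nlminb()] (defaults: `iter.max = 2000`,
#'   `eval.max = 8000`).
#' @return Object of class `"ace_fit"` with estimates, standard errors,
#'   `-2LL`, free-parameter count, observed-record count, convergence
#'   diagnostics and the spec. Supports `print`, `summary`, `coef`, `vcov`,
#'   `logLik`, `AIC`, `anova`, `confint` and `simulate`.
#' @export
ace_fit <- function(pairs, model = "1a", covariates = TRUE,
                    moderator_mean = FALSE, starts = NULL, n_restarts = 5,
                    seed = 1, se = TRUE, control = list()) {
  spec <- if (inherits(model, "ace_model_spec")) model
          else ace_model_spec(model, covariates = covariates,
                              moderator_mean = moderator_mean)
  dat <- .prepare_fit_data(pairs)
  obj <- function(theta) .neg2ll_prepared(theta, spec, dat)

  base_start <- if (is.null(starts)) .falconer_start(spec, pairs, dat)
                else starts
  start_mat <- if (is.matrix(base_start)) base_start
               else matrix(base_start, nrow = 1)
  if (ncol(start_mat) != n_free_parameters(spec))
    stop("start vector length does not match the spec")

  ctrl <- utils::modifyList(list(iter.max = 2000, eval.max = 8000), control)
  set.seed(seed)
  fits <- list()
  for (k in seq_len(max(n_restarts, nrow(start_mat)))) {
    th0 <- start_mat[1 + (k - 1) %% nrow(start_mat), ]
    if (k > nrow(start_mat))
      th0 <- th0 * (1 + 0.15 * stats::rnorm(length(th0))) +
        0.02 * stats::rnorm(length(th0))
    res <- tryCatch(
      stats::nlminb(th0, obj, control = ctrl,
                    scale = 1 / pmax(abs(th0), 0.05)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$objective)) fits[[length(fits) + 1]] <- res
  }
  if (!length(fits))
    stop("all optimizer starts failed; check the data and spec")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]

  theta <- .canonicalize_signs(best$par, spec)
  names(theta) <- spec$param_names
  n2ll <- obj(theta)
  grad <- .num_gradient(obj, theta)
  sing <- .neg2ll_prepared(theta, spec, dat, details = TRUE)$n_singular

  V <- NULL; se_vec <- rep(NA_real_, length(theta))
  if (se) {
    H <- .num_hessian(obj, theta)
    V <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se_vec <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
      dimnames(V) <- list(spec$param_names, spec$param_names)
    } else {
      warning("Hessian not invertible; standard errors unavailable")
    }
  }
  names(se_vec) <- spec$param_names

  structure(list(coefficients = theta, se = se_vec, vcov = V,
                 neg2ll = n2ll, npar = n_free_parameters(spec),
                 n_records = dat$n_records, n_pairs = dat$n_pairs,
                 group_n = dat$group_n, spec = spec,
                 convergence = best$convergence, message = best$message,
                 grad_norm = max(abs(grad)), n_singular = sing,
                 n_starts = length(fits), seed = seed,
                 x_range = range(c(dat$X1[dat$obs[, 1]],
                                   dat$X2[dat$obs[, 3]])),
                 moderator_mean = spec$moderator_mean,
                 centering = attr(pairs, "centering"),
                 call = match.call()),
            class = "ace_fit")
}

#' Map a fitted model's estimates onto another specification's start vector
#'
#' Builds a starting vector for `spec` from the estimates of a (typically
#' nested) fitted model: parameters shared by name are copied, per-status
#' parameters fall back to the fitted shared (`.all`) value, and anything
#' else starts at 0. Warm-starting the wider model from the nested optimum
#' speeds up nested model sequences considerably.
#'
#' @param fit A fitted [ace_fit()].
#' @param spec Target [ace_model_spec()].
#' @return Named numeric start vector for `spec`.
#' @export
warm_start <- function(fit, spec) {
  from <- coef(fit)
  vapply(spec$param_names, function(nm) {
    if (nm %in% names(from)) return(from[[nm]])
    shared <- sub("\\.(immediate|delayed|missing)$", ".all", nm)
    if (shared %in% names(from)) from[[shared]] else 0
  }, numeric(1))
}

#' @export
coef.ace_fit <- function(object, ...) object$coefficients

#' @export
vcov.ace_fit <- function(object, ...) object$vcov

#' @export
logLik.ace_fit <- function(object, ...) {
  structure(-object$neg2ll / 2, df = object$npar,
            nobs = object$n_records, class = "logLik")
}

#' @export
print.ace_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Moderated Cholesky ACE fit (model %s), %d pairs, %d observed records\n",
              x$spec$model, x$n_pairs, x$n_records))
  cat(sprintf("-2 log-likelihood: %.1f  free parameters: %d\n",
              x$neg2ll, x$npar))
  a <- aic_conventions(x)
  cat(sprintf("AIC: %.1f (standard)  %.1f (Mx convention)\n",
              a[["standard"]], a[["mx"]]))
  cat(sprintf("convergence code %d, max |gradient| %.2e, %d start(s)\n",
              x$convergence, x$grad_norm, x$n_starts))
  invisible(x)
}

#' @export
summary.ace_fit <- function(object, ...) {
  out <- list(fit = object, table = decomposition_table(object))
  class(out) <- "summary.ace_fit"
  out
}

#' @export
print.summary.ace_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Both AIC conventions for a fitted model
#'
#' `standard` is `-2LL + 2k`. `mx` is the Mx/SEM convention
#' `-2LL - 2*(records - k)`, where `records` is the number of observed data
#' values (each twin's non-missing phenotypes) — the convention under which
#' published twin-model AICs are often far below the -2LL.
#'
#' @param fit An [ace_fit()] object (or a list with `neg2ll`, `npar`,
#'   `n_records`).
#' @return Named numeric vector `c(standard = , mx = )`.
#' @export
aic_conventions <- function(fit) {
  c(standard = fit$neg2ll + 2 * fit$npar,
    mx = fit$neg2ll - 2 * (fit$n_records - fit$npar))
}

#' Likelihood-ratio test between nested FIML fits
#'
#' @param nested,full Either [ace_fit()] objects or bare -2 log-likelihood
#'   values (then `df` must be given).
#' @param df Degrees of freedom; defaults to the difference in
#'   free-parameter counts when fits are supplied.
#' @return Object of class `"ace_lrt"`: statistic, df, p-value, model
#'   labels.
#' @examples
#' likelihood_ratio_test(73003.2, 72691.1, df = 22)  # statistic 312.1
#' @export
likelihood_ratio_test <- function(nested, full, df = NULL) {
  get_n2ll <- function(f) if (inherits(f, "ace_fit")) f$neg2ll else as.numeric(f)
  stat <- get_n2ll(nested) - get_n2ll(full)
  if (is.null(df)) {
    if (!inherits(nested, "ace_fit") || !inherits(full, "ace_fit"))
      stop("df must be given when fits are supplied as bare -2LL values")
    df <- full$npar - nested$npar
  }
  if (df <= 0) stop("full model must have more free parameters than nested")
  if (stat < -1e-3)
    warning("negative LRT statistic (", format(stat),
            "); the full model may not have converged - consider refitting")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 nested = if (inherits(nested, "ace_fit"))
                   nested$spec$model else "nested",
                 full = if (inherits(full, "ace_fit"))
                   full$spec$model else "full"),
            class = "ace_lrt")
}

#' @export
print.ace_lrt <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: Chi2(%d) = %.1f, p = %.3g\n",
              x$nested, x$full, x$df, x$statistic, x$p.value))
  invisible(x)
}

#' @export
anova.ace_fit <- function(object, ...) {
  others <- list(...)
  others <- others[vapply(others, inherits, logical(1), "ace_fit")]
  if (!length(others)) stop("supply a second ace_fit to compare")
  fits <- c(list(object), others)
  ord <- order(vapply(fits, `[[`, numeric(1), "npar"))
  fits <- fits[ord]
  rows <- lapply(seq_along(fits)[-1], function(i)
    likelihood_ratio_test(fits[[i - 1]], fits[[i]]))
  tab <- data.frame(
    npar = vapply(fits, `[[`, numeric(1), "npar"),
    neg2LL = vapply(fits, `[[`, numeric(1), "neg2ll"),
    Chisq = c(NA, vapply(rows, `[[`, numeric(1), "statistic")),
    df = c(NA, vapply(rows, `[[`, numeric(1), "df")),
    p.value = c(NA, vapply(rows, `[[`, numeric(1), "p.value")),
    row.names = make.unique(paste("model",
                                  vapply(fits, function(f) f$spec$model,
                                         character(1)))))
  class(tab) <- c("anova", "data.frame")
  tab
}

#' Delta-method confidence interval for a parameter transform
#'
#' Gradient-based interval for a smooth scalar function of the free
#' parameters (standardized variance components, variance sums, ...).
#'
#' @param fit A converged [ace_fit()] with standard errors.
#' @param transform Function mapping the free-parameter vector to a scalar.
#' @param level Confidence level.
#' @return Named vector `c(estimate, se, lower, upper)`.
#' @export
delta_ci <- function(fit, transform, level = 0.95) {
  if (is.null(fit$vcov))
    stop("fit has no covariance matrix; interval unavailable")
  th <- coef(fit)
  est <- unname(transform(th))
  g <- .num_gradient(function(t) transform(t), th)
  v <- drop(t(g) %*% fit$vcov %*% g)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(estimate = est, se = se, lower = est - z * se, upper = est + z * se)
}

#' Simulate new pair tables from a fitted model
#'
#' Uses the fitted path sets, intercepts and covariate slopes as generating
#' values; tracking statuses, zygosity, covariates and missingness pattern
#' are resampled from their empirical configuration sizes.
#'
#' @param object An [ace_fit()].
#' @param nsim Number of tables.
#' @param seed RNG seed.
#' @param n_mz,n_dz Pair counts (defaults: the fitted group sizes).
#' @param ... Unused.
#' @return A pair table, or a list of them when `nsim > 1`.
#' @export
simulate.ace_fit <- function(object, nsim = 1, seed = NULL,
                             n_mz = NULL, n_dz = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ex <- .expand_params(coef(object), object$spec)
  grp <- object$group_n
  if (is.null(n_mz)) n_mz <- sum(grp[grepl("^MZ", names(grp))])
  if (is.null(n_dz)) n_dz <- sum(grp[grepl("^DZ", names(grp))])
  mk <- function() {
    cfg <- sim_config(n_mz = n_mz, n_dz = n_dz,
                      paths = list(
                        immediate = .paths_for_status(ex, "immediate"),
                        delayed = .paths_for_status(ex, "delayed"),
                        missing = .paths_for_status(ex, "missing")),
                      means = list(
                        immediate = as.list(ex$mu["immediate", ]),
                        delayed = as.list(ex$mu["delayed", ]),
                        missing = as.list(ex$mu["missing", ])),
                      betas = stats::setNames(as.list(ex$beta), .beta_roles),
                      seed = sample.int(2^31 - 2, 1))
    simulate_pairs(cfg)
  }
  if (nsim == 1) mk() else replicate(nsim, mk(), simplify = FALSE)
}
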