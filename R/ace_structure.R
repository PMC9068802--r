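#' @useDynLib trackace, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Role names for a bivariate Cholesky path set with attainment-path moderation.
# x = performance (first Cholesky variable), y = attainment (second).
# "_mod" entries are the linear moderation slopes on the six attainment paths;
# the x-paths carry no moderation by construction.
.path_roles <- c("a_xx", "c_xx", "e_xx",
                 "a_yx", "c_yx", "e_yx",
                 "a_yy", "c_yy", "e_yy",
                 "a_yx_mod", "c_yx_mod", "e_yx_mod",
                 "a_yy_mod", "c_yy_mod", "e_yy_mod")

#' Construct a moderated bivariate Cholesky path set
#'
#' Bundles the nine path coefficients of a bivariate Cholesky ACE model
#' (three for performance, three "common" paths from the performance factors
#' to attainment, three "unique" attainment paths) together with the six
#' moderation slopes by which the attainment paths may depend linearly on
#' the twin's own (centered) performance. Slopes default to zero, i.e. an
#' unmoderated model.
#'
#' @param a_xx,c_xx,e_xx Performance paths (A, C, E).
#' @param a_yx,c_yx,e_yx Attainment paths common with performance.
#' @param a_yy,c_yy,e_yy Attainment paths unique to attainment.
#' @param a_yx_mod,c_yx_mod,e_yx_mod,a_yy_mod,c_yy_mod,e_yy_mod Moderation
#'   slopes (per unit of centered performance) on the corresponding paths.
#' @return A named numeric vector of class `"moderated_paths"` with 15
#'   elements in canonical role order.
#' @examples
#' p <- moderated_paths(a_xx = 7.08, c_xx = 2.74, e_xx = 3.69,
#'                      a_yx = 0.65, c_yx = 0.53, e_yx = 0.20,
#'                      a_yy = 0.56, c_yy = 0.00, e_yy = 0.45)
#' variance_components(p)
#' @export
moderated_paths <- function(a_xx = 0, c_xx = 0, e_xx = 0,
                            a_yx = 0, c_yx = 0, e_yx = 0,
                            a_yy = 0, c_yy = 0, e_yy = 0,
                            a_yx_mod = 0, c_yx_mod = 0, e_yx_mod = 0,
                            a_yy_mod = 0, c_yy_mod = 0, e_yy_mod = 0) {
  p <- c(a_xx = a_xx, c_xx = c_xx, e_xx = e_xx,
         a_yx = a_yx, c_yx = c_yx, e_yx = e_yx,
         a_yy = a_yy, c_yy = c_yy, e_yy = e_yy,
         a_yx_mod = a_yx_mod, c_yx_mod = c_yx_mod, e_yx_mod = e_yx_mod,
         a_yy_mod = a_yy_mod, c_yy_mod = c_yy_mod, e_yy_mod = e_yy_mod)
  if (!all(is.finite(p))) stop("path coefficients must be finite")
  class(p) <- "moderated_paths"
  p
}

.as_pathvec <- function(paths) {
  p <- unclass(paths)
  missing_roles <- setdiff(.path_roles, names(p))
  if (length(missing_roles))
    stop("path set lacks roles: ", paste(missing_roles, collapse = ", "))
  p[.path_roles]
}

#' Evaluate a moderated path coefficient
#'
#' The effective path is `base + slope * X`, where `X` is the twin's own
#' centered moderator value (here: centered performance).
#'
#' @param base Baseline path coefficient.
#' @param slope Moderation slope.
#' @param X Centered moderator value(s); vectorized.
#' @return `base + slope * X`.
#' @examples
#' moderated_path(0.67, -0.01, 0)   # 0.67
#' moderated_path(0.67, -0.01, 10)  # 0.57
#' @export
moderated_path <- function(base, slope, X) {
  stopifnot(is.finite(base), is.finite(slope), all(is.finite(X)))
  base + slope * X
}

# Effective six attainment paths at moderator value X, as a named vector.
.effective_y_paths <- function(p, X) {
  c(a_yx = p[["a_yx"]] + p[["a_yx_mod"]] * X,
    c_yx = p[["c_yx"]] + p[["c_yx_mod"]] * X,
    e_yx = p[["e_yx"]] + p[["e_yx_mod"]] * X,
    a_yy = p[["a_yy"]] + p[["a_yy_mod"]] * X,
    c_yy = p[["c_yy"]] + p[["c_yy_mod"]] * X,
    e_yy = p[["e_yy"]] + p[["e_yy_mod"]] * X)
}

#' Model-implied covariance of a twin pair
#'
#' Builds the 4x4 model-implied covariance matrix over
#' `(x1, y1, x2, y2)` — performance and attainment of twin 1 and twin 2 —
#' for a pair with additive-genetic relatedness `r` (1 for MZ, 0.5 for DZ).
#' Each twin may have its own path set (e.g. in tracking-discordant pairs)
#' and its own moderator value; the attainment paths are evaluated at the
#' twin's own centered performance (definition-variable convention), and
#' cross-twin covariances multiply the twin-specific effective paths.
#'
#' A-factor cross-products are weighted by `r`, C-factors are fully shared,
#' and E contributes no cross-twin terms. In the univariate specialisation
#' (all y-paths zero) the performance block reduces to the classical
#' `Cov_MZ = a^2 + c^2`, `Cov_DZ = 0.5 a^2 + c^2`.
#'
#' @param paths1,paths2 [moderated_paths()] sets for twin 1 and twin 2.
#' @param r Genetic relatedness; must be 1 (MZ) or 0.5 (DZ).
#' @param X1,X2 Centered moderator values for twin 1 and twin 2.
#' @return Symmetric positive semidefinite 4x4 matrix with dimnames
#'   `c("x1","y1","x2","y2")`.
#' @export
pair_covariance <- function(paths1, paths2 = paths1, r, X1 = 0, X2 = 0) {
  if (!isTRUE(r %in% c(1, 0.5)))
    stop("relatedness r must be 1 (MZ) or 0.5 (DZ)")
  p1 <- .as_pathvec(paths1)
  p2 <- .as_pathvec(paths2)
  y1 <- .effective_y_paths(p1, X1)
  y2 <- .effective_y_paths(p2, X2)

  S <- matrix(0, 4, 4, dimnames = list(c("x1", "y1", "x2", "y2"),
                                       c("x1", "y1", "x2", "y2")))
  S["x1", "x1"] <- p1[["a_xx"]]^2 + p1[["c_xx"]]^2 + p1[["e_xx"]]^2
  S["x2", "x2"] <- p2[["a_xx"]]^2 + p2[["c_xx"]]^2 + p2[["e_xx"]]^2
  S["y1", "y1"] <- sum(y1^2)
  S["y2", "y2"] <- sum(y2^2)
  S["x1", "y1"] <- S["y1", "x1"] <-
    p1[["a_xx"]] * y1[["a_yx"]] + p1[["c_xx"]] * y1[["c_yx"]] +
    p1[["e_xx"]] * y1[["e_yx"]]
  S["x2", "y2"] <- S["y2", "x2"] <-
    p2[["a_xx"]] * y2[["a_yx"]] + p2[["c_xx"]] * y2[["c_yx"]] +
    p2[["e_xx"]] * y2[["e_yx"]]
  S["x1", "x2"] <- S["x2", "x1"] <-
    r * p1[["a_xx"]] * p2[["a_xx"]] + p1[["c_xx"]] * p2[["c_xx"]]
  S["x1", "y2"] <- S["y2", "x1"] <-
    r * p1[["a_xx"]] * y2[["a_yx"]] + p1[["c_xx"]] * y2[["c_yx"]]
  S["y1", "x2"] <- S["x2", "y1"] <-
    r * y1[["a_yx"]] * p2[["a_xx"]] + y1[["c_yx"]] * p2[["c_xx"]]
  S["y1", "y2"] <- S["y2", "y1"] <-
    r * (y1[["a_yx"]] * y2[["a_yx"]] + y1[["a_yy"]] * y2[["a_yy"]]) +
    (y1[["c_yx"]] * y2[["c_yx"]] + y1[["c_yy"]] * y2[["c_yy"]])
  S
}

#' Model-implied mean vector of a twin pair
#'
#' Linear means: per-variable intercept plus fixed effects of the twin's
#' covariates (male dummy and centered birth year).
#'
#' @param means Named list/vector with `mu_x`, `mu_y` and slopes
#'   `beta_male_x`, `beta_male_y`, `beta_yob_x`, `beta_yob_y` (absent slopes
#'   are taken as 0). `mu_x`/`mu_y` may be length-2 vectors to give the two
#'   twins different intercepts (e.g. tracking-discordant pairs).
#' @param male1,male2 Male dummies (0/1) for twin 1 and 2.
#' @param yob1,yob2 Centered birth years.
#' @return Length-4 named vector over `(x1, y1, x2, y2)`.
#' @export
mean_vector <- function(means, male1 = 0, male2 = 0, yob1 = 0, yob2 = 0) {
  g <- function(nm, default = 0) {
    v <- means[[nm]]
    if (is.null(v)) default else v
  }
  mu_x <- rep_len(g("mu_x"), 2L)
  mu_y <- rep_len(g("mu_y"), 2L)
  bmx <- g("beta_male_x"); bmy <- g("beta_male_y")
  byx <- g("beta_yob_x");  byy <- g("beta_yob_y")
  c(x1 = mu_x[1] + bmx * male1 + byx * yob1,
    y1 = mu_y[1] + bmy * male1 + byy * yob1,
    x2 = mu_x[2] + bmx * male2 + byx * yob2,
    y2 = mu_y[2] + bmy * male2 + byy * yob2)
}

#' Raw A/C/E variance components of a moderated path set
#'
#' Components are squares of the (moderated) paths. Attainment components
#' are reported split into the part common with performance, the part unique
#' to attainment, and their sum; performance components come from the
#' x-paths, which are never moderated.
#'
#' @param paths A [moderated_paths()] set.
#' @param X Centered moderator value at which to evaluate the attainment
#'   paths (default 0 = average performance).
#' @return Object of class `"variance_components"`: a list with elements
#'   `performance` (VA, VC, VE, VT), `common`, `unique`, `attainment`
#'   (common + unique, with VT), and the evaluation point `X`.
#' @export
variance_components <- function(paths, X = 0) {
  p <- .as_pathvec(paths)
  y <- .effective_y_paths(p, X)
  perf <- c(VA = p[["a_xx"]]^2, VC = p[["c_xx"]]^2, VE = p[["e_xx"]]^2)
  perf <- c(perf, VT = sum(perf))
  common <- c(VA = y[["a_yx"]]^2, VC = y[["c_yx"]]^2, VE = y[["e_yx"]]^2)
  common <- c(common, VT = sum(common))
  unique_ <- c(VA = y[["a_yy"]]^2, VC = y[["c_yy"]]^2, VE = y[["e_yy"]]^2)
  unique_ <- c(unique_, VT = sum(unique_))
  att <- common + unique_
  structure(list(performance = perf, common = common, unique = unique_,
                 attainment = att, X = X),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, digits = 3, ...) {
  m <- rbind(performance = x$performance, common = x$common,
             unique = x$unique, attainment = x$attainment)
  cat("Raw ACE variance components (X =", format(x$X), ")\n")
  print(round(m, digits))
  invisible(x)
}

#' Standardize variance components to proportions
#'
#' Divides each raw component by the matching total variance. For
#' attainment, shares are reported three ways: components of the total
#' attainment variance, shares within the common part, and shares within
#' the unique part (the latter two are what "proportion of the common
#' variance due to genes" style statements refer to).
#'
#' @param vc A [variance_components()] object.
#' @return List of named proportion vectors (`performance`, `attainment`,
#'   `within_common`, `within_unique`), each summing to 1. A block whose
#'   total variance is zero yields `NA` proportions; if both phenotypes
#'   have zero total variance an error is raised.
#' @export
standardize_components <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$performance[["VT"]] <= 0 && vc$attainment[["VT"]] <= 0)
    stop("total variance is zero; proportions undefined")
  std <- function(v) {
    if (v[["VT"]] <= 0)
      return(stats::setNames(rep(NA_real_, 3), c("VA", "VC", "VE")))
    v[c("VA", "VC", "VE")] / v[["VT"]]
  }
  list(performance = std(vc$performance),
       attainment = std(vc$attainment),
       within_common = std(vc$common),
       within_unique = std(vc$unique))
}
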