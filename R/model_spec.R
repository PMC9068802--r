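# Multigroup model specifications.
#
# Parameters are indexed by (tracking status, role). A spec maps every
# required role of every status to exactly one free parameter (equality
# constraints = shared parameter names) or fixes it at zero. The three
# canonical models:
#   "1a": one common set of 9 paths + 2 intercepts for all statuses,
#         moderation slopes fixed at 0 (11 structural parameters).
#   "1b": separate 11-parameter sets for immediate, delayed and
#         tracking-missing twins (33), slopes still 0.
#   "2" : as 1b plus the 6 moderation slopes free in each status set (51).
# Covariate slopes (male, birth year; 4 parameters) are shared across all
# groups and statuses. With covariates the free counts are 15 / 37 / 55,
# so 1a -> 1b frees 22 parameters and 1b -> 2 frees 18.

.statuses <- c("immediate", "delayed", "missing")
.mean_roles <- c("mu_x", "mu_y")
.base_path_roles <- .path_roles[1:9]
.slope_roles <- .path_roles[10:15]
.beta_roles <- c("beta_male_x", "beta_male_y", "beta_yob_x", "beta_yob_y")

#' Build a multigroup ACE model specification
#'
#' @param model `"1a"` (all tracking statuses share one path/intercept set),
#'   `"1b"` (separate sets per status), or `"2"` (separate sets plus free
#'   moderation slopes on the six attainment paths in every set).
#' @param covariates Include shared fixed-effect slopes for the male dummy
#'   and centered birth year on both phenotypes?
#' @param moderator_mean Also give attainment a linear mean effect of the
#'   centered moderator (one slope per status set)? Off by default; whether
#'   it was used is recorded in every fit.
#' @return Object of class `"ace_model_spec"`.
#' @examples
#' n_free_parameters(ace_model_spec("1b")) -
#'   n_free_parameters(ace_model_spec("1a"))   # 22
#' @export
ace_model_spec <- function(model = c("1a", "1b", "2"),
                           covariates = TRUE, moderator_mean = FALSE) {
  model <- match.arg(model)
  set_of <- if (model == "1a") function(s) "all" else identity
  slopes_free <- model == "2"

  roles <- c(.path_roles, .mean_roles)
  idx <- matrix(0L, nrow = 3, ncol = length(roles),
                dimnames = list(.statuses, roles))
  param_names <- character(0)
  get_param <- function(name) {
    if (!name %in% param_names) param_names[[length(param_names) + 1L]] <<- name
    match(name, param_names)
  }
  for (s in .statuses) {
    for (role in c(.base_path_roles, .mean_roles))
      idx[s, role] <- get_param(paste(role, set_of(s), sep = "."))
    if (slopes_free)
      for (role in .slope_roles)
        idx[s, role] <- get_param(paste(role, set_of(s), sep = "."))
  }
  beta_idx <- if (covariates)
    vapply(.beta_roles, get_param, integer(1)) else rep(0L, 4)
  names(beta_idx) <- .beta_roles
  bmod_idx <- if (moderator_mean)
    vapply(.statuses, function(s)
      get_param(paste("beta_mod_y", set_of(s), sep = ".")), integer(1))
  else rep(0L, 3)
  names(bmod_idx) <- .statuses

  structure(list(model = model, covariates = covariates,
                 moderator_mean = moderator_mean, idx = idx,
                 beta_idx = beta_idx, bmod_idx = bmod_idx,
                 param_names = param_names),
            class = "ace_model_spec")
}

#' Number of free parameters of a model specification
#' @param spec An [ace_model_spec()].
#' @return Integer count.
#' @export
n_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "ace_model_spec"))
  length(spec$param_names)
}

#' @export
print.ace_model_spec <- function(x, ...) {
  cat(sprintf("ACE model spec '%s': %d free parameters (covariates: %s, moderator mean: %s)\n",
              x$model, n_free_parameters(x),
              x$covariates, x$moderator_mean))
  invisible(x)
}

# Expand a free-parameter vector into per-status structural arrays.
# Returns list(paths = 3x15 matrix, mu = 3x2 matrix, beta = numeric(4),
# bmod = numeric(3)).
.expand_params <- function(theta, spec) {
  if (length(theta) != n_free_parameters(spec))
    stop("parameter vector has length ", length(theta), ", spec needs ",
         n_free_parameters(spec))
  take <- function(i) ifelse(i == 0L, 0, theta[pmax(i, 1L)])
  full <- matrix(take(spec$idx), nrow = 3,
                 dimnames = dimnames(spec$idx))
  list(paths = full[, .path_roles, drop = FALSE],
       mu = full[, .mean_roles, drop = FALSE],
       beta = take(spec$beta_idx),
       bmod = take(spec$bmod_idx))
}

# Status-specific moderated_paths object from an expanded parameter set.
.paths_for_status <- function(expanded, status) {
  do.call(moderated_paths, as.list(expanded$paths[status, ]))
}

#' Serialize a model spec to YAML
#' @param spec An [ace_model_spec()].
#' @param path Optional file to write to.
#' @return YAML string (invisibly when `path` is given).
#' @export
spec_to_yaml <- function(spec, path = NULL) {
  txt <- yaml::as.yaml(list(model = spec$model,
                            covariates = spec$covariates,
                            moderator_mean = spec$moderator_mean))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Deserialize a model spec from YAML
#' @param x YAML string or file path.
#' @return An [ace_model_spec()].
#' @export
spec_from_yaml <- function(x) {
  lst <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  ace_model_spec(model = lst$model,
                 covariates = isTRUE(lst$covariates),
                 moderator_mean = isTRUE(lst$moderator_mean))
}
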