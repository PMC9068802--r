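# Descriptive statistics, decomposition tables, moderation curves,
# cluster-corrected crosstabs, and model-assumption checks.

#' Double-entry twin correlations by zygosity
#'
#' Each complete pair contributes both orderings (twin1-twin2 and
#' twin2-twin1), making the estimate invariant to twin labelling — the
#' standard convention in twin research.
#'
#' @param pairs A pair table.
#' @param phenotype `"attainment"` or `"performance"`.
#' @return Data.frame with `zygosity`, `rho`, `n_pairs` (complete pairs).
#'   `rho` is `NA` when fewer than 2 complete pairs are available.
#' @export
twin_correlations <- function(pairs,
                              phenotype = c("attainment", "performance")) {
  phenotype <- match.arg(phenotype)
  v1 <- pairs[[paste0(phenotype, "_1")]]
  v2 <- pairs[[paste0(phenotype, "_2")]]
  out <- lapply(c("MZ", "DZ"), function(z) {
    i <- pairs$zygosity == z
    ok <- i & !is.na(v1) & !is.na(v2)
    data.frame(zygosity = z,
               rho = if (sum(ok) >= 2) .double_entry_cor(v1[i], v2[i])
                     else NA_real_,
               n_pairs = sum(ok))
  })
  do.call(rbind, out)
}

# Distinct parameter sets of a fitted model: model 1a has one shared set.
.fit_sets <- function(fit) {
  if (fit$spec$model == "1a") c(all = "immediate")
  else c(immediate = "immediate", delayed = "delayed", missing = "missing")
}

#' Decomposition table of a fitted model
#'
#' Emits, per parameter set, the intercepts and path coefficients with
#' standard errors, the raw variance components of performance and of
#' attainment (split into common-with-performance, unique-to-attainment
#' and their sum, evaluated at average performance `X = 0`), and the
#' standardized shares. A pure function of the fit: rerunning gives
#' identical output.
#'
#' @param fit An [ace_fit()].
#' @return Long data.frame with columns `set`, `block`, `quantity`,
#'   `estimate`, `se`.
#' @export
decomposition_table <- function(fit) {
  ex <- .expand_params(coef(fit), fit$spec)
  sets <- .fit_sets(fit)
  se_of <- function(status, role) {
    i <- fit$spec$idx[status, role]
    if (i > 0L) fit$se[i] else NA_real_
  }
  rows <- list()
  add <- function(set, block, quantity, estimate, se = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      set = set, block = block, quantity = quantity,
      estimate = unname(estimate), se = unname(se))
  }
  for (k in seq_along(sets)) {
    set_name <- names(sets)[k]; s <- sets[[k]]
    add(set_name, "intercepts", "mu_x", ex$mu[s, "mu_x"], se_of(s, "mu_x"))
    add(set_name, "intercepts", "mu_y", ex$mu[s, "mu_y"], se_of(s, "mu_y"))
    roles <- if (fit$spec$model == "2") .path_roles else .base_path_roles
    for (role in roles)
      add(set_name, "paths", role, ex$paths[s, role], se_of(s, role))
    vc <- variance_components(.paths_for_status(ex, s), X = 0)
    for (part in c("performance", "common", "unique", "attainment"))
      for (q in c("VA", "VC", "VE", "VT"))
        add(set_name, part, q, vc[[part]][[q]])
    pr <- standardize_components(vc)
    for (part in names(pr))
      for (q in c("VA", "VC", "VE"))
        add(set_name, paste0("share_", part), q, pr[[part]][[q]])
  }
  if (fit$spec$covariates) {
    for (j in seq_along(.beta_roles))
      add("shared", "covariates", .beta_roles[j],
          ex$beta[j], fit$se[fit$spec$beta_idx[j]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Raw and standardized variance curves over the moderator
#'
#' Evaluates the attainment variance components of a moderated fit on a
#' grid of centered performance values, per tracking status: raw common,
#' unique and total components and their standardized versions (divided by
#' the total conditional variance `V_y|X`). Warns when the grid extends
#' beyond the observed moderator range.
#'
#' @param fit An [ace_fit()], normally of a moderated (model "2") spec.
#' @param x_grid Centered moderator values.
#' @param statuses Which status sets to evaluate.
#' @return Data.frame with columns `status`, `X`, `part`
#'   (common/unique/total), `component` (A/C/E), `raw`, `standardized`.
#' @export
conditional_variance_curves <- function(fit, x_grid = seq(-20, 10, by = 2),
                                        statuses = c("immediate",
                                                     "delayed")) {
  if (!is.null(fit$x_range) &&
      (min(x_grid) < fit$x_range[1] || max(x_grid) > fit$x_range[2]))
    warning("moderator grid extends beyond the observed performance range (",
            sprintf("%.1f to %.1f", fit$x_range[1], fit$x_range[2]), ")")
  ex <- .expand_params(coef(fit), fit$spec)
  out <- list()
  for (s in statuses) {
    p <- .paths_for_status(ex, s)
    for (X in x_grid) {
      vc <- variance_components(p, X = X)
      vt <- vc$attainment[["VT"]]
      for (part in c("common", "unique", "attainment")) {
        part_lab <- if (part == "attainment") "total" else part
        for (comp in c("VA", "VC", "VE")) {
          raw <- vc[[part]][[comp]]
          out[[length(out) + 1L]] <- data.frame(
            status = s, X = X, part = part_lab,
            component = sub("V", "", comp), raw = raw,
            standardized = if (vt > 0) raw / vt else NA_real_)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson chi-square with Rao-Scott second-order correction
#'
#' Tests independence of two categorical factors measured on individuals
#' that are nested in clusters (twins within pairs). The Pearson statistic
#' is divided by the mean generalized design effect and, in second order,
#' by `1 + a^2` (the squared coefficient of variation of the design-effect
#' eigenvalues); the result is referred to an F distribution with
#' Satterthwaite fractional degrees of freedom. With singleton clusters
#' the corrected statistic equals the ordinary Pearson chi-square, and the
#' statistic is invariant under duplication of every cluster.
#'
#' @param row,col Factors (or vectors) of equal length, one entry per
#'   individual. Entries with `NA` in either factor are dropped.
#' @param cluster Cluster identifiers; `NULL` treats individuals as
#'   independent.
#' @return Object of class `"raoscott_crosstab"`: `counts`, `row_pct`,
#'   `pearson` (uncorrected X2), `statistic` (second-order corrected X2),
#'   `F`, `df1`, `df2`, `p.value`, `delta_bar`, `a2`, `n`, `n_clusters`.
#' @export
crosstab_with_raoscott <- function(row, col, cluster = NULL) {
  if (is.null(cluster)) cluster <- seq_along(row)
  keep <- !is.na(row) & !is.na(col)
  row <- factor(row[keep]); col <- factor(col[keep])
  cluster <- cluster[keep]
  counts <- table(row, col)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    message("dropping empty rows: ",
            paste(rownames(counts)[empty], collapse = ", "))
    row <- droplevels(row)
    counts <- table(row, col)
  }
  n <- sum(counts)
  R <- nrow(counts); C <- ncol(counts)
  if (R < 2 || C < 2) stop("crosstab needs at least 2x2 non-empty cells")
  p <- counts / n
  pr <- rowSums(p); pc <- colSums(p)
  expected <- outer(pr, pc)
  X2 <- n * sum((p - expected)^2 / expected)

  # per-individual influence of the independence residuals
  Ir <- outer(as.integer(row), seq_len(R), function(i, r) (i == r) + 0) -
    matrix(pr, length(row), R, byrow = TRUE)
  Ic <- outer(as.integer(col), seq_len(C), function(i, c) (i == c) + 0) -
    matrix(pc, length(col), C, byrow = TRUE)
  Z <- matrix(NA_real_, length(row), R * C)
  for (cc in seq_len(C))
    Z[, (cc - 1) * R + seq_len(R)] <- Ir * Ic[, cc]
  zbar <- colMeans(Z)
  Zc <- sweep(Z, 2, zbar)
  V_srs <- crossprod(Zc) / n^2
  Zk <- rowsum(Z, cluster)
  mk <- as.vector(rowsum(rep(1, length(row)), cluster))
  Zkc <- Zk - outer(mk, zbar)
  V_clust <- crossprod(Zkc) / n^2
  G <- length(mk)

  dsc <- 1 / sqrt(as.vector(expected))
  M_srs <- n * (V_srs * outer(dsc, dsc))
  M_clust <- n * (V_clust * outer(dsc, dsc))
  es <- eigen(M_srs, symmetric = TRUE)
  tol <- max(es$values) * 1e-9
  keep_ev <- es$values > tol
  B <- es$vectors[, keep_ev, drop = FALSE]
  lam <- es$values[keep_ev]
  W <- sweep(crossprod(B, M_clust %*% B), 1, sqrt(lam), "/")
  W <- sweep(W, 2, sqrt(lam), "/")
  delta <- eigen((W + t(W)) / 2, symmetric = TRUE)$values
  d <- length(delta)
  delta_bar <- mean(delta)
  a2 <- sum((delta - delta_bar)^2) / (d * delta_bar^2)

  stat <- X2 / (delta_bar * (1 + a2))
  Fstat <- X2 / (d * delta_bar)
  df1 <- d / (1 + a2)
  df2 <- df1 * (G - 1)
  structure(list(counts = unclass(counts),
                 row_pct = 100 * sweep(unclass(counts), 1,
                                       rowSums(counts), "/"),
                 pearson = X2, statistic = stat, F = Fstat,
                 df1 = df1, df2 = df2,
                 p.value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 delta_bar = delta_bar, a2 = a2, n = n, n_clusters = G),
            class = "raoscott_crosstab")
}

#' @export
print.raoscott_crosstab <- function(x, digits = 1, ...) {
  tab <- cbind(x$counts, Total = rowSums(x$counts))
  cat("Counts (twins):\n"); print(tab)
  cat("Row percentages:\n")
  print(round(cbind(x$row_pct, Total = 100), digits))
  tot <- colSums(x$counts)
  cat("Column totals:", paste(sprintf("%s %d (%.1f%%)", colnames(x$counts),
                                      tot, 100 * tot / x$n),
                              collapse = ", "), "\n")
  cat(sprintf("F(%.2f, %.2f) = %.2f, p = %.3g (Rao-Scott 2nd-order corrected Pearson Chi2)\n",
              x$df1, x$df2, x$F, x$p.value))
  invisible(x)
}

#' Percentage summary of a printed count table
#'
#' Builds the counts/row-percentage part of a crosstab report directly
#' from a count matrix (e.g. transcribed from a published table), with the
#' column shares of the totals row.
#'
#' @param counts Numeric matrix of counts (rows x columns).
#' @return List with `counts`, `row_pct`, `total_counts`, `total_pct`.
#' @export
crosstab_report <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  list(counts = counts,
       row_pct = 100 * sweep(counts, 1, rowSums(counts), "/"),
       total_counts = tot,
       total_pct = 100 * tot / sum(counts))
}

#' Default CITO performance bins
#'
#' Bins raw CITO-like scores into the conventional track-correspondence
#' intervals 500-518, 519-525, 526-528, 529-532, 533-536, 537-539,
#' 540-544, 545-550.
#'
#' @param performance Raw scores.
#' @return Factor of bin labels.
#' @export
cito_bins <- function(performance) {
  edges <- c(500, 518, 525, 528, 532, 536, 539, 544, 550)
  labels <- paste(edges[-length(edges)] + c(0, rep(1, length(edges) - 2)),
                  edges[-1], sep = "-")
  cut(performance, breaks = c(-Inf, edges[-1]), labels = labels,
      right = TRUE)
}

#' Tracking crosstab from a pair table
#'
#' Twin-level crosstab of a per-twin variable against tracking status
#' (immediate/delayed; tracking-missing twins dropped) with the Rao-Scott
#' correction clustering on pairs.
#'
#' @param pairs A pair table.
#' @param by `"performance_bin"` (default CITO bins of raw performance) or
#'   the prefix of any per-twin column (e.g. `"male"`).
#' @return A [crosstab_with_raoscott()] report.
#' @export
tracking_crosstab <- function(pairs, by = "performance_bin") {
  pull <- function(prefix) c(pairs[[paste0(prefix, "_1")]],
                             pairs[[paste0(prefix, "_2")]])
  row <- if (by == "performance_bin") cito_bins(pull("performance"))
         else pull(by)
  col <- pull("tracking")
  col[!col %in% c("immediate", "delayed")] <- NA
  cluster <- rep(pairs$pair_id, 2)
  crosstab_with_raoscott(row, col, cluster)
}

# -------------------------------------------------------------------------
# Homogeneity checks: saturated Gaussian FIML fits per phenotype with
# means/SDs by subgroup and a twin correlation per zygosity, constrained
# step by step (free -> variances equated -> means equated), each step an
# LRT. Pairs with one missing member contribute their marginal density.

.bvn_neg2ll <- function(m1, m2, s1, s2, rho, v1, v2) {
  o1 <- !is.na(v1); o2 <- !is.na(v2)
  tot <- 0
  both <- o1 & o2
  if (any(both)) {
    z1 <- (v1[both] - m1[both]) / s1[both]
    z2 <- (v2[both] - m2[both]) / s2[both]
    rr <- rho[both]
    q <- (z1^2 - 2 * rr * z1 * z2 + z2^2) / (1 - rr^2)
    tot <- tot + sum(2 * log(2 * pi) + 2 * log(s1[both]) +
                       2 * log(s2[both]) + log(1 - rr^2) + q)
  }
  only1 <- o1 & !o2
  if (any(only1)) {
    z <- (v1[only1] - m1[only1]) / s1[only1]
    tot <- tot + sum(log(2 * pi) + 2 * log(s1[only1]) + z^2)
  }
  only2 <- o2 & !o1
  if (any(only2)) {
    z <- (v2[only2] - m2[only2]) / s2[only2]
    tot <- tot + sum(log(2 * pi) + 2 * log(s2[only2]) + z^2)
  }
  tot
}

.fit_saturated <- function(pairs, phenotype, groups1, groups2,
                           equal_var, equal_mean) {
  v1 <- pairs[[paste0(phenotype, "_1")]]
  v2 <- pairs[[paste0(phenotype, "_2")]]
  lev <- sort(unique(c(groups1, groups2)))
  g1 <- match(groups1, lev); g2 <- match(groups2, lev)
  v1[is.na(g1)] <- NA; v2[is.na(g2)] <- NA
  g1[is.na(g1)] <- 1L; g2[is.na(g2)] <- 1L
  zyg <- match(pairs$zygosity, c("MZ", "DZ"))
  K <- length(lev)
  n_mu <- if (equal_mean) 1L else K
  n_sd <- if (equal_var) 1L else K
  mu0 <- mean(c(v1, v2), na.rm = TRUE)
  sd0 <- stats::sd(c(v1, v2), na.rm = TRUE)
  start <- c(rep(mu0, n_mu), rep(log(sd0), n_sd), atanh(c(0.6, 0.35)))
  obj <- function(th) {
    mu <- th[seq_len(n_mu)]
    lsd <- th[n_mu + seq_len(n_sd)]
    rho <- tanh(th[n_mu + n_sd + 1:2])
    mg <- if (equal_mean) rep(mu, K) else mu
    sg <- exp(if (equal_var) rep(lsd, K) else lsd)
    .bvn_neg2ll(mg[g1], mg[g2], sg[g1], sg[g2], rho[zyg], v1, v2)
  }
  res <- stats::nlminb(start, obj, control = list(iter.max = 500))
  list(neg2ll = res$objective, npar = length(start),
       convergence = res$convergence)
}

#' Stepwise homogeneity checks of means and variances
#'
#' Tests the twin-model assumption that phenotype means and variances do
#' not depend on birth order, zygosity or sex: a saturated Gaussian model
#' with subgroup-specific means and variances (and a twin correlation per
#' zygosity) is constrained step by step — variances equated, then means
#' equated — and each step is evaluated by a likelihood-ratio test.
#'
#' @param pairs A pair table.
#' @param phenotype `"attainment"` or `"performance"`.
#' @param by Factors defining the subgroups; any subset of
#'   `c("birth_order", "zygosity", "sex")`.
#' @return Data.frame with one row per model (`free`, `equal variances`,
#'   `equal variances + means`): `npar`, `neg2LL`, `Chisq`, `df`,
#'   `p.value` (LRT against the previous step).
#' @export
homogeneity_checks <- function(pairs,
                               phenotype = c("attainment", "performance"),
                               by = c("birth_order", "zygosity", "sex")) {
  phenotype <- match.arg(phenotype)
  by <- match.arg(by, several.ok = TRUE)
  part <- function(twin) {
    parts <- list()
    if ("birth_order" %in% by) parts$bo <- rep(twin, nrow(pairs))
    if ("zygosity" %in% by) parts$zyg <- pairs$zygosity
    if ("sex" %in% by) parts$sex <- pairs[[paste0("male_", twin)]]
    if (!length(parts)) return(rep("all", nrow(pairs)))
    do.call(paste, c(parts, sep = "/"))
  }
  g1 <- part(1); g2 <- part(2)
  g1[grepl("NA", g1)] <- NA; g2[grepl("NA", g2)] <- NA
  steps <- list(
    free = .fit_saturated(pairs, phenotype, g1, g2, FALSE, FALSE),
    `equal variances` = .fit_saturated(pairs, phenotype, g1, g2,
                                       TRUE, FALSE),
    `equal variances + means` = .fit_saturated(pairs, phenotype, g1, g2,
                                               TRUE, TRUE))
  n2 <- vapply(steps, `[[`, numeric(1), "neg2ll")
  np <- vapply(steps, `[[`, numeric(1), "npar")
  chisq <- c(NA, diff(n2))
  df <- c(NA, -diff(np))
  data.frame(model = names(steps), phenotype = phenotype, npar = np,
             neg2LL = n2, Chisq = pmax(chisq, 0), df = df,
             p.value = ifelse(is.na(df), NA,
                              stats::pchisq(pmax(chisq, 0), df,
                                            lower.tail = FALSE)),
             row.names = NULL)
}

#' Export a fit as JSON
#' @param fit An [ace_fit()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$spec$model,
         estimates = as.list(coef(fit)),
         se = as.list(fit$se),
         neg2ll = fit$neg2ll, npar = fit$npar,
         aic = as.list(aic_conventions(fit)),
         n_pairs = fit$n_pairs, n_records = fit$n_records,
         convergence = fit$convergence, grad_norm = fit$grad_norm,
         moderator_mean = fit$moderator_mean,
         centering = fit$centering),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a decomposition table as TSV
#' @param fit An [ace_fit()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_fit_tsv <- function(fit, path) {
  utils::write.table(decomposition_table(fit), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
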