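#' Specification for the two-way fixed-effects DID regression
#'
#' Describes the benchmark regression
#' \deqn{MRAE_{it} = \alpha_0 + \alpha_1\, du{\cdot}dt_{it}
#'   + \beta X_{it} + \mu_i + v_t + \varepsilon_{it}}
#' where `du_dt` is the staggered-adoption policy indicator, `X` the
#' controls, and \eqn{\mu_i}, \eqn{v_t} optional unit and period fixed
#' effects.
#'
#' @param outcome outcome column name (default `"mrae"`).
#' @param policy policy indicator column (default `"du_dt"`).
#' @param controls character vector of control columns (subset of the
#'   panel's control block), possibly empty.
#' @param unit_fe,time_fe absorb unit / period intercepts.
#' @param se_type `"conventional"` or `"cluster_by_unit"`.
#' @return a `did_spec` list.
#' @export
did_spec <- function(outcome = "mrae", policy = "du_dt",
                     controls = character(),
                     unit_fe = TRUE, time_fe = TRUE,
                     se_type = c("conventional", "cluster_by_unit")) {
  se_type <- match.arg(se_type)
  if (anyDuplicated(controls)) {
    stop_mraedid("controls must be distinct", "spec_error")
  }
  structure(list(outcome = outcome, policy = policy, controls = controls,
                 unit_fe = unit_fe, time_fe = time_fe, se_type = se_type),
            class = "did_spec")
}

# iterative two-way demeaning; exact in one sweep on balanced panels,
# iterated to convergence otherwise
demean_twoway <- function(M, unit = NULL, time = NULL,
                          tol = 1e-11, maxit = 200L) {
  M <- as.matrix(M)
  if (is.null(unit) && is.null(time)) return(M)
  for (it in seq_len(maxit)) {
    if (!is.null(unit)) {
      M <- M - apply(M, 2, function(v) ave(v, unit))
    }
    if (!is.null(time)) {
      M <- M - apply(M, 2, function(v) ave(v, time))
    }
    drift <- 0
    if (!is.null(unit)) {
      drift <- max(drift, max(abs(apply(M, 2, function(v)
        tapply(v, unit, mean)))))
    }
    if (!is.null(time)) {
      drift <- max(drift, max(abs(apply(M, 2, function(v)
        tapply(v, time, mean)))))
    }
    if (drift < tol) break
  }
  M
}

# core least-squares with absorbed fixed effects; shared by the DID
# and event-study fits
fe_ols <- function(y, Z, unit, time, unit_fe, time_fe, se_type,
                   cluster = NULL) {
  n <- length(y)
  Z <- as.matrix(Z)
  k <- ncol(Z)
  u <- if (unit_fe) unit else NULL
  t_ <- if (time_fe) time else NULL
  W <- demean_twoway(cbind(y, Z), u, t_)
  has_fe <- unit_fe || time_fe
  if (!has_fe) W <- cbind(W, intercept = 1)
  yd <- W[, 1]
  Zd <- W[, -1, drop = FALSE]
  qr_ <- qr(Zd)
  if (qr_$rank < ncol(Zd)) {
    drop <- colnames(Zd)[qr_$pivot[(qr_$rank + 1):ncol(Zd)]]
    stop_mraedid(paste0("collinear regressor(s) after fixed-effect ",
                        "absorption: ", paste(drop, collapse = ", ")),
                 "collinearity_error", list(columns = drop))
  }
  beta <- qr.coef(qr_, yd)
  res <- yd - Zd %*% beta
  absorbed <- (if (unit_fe) length(unique(unit)) - 1L else 0L) +
    (if (time_fe) length(unique(time)) - 1L else 0L) +
    (if (has_fe) 1L else 0L)
  kk <- ncol(Zd)                      # includes intercept when no FE
  dof <- n - kk - absorbed
  XtXinv <- chol2inv(qr.R(qr_))
  if (dof <= 0) {
    # saturated design (e.g. the 2x2 fixture): coefficients are exact,
    # uncertainty is undefined
    vcov <- matrix(NaN, kk, kk)
    se_dof <- 0L
  } else if (se_type == "cluster_by_unit") {
    cl <- cluster %||% unit
    G <- length(unique(cl))
    meat <- matrix(0, kk, kk)
    for (g in unique(cl)) {
      idx <- which(cl == g)
      sg <- crossprod(Zd[idx, , drop = FALSE], res[idx])
      meat <- meat + tcrossprod(sg)
    }
    adj <- G / (G - 1) * (n - 1) / (n - kk - absorbed)
    vcov <- adj * XtXinv %*% meat %*% XtXinv
    se_dof <- G - 1L
  } else {
    sigma2 <- sum(res^2) / dof
    vcov <- sigma2 * XtXinv
    se_dof <- dof
  }
  se <- sqrt(diag(vcov))
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), se_dof)
  tss <- sum((yd - mean(yd))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
  names(beta) <- names(se) <- names(tstat) <- names(pval) <- colnames(Zd)
  list(beta = beta, se = se, t = tstat, p = pval, vcov = vcov,
       residuals = as.vector(res), r_squared = max(0, min(1, r2)),
       dof = se_dof, n_obs = n, Zd = Zd, yd = yd)
}

#' Fit the two-way fixed-effects DID regression
#'
#' Least squares of the outcome on the policy indicator and controls
#' with unit and/or period fixed effects absorbed by two-way
#' demeaning (numerically identical to dummy-variable least squares).
#' Standard errors are conventional by default or clustered by
#' province (CR1); p-values use the t distribution with residual
#' degrees of freedom after absorption (cluster count minus one when
#' clustered).  The reported R-squared is the within R-squared of the
#' demeaned regression.
#'
#' @param data data frame with `province`, `year`, the outcome, the
#'   policy indicator and any controls (e.g. a scored panel from
#'   [run_pipeline()] or [attach_treatment()] plus a score merge).
#' @param spec a [did_spec()].
#' @return a `did_result`: `alpha0` (grand intercept), `alpha1`
#'   (policy coefficient), `beta` (controls), `se_alpha1`, `t_alpha1`,
#'   `p_alpha1`, `se`, `p`, `vcov`, `r_squared`, `n_obs`, `dof`,
#'   `spec`.
#' @export
fit_twfe_did <- function(data, spec = did_spec()) {
  df <- as.data.frame(data)
  need <- c("province", "year", spec$outcome, spec$policy, spec$controls)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_mraedid(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                 "spec_error")
  }
  if (length(unique(df$year)) < 2L || length(unique(df$province)) < 2L) {
    stop_mraedid("need at least 2 units and 2 periods", "design_error")
  }
  vars <- c(spec$policy, spec$controls)
  fit <- fe_ols(df[[spec$outcome]], df[, vars, drop = FALSE],
                df$province, df$year, spec$unit_fe, spec$time_fe,
                spec$se_type)
  b <- fit$beta
  alpha1 <- unname(b[spec$policy])
  ctrl <- b[spec$controls]
  # grand intercept on the original scale
  alpha0 <- if (spec$unit_fe || spec$time_fe) {
    mean(df[[spec$outcome]]) -
      sum(colMeans(as.matrix(df[, vars, drop = FALSE])) * b[vars])
  } else unname(b["intercept"])
  structure(list(alpha0 = alpha0, alpha1 = alpha1, beta = ctrl,
                 se_alpha1 = unname(fit$se[spec$policy]),
                 t_alpha1 = unname(fit$t[spec$policy]),
                 p_alpha1 = unname(fit$p[spec$policy]),
                 se = fit$se, p = fit$p, vcov = fit$vcov,
                 r_squared = fit$r_squared, n_obs = fit$n_obs,
                 dof = fit$dof, spec = spec),
            class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat("Two-way FE DID:", x$spec$outcome, "~", x$spec$policy,
      if (length(x$spec$controls)) paste("+", length(x$spec$controls),
                                         "controls") else "", "\n")
  cat(sprintf("  alpha1 = %.4f (SE %.4f, t = %.2f, p = %.4g)\n",
              x$alpha1, x$se_alpha1, x$t_alpha1, x$p_alpha1))
  cat(sprintf("  within R^2 = %.3f, n = %d\n", x$r_squared, x$n_obs))
  invisible(x)
}

#' Event-study specification and fit
#'
#' Replaces the single policy indicator with lead and lag indicators
#' in event time `e = year - adoption year` of each treated
#' province's own batch: leads `before_1 .. before_6` cover
#' `e = -2 .. -6` with `e <= -7` pooled into `before_6`; lags
#' `after_1 .. after_6` cover `e = 0 .. 4` with `e >= 5` pooled into
#' `after_6`.  The period immediately before adoption (`e = -1`) is
#' the omitted category.  Insignificant leads support the parallel
#' trends assumption; the lag path traces the dynamic effect.
#'
#' @param data data frame with `province`, `year`, `batch_year`
#'   (`NA` for never-treated), the outcome and controls.
#' @param spec a [did_spec()] (its `policy` field is ignored).
#' @param leads,lags number of lead / lag bins (default 6 + 6 as in
#'   the benchmark design; shorter panels need shorter windows).
#' @param conf_level confidence level for the reported intervals.
#' @return an `event_study_result` with `coefficients` (data frame:
#'   `term`, `event_time`, `estimate`, `se`, `p`, `ci_lo`, `ci_hi`),
#'   `controls`, `joint_leads` (F test of all leads = 0), `n_obs`.
#' @export
fit_event_study <- function(data, spec = did_spec(), leads = 6L,
                            lags = 6L, conf_level = 0.95) {
  df <- as.data.frame(data)
  if (!"batch_year" %in% names(df)) {
    stop_mraedid("event study needs a batch_year column", "spec_error")
  }
  if (leads < 1L || lags < 1L) {
    stop_mraedid("need at least one lead and one lag bin", "spec_error")
  }
  e <- ifelse(is.na(df$batch_year), NA_real_, df$year - df$batch_year)
  bins <- list()
  labs <- character(); etime <- character()
  for (j in seq_len(leads)) {
    hit <- if (j < leads) !is.na(e) & e == -(j + 1)
           else !is.na(e) & e <= -(leads + 1)
    bins[[paste0("before_", j)]] <- as.numeric(hit)
    labs <- c(labs, paste0("before_", j))
    etime <- c(etime, if (j < leads) as.character(-(j + 1))
                      else paste0("<=", -(leads + 1)))
  }
  for (j in seq_len(lags)) {
    hit <- if (j < lags) !is.na(e) & e == (j - 1)
           else !is.na(e) & e >= lags - 1
    bins[[paste0("after_", j)]] <- as.numeric(hit)
    labs <- c(labs, paste0("after_", j))
    etime <- c(etime, if (j < lags) as.character(j - 1)
                      else paste0(">=", lags - 1))
  }
  D <- do.call(cbind, bins)
  empty <- labs[colSums(D) == 0]
  if (length(empty)) {
    stop_mraedid(paste0("empty event-time cell(s): ",
                        paste(empty, collapse = ", ")),
                 "degenerate_design_error", list(cells = empty))
  }
  Z <- cbind(D, as.matrix(df[, spec$controls, drop = FALSE]))
  fit <- fe_ols(df[[spec$outcome]], Z, df$province, df$year,
                spec$unit_fe, spec$time_fe, spec$se_type)
  idx <- match(labs, names(fit$beta))
  crit <- stats::qt(1 - (1 - conf_level) / 2, fit$dof)
  coefs <- data.frame(term = labs, event_time = etime,
                      estimate = unname(fit$beta[idx]),
                      se = unname(fit$se[idx]), p = unname(fit$p[idx]),
                      stringsAsFactors = FALSE)
  coefs$ci_lo <- coefs$estimate - crit * coefs$se
  coefs$ci_hi <- coefs$estimate + crit * coefs$se
  # joint F test that all lead coefficients are zero
  li <- idx[seq_len(leads)]
  bl <- fit$beta[li]
  Vl <- fit$vcov[li, li]
  Fstat <- drop(t(bl) %*% solve(Vl, bl)) / leads
  pF <- stats::pf(Fstat, leads, fit$dof, lower.tail = FALSE)
  structure(list(coefficients = coefs,
                 controls = fit$beta[spec$controls],
                 joint_leads = list(F = Fstat, df1 = 6L, df2 = fit$dof,
                                    p = pF),
                 conf_level = conf_level,
                 n_obs = fit$n_obs),
            class = "event_study_result")
}

#' Permutation placebo test
#'
#' Redraws which provinces are treated — keeping the two batch years
#' and batch sizes of the true assignment fixed — rebuilds the
#' `du_dt` indicator, refits the DID regression, and records the
#' placebo coefficient and its p-value.  A genuine effect should make
#' the benchmark coefficient extreme relative to the permutation
#' distribution, with most permutation p-values large.
#'
#' @param data data frame with `province`, `year`, `batch_year` (the
#'   true assignment), the outcome and controls.
#' @param spec a [did_spec()].
#' @param n_perm number of permutations.
#' @param seed RNG seed (set when not `NULL`).
#' @param assignments optional list of named integer vectors
#'   (province -> batch year) overriding the random draws, e.g. to
#'   force the identity permutation.
#' @return a `placebo_result`: `benchmark_coef`, `benchmark_p`,
#'   `perm_coefs`, `perm_pvalues`, `empirical_p` (share of
#'   permutations with `|coef| >=` the benchmark's), `seed`.
#' @export
placebo_test <- function(data, spec = did_spec(), n_perm = 1000L,
                         seed = NULL, assignments = NULL) {
  df <- as.data.frame(data)
  if (!"batch_year" %in% names(df)) {
    stop_mraedid("placebo test needs the true batch_year column",
                 "spec_error")
  }
  if (!is.null(seed)) set.seed(seed)
  provs <- unique(df$province)
  truth <- df$batch_year[match(provs, df$province)]
  sizes <- table(truth[!is.na(truth)])
  n_treat <- sum(sizes)
  if (n_treat > length(provs)) {
    stop_mraedid("more treated provinces than provinces", "sampling_error")
  }
  refit <- function(batch_year_by_prov) {
    by <- batch_year_by_prov[df$province]
    df[[spec$policy]] <- as.integer(!is.na(by) & df$year >= by)
    fit_twfe_did(df, spec)
  }
  bench <- refit(stats::setNames(truth, provs))
  if (is.null(assignments)) {
    n_use <- n_perm
    draw <- function(i) {
      picked <- sample(provs, n_treat)
      by <- stats::setNames(rep(NA_integer_, length(provs)), provs)
      off <- 0L
      for (yname in names(sizes)) {
        by[picked[(off + 1L):(off + sizes[[yname]])]] <- as.integer(yname)
        off <- off + sizes[[yname]]
      }
      by
    }
  } else {
    n_use <- length(assignments)
    draw <- function(i) assignments[[i]]
  }
  coefs <- numeric(n_use)
  pvals <- numeric(n_use)
  for (i in seq_len(n_use)) {
    f <- refit(draw(i))
    coefs[i] <- f$alpha1
    pvals[i] <- f$p_alpha1
  }
  structure(list(benchmark_coef = bench$alpha1,
                 benchmark_p = bench$p_alpha1,
                 perm_coefs = coefs, perm_pvalues = pvals,
                 empirical_p = mean(abs(coefs) >= abs(bench$alpha1)),
                 n_perm = n_use, seed = seed),
            class = "placebo_result")
}

#' Heterogeneity subgroup DID
#'
#' Refits the DID regression within each subgroup of provinces.  A
#' subgroup must contain at least one treated and one never-treated
#' province to be estimable.
#'
#' @param data data frame as in [fit_twfe_did()], plus `batch_year`
#'   (to identify treated provinces) and `region` when splitting by
#'   region.
#' @param spec a [did_spec()].
#' @param splitter named character vector province -> group label, or
#'   a function of the data returning one; see [split_by_region()]
#'   and [split_by_median()].
#' @return named list of `did_result`, one per subgroup.
#' @export
subgroup_did <- function(data, spec = did_spec(),
                         splitter = split_by_region) {
  df <- as.data.frame(data)
  groups <- if (is.function(splitter)) splitter(df) else splitter
  uncovered <- setdiff(unique(df$province), names(groups))
  if (length(uncovered)) {
    stop_mraedid(paste0("splitter misses province(s): ",
                        paste(uncovered, collapse = ", ")),
                 "splitter_error")
  }
  out <- list()
  for (g in unique(groups)) {
    sub <- df[df$province %in% names(groups)[groups == g], , drop = FALSE]
    treated <- unique(sub$province[!is.na(sub$batch_year)])
    control <- unique(sub$province[is.na(sub$batch_year)])
    if (!length(treated) || !length(control)) {
      stop_mraedid(sprintf(
        "subgroup '%s' has no %s province; effect inestimable", g,
        if (length(treated)) "control" else "treated"),
        "inestimable_subgroup_error", list(group = g))
    }
    out[[g]] <- fit_twfe_did(sub, spec)
  }
  out
}

#' Subgroup splitters
#'
#' `split_by_region()` maps each province to its region label.
#' `split_by_median()` time-averages `var` per province and splits at
#' the median of those averages; ties at the median go to the
#' `"low"` group.
#'
#' @param data data frame with `province` and the relevant columns.
#' @param var column to split on (for `split_by_median`).
#' @return named character vector province -> group label.
#' @export
split_by_region <- function(data) {
  df <- as.data.frame(data)
  first <- !duplicated(df$province)
  stats::setNames(df$region[first], df$province[first])
}

#' @rdname split_by_region
#' @export
split_by_median <- function(data, var) {
  df <- as.data.frame(data)
  avg <- tapply(df[[var]], df$province, mean)
  med <- stats::median(avg)
  stats::setNames(ifelse(avg <= med, "low", "high"), names(avg))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column `j` on the other
#' columns (with intercept).  Values of 10 or more conventionally flag
#' serious multicollinearity; perfect collinearity is reported as
#' `Inf` with a warning naming the column.
#'
#' @param data data frame holding the columns.
#' @param columns character vector of at least two column names.
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(data, columns) {
  df <- as.data.frame(data)
  if (length(columns) < 2L) {
    stop_mraedid("need at least 2 columns", "spec_error")
  }
  if (nrow(df) <= length(columns)) {
    stop_mraedid("need more records than columns", "spec_error")
  }
  M <- as.matrix(df[, columns])
  out <- stats::setNames(numeric(length(columns)), columns)
  for (j in seq_along(columns)) {
    y <- M[, j]
    X <- cbind(1, M[, -j, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    res <- fit$residuals
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
    if (r2 >= 1 - 1e-12) {
      warning("perfect collinearity: ", columns[j])
      out[j] <- Inf
    } else {
      out[j] <- 1 / (1 - r2)
    }
  }
  out
}
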