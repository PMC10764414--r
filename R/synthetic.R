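#' Configuration of the synthetic province panel
#'
#' Declares the data-generating process used throughout the test
#' suite: a balanced panel at the study dimensions (30 provinces,
#' 2009-2021, East/Central/West of sizes 11/8/11), two staggered
#' adoption batches (4 provinces in 2015, 7 in 2016, drawn with the
#' regional composition of the actual pilot batches when the default
#' dimensions are used), a Cobb-Douglas production frontier with a
#' multiplicative technology disadvantage per region (inducing
#' technology gap ratios below 1), half-normal unit-period
#' inefficiency, and an additive post-treatment efficiency gain
#' `delta`.
#'
#' @param n_provinces number of provinces.
#' @param years integer vector of calendar years.
#' @param region_sizes named integer vector of provinces per region
#'   (must sum to `n_provinces`).
#' @param batches named list mapping adoption year to the number of
#'   provinces adopting in that year.
#' @param delta additive post-treatment efficiency gain (the true
#'   policy effect recovered by the DID stage).
#' @param inefficiency_scale overall scale of the half-normal
#'   inefficiency `u`, split 3:1 into a persistent province component
#'   and a transient unit-period component; the default 0.2 puts mean
#'   true efficiency `E[exp(-u)]` near 0.86.
#' @param noise_sd log-scale measurement noise on outputs.
#' @param group_tech_gap named vector of multiplicative frontier
#'   factors per region (1 = global best practice).
#' @param control_effects length-5 coefficient vector linking the
#'   centred controls to true efficiency (zero by default so
#'   efficiency is a pure production quantity).
#' @param input_persistence AR(1) coefficient of log-input dynamics.
#' @param seed RNG seed (set when not `NULL`).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_provinces = 30L,
                             years = 2009:2021,
                             region_sizes = c(East = 11L, Central = 8L,
                                              West = 11L),
                             batches = list("2015" = 4L, "2016" = 7L),
                             delta = 0.03,
                             inefficiency_scale = 0.2,
                             noise_sd = 0.01,
                             group_tech_gap = c(East = 1, Central = 0.8,
                                                West = 0.92),
                             control_effects = rep(0, 5),
                             input_persistence = 0.85,
                             seed = NULL) {
  if (sum(region_sizes) != n_provinces) {
    stop_mraedid("region sizes must sum to n_provinces", "config_error")
  }
  n_treat <- sum(unlist(batches))
  if (n_treat > n_provinces) {
    stop_mraedid("batch sizes exceed n_provinces", "config_error")
  }
  if (length(batches) && (any(as.integer(names(batches)) < min(years)) ||
                          any(as.integer(names(batches)) > max(years)))) {
    stop_mraedid("batch years outside panel years", "config_error")
  }
  if (delta < 0 || delta >= 0.5) {
    stop_mraedid("delta must lie in [0, 0.5)", "config_error")
  }
  if (inefficiency_scale < 0 || noise_sd < 0) {
    stop_mraedid("scale parameters must be >= 0", "config_error")
  }
  if (any(group_tech_gap <= 0 | group_tech_gap > 1) ||
      !setequal(names(group_tech_gap), names(region_sizes))) {
    stop_mraedid("group_tech_gap must be in (0, 1] and name every region",
                 "config_error")
  }
  if (length(control_effects) != 5L) {
    stop_mraedid("control_effects must have length 5", "config_error")
  }
  structure(list(n_provinces = as.integer(n_provinces), years = years,
                 region_sizes = region_sizes, batches = batches,
                 delta = delta, inefficiency_scale = inefficiency_scale,
                 noise_sd = noise_sd, group_tech_gap = group_tech_gap,
                 control_effects = control_effects,
                 input_persistence = input_persistence, seed = seed),
            class = "synthetic_config")
}

# regional composition of the two actual pilot batches (East 2+2,
# Central 1+1, West 1+4); used when the configured dimensions allow it
default_batch_mix <- function(cfg) {
  if (identical(unname(cfg$region_sizes), c(11L, 8L, 11L)) &&
      identical(names(cfg$batches), c("2015", "2016")) &&
      identical(unname(unlist(cfg$batches)), c(4L, 7L))) {
    list("2015" = c(East = 2L, Central = 1L, West = 1L),
         "2016" = c(East = 2L, Central = 1L, West = 4L))
  } else NULL
}

#' Generate a synthetic province panel with known truth
#'
#' Draws a balanced panel from the declared DGP: log inputs follow
#' province-level AR(1) processes with deterministic growth; frontier
#' desirable outputs are Cobb-Douglas in the inputs scaled by the
#' region's technology factor; realised outputs are frontier times the
#' true efficiency `e = exp(-u) + delta * post` (u half-normal) times
#' log-normal noise; undesirable outputs rise with activity and with
#' inefficiency; controls are drawn with mild covariance to treatment
#' status.  The hidden truth (true efficiency, treated set, frontier
#' parameters) is attached as attribute `"truth"` and retrievable with
#' [panel_truth()].
#'
#' @param config a [synthetic_config()].
#' @return a `province_panel` with treatment columns attached and a
#'   `"truth"` attribute.
#' @export
generate_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  P <- config$n_provinces
  yrs <- config$years
  Tn <- length(yrs)
  provs <- sprintf("P%02d", seq_len(P))
  region <- rep(names(config$region_sizes), config$region_sizes)
  names(region) <- provs

  # staggered treatment draw, stratified by region when the default
  # pilot composition applies
  mix <- default_batch_mix(config)
  batch_year <- stats::setNames(rep(NA_integer_, P), provs)
  avail <- provs
  for (by in names(config$batches)) {
    y <- as.integer(by)
    if (!is.null(mix)) {
      pick <- character()
      for (rg in names(mix[[by]])) {
        pool <- avail[region[avail] == rg]
        pick <- c(pick, sample(pool, mix[[by]][[rg]]))
      }
    } else {
      pick <- sample(avail, config$batches[[by]])
    }
    batch_year[pick] <- y
    avail <- setdiff(avail, pick)
  }

  # log inputs: unit mean + growth trend + AR(1) innovation
  base <- c(HE = 6, HP = 4, MIB = 4.5, MI = 3.5)
  trend <- c(HE = 0.08, HP = 0.02, MIB = 0.03, MI = 0.01)
  rho <- config$input_persistence
  inputs <- list()
  for (nm in input_cols()) {
    mu <- stats::rnorm(P, base[[nm]], 0.3)
    z <- matrix(0, P, Tn)
    z[, 1] <- stats::rnorm(P, 0, 0.08 / sqrt(1 - rho^2))
    for (t in 2:Tn) z[, t] <- rho * z[, t - 1] + stats::rnorm(P, 0, 0.08)
    inputs[[nm]] <- exp(mu + outer(rep(1, P), (seq_len(Tn) - 1)) *
                          trend[[nm]] + z)
  }

  # true efficiency: inefficiency is mostly persistent (structural
  # province-level capacity) plus a smaller transient component; the
  # 3:1 split of the overall scale keeps province rankings stable over
  # time the way published provincial scores are
  s_u <- 0.75 * config$inefficiency_scale
  s_w <- 0.25 * config$inefficiency_scale
  u_unit <- abs(stats::rnorm(P, 0, s_u))
  u <- u_unit + matrix(abs(stats::rnorm(P * Tn, 0, s_w)), P, Tn)
  post <- outer(batch_year, yrs, function(b, y) !is.na(b) & y >= b)
  eff <- exp(-u) + config$delta * post

  # controls (unit heterogeneity, trends, mild treated/control shift)
  du <- as.numeric(!is.na(batch_year))
  tgrid <- seq_len(Tn) - 1
  mk <- function(lvl, unit_sd, du_shift, trend, noise) {
    ui <- stats::rnorm(P, 0, unit_sd) + du_shift * du
    lvl + outer(ui, rep(1, Tn)) + outer(rep(1, P), tgrid) * trend +
      matrix(stats::rnorm(P * Tn, 0, noise), P, Tn)
  }
  ctrl <- list(
    lnPGDP = mk(10.7, 0.4, 0.15, 0.030, 0.05),
    lnPOP  = mk(8.2, 0.7, -0.05, 0.005, 0.02),
    Gov    = pmin(pmax(mk(0.08, 0.015, 0, 0.0005, 0.004), 0.02), 0.30),
    Idu    = pmax(mk(1.2, 0.5, -0.1, 0.020, 0.05), 0.2),
    lnPat  = mk(9.4, 1.2, 0.2, 0.100, 0.08)
  )
  ce <- config$control_effects
  if (any(ce != 0)) {
    shift <- Reduce(`+`, Map(function(M, w) w * (M - mean(M)), ctrl, ce))
    eff <- eff + shift
  }

  # frontier outputs: Cobb-Douglas scaled by the region technology
  gamma <- c(HE = 0.25, HP = 0.35, MIB = 0.25, MI = 0.15)
  A <- config$group_tech_gap[region]
  cd <- Reduce(`*`, Map(function(M, g) M^g, inputs[input_cols()],
                        gamma[input_cols()]))
  noise <- function() exp(matrix(stats::rnorm(P * Tn, 0, config$noise_sd),
                                 P, Tn))
  OV <- 3 * A * cd * eff * noise()
  DR <- 90 * A^0.3 * eff * noise()
  BU <- 85 * A^0.3 * eff * noise()
  MOR <- 0.30 * sqrt(inputs$HP) * exp(u) * noise()
  EM <- 0.15 * sqrt(inputs$HP) * exp(u) * noise()

  flat <- function(M) as.vector(t(M))          # province-major, year-minor
  df <- data.frame(
    province = rep(provs, each = Tn),
    year = rep(yrs, times = P),
    region = rep(unname(region), each = Tn),
    HE = flat(inputs$HE), HP = flat(inputs$HP),
    MIB = flat(inputs$MIB), MI = flat(inputs$MI),
    OV = flat(OV), DR = flat(DR), BU = flat(BU),
    MOR = flat(MOR), EM = flat(EM),
    lnPGDP = flat(ctrl$lnPGDP), lnPOP = flat(ctrl$lnPOP),
    Gov = flat(ctrl$Gov), Idu = flat(ctrl$Idu), lnPat = flat(ctrl$lnPat),
    treat_batch = rep(ifelse(is.na(batch_year), "never",
                             as.character(batch_year)), each = Tn),
    stringsAsFactors = FALSE)
  panel <- province_panel(df)
  treated <- batch_year[!is.na(batch_year)]
  batches <- lapply(split(names(treated), treated), identity)
  panel <- attach_treatment(panel, batches)
  truth <- list(
    delta = config$delta,
    treated = treated,
    efficiency = data.frame(province = rep(provs, each = Tn),
                            year = rep(yrs, times = P),
                            true_eff = flat(eff),
                            u = flat(u), stringsAsFactors = FALSE),
    frontier = list(gamma = gamma, tech = config$group_tech_gap,
                    region = region),
    config = config)
  attr(panel, "truth") <- truth
  panel
}

#' Hidden truth of a synthetic panel
#'
#' @param panel a panel produced by [generate_panel()].
#' @return the truth record (`delta`, treated set, true efficiency,
#'   frontier parameters, config).
#' @export
panel_truth <- function(panel) {
  tr <- attr(panel, "truth")
  if (is.null(tr)) {
    stop_mraedid("panel carries no truth record", "truth_error")
  }
  tr
}

#' Small DEA instances with a known efficient set
#'
#' Builds toy reference datasets for oracle tests of the LP scorer:
#' `"dominant"` makes unit 1 strictly dominate every other unit
#' (less input, more desirable output, less undesirable output), so
#' the efficient set is exactly unit 1; `"ray"` places all units on a
#' common ray, so under constant returns every unit is efficient;
#' `"random"` draws positive data freely.
#'
#' @param n_dmus number of units (>= 2).
#' @param dims named vector `c(N = , M = , I = )` of input /
#'   desirable / undesirable dimensions.
#' @param type instance family.
#' @param seed RNG seed (set when not `NULL`).
#' @return list `X`, `Y`, `B`, `type`, and `efficient` (indices, or
#'   `NA` when analytically unknown).
#' @export
generate_dea_toy <- function(n_dmus = 5L, dims = c(N = 2, M = 2, I = 1),
                             type = c("random", "dominant", "ray"),
                             seed = NULL) {
  type <- match.arg(type)
  if (n_dmus < 2L) stop_mraedid("need at least 2 DMUs", "config_error")
  if (!is.null(seed)) set.seed(seed)
  N <- dims[["N"]]; M <- dims[["M"]]; I <- dims[["I"]]
  rmat <- function(r, c, mean = 0) matrix(exp(stats::rnorm(r * c, mean, 0.4)),
                                          r, c)
  if (type == "ray") {
    scale <- exp(stats::rnorm(n_dmus, 0, 0.5))
    X <- outer(exp(stats::rnorm(N, 0, 0.3)), scale)
    Y <- outer(exp(stats::rnorm(M, 0, 0.3)), scale)
    B <- outer(exp(stats::rnorm(I, 0, 0.3)), scale)
    eff_set <- seq_len(n_dmus)
  } else {
    X <- rmat(N, n_dmus); Y <- rmat(M, n_dmus); B <- rmat(I, n_dmus)
    if (type == "dominant") {
      X[, 1] <- apply(X, 1, min) * 0.8
      Y[, 1] <- apply(Y, 1, max) * 1.25
      B[, 1] <- apply(B, 1, min) * 0.8
      eff_set <- 1L
    } else {
      eff_set <- NA_integer_
    }
  }
  list(X = X, Y = Y, B = B, type = type, efficient = eff_set)
}

#' Pairwise-dominance pre-filter
#'
#' Unit j is dominated if some other unit uses no more of every input,
#' produces no less of every desirable output and no more of every
#' undesirable output, with at least one strict inequality.  Dominated
#' units can never be efficient, so this is a necessary-condition
#' check for the LP scorer.
#'
#' @param X,Y,B technology matrices (columns = units).
#' @return logical vector, `TRUE` where the unit is dominated.
#' @export
dominated_units <- function(X, Y, B) {
  J <- ncol(X)
  vapply(seq_len(J), function(j) {
    any(vapply(setdiff(seq_len(J), j), function(k) {
      wk <- all(X[, k] <= X[, j]) && all(Y[, k] >= Y[, j]) &&
        all(B[, k] <= B[, j])
      strict <- any(X[, k] < X[, j]) || any(Y[, k] > Y[, j]) ||
        any(B[, k] < B[, j])
      wk && strict
    }, logical(1)))
  }, logical(1))
}
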