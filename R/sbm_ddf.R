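#' Reference technology for DEA scoring
#'
#' Bundles the observed inputs `X` (N x J), desirable outputs `Y`
#' (M x J) and undesirable outputs `B` (I x J) of the J reference
#' decision-making units (DMUs) that span the production possibility
#' set, together with the returns-to-scale assumption.
#'
#' @param X,Y,B numeric matrices with one column per reference DMU;
#'   all entries must be strictly positive.
#' @param rts `"CRS"` (constant returns, intensity weights free) or
#'   `"VRS"` (variable returns, weights sum to one).
#' @return a `reference_technology` list.
#' @export
reference_technology <- function(X, Y, B, rts = c("CRS", "VRS")) {
  rts <- match.arg(rts)
  X <- as.matrix(X); Y <- as.matrix(Y); B <- as.matrix(B)
  J <- ncol(X)
  if (J < 1L || ncol(Y) != J || ncol(B) != J) {
    stop_mraedid("X, Y, B must share a positive number of columns",
                 "technology_error")
  }
  if (any(X <= 0) || any(Y <= 0) || any(B <= 0)) {
    stop_mraedid("reference technology entries must be strictly positive",
                 "technology_error")
  }
  structure(list(X = X, Y = Y, B = B, rts = rts, J = J),
            class = "reference_technology")
}

#' Direction vector of the directional distance function
#'
#' The direction `g = (g_x, g_y, g_b)` along which slacks are scaled in
#' the SBM-DDF objective.  The default throughout the package is the
#' evaluated DMU's own observed quantities, which makes the score
#' unit-free.
#'
#' @param g_x,g_y,g_b strictly positive numeric vectors for inputs,
#'   desirable outputs and undesirable outputs.
#' @return a `direction_vector` list.
#' @export
direction_vector <- function(g_x, g_y, g_b) {
  if (any(c(g_x, g_y, g_b) <= 0)) {
    stop_mraedid("direction vector must be strictly positive in every component",
                 "direction_error")
  }
  structure(list(g_x = as.numeric(g_x), g_y = as.numeric(g_y),
                 g_b = as.numeric(g_b)),
            class = "direction_vector")
}

#' Score one DMU with the SBM-DDF linear program
#'
#' Solves the slacks-based-measure directional-distance-function
#' program of Fukuyama and Weber for one DMU `(x0, y0, b0)` against a
#' [reference_technology()].  The program maximises the weighted mean
#' of slack-to-direction ratios
#' \deqn{\frac12\Big[\frac1N\sum_n \frac{s^x_n}{g^x_n}
#'   + \frac{1}{M+I}\Big(\sum_m \frac{s^y_m}{g^y_m}
#'   + \sum_i \frac{s^b_i}{g^b_i}\Big)\Big]}
#' subject to \eqn{X\lambda + s^x = x_0}, \eqn{Y\lambda - s^y = y_0},
#' \eqn{B\lambda + s^b = b_0}, \eqn{\lambda \ge 0} (and
#' \eqn{\sum\lambda = 1} under VRS), so desirable and undesirable
#' outputs may adjust by different amounts.  With `g` equal to the
#' DMU's own observed quantities the optimum is the unit's
#' inefficiency; efficiency is `1 - inefficiency`.
#'
#' Slacks are substituted out, leaving a linear program in the
#' intensity weights \eqn{\lambda} alone, solved by the package's
#' dense simplex; rows are normalised by the direction so the tableau
#' is well scaled regardless of measurement units.
#'
#' @param x0,y0,b0 strictly positive vectors for the evaluated DMU.
#' @param ref a [reference_technology()].
#' @param dir a [direction_vector()], or `NULL` for the default
#'   `g = (x0, y0, b0)`.
#' @param weights optional list with elements `w_x`, `w_y`, `w_b`
#'   overriding the Fukuyama-Weber objective weights
#'   (`1/(2N)` per input, `1/(2(M+I))` per output).
#' @param tol solver feasibility/optimality tolerance.
#' @return a `dea_solution`: `inefficiency`, slack vectors `s_x`,
#'   `s_y`, `s_b`, intensity weights `lambda`, and `status`.
#' @export
solve_sbm_ddf <- function(x0, y0, b0, ref, dir = NULL, weights = NULL,
                          tol = 1e-9) {
  stopifnot(inherits(ref, "reference_technology"))
  x0 <- as.numeric(x0); y0 <- as.numeric(y0); b0 <- as.numeric(b0)
  N <- nrow(ref$X); M <- nrow(ref$Y); I <- nrow(ref$B)
  if (length(x0) != N || length(y0) != M || length(b0) != I) {
    stop_mraedid("DMU dimensions do not match the reference technology",
                 "dimension_error")
  }
  if (any(c(x0, y0, b0) <= 0)) {
    stop_mraedid("evaluated DMU must be strictly positive in every component",
                 "dea_input_error")
  }
  if (is.null(dir)) dir <- direction_vector(x0, y0, b0)
  if (length(dir$g_x) != N || length(dir$g_y) != M || length(dir$g_b) != I) {
    stop_mraedid("direction vector dimensions do not match", "dimension_error")
  }
  w_x <- weights$w_x %||% rep(1 / (2 * N), N)
  w_y <- weights$w_y %||% rep(1 / (2 * (M + I)), M)
  w_b <- weights$w_b %||% rep(1 / (2 * (M + I)), I)

  # substitute slacks: s_x = x0 - X l, s_y = Y l - y0, s_b = b0 - B l.
  # objective in lambda:  c'l + const
  Xg <- ref$X / dir$g_x   # rows scaled by direction (recycled by row)
  Yg <- ref$Y / dir$g_y
  Bg <- ref$B / dir$g_b
  cvec <- -as.vector(crossprod(Xg, w_x)) +
    as.vector(crossprod(Yg, w_y)) -
    as.vector(crossprod(Bg, w_b))
  const <- sum(w_x * x0 / dir$g_x) - sum(w_y * y0 / dir$g_y) +
    sum(w_b * b0 / dir$g_b)

  A_le <- rbind(ref$X / x0, ref$B / b0)        # X l <= x0, B l <= b0
  b_le <- rep(1, N + I)
  A_ge <- ref$Y / y0                           # Y l >= y0
  b_ge <- rep(1, M)
  A_eq <- NULL; b_eq <- NULL
  if (ref$rts == "VRS") {
    A_eq <- matrix(1, 1, ref$J); b_eq <- 1
  }
  sol <- lp_solve_max(cvec, A_le = A_le, b_le = b_le,
                      A_ge = A_ge, b_ge = b_ge,
                      A_eq = A_eq, b_eq = b_eq, tol = tol)
  if (sol$status == "infeasible") {
    stop_mraedid("SBM-DDF program infeasible for this DMU (can occur under VRS)",
                 "dea_infeasible_error",
                 list(dmu = list(x0 = x0, y0 = y0, b0 = b0), rts = ref$rts))
  }
  if (sol$status != "optimal") {
    stop_mraedid(paste0("LP solver did not converge: status ", sol$status),
                 "dea_numerical_error", list(status = sol$status))
  }
  lambda <- sol$x
  s_x <- pmax(x0 - as.vector(ref$X %*% lambda), 0)
  s_y <- pmax(as.vector(ref$Y %*% lambda) - y0, 0)
  s_b <- pmax(b0 - as.vector(ref$B %*% lambda), 0)
  structure(list(inefficiency = sol$value + const,
                 s_x = s_x, s_y = s_y, s_b = s_b,
                 lambda = lambda, status = "optimal"),
            class = "dea_solution")
}

#' Efficiency score from an SBM-DDF solution
#'
#' With the direction set to the DMU's own observed quantities the
#' inefficiency lies in `[0, 1]` up to solver round-off; the efficiency
#' score is `1 - inefficiency`, clipped to `[0, 1]`.  A score of 1
#' means the unit sits on the production frontier.
#'
#' @param sol a `dea_solution` from [solve_sbm_ddf()].
#' @return efficiency score in `[0, 1]`.
#' @export
efficiency_from_solution <- function(sol) {
  stopifnot(inherits(sol, "dea_solution"))
  if (sol$status != "optimal") {
    stop_mraedid("solution is not optimal", "dea_state_error")
  }
  min(max(1 - sol$inefficiency, 0), 1)
}

# extract the (x, y, b) columns of a set of panel rows as matrices
panel_xyb <- function(df) {
  list(X = t(as.matrix(df[, input_cols()])),
       Y = t(as.matrix(df[, desirable_cols()])),
       B = t(as.matrix(df[, undesirable_cols()])))
}

#' Score every province-year in a panel
#'
#' Batch driver: scores each unit-period against the reference
#' technology named by `scope` (see [frontier_scope()]); the reference
#' pools observations over all years by default, so a single
#' intertemporal frontier is used per scope.
#'
#' @param panel a `province_panel`.
#' @param scope a [frontier_scope()].
#' @param rts returns-to-scale assumption passed to the technology.
#' @param tol solver tolerance.
#' @return an efficiency table: data frame `province`, `year`,
#'   `scope`, `efficiency`.
#' @export
score_all <- function(panel, scope = frontier_scope("meta"),
                      rts = "CRS", tol = 1e-9) {
  stopifnot(inherits(panel, "province_panel"),
            inherits(scope, "frontier_scope"))
  df <- as.data.frame(panel)
  if (scope$kind == "meta") {
    member <- stats::setNames(rep("all", length(attr(panel, "provinces"))),
                              attr(panel, "provinces"))
  } else {
    member <- scope$grouping
    uncovered <- setdiff(attr(panel, "provinces"), names(member))
    if (length(uncovered)) {
      stop_mraedid(paste0("grouping does not cover province(s): ",
                          paste(uncovered, collapse = ", ")),
                   "grouping_error")
    }
  }
  df$.group <- member[df$province]
  eff <- numeric(nrow(df))
  for (g in unique(df$.group)) {
    rows <- which(df$.group == g)
    for (r in rows) {
      ref_rows <- if (scope$pooling == "pooled_years") rows
                  else rows[df$year[rows] == df$year[r]]
      mats <- panel_xyb(df[ref_rows, , drop = FALSE])
      ref <- reference_technology(mats$X, mats$Y, mats$B, rts = rts)
      sol <- tryCatch(
        solve_sbm_ddf(as.numeric(df[r, input_cols()]),
                      as.numeric(df[r, desirable_cols()]),
                      as.numeric(df[r, undesirable_cols()]),
                      ref, tol = tol),
        mraedid_error = function(e) {
          stop_mraedid(sprintf("scoring failed for (%s, %d): %s",
                               df$province[r], df$year[r],
                               conditionMessage(e)),
                       "dea_batch_error")
        })
      eff[r] <- efficiency_from_solution(sol)
    }
  }
  out <- data.frame(province = df$province, year = df$year,
                    scope = scope$kind, efficiency = eff,
                    stringsAsFactors = FALSE)
  class(out) <- c("efficiency_table", "data.frame")
  out
}
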