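#' Dense linear-program solver (two-phase primal simplex)
#'
#' Solves `max c'x` subject to `A_le x <= b_le`, `A_ge x >= b_ge`,
#' `A_eq x == b_eq`, `x >= 0`.  Written for the small, dense LPs that
#' arise when scoring one decision-making unit against a reference
#' technology: a handful of constraint rows and up to a few hundred
#' intensity variables.  Phase one minimises the sum of artificial
#' variables; phase two optimises the user objective.  Dantzig pricing
#' with a switch to Bland's rule guards against cycling.
#'
#' @param obj numeric objective coefficients (maximised).
#' @param A_le,b_le inequality block `A_le x <= b_le` (or `NULL`).
#' @param A_ge,b_ge inequality block `A_ge x >= b_ge` (or `NULL`).
#' @param A_eq,b_eq equality block `A_eq x == b_eq` (or `NULL`).
#' @param tol numerical tolerance for pivoting and feasibility.
#' @param maxit iteration cap per phase.
#'
#' @return list with `x` (optimal point), `value` (objective at `x`),
#'   and `status`: `"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"maxit"`.
#' @keywords internal
lp_solve_max <- function(obj,
                         A_le = NULL, b_le = NULL,
                         A_ge = NULL, b_ge = NULL,
                         A_eq = NULL, b_eq = NULL,
                         tol = 1e-9, maxit = 10000L) {
  nv <- length(obj)
  blk <- function(A, b, nm) {
    if (is.null(A)) {
      return(list(A = matrix(0, 0, nv), b = numeric(0)))
    }
    A <- matrix(as.numeric(A), ncol = nv)
    stopifnot(length(b) == nrow(A))
    list(A = A, b = as.numeric(b))
  }
  le <- blk(A_le, b_le)
  ge <- blk(A_ge, b_ge)
  eq <- blk(A_eq, b_eq)

  # canonical rows: A x (=) b with b >= 0; record the slack sign per row
  A <- rbind(le$A, ge$A, eq$A)
  b <- c(le$b, ge$b, eq$b)
  slack_sign <- c(rep(1, nrow(le$A)), rep(-1, nrow(ge$A)), rep(0, nrow(eq$A)))
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  slack_sign[neg] <- -slack_sign[neg]

  m <- nrow(A)
  if (m == 0L) {
    # unconstrained except x >= 0
    if (any(obj > tol)) {
      return(list(x = rep(0, nv), value = Inf, status = "unbounded"))
    }
    return(list(x = rep(0, nv), value = 0, status = "optimal"))
  }

  # columns: structural | slacks/surpluses | artificials
  n_slack <- sum(slack_sign != 0)
  slack_col <- integer(m)
  Smat <- matrix(0, m, n_slack)
  k <- 0L
  for (i in seq_len(m)) {
    if (slack_sign[i] != 0) {
      k <- k + 1L
      Smat[i, k] <- slack_sign[i]
      slack_col[i] <- nv + k
    }
  }
  # rows needing an artificial: surplus rows and equality rows
  need_art <- slack_sign <= 0
  n_art <- sum(need_art)
  Amat <- matrix(0, m, n_art)
  art_col <- integer(m)
  k <- 0L
  for (i in seq_len(m)) {
    if (need_art[i]) {
      k <- k + 1L
      Amat[i, k] <- 1
      art_col[i] <- nv + n_slack + k
    }
  }
  Tab <- cbind(A, Smat, Amat, b)
  ntot <- nv + n_slack + n_art
  basis <- ifelse(need_art, art_col, slack_col)
  art_cols <- which(seq_len(ntot) > nv + n_slack)

  run <- function(Tab, basis, cost) {
    m <- nrow(Tab)
    n <- ncol(Tab) - 1L
    for (it in seq_len(maxit)) {
      rc <- cost - as.vector(crossprod(Tab[, seq_len(n), drop = FALSE],
                                       cost[basis]))
      cand <- which(rc < -tol)
      if (!length(cand)) {
        return(list(Tab = Tab, basis = basis, status = "optimal"))
      }
      bland <- it > maxit %/% 2L
      j <- if (bland) cand[1L] else cand[which.min(rc[cand])]
      col <- Tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) {
        return(list(Tab = Tab, basis = basis, status = "unbounded"))
      }
      ratio <- Tab[pos, n + 1L] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol]
      i <- if (bland) ties[which.min(basis[ties])] else ties[1L]
      piv <- Tab[i, j]
      Tab[i, ] <- Tab[i, ] / piv
      rest <- setdiff(seq_len(m), i)
      Tab[rest, ] <- Tab[rest, ] - outer(Tab[rest, j], Tab[i, ])
      basis[i] <- j
    }
    list(Tab = Tab, basis = basis, status = "maxit")
  }

  # phase 1: drive artificials to zero
  if (n_art > 0L) {
    cost1 <- c(rep(0, nv + n_slack), rep(1, n_art))
    r1 <- run(Tab, basis, cost1)
    if (r1$status != "optimal") {
      return(list(x = rep(NA_real_, nv), value = NA_real_, status = r1$status))
    }
    Tab <- r1$Tab
    basis <- r1$basis
    p1val <- sum(cost1[basis] * Tab[, ncol(Tab)])
    if (p1val > sqrt(tol)) {
      return(list(x = rep(NA_real_, nv), value = NA_real_,
                  status = "infeasible"))
    }
    # pivot out any artificial still basic at zero level
    for (i in which(basis %in% art_cols)) {
      row <- Tab[i, seq_len(nv + n_slack)]
      j <- which(abs(row) > tol)[1L]
      if (!is.na(j)) {
        piv <- Tab[i, j]
        Tab[i, ] <- Tab[i, ] / piv
        rest <- setdiff(seq_len(nrow(Tab)), i)
        Tab[rest, ] <- Tab[rest, ] - outer(Tab[rest, j], Tab[i, ])
        basis[i] <- j
      }
    }
    # neutralise artificial columns so they can never re-enter
    Tab[, art_cols] <- 0
  }

  cost2 <- c(-obj, rep(0, n_slack + n_art))  # simplex core minimises
  r2 <- run(Tab, basis, cost2)
  if (r2$status == "unbounded") {
    return(list(x = rep(NA_real_, nv), value = Inf, status = "unbounded"))
  }
  Tab <- r2$Tab
  basis <- r2$basis
  x <- numeric(ntot)
  x[basis] <- Tab[, ncol(Tab)]
  xs <- x[seq_len(nv)]
  list(x = xs, value = sum(obj * xs), status = r2$status)
}
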