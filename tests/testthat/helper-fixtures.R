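# Shared fixtures: small panels built in code, and the independent
# vertex-enumeration oracle used to check the simplex-based scorer.

# minimal valid panel with arbitrary province names (constant-ish data)
make_flat_panel <- function(provinces, years = 2009:2021,
                            regions = NULL, seed = 1) {
  set.seed(seed)
  n <- length(provinces) * length(years)
  if (is.null(regions)) regions <- rep("East", length(provinces))
  df <- data.frame(
    province = rep(provinces, each = length(years)),
    year = rep(years, times = length(provinces)),
    region = rep(regions, each = length(years)),
    HE = exp(rnorm(n, 6, 0.1)), HP = exp(rnorm(n, 4, 0.1)),
    MIB = exp(rnorm(n, 4.5, 0.1)), MI = exp(rnorm(n, 3.5, 0.1)),
    OV = exp(rnorm(n, 5, 0.1)), DR = runif(n, 70, 95),
    BU = runif(n, 70, 95), MOR = exp(rnorm(n, 0, 0.1)),
    EM = exp(rnorm(n, -0.5, 0.1)),
    lnPGDP = rnorm(n, 10.7, 0.3), lnPOP = rnorm(n, 8.2, 0.5),
    Gov = runif(n, 0.05, 0.12), Idu = runif(n, 0.8, 1.8),
    lnPat = rnorm(n, 9.4, 0.8),
    treat_batch = "never", stringsAsFactors = FALSE)
  province_panel(df)
}

# a small synthetic panel (fast DEA problem sizes)
small_synth <- function(seed, n_prov = 9, years = 2011:2016,
                        batches = list("2015" = 2), delta = 0.03, ...) {
  sizes <- c(East = ceiling(n_prov / 3),
             Central = floor(n_prov / 3),
             West = n_prov - ceiling(n_prov / 3) - floor(n_prov / 3))
  generate_panel(synthetic_config(
    n_provinces = n_prov, years = years, region_sizes = sizes,
    batches = batches, delta = delta, seed = seed, ...))
}

# merge a score table into the panel data frame as `mrae`
with_outcome <- function(panel, scores, col = "efficiency") {
  df <- as.data.frame(panel)
  key <- paste(df$province, df$year)
  df$mrae <- scores[[col]][match(key, paste(scores$province, scores$year))]
  df
}

# data frame with the true efficiency as outcome
with_true_outcome <- function(panel) {
  tr <- panel_truth(panel)$efficiency
  df <- as.data.frame(panel)
  key <- paste(df$province, df$year)
  df$mrae <- tr$true_eff[match(key, paste(tr$province, tr$year))]
  df
}

# independent oracle for max a'l s.t. A l <= b, l >= 0: enumerate all
# basic solutions (vertices) and take the best feasible one
lp_vertex_oracle <- function(a, A, b) {
  A <- rbind(A, -diag(length(a)))
  b <- c(b, rep(0, length(a)))
  J <- length(a)
  best <- -Inf
  idx <- utils::combn(nrow(A), J)
  for (k in seq_len(ncol(idx))) {
    S <- idx[, k]
    As <- A[S, , drop = FALSE]
    d <- tryCatch(abs(det(As)), error = function(e) 0)
    if (d < 1e-10) next
    l <- tryCatch(solve(As, b[S]), error = function(e) NULL)
    if (is.null(l)) next
    if (all(A %*% l <= b + 1e-8)) best <- max(best, sum(a * l))
  }
  best
}

# SBM-DDF inefficiency for one DMU computed entirely through the
# vertex oracle (no shared code with solve_sbm_ddf beyond the data)
sbm_oracle <- function(x0, y0, b0, X, Y, B) {
  N <- length(x0); M <- length(y0); I <- length(b0)
  w_in <- 1 / (2 * N); w_out <- 1 / (2 * (M + I))
  a <- -w_in * colSums(X / x0) + w_out * colSums(Y / y0) -
    w_out * colSums(B / b0)
  A <- rbind(X / x0, B / b0, -Y / y0)
  bb <- c(rep(1, N + I), rep(-1, M))
  const <- w_in * N - w_out * M + w_out * I
  lp_vertex_oracle(a, A, bb) + const
}

# random small SBM instance
random_sbm_instance <- function(J, N = 2, M = 2, I = 1) {
  list(X = matrix(exp(rnorm(N * J, 0, 0.5)), N, J),
       Y = matrix(exp(rnorm(M * J, 0, 0.5)), M, J),
       B = matrix(exp(rnorm(I * J, 0, 0.5)), I, J))
}
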