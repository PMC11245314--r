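# Shared test utilities: independent oracles and small statistical helpers.

# Dense-scan chord oracle: feasibility of origin + lambda * d on a fine grid
# over a bracketing interval; independent of the analytic ratio formula.
chord_by_scan <- function(P, origin, direction, span = 10, grid = 1e6) {
  lambdas <- seq(-span, span, length.out = grid)
  shifts <- outer(lambdas, as.numeric(P$A %*% direction))
  slack0 <- as.numeric(P$b - P$A %*% origin)
  feas <- rowSums(shifts > rep(slack0, each = grid)) == 0
  inside <- which(feas)
  c(lambdas[min(inside)], lambdas[max(inside)])
}

# mean / variance z-scores with ESS-based standard errors, per dimension
moment_z <- function(draws3d, true_mean, true_var) {
  ess <- effective_sample_size(draws3d)
  nd <- dim(draws3d)[3]
  stats <- vapply(seq_len(nd), function(d) {
    v <- as.vector(draws3d[, , d])
    m <- mean(v)
    c(m, stats::var(v), mean((v - m)^4))
  }, numeric(3))
  zm <- abs(stats[1, ] - true_mean) / sqrt(true_var / ess)
  zv <- abs(stats[2, ] - true_var) /
    sqrt(pmax(stats[3, ] - true_var^2, 1e-12) / ess)
  list(z_mean = zm, z_var = zv, ess = ess)
}

# chi-squared uniformity statistic over a fixed partition of the simplex:
# cells are indexed by which coordinate bin each of the first two
# coordinates falls into. Counts are scaled by ESS/N to account for
# autocorrelation before comparison with the chi-squared quantile.
simplex_chi2_pvalue <- function(draws2d, ess) {
  stopifnot(ncol(draws2d) >= 2)
  # 20 cells: 4 bins on x1 conditional scale, 5 on x2 conditional scale
  u1 <- 1 - (1 - draws2d[, 1])^3        # Beta(1,3) PIT -> uniform
  rest <- pmax(1 - draws2d[, 1], 1e-12)
  u2 <- 1 - (1 - draws2d[, 2] / rest)^2 # conditional Beta(1,2) PIT
  cell <- (pmin(floor(u1 * 4), 3)) * 5 + pmin(floor(u2 * 5), 4) + 1
  n_eff <- min(ess)
  counts <- tabulate(cell, nbins = 20)
  p_hat <- counts / sum(counts)
  stat <- n_eff * sum((p_hat - 1 / 20)^2 / (1 / 20))
  stats::pchisq(stat, df = 19, lower.tail = FALSE)
}

expect_cw_error <- function(expr, class) {
  expect_error(expr, class = class)
}
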