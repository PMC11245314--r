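test_that("polytope construction validates shapes and finiteness", {
  expect_s3_class(polytope(diag(2), c(1, 1)), "polytope")
  expect_cw_error(polytope(diag(2), c(1, 1, 1)), "cw_dim_error")
  expect_cw_error(polytope(matrix(c(1, NA), 1), 1), "cw_validation_error")
  expect_cw_error(polytope(matrix(0, 1, 2), -1), "cw_validation_error")
})

test_that("membership respects tolerance and dimension", {
  P <- hypercube(2)
  expect_true(contains(P, c(0.5, 0.5), tol = 0))
  expect_false(contains(P, c(1.5, 0.5), tol = 0))
  expect_true(contains(P, c(1 + 1e-12, 0.5), tol = 1e-9))
  expect_cw_error(contains(P, c(0.5, 0.5, 0.5)), "cw_dim_error")
})

test_that("chord bounds match closed forms on the unit square", {
  P <- hypercube(2)
  cb <- chord_bounds(P, c(0.5, 0.5), c(1, 0))
  expect_equal(unname(cb), c(-0.5, 0.5))
  cb_diag <- chord_bounds(P, c(0.5, 0.5), c(1, 1) / sqrt(2))
  expect_equal(unname(cb_diag), c(-sqrt(2) / 2, sqrt(2) / 2))
  # errors
  expect_cw_error(chord_bounds(P, c(1, 0.5), c(1, 0)), "cw_feasibility_error")
  expect_cw_error(chord_bounds(polytope(matrix(c(1, 0), 1), 1),
                               c(0, 0), c(1, 0)),
                  "cw_unbounded_error")
  expect_cw_error(chord_bounds(P, c(0.5, 0.5), c(0, 0)),
                  "cw_validation_error")
})

test_that("chord bounds agree with a dense-scan oracle on a random 5D polytope", {
  rng <- make_rng(7, 0)
  # random bounded polytope: box plus random cutting planes
  n <- 5
  A <- rbind(diag(n), -diag(n))
  b <- rep(1, 2 * n)
  for (i in 1:6) {
    a <- rng_normal(rng, n)
    a <- a / sqrt(sum(a^2))
    x <- 0.5 * (rng_uniform(rng, n) - 0.5)
    if (sum(a * x) < 0) a <- -a
    A <- rbind(A, a)
    b <- c(b, sum(a * x) + 0.1)
  }
  P <- polytope(A, b)
  origin <- rep(0, n)
  for (rep_i in 1:3) {
    d <- rng_normal(rng, n)
    d <- d / sqrt(sum(d^2))
    cb <- chord_bounds(P, origin, d)
    scan <- chord_by_scan(P, origin, d, span = 3, grid = 1e6)
    res <- 6 / 1e6
    expect_lt(abs(cb[[1]] - scan[1]), 2 * res)
    expect_lt(abs(cb[[2]] - scan[2]), 2 * res)
    # endpoints are members at tolerance
    expect_true(contains(P, origin + cb[[1]] * d, tol = 1e-9))
    expect_true(contains(P, origin + cb[[2]] * d, tol = 1e-9))
  }
})

test_that("chebyshev center solves the inscribed-ball program", {
  cc <- chebyshev_center(hypercube(2))
  expect_equal(cc$center, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(cc$radius, 0.5, tolerance = 1e-8)
  # right isoceles triangle: incircle radius (2 - sqrt(2)) / 2
  tri <- polytope(rbind(c(-1, 0), c(0, -1), c(1, 1)), c(0, 0, 1))
  expect_equal(chebyshev_center(tri)$radius, (2 - sqrt(2)) / 2,
               tolerance = 1e-8)
  expect_cw_error(chebyshev_center(polytope(rbind(1, -1), c(0, -1))),
                  "cw_feasibility_error")
})

test_that("chebyshev radius is certified feasible and optimal", {
  rng <- make_rng(11, 0)
  n_pracma <- 0
  for (rep_i in 1:5) {
    n <- 3
    A <- rbind(diag(n), -diag(n), matrix(rng_normal(rng, 2 * n), 2))
    b <- c(rep(1, 2 * n), 1, 1)
    P <- polytope(A, b)
    rn <- sqrt(rowSums(A^2))
    cc <- chebyshev_center(P)
    # certificate: the reported ball fits
    expect_lt(max(A %*% cc$center + cc$radius * rn - b), 1e-8)
    # optimality oracle: no random candidate center inscribes a larger ball
    cand <- matrix(2.2 * rng_uniform(rng, 2000 * n) - 1.1, ncol = n)
    inscribed <- apply(cand, 1, function(x) {
      min((b - as.numeric(A %*% x)) / rn)
    })
    expect_lt(max(inscribed), cc$radius + 1e-6)
    # where the external LP solver converges, values must agree
    if (requireNamespace("pracma", quietly = TRUE)) {
      sol <- tryCatch(
        pracma::linprog(c(rep(0, 2 * n), 1), A = cbind(A, -A, rn), b = b,
                        maximize = TRUE, maxiter = 500),
        error = function(e) NULL)
      if (!is.null(sol) && isTRUE(sol$errno == 1)) {
        n_pracma <- n_pracma + 1
        expect_equal(cc$radius, sol$fval, tolerance = 1e-6)
      }
    }
  }
})

test_that("redundant constraints are removed and the point set is unchanged", {
  P <- hypercube(2)
  dup <- polytope(rbind(P$A, c(1, 0)), c(P$b, 1))
  expect_equal(nrow(remove_redundant_constraints(dup)$A), 4)
  dom <- polytope(rbind(P$A, c(1, 0)), c(P$b, 2))
  out <- remove_redundant_constraints(dom)
  expect_equal(nrow(out$A), 4)
  expect_cw_error(remove_redundant_constraints(
    polytope(rbind(1, -1), c(0, -1))), "cw_feasibility_error")
})

test_that("redundancy removal preserves membership on a random 4D fixture", {
  rng <- make_rng(13, 0)
  n <- 4
  A <- rbind(diag(n), -diag(n))
  b <- rep(1, 2 * n)
  # plant 10 redundant rows: weakened copies of existing constraints
  for (i in 1:10) {
    j <- rng_integer(rng, 1, nrow(A))
    A <- rbind(A, A[j, ])
    b <- c(b, b[j] + rng_uniform(rng, 1))
  }
  P <- polytope(A, b)
  out <- remove_redundant_constraints(P)
  expect_equal(nrow(out$A), 2 * n)
  pts <- matrix(3 * rng_uniform(rng, 1e4 * n) - 1.5, ncol = n)
  in_old <- apply(pts, 1, function(p) contains(P, p))
  in_new <- apply(pts, 1, function(p) contains(out, p))
  expect_identical(in_old, in_new)
  # idempotence
  twice <- remove_redundant_constraints(out)
  expect_equal(twice$A, out$A)
  expect_equal(twice$b, out$b)
})

test_that("equality embedding reduces dimension and round-trips", {
  # sum-to-one on 5 nonnegative variables -> reduced dimension 4
  sx <- simplex_polytope(5, implicit = TRUE)
  emb <- embed_equalities(sx$equalities, sx$polytope)
  expect_equal(polytope_dim(emb$polytope), 4)
  rng <- make_rng(3, 0)
  cc <- chebyshev_center(emb$polytope)
  for (i in 1:20) {
    z <- cc$center + 0.5 * cc$radius * rng_normal(rng, 4) / sqrt(4)
    full <- map_point(emb$transform, z)
    expect_lt(abs(sum(full) - 1), 1e-10)
    # orthonormal basis: transpose inverts the map
    back <- as.numeric(t(emb$transform$basis) %*%
                         (full - emb$transform$shift))
    expect_lt(max(abs(back - z)), 1e-10)
  }
  # full-rank system pins a single point
  expect_cw_error(
    embed_equalities(equality_system(diag(3), c(1, 2, 3)), hypercube(3)),
    "cw_degenerate_error")
  # inconsistent system
  expect_cw_error(
    embed_equalities(equality_system(rbind(c(1, 1), c(1, 1)), c(1, 2)),
                     hypercube(2)),
    "cw_inconsistent_error")
})

test_that("standard polytope factories have the documented geometry", {
  h1 <- hypercube(1)
  expect_equal(unname(h1$A), rbind(1, -1))
  expect_equal(h1$b, c(1, 0))
  expect_true(contains(hypercube(3), rep(0.5, 3)))
  for (n in c(2, 4, 7)) {
    expect_equal(chebyshev_center(hypercube(n))$radius, 0.5,
                 tolerance = 1e-8)
  }
  s2 <- simplex_polytope(2)
  expect_equal(nrow(s2$A), 3)
  expect_true(contains(s2, c(0.2, 0.2)))
  expect_false(contains(s2, c(0.6, 0.6)))
  expect_equal(chebyshev_center(s2)$radius, (2 - sqrt(2)) / 2,
               tolerance = 1e-8)
})

test_that("birkhoff reduced dimension is (n-1)^2 with a rank oracle", {
  expect_equal(polytope_dim(birkhoff_polytope(2)$polytope), 1)
  for (n in 2:6) {
    bk <- birkhoff_polytope(n)
    expect_equal(polytope_dim(bk$polytope), (n - 1)^2)
    # oracle: numerical rank of the stacked sum-constraint matrix is 2n - 1
    row_sum <- matrix(0, n, n * n)
    col_sum <- matrix(0, n, n * n)
    for (i in seq_len(n)) {
      row_sum[i, (seq_len(n) - 1) * n + i] <- 1
      col_sum[i, (i - 1) * n + seq_len(n)] <- 1
    }
    d <- svd(rbind(row_sum, col_sum))$d
    expect_equal(sum(d > max(d) * 2 * n * .Machine$double.eps), 2 * n - 1)
  }
  expect_cw_error(birkhoff_polytope(1), "cw_domain_error")
})

test_that("birkhoff samples map back to doubly stochastic matrices", {
  bk <- birkhoff_polytope(3)
  pb <- sampling_problem(bk$polytope, transform = bk$transform)
  sb <- sample_polytope(pb, n_chains = 1, n_samples = 200, seed = 2)
  for (i in c(1, 100, 200)) {
    M <- matrix(sb$draws[1, i, ], 3, 3)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-10)
    expect_lt(max(abs(colSums(M) - 1)), 1e-10)
    expect_gt(min(M), -1e-10)
  }
})
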