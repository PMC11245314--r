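test_that("chord-uniform hit-and-run accepts everything on a uniform target", {
  pb <- sampling_problem(hypercube(2))
  sb <- sample_polytope(pb, "hit_and_run", n_chains = 1, n_samples = 5000,
                        seed = 1)
  expect_equal(sb$acceptance_rates, 1)
})

test_that("1D hit-and-run proposals are uniform on the polytope (KS oracle)", {
  P <- polytope(rbind(1, -1), c(1, 0))
  pb <- sampling_problem(P)
  prop <- hit_and_run_proposal(pb, 0.3)
  rng <- make_rng(17, 0)
  draws <- vapply(1:10000, function(i) prop$propose(rng, 0.3)$point,
                  numeric(1))
  ks <- suppressWarnings(stats::ks.test(draws, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("coordinate hit-and-run changes one coordinate and picks axes fairly", {
  pb <- sampling_problem(hypercube(4))
  prop <- coordinate_hit_and_run_proposal(pb, rep(0.5, 4))
  rng <- make_rng(3, 0)
  x <- rep(0.5, 4)
  axis_count <- numeric(4)
  for (i in 1:10000) {
    y <- prop$propose(rng, x)$point
    changed <- which(y != x)
    expect_length(changed, 1)
    axis_count[changed] <- axis_count[changed] + 1
  }
  # fair-die bands: 3 sigma binomial
  p <- 1 / 4
  expect_true(all(abs(axis_count / 10000 - p) <
                    3 * sqrt(p * (1 - p) / 10000)))
})

test_that("gaussian hit-and-run stays on the chord and reports the exact correction", {
  pb <- sampling_problem(hypercube(2))
  prop <- gaussian_hit_and_run_proposal(pb, c(0.9, 0.9), step_size = 0.5)
  rng <- make_rng(9, 0)
  for (i in 1:200) {
    pr <- prop$propose(rng, c(0.9, 0.9))
    expect_true(contains(hypercube(2), pr$point, tol = 1e-9))
    expect_true(is.finite(pr$log_correction))
  }
  expect_cw_error(gaussian_hit_and_run_proposal(pb, c(0.5, 0.5),
                                                step_size = -1),
                  "cw_validation_error")
})

test_that("gaussian hit-and-run acceptance sits in a sensible band on a peaked target", {
  pb <- sampling_problem(hypercube(2),
                         gaussian_model(c(0.5, 0.5), diag(0.01, 2)))
  sb <- sample_polytope(pb, "gaussian_hit_and_run", n_chains = 1,
                        n_samples = 10000, seed = 1,
                        proposal_params = list(step_size = 0.05))
  expect_gt(sb$acceptance_rates, 0.2)
  expect_lt(sb$acceptance_rates, 0.9)
})

test_that("over-relaxation reflects through the chord midpoint", {
  # 1D: from 0.2 along +1 the chord is (-0.2, 0.8); candidate = 0.8
  P <- polytope(rbind(1, -1), c(1, 0))
  cb <- chord_bounds(P, 0.2, 1)
  expect_equal(unname(cb), c(-0.2, 0.8))
  expect_equal(0.2 + (cb[[1]] + cb[[2]]), 0.8)
  # center of the square is a fixed point of every reflection
  pb <- sampling_problem(hypercube(2))
  prop <- over_relaxed_hit_and_run_proposal(pb, c(0.5, 0.5))
  rng <- make_rng(2, 0)
  for (i in 1:50) {
    pr <- prop$propose(rng, c(0.5, 0.5))
    expect_equal(pr$point, c(0.5, 0.5), tolerance = 1e-9)
  }
  # refuses non-uniform targets
  gauss <- sampling_problem(hypercube(2),
                            gaussian_model(c(0.5, 0.5), diag(2)))
  expect_cw_error(over_relaxed_hit_and_run_proposal(gauss, c(0.5, 0.5)),
                  "cw_unsupported_target_error")
})

test_that("over-relaxation induces antithetic moves with correct moments", {
  pb <- sampling_problem(hypercube(5))
  sb <- sample_polytope(pb, "over_relaxed_hit_and_run", n_chains = 1,
                        n_samples = 20000, seed = 1)
  mz <- moment_z(sb$draws, rep(0.5, 5), rep(1 / 12, 5))
  expect_true(all(mz$z_mean < 3))
  expect_true(all(mz$z_var < 3))
  # in 1D the reflection is x -> 1 - x: perfectly antithetic
  p1 <- sampling_problem(polytope(rbind(1, -1), c(1, 0)))
  s1 <- sample_polytope(p1, "over_relaxed_hit_and_run", n_chains = 1,
                        n_samples = 2000, seed = 1)
  lag1 <- stats::acf(as.vector(s1$draws), lag.max = 1,
                     plot = FALSE)$acf[2]
  expect_lt(lag1, -0.99)
  # the antithetic moves pay off as a higher effective sample size than
  # the plain chord-uniform kernel at the same budget
  ref <- sample_polytope(pb, "hit_and_run", n_chains = 1,
                         n_samples = 20000, seed = 1)
  expect_gt(min(effective_sample_size(sb$draws)),
            min(effective_sample_size(ref$draws)))
})

test_that("adaptive SVD freezes to a near-isotropic direction matrix on a cube", {
  pb <- sampling_problem(hypercube(4))
  ch <- init_chain(pb, "adaptive_svd", seed = 6,
                   proposal_params = list(update_interval = 500,
                                          adaptation_horizon = 10000))
  invisible(advance_chain(ch, 10500, 1))
  snap <- ch$proposal$snapshot()
  expect_true(snap$frozen)
  sv <- svd(snap$dirmat)$d
  # the empirical covariance of a round body is isotropic; with ~1e3
  # effective draws the eigenvalue spread of the square root stays under
  # ~3 x sqrt(2 / ess) ~ 15%
  expect_lt(max(sv) / min(sv), 1.15)
  expect_cw_error(adaptive_svd_proposal(pb, rep(0.5, 4),
                                        update_interval = 0),
                  "cw_validation_error")
})

test_that("adaptive SVD beats plain hit-and-run on an anisotropic box", {
  d <- withr::local_tempdir()
  mf <- make_fixture("stretched_box", n = 2, seed = 7, dir = d)
  P <- read_polytope(file.path(d, "polytope"))
  u <- mf$long_axis
  pb <- sampling_problem(P)
  plain <- sample_polytope(pb, "hit_and_run", n_chains = 1,
                           n_samples = 10000, seed = 1)
  adapt <- sample_polytope(pb, "adaptive_svd", n_chains = 1,
                           n_samples = 10000, seed = 1,
                           proposal_params = list(
                             update_interval = 200,
                             adaptation_horizon = 4000))
  drop <- adapt$meta$burn_in_draws
  ess_plain <- effective_sample_size(
    array(plain$draws[1, , ] %*% u, c(1, 10000, 1)))
  ess_adapt <- effective_sample_size(
    array(adapt$draws[1, (drop + 1):10000, ] %*% u,
          c(1, 10000 - drop, 1)))
  # per-step efficiency on the long axis
  expect_gt((ess_adapt / (10000 - drop)) / (ess_plain / 10000), 2)
})

test_that("covariance startup with a single observation falls back to isotropic", {
  pb <- sampling_problem(hypercube(3))
  prop <- adaptive_svd_proposal(pb, rep(0.5, 3), update_interval = 1,
                                adaptation_horizon = 10)
  rng <- make_rng(1, 0)
  prop$advance(rep(0.5, 3)) # n_obs = 1: no update possible
  expect_null(prop$snapshot()$dirmat)
  pr <- prop$propose(rng, rep(0.5, 3))
  expect_true(contains(hypercube(3), pr$point, tol = 1e-9))
})

test_that("every shipped proposal preserves the uniform law on simplex(3)", {
  pb <- sampling_problem(simplex_polytope(3))
  props <- list(
    list(name = "hit_and_run"),
    list(name = "coordinate_hit_and_run"),
    list(name = "gaussian_hit_and_run", params = list(step_size = 1)),
    list(name = "over_relaxed_hit_and_run"),
    list(name = "adaptive_svd")
  )
  for (p in props) {
    sb <- sample_polytope(pb, p$name, n_chains = 1, n_samples = 20000,
                          seed = 1,
                          proposal_params = if (is.null(p$params)) list()
                                            else p$params)
    drop <- sb$meta$burn_in_draws
    x <- sb$draws[1, (drop + 1):20000, , drop = FALSE]
    ess <- effective_sample_size(x)
    pval <- simplex_chi2_pvalue(x[1, , ], ess)
    expect_gt(pval, 0.001)
  }
})

test_that("proposals are deterministic given (seed, start, config)", {
  pb <- sampling_problem(simplex_polytope(4))
  for (nm in c("hit_and_run", "coordinate_hit_and_run", "adaptive_svd")) {
    s1 <- sample_polytope(pb, nm, n_chains = 2, n_samples = 300, seed = 12)
    s2 <- sample_polytope(pb, nm, n_chains = 2, n_samples = 300, seed = 12)
    expect_identical(s1$draws, s2$draws)
  }
})

test_that("the registry lists builtins and rejects unknown names", {
  expect_true(all(c("hit_and_run", "coordinate_hit_and_run",
                    "gaussian_hit_and_run", "over_relaxed_hit_and_run",
                    "adaptive_svd") %in% proposal_names()))
  pb <- sampling_problem(hypercube(2))
  err <- tryCatch(make_proposal("warp_drive", pb, c(0.5, 0.5)),
                  error = function(e) e)
  expect_s3_class(err, "cw_registry_error")
  expect_match(conditionMessage(err), "hit_and_run")
  # third-party registration integrates with the engine
  register_proposal("test_custom", function(problem, start) {
    hit_and_run_proposal(problem, start)
  })
  sb <- sample_polytope(pb, "test_custom", n_chains = 1, n_samples = 100,
                        seed = 1)
  ref <- sample_polytope(pb, "hit_and_run", n_chains = 1, n_samples = 100,
                         seed = 1)
  expect_identical(sb$draws, ref$draws)
})
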