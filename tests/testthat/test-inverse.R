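# Levenberg-Marquardt updates and the MoBIIR reconstruction loop.

test_that("cost_and_mse computes the L2 misfit and mean squared error", {
  expect_equal(cost_and_mse(c(1, 2), c(1, 2)), list(misfit = 0, mse = 0))
  cm <- cost_and_mse(c(1, 2), c(0, 0))
  expect_equal(cm$misfit, sqrt(5))
  expect_equal(cm$mse, 2.5)
  # homogeneity: scaling both vectors scales misfit linearly, MSE quadratically
  a <- 3.7
  cm2 <- cost_and_mse(a * c(1, 2), a * c(0, 0))
  expect_equal(cm2$misfit, a * sqrt(5))
  expect_equal(cm2$mse, a^2 * 2.5)
  expect_error(cost_and_mse(1:3, 1:2), "invalid-argument")
})

test_that("lm_update solves the damped normal equations", {
  # identity Jacobian, no damping: the step reproduces the misfit
  v <- c(1, -2, 3)
  expect_equal(lm_update(diag(3), v, 0), v)
  # large damping annihilates the step
  set.seed(2)
  J <- matrix(stats::rnorm(40), 8, 5)
  dM <- stats::rnorm(8)
  step <- lm_update(J, dM, 1e12)
  expect_lt(sqrt(sum(step^2)), 1e-9 * sqrt(sum(crossprod(J, dM)^2)))
  # rank-deficient system demands regularization
  expect_error(lm_update(matrix(stats::rnorm(20), 4, 5), stats::rnorm(4), 0),
    "regularization-required")
})

test_that("lm_update agrees with a dense damped-pseudo-inverse oracle in both regimes", {
  set.seed(3)
  for (dims in list(c(20, 50), c(50, 20))) {
    J <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
    dM <- stats::rnorm(dims[1])
    for (lambda in c(1e-3, 1, 1e3)) {
      oracle <- solve(crossprod(J) + diag(lambda, dims[2]), crossprod(J, dM))[, 1]
      expect_equal(lm_update(J, dM, lambda), oracle, tolerance = 1e-9)
    }
    # step norm is non-increasing in lambda
    norms <- vapply(c(1e-3, 1, 1e3),
      function(l) sqrt(sum(lm_update(J, dM, l)^2)), numeric(1))
    expect_true(all(diff(norms) < 0))
  }
})

test_that("calibration rescales data onto the model's own homogeneous response", {
  g <- build_scan_geometry(n_planes = 2)
  me <- measurement_set(rep(2, 168), g)
  ref_meas <- measurement_set(rep(2, 168), g)
  ref_pred <- measurement_set(rep(0.5, 168), g)
  cal <- calibrate_measurements(me, ref_meas, ref_pred)
  expect_equal(cal$values, rep(0.5, 168)) # identical phantom == reference
  expect_true(isTRUE(cal$meta$calibrated))
})

test_that("reconstruction from self-consistent data is a fixed point", {
  m <- tiny_mesh()
  g <- build_scan_geometry(n_planes = 2)
  truth <- optical_map(m, 0.01, 1.0)
  me <- simulate_measurements(truth, m, g)
  rec <- mobiir_reconstruct(me, m, initial = truth,
    settings = mobiir_settings(max_iter = 5, inverse_crime_ok = TRUE))
  expect_lte(rec$iterations, 1L)
  expect_equal(rec$mu, truth$mu_a, tolerance = 1e-6)
  expect_lt(rec$cost_history[1], 1e-12)
})

test_that("the inverse-crime guard rejects data simulated on the reconstruction mesh", {
  m <- tiny_mesh()
  g <- build_scan_geometry(n_planes = 2)
  me <- simulate_measurements(optical_map(m, 0.01, 1.0), m, g)
  expect_error(mobiir_reconstruct(me, m), "inverse-crime")
})

test_that("MoBIIR reduces the misfit on a small two-mesh phantom study", {
  data_mesh <- small_mesh()
  recon_mesh <- tiny_mesh()
  g <- build_scan_geometry(n_planes = 2)
  truth <- build_phantom(data_mesh, 0.01, 1.0,
    list(inhomogeneity_spec("cylinder-z", c(0, 16), 10, 0.03)))
  me <- simulate_measurements(truth, data_mesh, g)
  ref <- simulate_measurements(optical_map(data_mesh, 0.01, 1.0), data_mesh, g)
  rec <- mobiir_reconstruct(me, recon_mesh,
    settings = mobiir_settings(max_iter = 6, rel_tol = 1e-8), reference = ref)
  n <- length(rec$cost_history)
  expect_gt(n, 2)
  expect_true(all(diff(rec$cost_history) < 0)) # accepted steps only
  expect_lt(rec$cost_history[n], 0.7 * rec$cost_history[1])
  expect_equal(rec$jacobian_builds, 1L) # Broyden: a single adjoint build
  # the absorber region ends up above the background estimate
  inside <- inclusion_membership(recon_mesh,
    inhomogeneity_spec("cylinder-z", c(0, 16), 10, 0.03))
  expect_gt(mean(rec$mu[inside]), mean(rec$mu[!inside]))
})

test_that("conventional mode rebuilds the Jacobian every iteration at equal image quality", {
  data_mesh <- small_mesh()
  recon_mesh <- tiny_mesh()
  g <- build_scan_geometry(n_planes = 2)
  spec <- inhomogeneity_spec("cylinder-z", c(0, 16), 10, 0.03)
  truth <- build_phantom(data_mesh, 0.01, 1.0, list(spec))
  me <- simulate_measurements(truth, data_mesh, g)
  ref <- simulate_measurements(optical_map(data_mesh, 0.01, 1.0), data_mesh, g)
  rec_c <- mobiir_reconstruct(me, recon_mesh,
    settings = mobiir_settings(max_iter = 8, rel_tol = 1e-10, broyden = FALSE),
    reference = ref)
  expect_equal(rec_c$jacobian_builds, 1L + rec_c$iterations)
  rec_b <- mobiir_reconstruct(me, recon_mesh,
    settings = mobiir_settings(max_iter = 8, rel_tol = 1e-10), reference = ref)
  expect_equal(rec_b$jacobian_builds, 1L)
  # Broyden preserves reconstruction quality while skipping the rebuilds:
  # both modes fit the bulk of the signal and recover the same contrast
  ratio_b <- rec_b$cost_history[length(rec_b$cost_history)] / rec_b$cost_history[1]
  ratio_c <- rec_c$cost_history[length(rec_c$cost_history)] / rec_c$cost_history[1]
  expect_lt(ratio_b, 0.10)
  expect_lt(ratio_c, 0.10)
  con_b <- inclusion_recovery(rec_b, recon_mesh, spec, 0.01)$contrast
  con_c <- inclusion_recovery(rec_c, recon_mesh, spec, 0.01)$contrast
  expect_lt(abs(con_b - con_c) / con_c, 0.10)
})

test_that("final misfit varies smoothly across damping scales without failures", {
  data_mesh <- small_mesh()
  recon_mesh <- tiny_mesh()
  g <- build_scan_geometry(n_planes = 2)
  truth <- build_phantom(data_mesh, 0.01, 1.0,
    list(inhomogeneity_spec("cylinder-z", c(0, 16), 10, 0.03)))
  me <- simulate_measurements(truth, data_mesh, g)
  ref <- simulate_measurements(optical_map(data_mesh, 0.01, 1.0), data_mesh, g)
  finals <- vapply(c(1e-3, 1e-1, 1e1), function(a) {
    rec <- mobiir_reconstruct(me, recon_mesh,
      settings = mobiir_settings(max_iter = 3, alpha = a), reference = ref)
    rec$cost_history[length(rec$cost_history)]
  }, numeric(1))
  expect_true(all(is.finite(finals)))
  expect_true(all(finals > 0))
})
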