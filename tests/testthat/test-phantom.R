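# Synthetic phantoms, scan geometry and the measurement-noise model.

test_that("simulation phantom reproduces the standard optical coefficients", {
  m <- coarse_mesh()
  ph <- build_simulation_phantom(m)
  expect_equal(mu_a_at(ph, m, c(20, 0, 0)), 0.01)        # background
  expect_equal(mu_a_at(ph, m, c(0, -16, -10)), 0.02)     # sphere centre
  expect_equal(mu_a_at(ph, m, c(0, 16, 20)), 0.03)       # cylinder, any height
  expect_true(all(ph$mu_s_prime == 1.0))
  expect_equal(ph$kappa, 1 / (3 * (ph$mu_a + ph$mu_s_prime)))
})

test_that("inclusion membership equals the brute-force centroid test", {
  m <- coarse_mesh()
  ph <- build_simulation_phantom(m)
  cen <- element_centroids(m)
  in_sphere <- rowSums(sweep(cen, 2, c(0, -16, -10))^2) <= (7.9 / 2)^2
  in_cyl <- cen[, 1]^2 + (cen[, 2] - 16)^2 <= (7.9 / 2)^2
  expect_equal(sum(ph$mu_a == 0.02), sum(in_sphere & !in_cyl))
  expect_equal(sum(ph$mu_a == 0.03), sum(in_cyl))
  expect_gt(sum(in_sphere), 0)
})

test_that("experimental phantom uses its own background and inclusion coefficients", {
  m <- coarse_mesh()
  ph <- build_experimental_phantom(m)
  expect_equal(mu_a_at(ph, m, c(20, 0, 0)), 0.005)
  expect_equal(mu_a_at(ph, m, c(0, -16, 0)), 0.02)   # 10 mm cylinder
  expect_equal(mu_a_at(ph, m, c(0, 16, 0)), 0.035)   # 12 mm cylinder
  expect_true(all(ph$mu_s_prime == 0.8))
  hom <- build_experimental_phantom(m, n_inclusions = 0L)
  expect_true(all(hom$mu_a == 0.005))
})

test_that("optical maps enforce positivity and kappa consistency", {
  m <- single_tet()
  expect_error(optical_map(m, -0.01, 1), "positive")
  expect_warning(optical_map(m, 0.5, 1), "diffusion approximation")
  om <- optical_map(m, 0.01, 1)
  om2 <- set_mu_a(om, 0.05)
  expect_equal(om2$kappa, 1 / (3 * (0.05 + 1)))
})

test_that("scan geometry has the stated pair structure on the cylinder surface", {
  g2 <- build_scan_geometry(n_planes = 2)
  g3 <- build_scan_geometry(n_planes = 3)
  expect_equal(nrow(g2$pairs), 168L) # 12 x 7 x 2
  expect_equal(nrow(g3$pairs), 252L) # 12 x 7 x 3
  expect_error(build_scan_geometry(n_planes = 4), "invalid-argument")

  r_src <- sqrt(g2$pairs$sx^2 + g2$pairs$sy^2)
  r_det <- sqrt(g2$pairs$dx^2 + g2$pairs$dy^2)
  expect_lt(max(abs(r_src - 30)), 1e-9)
  expect_lt(max(abs(r_det - 30)), 1e-9)

  # plane-major, then source, then detector ordering
  expect_equal(g2$pairs$plane, rep(1:2, each = 84))
  expect_equal(g2$pairs$source[1:84], rep(1:12, each = 7))
  expect_equal(g2$pairs$detector[1:7], 1:7)
  expect_equal(g2$plane_z, c(-10, 10))
  expect_equal(g3$plane_z, c(-15, 0, 15))

  # detectors sit opposite their source (azimuth gap 120..240 degrees)
  az_s <- atan2(g2$pairs$sy, g2$pairs$sx)
  az_d <- atan2(g2$pairs$dy, g2$pairs$dx)
  gap <- (az_d - az_s) %% (2 * pi) * 180 / pi
  expect_true(all(gap > 119.9 & gap < 240.1))
})

test_that("multiplicative noise has the stated level, determinism and identity at zero", {
  g <- build_scan_geometry(n_planes = 2)
  ms <- measurement_set(rep(1, 168), g)
  expect_identical(add_noise(ms, 0), ms)
  expect_error(add_noise(ms, -0.1), "invalid-argument")

  n1 <- add_noise(ms, 0.02, seed = 7)
  n2 <- add_noise(ms, 0.02, seed = 7)
  expect_identical(n1$values, n2$values)

  x <- rep(1, 1e5)
  noisy <- add_noise(x, 0.02, seed = 11)
  s <- stats::sd((noisy - x) / x)
  se <- 0.02 / sqrt(2 * (1e5 - 1)) # sampling error of the sd estimator
  expect_lt(abs(s - 0.02), 3 * se)
  expect_lt(abs(mean(noisy / x) - 1), 3 * 0.02 / sqrt(1e5))
})

test_that("measurement sets serialize to TSV + JSON and back without loss", {
  g <- build_scan_geometry(n_planes = 2)
  set.seed(3)
  ms <- measurement_set(stats::runif(168, 1e-9, 1e-7), g,
    meta = list(kind = "simulated", noise_level = 0.02, seed = 3L))
  path <- tempfile(fileext = ".tsv")
  write_measurements(ms, path)
  back <- read_measurements(path)
  expect_equal(back$values, ms$values)
  expect_equal(back$meta$noise_level, 0.02)
  expect_equal(nrow(back$geometry$pairs), 168L)
  expect_equal(back$geometry$pairs$plane, ms$geometry$pairs$plane)
  unlink(c(path, paste0(path, ".json")))
})

test_that("simulated boundary data are positive and converge to the scan's rotational symmetry", {
  g <- build_scan_geometry(n_planes = 2)
  ms <- simulate_measurements(optical_map(small_mesh(), 0.01, 1.0), small_mesh(), g)
  expect_true(all(ms$values > 0))

  # the continuum problem is invariant under a 60-degree rotation (a shift
  # of two source positions); the node layout repeats every 60 degrees but
  # the index-based tetrahedralization does not, so the symmetry holds only
  # up to discretization error, which must shrink under refinement
  asym <- function(values) {
    v <- matrix(values, nrow = 7)
    worst <- 0
    for (p in 0:1) {
      b <- v[, p * 12 + (1:12)]
      s <- b[, c(3:12, 1:2)]
      worst <- max(worst, abs(b - s) / pmax(abs(b), abs(s)))
    }
    worst
  }
  a_small <- asym(ms$values)
  a_fine <- asym(phantom_study()$reference$values) # homogeneous, fine preset
  expect_lt(a_fine, 0.10)
  expect_lt(a_fine, a_small / 2)
})

test_that("an absorber between source and detector reduces the transmitted signal", {
  m <- small_mesh()
  g <- build_scan_geometry(n_planes = 2)
  hom <- optical_map(m, 0.01, 1.0)
  ms0 <- simulate_measurements(hom, m, g)
  # absorbing ball on the chord from source 1 (az 0, z -10) to its middle
  # detector (az 180): centre of the domain at that plane
  blocked <- build_phantom(m, 0.01, 1.0,
    list(inhomogeneity_spec("sphere", c(0, 0, -10), 12, 0.05)))
  ms1 <- simulate_measurements(blocked, m, g)
  mid <- which(g$pairs$plane == 1 & g$pairs$source == 1 & g$pairs$detector == 4)
  expect_lt(ms1$values[mid], ms0$values[mid])
})
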