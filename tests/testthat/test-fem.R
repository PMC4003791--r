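# Galerkin assembly and forward solution of the diffusion system.

# independent element oracle: basis coefficients from a 4x4 vandermonde
# solve, mass integrals by 4-point degree-2 Gauss quadrature
element_oracle <- function(p, kappa_e, mu_a_e) {
  A <- cbind(1, p) # b_i(x) = c0 + c . x, rows of solve(A) give coefficients
  C <- solve(A)    # column i: coefficients of basis i
  grads <- C[2:4, , drop = FALSE]
  v <- element_volume(p)
  stiff <- kappa_e * v * crossprod(grads)
  a <- (5 + 3 * sqrt(5)) / 20
  b <- (5 - sqrt(5)) / 20
  qp <- rbind(
    c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a)
  ) # barycentric quadrature points, weights 1/4
  mass <- matrix(0, 4, 4)
  for (q in 1:4) {
    x <- colSums(qp[q, ] * p)
    bv <- as.vector(crossprod(C, c(1, x))) # basis values at the point
    mass <- mass + (v / 4) * tcrossprod(bv)
  }
  list(stiffness = stiff, mass = mu_a_e * mass)
}

test_that("elemental matrices match exact integration of linear basis products", {
  # reference tetrahedron: closed-form mass matrix V/10 diag, V/20 off-diag
  unit <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  em <- element_matrices(unit, kappa_e = 1, mu_a_e = 1)
  v <- 1 / 6
  expect_equal(diag(em$mass), rep(v / 10, 4))
  expect_equal(em$mass[upper.tri(em$mass)], rep(v / 20, 6))

  set.seed(7)
  for (i in 1:8) {
    p <- random_tet()
    kap <- stats::runif(1, 0.1, 1)
    mua <- stats::runif(1, 0.005, 0.05)
    em <- element_matrices(p, kap, mua)
    or <- element_oracle(p, kap, mua)
    expect_equal(em$stiffness, or$stiffness, tolerance = 1e-9)
    expect_equal(em$mass, or$mass, tolerance = 1e-9)
    # constants lie in the null space of the gradient term
    expect_lt(max(abs(rowSums(em$stiffness))), 1e-12 * max(abs(em$stiffness)))
  }
  expect_error(element_matrices(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)), 1, 1),
    "degenerate-element")
})

test_that("global assembly equals an independent per-element scatter", {
  m <- two_tets()
  om <- optical_map(m, c(0.01, 0.02), c(1, 0.9))
  sys <- assemble_system(m, om, fresnel_A = 1.0, boundary = FALSE)
  K_oracle <- matrix(0, 5, 5)
  for (e in 1:2) {
    idx <- m$elements[e, ]
    em <- element_matrices(m$nodes[idx, ], om$kappa[e], om$mu_a[e])
    K_oracle[idx, idx] <- K_oracle[idx, idx] + em$stiffness + em$mass
  }
  expect_equal(as.matrix(sys$K), K_oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("assembled system is square, symmetric and positive definite", {
  m <- tiny_mesh()
  om <- optical_map(m, 0.01, 1.0)
  sys <- assemble_system(m, om)
  expect_equal(dim(sys$K), c(m$n_nodes, m$n_nodes))
  expect_lt(max(abs(sys$K - Matrix::t(sys$K))), 1e-10 * max(abs(sys$K)))
  ev <- min(eigen(as.matrix(sys$K), symmetric = TRUE, only.values = TRUE)$values)
  expect_gt(ev, 0)
})

test_that("without absorption and boundary term the operator annihilates constants", {
  m <- tiny_mesh()
  om <- suppressWarnings(optical_map(m, 1e-300, 1.0))
  sys <- assemble_system(m, om, boundary = FALSE)
  rs <- as.vector(sys$K %*% rep(1, m$n_nodes))
  expect_lt(max(abs(rs)), 1e-10 * max(abs(sys$K)))
})

test_that("source vectors have unit strength at one transport mean free path depth", {
  m <- small_mesh()
  om <- optical_map(m, 0.01, 1.0)
  src <- build_source_vector(m, c(30, 0, 0), om)
  expect_equal(sum(src$Q), 1)
  expect_equal(src$depth, 1.0) # 1/mu_s' for mu_s' = 1
  # one mean free path inside, up to the faceting of the polyhedral surface
  expect_equal(sqrt(sum(src$point[1:2]^2)), 29, tolerance = 0.01)
  expect_error(build_source_vector(m, c(60, 0, 0), om), "geometry-mismatch")
})

test_that("forward solve meets the residual contract for multiple right-hand sides", {
  m <- tiny_mesh()
  om <- optical_map(m, 0.01, 1.0)
  sys <- assemble_system(m, om)
  Q <- matrix(0, m$n_nodes, 2)
  Q[10, 1] <- 1
  Q[200, 2] <- 1
  phi <- solve_forward(sys, Q)
  res <- sqrt(colSums(as.matrix(sys$K %*% phi - Q)^2)) / sqrt(colSums(Q^2))
  expect_true(all(res <= 1e-8))
  expect_error(solve_forward(sys, numeric(3)), "rhs size")
})

test_that("detector weights interpolate on the boundary; a node position is exact", {
  m <- small_mesh()
  om <- optical_map(m, 0.01, 1.0)
  sys <- assemble_system(m, om)
  src <- build_source_vector(m, c(30, 0, 0), om)
  phi <- solve_forward(sys, src$Q)[, 1]
  # pick an actual boundary node on the lateral surface
  bn <- unique(as.vector(m$boundary_faces))
  bn <- bn[abs(sqrt(rowSums(m$nodes[bn, 1:2]^2)) - 30) < 1e-9][1]
  w <- detector_weights(m, m$nodes[bn, ])
  expect_equal(sum(w$weights), 1)
  expect_equal(sum(phi[w$nodes] * w$weights), phi[bn])
  expect_error(detector_weights(m, c(50, 0, 0)), "geometry-mismatch")
})

test_that("discrete reciprocity: reading Phi_s at the detector equals reading Phi_d at the source", {
  m <- small_mesh()
  om <- optical_map(m, 0.01, 1.0)
  sys <- assemble_system(m, om)
  src <- build_source_vector(m, c(30, 0, -10), om)
  det <- detector_weights(m, c(-30 * cos(pi / 3), 30 * sin(pi / 3), -10))
  w <- numeric(m$n_nodes)
  w[det$nodes] <- det$weights
  phi_s <- solve_forward(sys, src$Q)[, 1]
  phi_d <- solve_forward(sys, w)[, 1]
  expect_equal(sum(phi_s * w), sum(phi_d * src$Q), tolerance = 1e-10)
})

test_that("predicted measurements follow geometry order and increase nowhere when mu_a rises", {
  m <- small_mesh()
  g <- build_scan_geometry(n_planes = 2)
  base <- simulate_measurements(optical_map(m, 0.01, 1.0), m, g)
  expect_equal(length(base$values), nrow(g$pairs))
  raised <- simulate_measurements(optical_map(m, 0.012, 1.0), m, g)
  expect_true(all(raised$values < base$values))
})
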