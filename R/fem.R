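# Galerkin finite-element discretization of the continuous-wave photon
# diffusion equation
#
#   -div(kappa grad Phi) + mu_a Phi = q0      in the domain,
#   Phi + 2 A kappa dPhi/dn = 0               on the boundary (Robin),
#
# on linear tetrahedra.  The assembled system is
# (K(kappa) + C(mu_a) + F) Phi = Q with K the stiffness matrix, C the
# absorption mass matrix and F the Robin boundary mass term scaled by
# 1/(2A).  All element integrals of linear basis products are exact:
# stiffness kappa*V*(g_i . g_j) with constant gradients g_i, tet mass
# mu_a*V/10 (diagonal) and mu_a*V/20 (off-diagonal), triangle boundary mass
# Area/6 (diagonal) and Area/12 (off-diagonal).

# per-mesh geometry cache: element volumes, basis gradients, centroids
mesh_geometry <- function(mesh) {
  cache <- mesh$cache
  if (!is.null(cache$geom)) return(cache$geom)
  nodes <- mesh$nodes
  el <- mesh$elements
  a <- nodes[el[, 1L], , drop = FALSE]
  r1 <- nodes[el[, 2L], , drop = FALSE] - a
  r2 <- nodes[el[, 3L], , drop = FALSE] - a
  r3 <- nodes[el[, 4L], , drop = FALSE] - a
  d <- det3_rows(r1, r2, r3) # = 6V, positive by mesh orientation
  g2 <- cross_rows(r2, r3) / d
  g3 <- cross_rows(r3, r1) / d
  g4 <- cross_rows(r1, r2) / d
  g1 <- -(g2 + g3 + g4)
  geom <- list(
    vol = d / 6,
    grads = list(g1, g2, g3, g4),
    origin = a,
    centroids = element_centroids(mesh)
  )
  cache$geom <- geom
  geom
}

#' Elemental stiffness and mass matrices for one tetrahedron
#'
#' @param tet_coords 4 x 3 vertex coordinate matrix, mm.
#' @param kappa_e element diffusion coefficient, mm.
#' @param mu_a_e element absorption coefficient, mm^-1.
#' @return List with `stiffness` (4 x 4, `kappa_e * V * g_i . g_j`) and
#'   `mass` (4 x 4, `mu_a_e * V/10` diagonal / `V/20` off-diagonal), plus
#'   the element `volume`.
#' @export
element_matrices <- function(tet_coords, kappa_e, mu_a_e) {
  tet_coords <- as.matrix(tet_coords)
  e <- sweep(tet_coords[2:4, , drop = FALSE], 2, tet_coords[1, ])
  d <- det(e)
  if (abs(d) < 6e-12) stop("degenerate-element: tetrahedron volume below 1e-12 mm^3")
  v <- abs(d) / 6
  g <- matrix(0, 4, 3)
  g[2, ] <- crossp(e[2, ], e[3, ]) / d
  g[3, ] <- crossp(e[3, ], e[1, ]) / d
  g[4, ] <- crossp(e[1, ], e[2, ]) / d
  g[1, ] <- -colSums(g[2:4, , drop = FALSE])
  stiff <- kappa_e * v * tcrossprod(g)
  mass <- mu_a_e * v / 20 * (matrix(1, 4, 4) + diag(4))
  list(stiffness = stiff, mass = mass, volume = v)
}

crossp <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Assemble the global FEM system matrix
#'
#' Scatter-adds all elemental stiffness and absorption-mass contributions by
#' global node number and adds the Robin boundary term
#' `(1/(2A)) * int b_i b_j dS` over every boundary triangle.
#'
#' @param mesh a [tet_mesh()].
#' @param optical an `optical_map` sized to the mesh.
#' @param fresnel_A Fresnel reflection coefficient A of the Robin condition
#'   (> 0; 1 = index-matched boundary).
#' @param boundary logical; include the boundary term (disabling it leaves
#'   the pure-Neumann operator, useful for diagnostics only).
#' @return A `dot_system` holding the sparse symmetric matrix `K`
#'   (n_nodes x n_nodes), assembly metadata, and a lazily computed sparse
#'   Cholesky factorization.
#' @export
assemble_system <- function(mesh, optical, fresnel_A = 1.0, boundary = TRUE) {
  if (optical$n_elements != mesh$n_elements) {
    stop("assembly-error: optical map sized for a different mesh")
  }
  if (fresnel_A <= 0) stop("invalid-argument: fresnel_A must be positive")
  geom <- mesh_geometry(mesh)
  el <- mesh$elements
  n <- mesh$n_nodes
  v <- geom$vol
  g <- geom$grads
  ne <- mesh$n_elements
  # 16 entries per element
  ii <- jj <- integer(16L * ne)
  xx <- numeric(16L * ne)
  k <- 0L
  for (i in 1:4) {
    for (j in 1:4) {
      idx <- k * ne + seq_len(ne)
      ii[idx] <- el[, i]
      jj[idx] <- el[, j]
      xx[idx] <- optical$kappa * v * rowSums(g[[i]] * g[[j]]) +
        optical$mu_a * v / (if (i == j) 10 else 20)
      k <- k + 1L
    }
  }
  if (boundary) {
    bd <- mesh$boundary_faces
    v1 <- mesh$nodes[bd[, 2L], , drop = FALSE] - mesh$nodes[bd[, 1L], , drop = FALSE]
    v2 <- mesh$nodes[bd[, 3L], , drop = FALSE] - mesh$nodes[bd[, 1L], , drop = FALSE]
    area <- sqrt(rowSums(cross_rows(v1, v2)^2)) / 2
    nb <- nrow(bd)
    bi <- bj <- integer(9L * nb)
    bx <- numeric(9L * nb)
    k <- 0L
    for (i in 1:3) {
      for (j in 1:3) {
        idx <- k * nb + seq_len(nb)
        bi[idx] <- bd[, i]
        bj[idx] <- bd[, j]
        bx[idx] <- area / (if (i == j) 6 else 12) / (2 * fresnel_A)
        k <- k + 1L
      }
    }
    ii <- c(ii, bi)
    jj <- c(jj, bj)
    xx <- c(xx, bx)
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  structure(
    list(
      K = K,
      n_nodes = n,
      fresnel_A = fresnel_A,
      boundary = boundary,
      solver = "sparse-cholesky",
      cache = new.env(parent = emptyenv())
    ),
    class = "dot_system"
  )
}

#' @export
print.dot_system <- function(x, ...) {
  cat(sprintf(
    "dot_system: %d x %d sparse symmetric matrix, %d nonzeros, Robin A = %g\n",
    x$n_nodes, x$n_nodes, Matrix::nnzero(x$K), x$fresnel_A
  ))
  invisible(x)
}

#' Export a system matrix in Matrix Market coordinate format
#'
#' @param system a `dot_system`.
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_system_mtx <- function(system, path) {
  Matrix::writeMM(methods::as(system$K, "CsparseMatrix"), path)
  invisible(path)
}

# ---- solver with call accounting --------------------------------------------

.solver_state <- new.env(parent = emptyenv())
.solver_state$factorizations <- 0L
.solver_state$solves <- 0L

#' Reset the forward-solver call counters
#'
#' The package counts sparse factorizations and right-hand-side solves;
#' the counters support cost accounting of reconstruction variants (one
#' adjoint Jacobian build should cost on the order of n_sources +
#' n_detectors solves, not n_elements).
#'
#' @return Invisibly, the counter values before the reset.
#' @export
reset_solver_counter <- function() {
  old <- solver_counter()
  .solver_state$factorizations <- 0L
  .solver_state$solves <- 0L
  invisible(old)
}

#' Read the forward-solver call counters
#'
#' @return Named list with `factorizations` and `solves` (right-hand sides
#'   solved) since the last [reset_solver_counter()].
#' @export
solver_counter <- function() {
  list(
    factorizations = .solver_state$factorizations,
    solves = .solver_state$solves
  )
}

system_factor <- function(system) {
  if (is.null(system$cache$factor)) {
    f <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(system$K), LDL = FALSE),
      error = function(e) {
        stop("solver-failure: sparse Cholesky failed (matrix not positive definite?): ",
          conditionMessage(e))
      }
    )
    system$cache$factor <- f
    .solver_state$factorizations <- .solver_state$factorizations + 1L
  }
  system$cache$factor
}

#' Solve the forward diffusion system
#'
#' Direct sparse Cholesky solve; the factorization is cached on the system
#' object so multiple right-hand sides reuse it.  The relative residual of
#' every solution is checked against 1e-8.
#'
#' @param system a `dot_system` from [assemble_system()].
#' @param Q right-hand side: numeric vector or n_nodes x k matrix (one
#'   column per source).
#' @return Numeric matrix of nodal photon densities, one column per
#'   right-hand side.
#' @export
solve_forward <- function(system, Q) {
  Q <- as.matrix(Q)
  if (nrow(Q) != system$n_nodes) stop("invalid-argument: rhs size mismatch")
  f <- system_factor(system)
  phi <- as.matrix(Matrix::solve(f, Q, system = "A"))
  .solver_state$solves <- .solver_state$solves + ncol(Q)
  res <- sqrt(colSums(as.matrix(system$K %*% phi - Q)^2)) /
    pmax(sqrt(colSums(Q^2)), .Machine$double.xmin)
  if (any(res > 1e-8)) {
    stop(sprintf("solver-failure: relative residual %.3g exceeds 1e-8", max(res)))
  }
  phi
}

# ---- point location and boundary interpolation ------------------------------

#' Locate the element containing a point
#'
#' Barycentric membership test against all elements (vectorised); returns
#' the element whose smallest barycentric coordinate is largest, or `NA` if
#' the point lies outside every element beyond the tolerance.
#'
#' @param mesh a [tet_mesh()].
#' @param point `c(x, y, z)` in mm.
#' @param tol barycentric slack allowed at element boundaries.
#' @return Element index or `NA_integer_`.
#' @export
locate_point <- function(mesh, point, tol = 1e-9) {
  b <- barycentric_all(mesh, point)
  worst <- pmin(b[, 1], b[, 2], b[, 3], b[, 4])
  e <- which.max(worst)
  if (worst[e] < -tol) return(NA_integer_)
  e
}

# barycentric coordinates of one point in every element
barycentric_all <- function(mesh, point) {
  geom <- mesh_geometry(mesh)
  dx <- sweep(geom$origin, 2, point, "-") * -1
  l2 <- rowSums(geom$grads[[2]] * dx)
  l3 <- rowSums(geom$grads[[3]] * dx)
  l4 <- rowSums(geom$grads[[4]] * dx)
  cbind(1 - l2 - l3 - l4, l2, l3, l4)
}

#' Build the source vector for a boundary illumination position
#'
#' The collimated source is modelled as an isotropic point source one
#' transport mean free path (1 / mu_s', background value) inside the surface
#' along the inward normal of the nearest boundary face.  Its unit strength
#' is distributed to the nodes of the enclosing tetrahedron by barycentric
#' weights, so the vector sums to exactly 1.
#'
#' @param mesh a [tet_mesh()].
#' @param position surface position `c(x, y, z)` in mm.
#' @param optical an `optical_map` (supplies the background `mu_s_prime`).
#' @param surface_tol maximum allowed distance from `position` to the mesh
#'   surface, mm.
#' @return List with the sparse-as-dense rhs vector `Q` (length n_nodes),
#'   the interior `point`, the placement `depth` (mm) and the enclosing
#'   `element`.
#' @export
build_source_vector <- function(mesh, position, optical, surface_tol = 2.0) {
  fc <- boundary_face_centroids(mesh)
  d2 <- colSums((t(fc$centroids) - position)^2)
  nearest <- which.min(d2)
  if (sqrt(d2[nearest]) > max(surface_tol, fc$max_edge)) {
    stop("geometry-mismatch: source position is not on the mesh surface")
  }
  depth <- 1 / stats::median(optical$mu_s_prime)
  p_in <- position - fc$normals[nearest, ] * depth
  e <- locate_point(mesh, p_in, tol = 1e-6)
  if (is.na(e)) stop("source-placement: interior source point not inside the mesh")
  w <- barycentric_all(mesh, p_in)[e, ]
  w <- pmax(w, 0)
  w <- w / sum(w)
  Q <- numeric(mesh$n_nodes)
  Q[mesh$elements[e, ]] <- w
  list(Q = Q, point = p_in, depth = depth, element = e)
}

boundary_face_centroids <- function(mesh) {
  cache <- mesh$cache
  if (!is.null(cache$bdgeom)) return(cache$bdgeom)
  bd <- mesh$boundary_faces
  p1 <- mesh$nodes[bd[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[bd[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[bd[, 3L], , drop = FALSE]
  cen <- (p1 + p2 + p3) / 3
  nrm <- cross_rows(p2 - p1, p3 - p1)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  max_edge <- sqrt(max(rowSums((p2 - p1)^2), rowSums((p3 - p2)^2), rowSums((p1 - p3)^2)))
  out <- list(centroids = cen, normals = nrm, max_edge = max_edge)
  cache$bdgeom <- out
  out
}

#' Measurement weights for a detector position
#'
#' Projects the detector position onto the nearest boundary face and returns
#' barycentric interpolation weights on that face's three nodes; a detector
#' coincident with a node gets all weight on that node.
#'
#' @param mesh a [tet_mesh()].
#' @param position detector position `c(x, y, z)` in mm.
#' @param surface_tol maximum allowed distance to the surface, mm.
#' @return List with node indices `nodes` (length 3) and `weights` summing
#'   to 1.
#' @export
detector_weights <- function(mesh, position, surface_tol = 2.0) {
  fc <- boundary_face_centroids(mesh)
  d2 <- colSums((t(fc$centroids) - position)^2)
  ord <- order(d2)[seq_len(min(40L, length(d2)))]
  bd <- mesh$boundary_faces
  best <- NULL
  best_d <- Inf
  for (f in ord) {
    tri <- bd[f, ]
    w <- triangle_barycentric(mesh$nodes[tri, , drop = FALSE], position)
    pen <- sum(pmax(-w$bary, 0)) # distance outside the triangle, bary units
    score <- abs(w$dist) + pen * fc$max_edge
    if (score < best_d) {
      best_d <- score
      best <- list(nodes = tri, weights = w$bary, dist = w$dist)
    }
  }
  if (abs(best$dist) > surface_tol) {
    stop("geometry-mismatch: detector position is not on the mesh surface")
  }
  w <- pmax(best$weights, 0)
  list(nodes = best$nodes, weights = w / sum(w))
}

# orthogonal projection of p onto the triangle plane + barycentric coords
triangle_barycentric <- function(tri, p) {
  u <- tri[2, ] - tri[1, ]
  v <- tri[3, ] - tri[1, ]
  n <- crossp(u, v)
  n <- n / sqrt(sum(n^2))
  d <- sum((p - tri[1, ]) * n)
  q <- p - d * n - tri[1, ]
  m <- rbind(c(sum(u * u), sum(u * v)), c(sum(u * v), sum(v * v)))
  rhs <- c(sum(q * u), sum(q * v))
  ab <- solve(m, rhs)
  list(bary = c(1 - ab[1] - ab[2], ab[1], ab[2]), dist = d)
}

# ---- boundary-data prediction ----------------------------------------------

# forward solutions for all unique source positions of a geometry
forward_solutions <- function(system, mesh, optical, geometry) {
  src <- geometry$sources$positions
  Q <- matrix(0, mesh$n_nodes, nrow(src))
  for (s in seq_len(nrow(src))) {
    Q[, s] <- build_source_vector(mesh, src[s, ], optical)$Q
  }
  solve_forward(system, Q)
}

# adjoint solutions for all unique detector positions (same symmetric system)
adjoint_solutions <- function(system, mesh, geometry) {
  det <- geometry$detectors$positions
  Q <- matrix(0, mesh$n_nodes, nrow(det))
  for (d in seq_len(nrow(det))) {
    w <- detector_weights(mesh, det[d, ])
    Q[w$nodes, d] <- w$weights
  }
  solve_forward(system, Q)
}

#' Predict boundary measurements from forward solutions
#'
#' Reads the photon density of each pair's source solution at the detector
#' position (barycentric interpolation on the containing boundary face), in
#' geometry pair order.
#'
#' @param phi matrix of nodal solutions, one column per unique source
#'   position (as produced internally for a geometry).
#' @param mesh the [tet_mesh()] the solutions live on.
#' @param geometry a [build_scan_geometry()] geometry.
#' @return A `measurement_set` of predicted data M^C.
#' @export
predict_measurements <- function(phi, mesh, geometry) {
  src_of_pair <- geometry$sources$index
  det_of_pair <- geometry$detectors$index
  dpos <- geometry$detectors$positions
  wts <- lapply(seq_len(nrow(dpos)), function(d) detector_weights(mesh, dpos[d, ]))
  vals <- numeric(nrow(geometry$pairs))
  for (p in seq_along(vals)) {
    w <- wts[[det_of_pair[p]]]
    vals[p] <- sum(phi[w$nodes, src_of_pair[p]] * w$weights)
  }
  measurement_set(vals, geometry, meta = list(
    kind = "predicted", n_nodes = mesh$n_nodes, n_elements = mesh$n_elements
  ))
}

# assemble + solve + predict for a full optical map
predict_measurements_from_map <- function(optical, mesh, geometry) {
  system <- assemble_system(mesh, optical, fresnel_A = geometry$fresnel_A)
  phi <- forward_solutions(system, mesh, optical, geometry)
  ms <- predict_measurements(phi, mesh, geometry)
  ms$meta$n_nodes <- mesh$n_nodes
  ms$meta$n_elements <- mesh$n_elements
  ms
}
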