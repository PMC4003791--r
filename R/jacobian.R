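# Measurement-to-parameter sensitivity (Jacobian) matrices.
#
# Row (s, d) of the Jacobian is the derivative of the predicted boundary
# datum for source s and detector d with respect to the element-wise
# absorption mu_a.  By the adjoint method it equals
#   dM/dmu_a(e) = - Phi_s^T (dK/dmu_a(e)) Phi_d = - Phi_s^T M_e Phi_d,
# where Phi_s is the forward field of the source, Phi_d the adjoint field of
# the detector functional (same symmetric system matrix), and M_e the element
# mass matrix at unit absorption (V/10 diagonal, V/20 off-diagonal).  With
# linear (positive) data an absorption increase can only lower the signal,
# so all entries are non-positive up to solver tolerance.

#' Adjoint-method Jacobian of the boundary data with respect to mu_a
#'
#' Builds the full dense sensitivity matrix from one forward solve per
#' unique source position and one adjoint solve per unique detector
#' position; the cost is O(n_sources + n_detectors) solves, never
#' O(n_elements).
#'
#' @param mesh a [tet_mesh()].
#' @param optical the `optical_map` at which the derivative is taken.
#' @param geometry a [build_scan_geometry()] geometry.
#' @param system optional pre-assembled `dot_system` (reused if supplied).
#' @return Dense matrix of shape (n_pairs, n_elements) with attributes
#'   `provenance = "adjoint"` and `parameter = "mu_a"`.
#' @export
adjoint_jacobian <- function(mesh, optical, geometry, system = NULL) {
  if (is.null(system)) {
    system <- assemble_system(mesh, optical, fresnel_A = geometry$fresnel_A)
  }
  phi_s <- forward_solutions(system, mesh, optical, geometry)
  phi_d <- adjoint_solutions(system, mesh, geometry)
  jacobian_from_fields(mesh, geometry, phi_s, phi_d)
}

#' Assemble a Jacobian from forward and adjoint fields
#'
#' @param mesh a [tet_mesh()].
#' @param geometry the scan geometry defining the pair order.
#' @param phi_s nodal forward solutions, one column per unique source.
#' @param phi_d nodal adjoint solutions, one column per unique detector.
#' @return The dense (n_pairs x n_elements) Jacobian.
#' @export
jacobian_from_fields <- function(mesh, geometry, phi_s, phi_d) {
  geom <- mesh_geometry(mesh)
  el <- mesh$elements
  n_pairs <- nrow(geometry$pairs)
  J <- matrix(0, n_pairs, mesh$n_elements)
  src_of_pair <- geometry$sources$index
  det_of_pair <- geometry$detectors$index
  # element-nodal gathers, cached per unique field
  gather <- function(phi_col) matrix(phi_col[el], mesh$n_elements, 4L)
  s_el <- lapply(seq_len(ncol(phi_s)), function(k) {
    m <- gather(phi_s[, k])
    list(m = m, s = rowSums(m))
  })
  d_el <- lapply(seq_len(ncol(phi_d)), function(k) {
    m <- gather(phi_d[, k])
    list(m = m, s = rowSums(m))
  })
  w <- geom$vol / 20
  for (p in seq_len(n_pairs)) {
    a <- s_el[[src_of_pair[p]]]
    b <- d_el[[det_of_pair[p]]]
    # int_e Phi_s Phi_d dV = V/20 * (sum_i a_i b_i + (sum_i a_i)(sum_j b_j))
    J[p, ] <- -w * (rowSums(a$m * b$m) + a$s * b$s)
  }
  attr(J, "provenance") <- "adjoint"
  attr(J, "parameter") <- "mu_a"
  J
}

#' Finite-difference Jacobian (verification oracle)
#'
#' Central differences of the predicted data under per-element absorption
#' perturbations; used in tests and diagnostics only — it costs two full
#' forward problems per element.  Like the adjoint Jacobian, the derivative
#' is taken with respect to the absorption term alone: the diffusion
#' coefficient is held fixed while differencing (the kappa(mu_a) cross
#' sensitivity is of relative order mu_a/mu_s' and is ignored in the
#' standard DOT linearization).
#'
#' @param mesh a [tet_mesh()].
#' @param optical base `optical_map`.
#' @param geometry scan geometry.
#' @param step central-difference step in mm^-1.
#' @param elements integer vector of element indices to difference.
#' @return Dense (n_pairs x length(elements)) matrix with
#'   `provenance = "finite-difference"`; columns follow `elements`.
#' @export
finite_difference_jacobian <- function(mesh, optical, geometry,
                                       step = 1e-6, elements) {
  if (step <= 0) stop("invalid-argument: step must be positive")
  if (length(elements) == 0L) stop("invalid-argument: empty element subset")
  if (step < 1e-12) warning("finite-difference step may underflow")
  J <- matrix(0, nrow(geometry$pairs), length(elements))
  perturbed <- function(e, delta) {
    out <- optical # kappa left untouched: absorption-only derivative
    out$mu_a[e] <- out$mu_a[e] + delta
    out
  }
  for (k in seq_along(elements)) {
    e <- elements[k]
    m_up <- predict_measurements_from_map(perturbed(e, step), mesh, geometry)
    m_dn <- predict_measurements_from_map(perturbed(e, -step), mesh, geometry)
    J[, k] <- (m_up$values - m_dn$values) / (2 * step)
  }
  attr(J, "provenance") <- "finite-difference"
  attr(J, "parameter") <- "mu_a"
  J
}

#' Broyden rank-1 Jacobian update
#'
#' The quasi-Newton secant update
#' `J_new = J + (delta_F - J delta_mu) delta_mu^T / (delta_mu . delta_mu)`:
#' among all matrices satisfying the secant condition
#' `J_new delta_mu = delta_F` it is the one closest to `J` in Frobenius
#' norm, and the correction has rank at most 1.  A vanishing step
#' (`||delta_mu||^2 <= tol`) skips the update and returns `J` unchanged
#' with attribute `broyden_skipped = TRUE`.
#'
#' @param J current Jacobian (n_pairs x n_elements).
#' @param delta_mu parameter step, length n_elements.
#' @param delta_F observed change of the predicted data over the step,
#'   length n_pairs.
#' @param tol squared-norm threshold below which the update is skipped.
#' @return The updated Jacobian with `provenance = "broyden-updated"`.
#' @export
broyden_update <- function(J, delta_mu, delta_F, tol = 1e-300) {
  if (length(delta_mu) != ncol(J) || length(delta_F) != nrow(J)) {
    stop("invalid-argument: shape mismatch in broyden_update")
  }
  nrm2 <- sum(delta_mu^2)
  if (nrm2 <= tol) {
    attr(J, "broyden_skipped") <- TRUE
    return(J)
  }
  resid <- delta_F - as.vector(J %*% delta_mu)
  J_new <- J + tcrossprod(resid, delta_mu) / nrm2
  attr(J_new, "provenance") <- "broyden-updated"
  attr(J_new, "parameter") <- attr(J, "parameter")
  J_new
}

#' Export a Jacobian in Matrix Market array format with a JSON sidecar
#'
#' The sidecar records the row (source-detector pair) and column (element)
#' ordering so the matrix can be interpreted outside the package.
#'
#' @param J dense Jacobian matrix.
#' @param geometry the geometry defining the row order.
#' @param path output `.mtx` path; sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_jacobian_mtx <- function(J, geometry, path) {
  con <- file(path, "w")
  writeLines("%%MatrixMarket matrix array real general", con)
  writeLines(sprintf("%d %d", nrow(J), ncol(J)), con)
  writeLines(sprintf("%.17g", as.vector(J)), con)
  close(con)
  jsonlite::write_json(
    list(
      rows = "source-detector pairs, plane-major then source then detector",
      n_pairs = nrow(J), n_elements = ncol(J),
      parameter = attr(J, "parameter") %||% "mu_a",
      provenance = attr(J, "provenance") %||% "unknown",
      pairs = geometry$pairs[, c("plane", "source", "detector")]
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
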