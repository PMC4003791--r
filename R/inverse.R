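# Model-based iterative image reconstruction (MoBIIR).
#
# Per iteration: forward-solve the current absorption map, form the data
# misfit dM = M^E - M^C, take a regularized Levenberg-Marquardt step
# dmu = (J^T J + lambda I)^{-1} J^T dM, clamp to the positivity floor, and
# maintain the Jacobian by Broyden rank-1 updates — the full adjoint
# Jacobian is computed only once, at the initial (homogeneous) estimate.

#' Data misfit and mean squared error between two measurement vectors
#'
#' @param m_e,m_c `measurement_set`s or plain numeric vectors of equal
#'   length (experimental and computed data).
#' @return List with `misfit` (L2 norm of the difference) and `mse` (mean
#'   of squared differences).
#' @export
cost_and_mse <- function(m_e, m_c) {
  a <- if (inherits(m_e, "measurement_set")) m_e$values else as.numeric(m_e)
  b <- if (inherits(m_c, "measurement_set")) m_c$values else as.numeric(m_c)
  if (length(a) != length(b)) stop("invalid-argument: measurement vectors differ in length")
  d <- a - b
  list(misfit = sqrt(sum(d^2)), mse = mean(d^2))
}

#' Regularized Levenberg-Marquardt parameter step
#'
#' Solves the damped normal equations
#' `(J^T J + lambda I) delta_mu = J^T delta_M`.  When the parameter count
#' exceeds the number of measurements the algebraically identical dual form
#' `delta_mu = J^T (J J^T + lambda I)^{-1} delta_M` is solved instead, so
#' the factorized system is never larger than n_pairs x n_pairs.
#'
#' @param J Jacobian (n_pairs x n_parameters).
#' @param delta_M data misfit vector, length n_pairs.
#' @param lambda non-negative damping parameter (absolute, already scaled).
#' @return The parameter step `delta_mu` (length n_parameters); its norm is
#'   non-increasing in `lambda`.
#' @export
lm_update <- function(J, delta_M, lambda) {
  if (lambda < 0) stop("invalid-argument: lambda must be >= 0")
  delta_M <- as.numeric(delta_M)
  if (length(delta_M) != nrow(J)) stop("invalid-argument: delta_M length mismatch")
  n <- ncol(J)
  m <- nrow(J)
  if (lambda == 0 && m < n) {
    stop("regularization-required: J^T J is rank deficient (fewer measurements than parameters)")
  }
  if (n <= m) {
    A <- crossprod(J) + diag(lambda, n)
    ch <- tryCatch(chol(A), error = function(e) {
      stop("regularization-required: normal equations singular at lambda = ", lambda)
    })
    as.vector(backsolve(ch, forwardsolve(t(ch), crossprod(J, delta_M))))
  } else {
    A <- tcrossprod(J) + diag(lambda, m)
    ch <- tryCatch(chol(A), error = function(e) {
      stop("regularization-required: dual system singular at lambda = ", lambda)
    })
    as.vector(crossprod(J, backsolve(ch, forwardsolve(t(ch), delta_M))))
  }
}

#' Default MoBIIR settings
#'
#' @param max_iter maximum accepted iterations.
#' @param rel_tol stop when the relative cost change drops below this.
#' @param alpha damping scale: `lambda = alpha * trace(J^T J) / n_elements`,
#'   recomputed each iteration from the current Jacobian.
#' @param alpha_decay multiplicative easing of `alpha` per iteration
#'   (1 = constant damping).
#' @param broyden maintain the Jacobian by rank-1 updates (`TRUE`, one full
#'   adjoint build per reconstruction) or rebuild it every iteration
#'   (`FALSE`, conventional mode).
#' @param mu_floor positivity floor for `mu_a` after every update, mm^-1.
#' @param backtrack_max maximum step halvings when the cost increases.
#' @param inverse_crime_ok allow reconstructing on the same mesh the data
#'   were simulated on.
#' @return Named list of settings for [mobiir_reconstruct()].
#' @export
mobiir_settings <- function(max_iter = 25L, rel_tol = 1e-4, alpha = 1.0,
                            alpha_decay = 1.0, broyden = TRUE,
                            mu_floor = 1e-4, backtrack_max = 5L,
                            inverse_crime_ok = FALSE) {
  list(
    max_iter = as.integer(max_iter), rel_tol = rel_tol, alpha = alpha,
    alpha_decay = alpha_decay, broyden = isTRUE(broyden), mu_floor = mu_floor,
    backtrack_max = as.integer(backtrack_max),
    inverse_crime_ok = isTRUE(inverse_crime_ok)
  )
}

#' Calibrate measured data against a homogeneous reference
#'
#' Scales each measured value by the ratio of the model prediction to the
#' measured value for a homogeneous reference medium:
#' `M^cal_i = M^E_i * M^C_ref_i / M^E_ref_i`.  This is the standard DOT
#' calibration: source/detector coupling factors and, in simulation studies,
#' the systematic discretization offset between the data-generation and
#' reconstruction meshes cancel pair by pair, leaving the inclusion-induced
#' perturbation on the model's own scale.
#'
#' @param m_e measured `measurement_set` of the actual phantom.
#' @param reference_measured measurement of the homogeneous reference medium
#'   acquired the same way as `m_e`.
#' @param reference_predicted model prediction for the same homogeneous
#'   medium on the reconstruction mesh.
#' @return The calibrated `measurement_set`.
#' @export
calibrate_measurements <- function(m_e, reference_measured, reference_predicted) {
  if (length(reference_measured$values) != length(m_e$values) ||
      length(reference_predicted$values) != length(m_e$values)) {
    stop("invalid-argument: calibration vectors must match the data length")
  }
  out <- m_e
  out$values <- m_e$values * reference_predicted$values / reference_measured$values
  out$meta$calibrated <- TRUE
  out
}

#' Reconstruct an absorption map by Broyden-accelerated MoBIIR
#'
#' Iterates forward solve, misfit, Levenberg-Marquardt update and Broyden
#' Jacobian maintenance until convergence.  Steps that increase the cost are
#' backtracked (halved up to `backtrack_max` times); if no decrease is found
#' the loop terminates.
#'
#' @param m_e experimental (or simulated) `measurement_set` M^E.
#' @param reference optional `measurement_set` of the homogeneous reference
#'   medium acquired like `m_e`; when supplied, `m_e` is calibrated against
#'   the initial guess's prediction via [calibrate_measurements()] before
#'   inversion (the initial guess should then be that homogeneous medium).
#' @param mesh reconstruction [tet_mesh()] (coarser than the data mesh
#'   unless `inverse_crime_ok`).
#' @param initial initial `optical_map` (homogeneous background by
#'   default: `mu_a` 0.01, `mu_s'` 1.0 mm^-1).
#' @param settings list from [mobiir_settings()].
#' @param truth_mu optional true per-element `mu_a` on `mesh`; when given,
#'   the parameter-error MSE is tracked per iteration as a diagnostic.
#' @return A `recon_state` with fields `mu` (final per-element `mu_a`),
#'   `mu_history`, `cost_history`, `mse_history` (data-misfit MSE per
#'   accepted iterate), `mse_mu_history`, `lambda_history`, `iterations`,
#'   `status`, `jacobian_builds` and `settings`.
#' @export
mobiir_reconstruct <- function(m_e, mesh, initial = NULL,
                               settings = mobiir_settings(), truth_mu = NULL,
                               reference = NULL) {
  geometry <- m_e$geometry
  if (!is.null(m_e$meta$n_elements) && m_e$meta$n_elements == mesh$n_elements &&
      !settings$inverse_crime_ok) {
    stop(paste0(
      "inverse-crime guard: measurement data were generated on a mesh with the ",
      "same element count as the reconstruction mesh; use a finer data mesh or ",
      "set inverse_crime_ok = TRUE"
    ))
  }
  if (is.null(initial)) initial <- optical_map(mesh, 0.01, 1.0)
  optical <- initial
  n_el <- mesh$n_elements
  jacobian_builds <- 0L

  forward <- function(opt) {
    predict_measurements_from_map(opt, mesh, geometry)
  }

  m_c <- forward(optical)
  if (!is.null(reference)) {
    m_e <- calibrate_measurements(m_e, reference, m_c)
  }
  cm <- cost_and_mse(m_e, m_c)
  cost0 <- cm$misfit
  cost_history <- cm$misfit
  mse_history <- cm$mse
  mse_mu_history <- if (!is.null(truth_mu)) mean((optical$mu_a - truth_mu)^2) else NULL
  mu_history <- list(optical$mu_a)
  lambda_history <- numeric(0)

  J <- adjoint_jacobian(mesh, optical, geometry)
  jacobian_builds <- jacobian_builds + 1L
  alpha <- settings$alpha
  status <- "max-iterations"
  iter <- 0L

  while (iter < settings$max_iter) {
    lambda <- alpha * sum(J^2) / n_el
    delta_M <- m_e$values - m_c$values
    dmu <- lm_update(J, delta_M, lambda)
    # backtracking line search on the data misfit
    step <- 1
    accepted <- FALSE
    for (bt in 0:settings$backtrack_max) {
      mu_try <- pmax(optical$mu_a + step * dmu, settings$mu_floor)
      opt_try <- set_mu_a(optical, mu_try)
      m_try <- forward(opt_try)
      cost_try <- cost_and_mse(m_e, m_try)
      if (cost_try$misfit < cost_history[length(cost_history)]) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      status <- "no-decrease"
      break
    }
    iter <- iter + 1L
    mu_step <- opt_try$mu_a - optical$mu_a # actual step incl. clamping
    dF <- m_try$values - m_c$values
    optical <- opt_try
    m_c <- m_try
    cost_history <- c(cost_history, cost_try$misfit)
    mse_history <- c(mse_history, cost_try$mse)
    lambda_history <- c(lambda_history, lambda)
    mu_history[[iter + 1L]] <- optical$mu_a
    if (!is.null(truth_mu)) {
      mse_mu_history <- c(mse_mu_history, mean((optical$mu_a - truth_mu)^2))
    }
    if (cost_try$misfit > 10 * cost0) {
      state <- list(cost_history = cost_history, mu_history = mu_history)
      cond <- structure(
        class = c("mobiir_divergence", "error", "condition"),
        list(message = "divergence: cost exceeded 10x the initial misfit",
          call = sys.call(-1), trajectory = state)
      )
      stop(cond)
    }
    if (settings$broyden) {
      J <- broyden_update(J, mu_step, dF)
    } else {
      J <- adjoint_jacobian(mesh, optical, geometry)
      jacobian_builds <- jacobian_builds + 1L
    }
    alpha <- alpha * settings$alpha_decay
    prev <- cost_history[length(cost_history) - 1L]
    if (abs(prev - cost_try$misfit) < settings$rel_tol * prev) {
      status <- "converged"
      break
    }
  }

  structure(
    list(
      mu = optical$mu_a,
      optical = optical,
      mu_history = mu_history,
      cost_history = cost_history,
      mse_history = mse_history,
      mse_mu_history = mse_mu_history,
      lambda_history = lambda_history,
      iterations = iter,
      status = status,
      jacobian_builds = jacobian_builds,
      settings = settings
    ),
    class = "recon_state"
  )
}

#' @export
print.recon_state <- function(x, ...) {
  cat(sprintf(
    "recon_state: %d accepted iterations (%s); misfit %.4g -> %.4g; %d Jacobian build(s)\n",
    x$iterations, x$status, x$cost_history[1],
    x$cost_history[length(x$cost_history)], x$jacobian_builds
  ))
  cat(sprintf("  mu_a range [%.4g, %.4g] mm^-1\n", min(x$mu), max(x$mu)))
  invisible(x)
}

#' Summarize recovery of a known inclusion
#'
#' Diagnostics against a known truth: the mean reconstructed `mu_a` inside
#' the true inclusion, its contrast over the background estimate, and the
#' centroid of the top-5 percent `mu_a` elements nearest this inclusion.
#'
#' @param recon a `recon_state` (or a plain `mu_a` vector).
#' @param mesh the reconstruction mesh.
#' @param spec the true [inhomogeneity_spec()].
#' @param background_mu_a the true background absorption, mm^-1.
#' @param top_frac fraction of highest-`mu_a` elements used for the
#'   localization centroid.
#' @param other_specs list of the other true inclusions; top elements closer
#'   to one of those are assigned there, not here.
#' @return List with `mean_inside`, `contrast` (`mean_inside /
#'   background_mu_a`), `centroid` of the assigned top elements and
#'   `centroid_error` (mm; for a z-cylinder, distance in the xy-plane to the
#'   axis).
#' @export
inclusion_recovery <- function(recon, mesh, spec, background_mu_a,
                               top_frac = 0.05, other_specs = list()) {
  mu <- if (inherits(recon, "recon_state")) recon$mu else as.numeric(recon)
  inside <- inclusion_membership(mesh, spec)
  cen <- element_centroids(mesh)
  dist_to <- function(s, pts) {
    if (s$shape == "sphere") {
      sqrt(rowSums(sweep(pts, 2, s$center)^2))
    } else {
      sqrt((pts[, 1] - s$center[1])^2 + (pts[, 2] - s$center[2])^2)
    }
  }
  n_top <- max(1L, ceiling(top_frac * length(mu)))
  top <- order(mu, decreasing = TRUE)[seq_len(n_top)]
  d_here <- dist_to(spec, cen[top, , drop = FALSE])
  if (length(other_specs)) {
    d_other <- do.call(pmin, lapply(other_specs, dist_to, pts = cen[top, , drop = FALSE]))
    top <- top[d_here <= d_other]
  }
  centroid <- colMeans(cen[top, , drop = FALSE])
  centroid_err <- if (spec$shape == "sphere") {
    sqrt(sum((centroid - spec$center)^2))
  } else {
    sqrt(sum((centroid[1:2] - spec$center)^2))
  }
  list(
    mean_inside = mean(mu[inside]),
    contrast = mean(mu[inside]) / background_mu_a,
    n_inside = sum(inside),
    centroid = centroid,
    centroid_error = centroid_err
  )
}
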