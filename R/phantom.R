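# Synthetic optical phantoms, scan geometry and the measurement-noise model.
#
# The standard simulation phantom is a 60 mm diameter x 70 mm height cylinder
# with background mu_a = 0.01 mm^-1, mu_s' = 1.0 mm^-1, one absorbing sphere
# (diameter 7.9 mm, centre (0, -16, -10), mu_a = 0.02 mm^-1) and one
# z-parallel absorbing cylinder (diameter 7.9 mm, full height,
# mu_a = 0.03 mm^-1).  Inclusion membership is decided by element centroid,
# which is unambiguous for element-wise constant coefficients.

#' Construct an optical-property map
#'
#' Per-element absorption and reduced-scattering coefficients with the
#' derived diffusion coefficient `kappa = 1 / (3 * (mu_a + mu_s_prime))`.
#' The diffusion approximation assumes `mu_s_prime >> mu_a`; a warning is
#' issued when `mu_s_prime < 10 * mu_a` anywhere.
#'
#' @param mesh a [tet_mesh()] the map is defined on.
#' @param mu_a absorption coefficient, mm^-1; scalar or one value per element.
#' @param mu_s_prime reduced scattering coefficient, mm^-1; scalar or
#'   per-element.
#' @return An object of class `optical_map` with fields `mu_a`,
#'   `mu_s_prime`, `kappa` (mm) and `n_elements`.
#' @export
optical_map <- function(mesh, mu_a, mu_s_prime) {
  n <- mesh$n_elements
  mu_a <- rep_len(as.numeric(mu_a), n)
  mu_s_prime <- rep_len(as.numeric(mu_s_prime), n)
  if (any(mu_a <= 0) || any(mu_s_prime <= 0)) {
    stop("invalid-argument: mu_a and mu_s_prime must be strictly positive")
  }
  if (any(mu_s_prime < 10 * mu_a)) {
    warning("diffusion approximation questionable: mu_s_prime < 10 * mu_a in some elements")
  }
  structure(
    list(
      mu_a = mu_a,
      mu_s_prime = mu_s_prime,
      kappa = 1 / (3 * (mu_a + mu_s_prime)),
      n_elements = n
    ),
    class = "optical_map"
  )
}

#' Update the absorption of an optical map
#'
#' Replaces `mu_a` and recomputes `kappa` so the two stay consistent.
#'
#' @param optical an `optical_map`.
#' @param mu_a new per-element absorption, mm^-1.
#' @return The updated `optical_map`.
#' @export
set_mu_a <- function(optical, mu_a) {
  optical$mu_a <- rep_len(as.numeric(mu_a), optical$n_elements)
  if (any(optical$mu_a <= 0)) stop("invalid-argument: mu_a must be positive")
  optical$kappa <- 1 / (3 * (optical$mu_a + optical$mu_s_prime))
  optical
}

#' @export
print.optical_map <- function(x, ...) {
  cat(sprintf(
    "optical_map: %d elements; mu_a in [%.4g, %.4g] mm^-1; mu_s' in [%.4g, %.4g] mm^-1\n",
    x$n_elements, min(x$mu_a), max(x$mu_a), min(x$mu_s_prime), max(x$mu_s_prime)
  ))
  invisible(x)
}

#' Describe an inclusion embedded in a phantom
#'
#' @param shape `"sphere"` or `"cylinder-z"` (axis parallel to z, full
#'   height).
#' @param center for a sphere, `c(x, y, z)`; for a z-cylinder, the axis
#'   `c(x, y)` (mm).
#' @param diameter inclusion diameter in mm.
#' @param mu_a absorption inside the inclusion, mm^-1.
#' @return An `inhomogeneity_spec` list.
#' @export
inhomogeneity_spec <- function(shape = c("sphere", "cylinder-z"), center, diameter, mu_a) {
  shape <- match.arg(shape)
  if (diameter <= 0) stop("invalid-argument: diameter must be positive")
  if (shape == "sphere" && length(center) != 3L) {
    stop("invalid-argument: sphere center must be c(x, y, z)")
  }
  if (shape == "cylinder-z" && length(center) != 2L) {
    stop("invalid-argument: cylinder-z center must be the axis c(x, y)")
  }
  structure(list(shape = shape, center = as.numeric(center),
    diameter = as.numeric(diameter), mu_a = as.numeric(mu_a)),
    class = "inhomogeneity_spec")
}

# logical vector: which element centroids fall inside the inclusion
inclusion_membership <- function(mesh, spec) {
  cen <- element_centroids(mesh)
  r <- spec$diameter / 2
  if (spec$shape == "sphere") {
    rowSums(sweep(cen, 2, spec$center)^2) <= r^2
  } else {
    (cen[, 1] - spec$center[1])^2 + (cen[, 2] - spec$center[2])^2 <= r^2
  }
}

#' Build a phantom from background coefficients and inclusions
#'
#' @param mesh a [tet_mesh()].
#' @param background_mu_a,background_mu_s background coefficients, mm^-1.
#' @param inclusions list of [inhomogeneity_spec()] objects; later inclusions
#'   override earlier ones where they overlap.  `mu_s_prime` is unchanged
#'   inside inclusions.
#' @return An `optical_map`; warns if an inclusion captures no element
#'   centroid (mesh too coarse).
#' @export
build_phantom <- function(mesh, background_mu_a, background_mu_s, inclusions = list()) {
  mu_a <- rep(background_mu_a, mesh$n_elements)
  for (spec in inclusions) {
    inside <- inclusion_membership(mesh, spec)
    if (!any(inside)) {
      warning(sprintf(
        "inclusion (%s, d = %g mm) contains no element centroid: mesh too coarse",
        spec$shape, spec$diameter
      ))
    }
    mu_a[inside] <- spec$mu_a
  }
  optical_map(mesh, mu_a, background_mu_s)
}

#' The standard simulation phantom
#'
#' Background `mu_a = 0.01`, `mu_s' = 1.0` mm^-1 with two absorbers: a
#' sphere of diameter 7.9 mm centred at (0, -16, -10) with
#' `mu_a = 0.02` mm^-1, and a z-parallel cylinder of diameter 7.9 mm running
#' the full height with `mu_a = 0.03` mm^-1.  The cylinder axis defaults to
#' (0, +16), mirroring the sphere on the opposite side of the domain.
#'
#' @param mesh a [tet_mesh()] of the 60 x 70 mm cylinder (or a scaled
#'   variant).
#' @param sphere_center,sphere_diameter,sphere_mu_a sphere inclusion
#'   parameters.
#' @param cylinder_axis,cylinder_diameter,cylinder_mu_a cylinder inclusion
#'   parameters (`cylinder_axis` is the x, y position of the axis).
#' @param background_mu_a,background_mu_s background coefficients, mm^-1.
#' @return An `optical_map`.
#' @export
build_simulation_phantom <- function(mesh,
                                     background_mu_a = 0.01,
                                     background_mu_s = 1.0,
                                     sphere_center = c(0, -16, -10),
                                     sphere_diameter = 7.9,
                                     sphere_mu_a = 0.02,
                                     cylinder_axis = c(0, 16),
                                     cylinder_diameter = 7.9,
                                     cylinder_mu_a = 0.03) {
  build_phantom(mesh, background_mu_a, background_mu_s, list(
    inhomogeneity_spec("sphere", sphere_center, sphere_diameter, sphere_mu_a),
    inhomogeneity_spec("cylinder-z", cylinder_axis, cylinder_diameter, cylinder_mu_a)
  ))
}

#' The experimental-style phantom
#'
#' Background `mu_a = 0.005`, `mu_s' = 0.8` mm^-1 with two full-height
#' cylindrical absorbers of diameters 10 and 12 mm and `mu_a = 0.02` and
#' `0.035` mm^-1.  Axis positions default to (0, -16) and (0, +16).
#'
#' @param mesh a [tet_mesh()].
#' @param axes list of two `c(x, y)` axis positions.
#' @param n_inclusions 0 for a homogeneous map, 2 (default) for both
#'   absorbers.
#' @return An `optical_map`.
#' @export
build_experimental_phantom <- function(mesh, axes = list(c(0, -16), c(0, 16)),
                                       n_inclusions = 2L) {
  incl <- list(
    inhomogeneity_spec("cylinder-z", axes[[1]], 10, 0.02),
    inhomogeneity_spec("cylinder-z", axes[[2]], 12, 0.035)
  )[seq_len(n_inclusions)]
  build_phantom(mesh, 0.005, 0.8, incl)
}

#' Absorption value at a point
#'
#' Looks up the element-wise constant `mu_a` of the element containing the
#' point.
#'
#' @param optical an `optical_map`.
#' @param mesh the [tet_mesh()] the map lives on.
#' @param point `c(x, y, z)` in mm.
#' @return `mu_a` at the point, mm^-1.
#' @export
mu_a_at <- function(optical, mesh, point) {
  e <- locate_point(mesh, point)
  if (is.na(e)) stop("invalid-argument: point outside mesh")
  optical$mu_a[e]
}

# ---- scan geometry ----------------------------------------------------------

#' Build the circular scan geometry
#'
#' Sources and detectors sit on the lateral surface of the cylinder in 2 or 3
#' measurement planes.  Each plane carries `n_sources` equally spaced source
#' azimuths (30 degree steps for the default 12) and, for every source,
#' `n_detectors` detectors on the opposite side at azimuths
#' `detector_arc[1]` to `detector_arc[2]` degrees relative to the source (20
#' degree steps for the default 7 spanning 120-240).  Pair order is
#' plane-major, then source, then detector.
#'
#' @param n_planes 2 or 3; plane z-levels default to `c(-10, 10)` and
#'   `c(-15, 0, 15)` mm.
#' @param radius,height cylinder dimensions in mm.
#' @param n_sources,n_detectors positions per plane.
#' @param detector_arc azimuth range of the detector fan relative to the
#'   source, degrees.
#' @param plane_z optional explicit z-levels overriding the defaults.
#' @param fresnel_A Fresnel reflection coefficient of the Robin boundary
#'   condition, carried as an acquisition setting (1 = index-matched).
#' @return A `scan_geometry` with a `pairs` data frame (plane, source,
#'   detector indices and both positions) plus unique `sources` and
#'   `detectors` tables.
#' @export
build_scan_geometry <- function(n_planes = 2L, radius = 30, height = 70,
                                n_sources = 12L, n_detectors = 7L,
                                detector_arc = c(120, 240),
                                plane_z = NULL, fresnel_A = 1.0) {
  if (!n_planes %in% c(2L, 3L)) stop("invalid-argument: n_planes must be 2 or 3")
  if (is.null(plane_z)) {
    plane_z <- if (n_planes == 2L) c(-10, 10) else c(-15, 0, 15)
  }
  plane_z <- plane_z * height / 70 # scale with non-standard domains
  src_az <- 2 * pi * (seq_len(n_sources) - 1L) / n_sources
  rel <- seq(detector_arc[1], detector_arc[2], length.out = n_detectors) * pi / 180
  rows <- vector("list", n_planes * n_sources)
  k <- 0L
  for (p in seq_len(n_planes)) {
    for (s in seq_len(n_sources)) {
      k <- k + 1L
      az_d <- src_az[s] + rel
      rows[[k]] <- data.frame(
        plane = p, source = s, detector = seq_len(n_detectors),
        sx = radius * cos(src_az[s]), sy = radius * sin(src_az[s]), sz = plane_z[p],
        dx = radius * cos(az_d), dy = radius * sin(az_d), dz = plane_z[p]
      )
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  structure(
    list(
      n_planes = n_planes, plane_z = plane_z, radius = radius, height = height,
      n_sources = n_sources, n_detectors = n_detectors,
      detector_arc = detector_arc, fresnel_A = fresnel_A,
      pairs = pairs,
      sources = unique_positions(pairs[, c("sx", "sy", "sz")]),
      detectors = unique_positions(pairs[, c("dx", "dy", "dz")])
    ),
    class = "scan_geometry"
  )
}

# de-duplicate positions (rows) up to rounding; returns matrix + index map
unique_positions <- function(xyz) {
  m <- as.matrix(xyz)
  key <- apply(round(m, 9), 1, paste, collapse = "_")
  u <- !duplicated(key)
  list(positions = m[u, , drop = FALSE], index = match(key, key[u]))
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "scan_geometry: %d planes (z = %s mm), %d sources x %d detectors per plane -> %d pairs\n",
    x$n_planes, paste(format(x$plane_z), collapse = ", "),
    x$n_sources, x$n_detectors, nrow(x$pairs)
  ))
  invisible(x)
}

# ---- measurement sets -------------------------------------------------------

#' Construct a measurement set
#'
#' Ordered boundary data, one value per source-detector pair of a
#' [build_scan_geometry()] geometry, plus provenance metadata.
#'
#' @param values numeric vector in geometry pair order.
#' @param geometry the `scan_geometry` the values refer to.
#' @param meta named list of provenance fields (mesh size, seed, noise
#'   level, ...).
#' @return A `measurement_set`.
#' @export
measurement_set <- function(values, geometry, meta = list()) {
  values <- as.numeric(values)
  if (length(values) != nrow(geometry$pairs)) {
    stop("invalid-argument: one value per source-detector pair required")
  }
  if (any(!is.finite(values))) stop("invalid-argument: non-finite measurement values")
  structure(list(values = values, geometry = geometry, meta = meta),
    class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf(
    "measurement_set: %d values in [%.3g, %.3g]; noise level %s\n",
    length(x$values), min(x$values), max(x$values),
    if (is.null(x$meta$noise_level)) "0" else format(x$meta$noise_level)
  ))
  invisible(x)
}

#' Forward-simulate boundary measurements for a phantom
#'
#' Solves the diffusion forward model on `mesh` for every source of the
#' geometry and reads the photon density at each detector, producing the
#' "experimental" data vector M^E in geometry pair order.  To avoid the
#' inverse crime, simulate on a strictly finer mesh than the one used for
#' reconstruction.
#'
#' @param truth an `optical_map` on `mesh` (the true phantom).
#' @param mesh the (fine) [tet_mesh()] used for data generation.
#' @param geometry a [build_scan_geometry()] geometry.
#' @return A `measurement_set` with all-positive values and metadata
#'   recording the mesh size.
#' @export
simulate_measurements <- function(truth, mesh, geometry) {
  ms <- predict_measurements_from_map(truth, mesh, geometry)
  ms$meta$kind <- "simulated"
  ms$meta$noise_level <- 0
  ms
}

#' Add multiplicative white Gaussian noise to measurements
#'
#' `noisy_i = clean_i * (1 + level * eps_i)` with independent standard-normal
#' `eps_i`; the stated percentage noise level of the robustness experiments
#' is relative (proportional) noise, which is scale-free across detectors.
#'
#' @param clean a `measurement_set`, or a plain numeric vector.
#' @param level relative noise level as a fraction (0.02 = 2 percent).
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return A noisy `measurement_set` with `noise_level` and `seed` recorded
#'   (or a numeric vector when `clean` is one).
#' @export
add_noise <- function(clean, level = 0.02, seed = 1L) {
  if (!is.numeric(level) || level < 0) stop("invalid-argument: noise level must be >= 0")
  if (level == 0) return(clean)
  plain <- is.numeric(clean)
  values <- if (plain) as.numeric(clean) else clean$values
  # keep the draw local so callers' RNG state is untouched
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  e <- stats::rnorm(length(values))
  noisy <- values * (1 + level * e)
  if (plain) return(noisy)
  out <- clean
  out$values <- noisy
  out$meta$noise_level <- level
  out$meta$seed <- seed
  out
}

#' Write a measurement set as TSV plus JSON sidecar
#'
#' The TSV has one row per source-detector pair with columns `plane`,
#' `source_index`, `detector_index`, the two positions and `value`; the
#' metadata (mesh size, seed, noise level, geometry settings) goes to
#' `<path>.json`.
#'
#' @param ms a `measurement_set`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(ms, path) {
  p <- ms$geometry$pairs
  tab <- data.frame(
    plane = p$plane, source_index = p$source, detector_index = p$detector,
    source_x = p$sx, source_y = p$sy, source_z = p$sz,
    detector_x = p$dx, detector_y = p$dy, detector_z = p$dz,
    value = ms$values
  )
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- ms$meta
  meta$geometry <- list(
    n_planes = ms$geometry$n_planes, plane_z = ms$geometry$plane_z,
    radius = ms$geometry$radius, height = ms$geometry$height,
    n_sources = ms$geometry$n_sources, n_detectors = ms$geometry$n_detectors,
    detector_arc = ms$geometry$detector_arc, fresnel_A = ms$geometry$fresnel_A
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a measurement set written by [write_measurements()]
#'
#' @param path TSV path (expects `<path>.json` sidecar next to it).
#' @return A `measurement_set`.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("parse-error: missing metadata sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  g <- meta$geometry
  geometry <- build_scan_geometry(
    n_planes = g$n_planes, radius = g$radius, height = g$height,
    n_sources = g$n_sources, n_detectors = g$n_detectors,
    detector_arc = g$detector_arc, plane_z = g$plane_z * 70 / g$height,
    fresnel_A = g$fresnel_A
  )
  meta$geometry <- NULL
  measurement_set(tab$value, geometry, meta)
}
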