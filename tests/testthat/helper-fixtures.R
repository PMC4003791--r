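# Shared fixtures, memoised so expensive meshes are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# ~1.1k-element cylinder: enough structure for topology/assembly tests
tiny_mesh <- function() memo("tiny", generate_cylinder_mesh(30, 70, c(3, 7)))

# ~9k elements: the smallest extrusion whose homogeneous boundary data are
# strictly positive everywhere; used where physics matters
small_mesh <- function() memo("small", generate_cylinder_mesh(30, 70, c(6, 14)))

coarse_mesh <- function() memo("coarse", generate_cylinder_mesh(30, 70, "coarse"))
fine_mesh <- function() memo("fine", generate_cylinder_mesh(30, 70, "fine"))

single_tet <- function() {
  tet_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    matrix(c(1L, 2L, 3L, 4L), 1)
  )
}

two_tets <- function() {
  tet_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)),
    rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L))
  )
}

random_tet <- function() {
  repeat {
    p <- matrix(stats::runif(12, -1, 1), 4, 3)
    if (element_volume(p) > 1e-3) return(p)
  }
}

# true inclusion specs of the standard simulation phantom
sphere_spec <- function() inhomogeneity_spec("sphere", c(0, -16, -10), 7.9, 0.02)
cylinder_spec <- function() inhomogeneity_spec("cylinder-z", c(0, 16), 7.9, 0.03)

# simulated data for the standard phantom study (fine data mesh) plus the
# homogeneous calibration reference; memoised for the acceptance blocks
phantom_study <- function() {
  memo("study", {
    g <- build_scan_geometry(n_planes = 2)
    fm <- fine_mesh()
    list(
      geometry = g,
      m_e = simulate_measurements(build_simulation_phantom(fm), fm, g),
      reference = simulate_measurements(optical_map(fm, 0.01, 1.0), fm, g)
    )
  })
}
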