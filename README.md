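# mobiir

Fully three-dimensional **diffuse optical tomography (DOT)** in R: a
finite-element forward solver for the photon-diffusion equation on
tetrahedral meshes, adjoint sensitivity matrices, and a Broyden-accelerated
Levenberg–Marquardt reconstruction loop (model-based iterative image
reconstruction, MoBIIR), exercised end to end on synthetic cylindrical
phantoms.

## Who this is for

DOT recovers maps of the tissue absorption coefficient μₐ (mm⁻¹) from
near-infrared light measurements on the tissue surface — the physical basis
of optical breast imaging and functional near-infrared brain imaging.  The
package is aimed at people developing or teaching DOT reconstruction
algorithms: everything from mesh generation through data simulation to the
inverse solve is plain, inspectable R, with file formats (Gmsh MSH, VTK,
Matrix Market, TSV/JSON) that interoperate with standard tools.

## The model

Light transport is modelled by the continuous-wave diffusion approximation

    −∇·κ(r)∇Φ(r) + μₐ(r)Φ(r) = q₀(r),     κ = 1 / (3(μₐ + μₛ′)),

with the Robin boundary condition `Φ + 2Aκ ∂Φ/∂n = 0` (A = Fresnel
reflection coefficient).  Galerkin finite elements on linear tetrahedra turn
this into the sparse symmetric positive-definite system

    [K(κ) + C(μₐ) + F] Φ = Q,

solved by sparse Cholesky factorization.  The inverse problem minimises
`χ(μₐ) = ‖Mᴱ − F(μₐ)‖₂` by damped Gauss–Newton steps

    Δμ = (JᵀJ + λI)⁻¹ Jᵀ ΔM,      ΔM = Mᴱ − Mᶜ,

where the Jacobian J is built **once** by the adjoint method
(J entries are −∫ₑ Φ_s Φ_d dV over each element) and thereafter maintained by
Broyden rank-1 secant updates

    J_{i+1} = J_i + (ΔM_i − J_i Δμ_i) Δμ_iᵀ / (Δμ_i·Δμ_i),

which removes the dominant per-iteration cost of classical Newton-type DOT
while preserving reconstruction quality.

## Worked example

Simulate the standard phantom study — a 60 mm × 70 mm cylinder
(μₐ = 0.01 mm⁻¹, μₛ′ = 1.0 mm⁻¹) containing a 7.9 mm absorbing sphere
(μₐ = 0.02) and a full-height 7.9 mm absorbing cylinder (μₐ = 0.03),
scanned by 12 sources × 7 detectors in 2 planes — and reconstruct it on a
coarser mesh:

```r
library(mobiir)

mesh     <- generate_cylinder_mesh(radius = 30, height = 70, resolution = "coarse")
geometry <- build_scan_geometry(n_planes = 2)

# data generation on a finer mesh (avoids the inverse crime), 2% noise
data_mesh <- generate_cylinder_mesh(30, 70, "fine")
m_e       <- simulate_measurements(build_simulation_phantom(data_mesh), data_mesh, geometry)
reference <- simulate_measurements(optical_map(data_mesh, 0.01, 1.0), data_mesh, geometry)
m_e       <- add_noise(m_e, level = 0.02, seed = 1)

rec <- mobiir_reconstruct(m_e, mesh, settings = mobiir_settings(max_iter = 15),
                          reference = reference)
rec
#> recon_state: 15 accepted iterations (max-iterations); misfit 5.556e-08 -> 7.498e-10; 1 Jacobian build(s)
#>   mu_a range [0.001549, 0.0234] mm^-1

cyl <- inhomogeneity_spec("cylinder-z", c(0, 16), 7.9, 0.03)
sph <- inhomogeneity_spec("sphere", c(0, -16, -10), 7.9, 0.02)
unlist(inclusion_recovery(rec, mesh, cyl, 0.01, other_specs = list(sph)))[c(2, 7)]
#>       contrast centroid_error
#>       1.423242       2.303075
```

The misfit drops by two orders of magnitude with a *single* adjoint Jacobian
build; the cylindrical absorber is recovered at 1.42× the background mean
within its true footprint and localized to 2.3 mm of its true axis.
`write_vtk_cell_data(mesh, rec$mu, "recon.vtk")` exports the map for
ParaView.

A command-line pipeline wrapping the same functions lives in
`inst/cli/dot.R`:

```sh
Rscript inst/cli/dot.R simulate    --config study.yaml --out run1
Rscript inst/cli/dot.R reconstruct --config study.yaml --out run1
Rscript inst/cli/dot.R report      --config study.yaml --out run1
```

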