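# fascitrace

Reconstruction of skeletal-muscle fascicle architecture from a volumetric
mesh of the muscle shape, using a Laplacian (harmonic) vector field.

## The problem

Muscle force is transmitted along fascicles — bundles of parallel fibers
running from the origin attachment to the insertion attachment. Volumetric
(finite-element) muscle models need a fascicle orientation at every point of
the muscle volume, but in-vivo measurements (ultrasound, DT-MRI) are sparse,
noisy, or unavailable. Observed fascicle trajectories share four physical
properties: they do not cross, do not branch, do not reverse direction
abruptly, and connect attachment to attachment. A vector field with exactly
these properties is one that is simultaneously rotation-free and
divergence-free, i.e. the gradient of a harmonic potential:

    v = ∇φ,   ∇²φ = 0   in the muscle volume Ω

with Neumann flux boundary conditions: zero normal flux on the muscle belly
surface (fascicles never pierce it) and a uniform flux on each tendon
attachment, balanced so the compatibility (mass) condition holds:

    g_o A_o + g_i A_i = 0

where `g_o, g_i` are the flux densities and `A_o, A_i` the areas of the
origin and insertion attachments. Only the orientation of `v` matters: the
solution is linear in the flux magnitude, and reversing the fluxes only
flips its sign.

`fascitrace` discretizes this problem with a cell-centered finite-volume
scheme on simplicial meshes (triangles in 2D, tetrahedra in 3D), which
yields a *conservative* single-valued flux through every element face.
Fascicle tracts are then traced element by element in barycentric
coordinates: inside a simplex with outward face fluxes `f_i` (face `i`
opposite vertex `i`, Σf_i = 0), the velocity is the unique constant vector

    v = -(1/(n V)) Σ_i f_i x_i

each barycentric coordinate decays linearly, `dλ_i/dt = -f_i/(nV)`, the
element intersection times are `t_i = λ_i n V / f_i` (for `f_i > 0`), the
time of flight is the minimum non-negative `t_i`, and the exit point is
`λ' = λ - τ f/(nV)`. Because the tracing is flux-consistent, tracts cannot
terminate inside the volume or on the zero-flux belly — every tract runs
attachment to attachment. Raw tracts are spline-smoothed and resampled to
100 equidistant points; fascicle length is the sum of consecutive point
distances, and the pennation angle at a seed is the mean of the angles
between the attachment tangent plane and the vectors from the seed to the
next five tract points (5% of the fascicle).

## Worked example

The classic workflow check: a 10 × 4 × 4 mm box (4998 tetrahedra) whose
exact solution is a uniform field along x.

```r
library(fascitrace)
res <- run_demo("box3d")
#> [mesh] building mesh
#> [bc] uniform attachment flux, total 1
#> [solve] finite-volume Laplace solve
#> [balance] ||r||2/Q = 7.768e-10
#> [trace] seeding patch 'insertion'
#> [trace] 98/98 tracts reached an attachment
#> [metrics] smoothing, length, pennation

print(res$balance)
#> balance_report: ||r||2/Q = 7.768e-10, max|r|/Q = 3.503e-11, boundary = 0.000e+00 [PASS]

subset(res$summary, row_type != "tract")
#>     seed_id     patch status length_mm pennation_deg row_type
#> 99       NA insertion   <NA>        10            90     mean
#> 100      NA insertion   <NA>         0             0       sd
#> 101      NA insertion   <NA>        10            90      min
#> 102      NA insertion   <NA>        10            90      max
```

Reading: the per-element flux-balance residual (two-norm, normalized by the
total inflow `Q`) ended below the 1e-8 stopping criterion; all 98 tracts
seeded on the insertion wall reached the origin wall; every fascicle length
equals the box length (10 mm) and every pennation angle is 90° (tracts
perpendicular to the end wall), as the uniform field requires.

Anatomical meshes come in as ASCII Gmsh MSH (v2.2 or v4.1) with physical
groups naming the attachment and belly surfaces:

```r
mesh <- read_gmsh_msh("tibialis.msh",
                      c(prox = "origin", dist = "insertion",
                        side = "belly"))
cfg <- run_config(mesh_file = "tibialis.msh",
                  patch_map = c(prox = "origin", dist = "insertion",
                                side = "belly"),
                  out_dir = "out")
run_pipeline(cfg)   # writes mesh+vector VTK, tract polylines, metrics CSV
```

A command-line front end with `run`, `demo`, and `check` commands lives in
`inst/cli/fascitrace.R` (JSON config mirrored by flags; exit codes 0/2/3
for success / configuration error / numeric failure).

## Scope

The package accepts finished volume meshes; MRI segmentation, surface
remeshing, and volume meshing are upstream concerns. Non-uniform attachment
fluxes are supported through the per-face boundary table
(`make_face_flux_bc`), but the optimization loop that would fit them to
measurements is out of scope. See `vignettes/fascicle-reconstruction.Rmd`
for the methods discussion.
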