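---
title: "Methods: Laplacian fascicle reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Laplacian fascicle reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fascitrace)
```

## Model and assumptions

Fascicle trajectories in most skeletal muscles are co-axially aligned
(non-crossing), non-branching, smoothly turning, and run from the origin
attachment to the insertion attachment. `fascitrace` encodes these
properties as a harmonic vector field: the orientation field is the
gradient of a potential, `v = ∇φ`, with `∇²φ = 0` in the muscle volume.
Rotation-freeness gives non-crossing alignment; divergence-freeness gives
non-branching, attachment-to-attachment behavior.

The boundary conditions are pure Neumann: zero normal flux on the muscle
belly, and a *uniform* flux density over each attachment surface, the two
attachments balanced so that `g_o A_o + g_i A_i = 0`. Uniform attachment
flux is a modeling hypothesis, not a derived fact: it states that fascicles
insert with uniform density over the tendon area. The per-face boundary
table (`make_face_flux_bc`) is the extension point for non-uniform
distributions; fitting them to measured pennation or length data would
require an optimization loop that this package deliberately does not
provide.

Assumptions and their consequences:

* **Pure Neumann problem.** The potential is defined up to an additive
  constant. We remove the nullspace by projecting iterates to zero mean and
  then shifting so one pinned element has a prescribed value
  (`pin_element = 1`, `pin_value = 0` by default). Pinning is deterministic
  here (some implementations pin a randomly chosen element instead); the
  field `v` is invariant to the choice, which the test suite verifies to
  1e-8.
* **Linearity.** Scaling the total flux scales `φ` and all fluxes; tract
  geometry is unchanged. Reversing the boundary fluxes negates the field
  and reverses tracts. Both are tested properties, so `total_flux` defaults
  to 1 and carries no physical meaning.
* **No twisting.** A rotation-free field cannot represent genuinely
  twisting fascicle systems (e.g. pectoralis major); that is a model
  limitation, not a numerical one.

## Discretization

The Laplace equation is discretized with a cell-centered finite-volume
scheme: each element's outward face fluxes must sum to zero. Interior
faces use a two-point orthogonal flux, `a_f (φ_N - φ_O)` with
`a_f = |N|²/(N·d)` (over-relaxed decomposition `N = a_f d + k`), plus an
explicit *deferred* non-orthogonality correction `ḡ_f · k`, where `ḡ_f`
is the average of the adjacent cells' gradients. Cell gradients are
reconstructed by the flux-weighted Green–Gauss formula
`g_E = (1/V) Σ_f F_f (c_f - c_E)`, which is exact for fields with constant
gradient (including at boundary elements, because the prescribed boundary
fluxes enter the sum). A weighted least-squares reconstruction was
evaluated and gave indistinguishable convergence, so the simpler formula
stayed.

The outer loop re-assembles and re-solves until the two-norm of the
per-element flux-balance residual drops below `outer_tol` (default 1e-8)
times the total inflow, or `max_outer` (default 50) is reached, which
flags a warning. The inner
symmetric system is solved by conjugate gradients with a Jacobi
preconditioner. Its relative tolerance defaults to 1e-8, but is tightened
adaptively (`min(inner_rtol, 0.1 · outer_tol · Q / ‖b‖)`): without this the
inner defect floors the outer residual near `1e-8 · ‖b‖`, which on some
geometries (the fan archetype) sits just above the outer target, and the
correction loop would stall for no physical reason.

Boundary fluxes are imposed exactly; compatibility is enforced by
renormalizing the outflow densities so the global balance closes to machine
precision before assembly (an inconsistent singular system never converges).

### What remains after convergence

The converged field is *almost* conservative: each element's flux imbalance
`r_E` is bounded by `outer_tol × Q` in the aggregate two-norm. The tracer
neutralizes the remainder locally — inside each element it works with
`q_i = f_i - r_E/(n+1)` — so that the tracing formulas see an exactly
divergence-free element while the shared face fluxes (and thus neighbor
consistency) stay untouched. Redistributing the residual on shared faces
instead would fix one element while unbalancing its neighbor.

## Tracing

Within a simplex, the constant velocity consistent with outward face
fluxes `f_i` (face `i` opposite vertex `i`, `Σ f_i = 0`) is
`v = -(1/(nV)) Σ_i f_i x_i`; each barycentric coordinate then changes at
the constant rate `dλ_i/dt = -f_i/(nV)`, giving intersection times
`t_i = λ_i n V / f_i` for decreasing coordinates (`f_i > 0`), time of
flight `τ = min` finite `t_i`, and exit state `λ' = λ - τ f/(nV)`. This
reconstruction was verified two ways before being relied on: symbolically
(the divergence-theorem identity `Σ_f F_f c_f = V v` for constant `v`
reduces to the formula when `Σ f = 0`) and against a brute-force oracle
(least-squares fit of a constant vector to the face-flux constraints, and
analytic ray/face intersection on 1000 random simplices).

Numerical hygiene choices:

* **Tie-breaking.** When two intersection times agree within 1e-12
  relative (exit through an edge or vertex), the lower local face index
  wins and the next element's entry coordinates are nudged toward its
  interior by 1e-10, preventing corner cycling deterministically.
* **λ hygiene.** After every step coordinates are clipped to [0, 1],
  components below 1e-12 snapped to zero, and the vector renormalized;
  drift across long trails otherwise accumulates.
* **max_steps** defaults to 10× the element count. A gradient field cannot
  cycle (the element-wise potential strictly increases along a downstream
  tract — a tested property), so reaching the bound indicates a defect.

Seeds are placed deterministically at attachment-face centroids (plus fixed
interior offsets for `per_face > 1`). Seeding density is a free modeling
choice; centroids-per-face is this package's default, exposed in the
configuration.

## Post-processing and metrics

Raw tracts are polylines with a kink at every element face. They are
subsampled to about `subsample_target = 30` control points (endpoints
kept), fitted per coordinate with a cubic smoothing spline under
chord-length parameterization, endpoint interpolation enforced by a linear
blend, and resampled at `n_points = 100` stations whose consecutive chord
distances are equalized by a short fixed-point iteration. The subsampling
rate before the spline is a tunable default (30), exposed in the
configuration.

The `smoothing` parameter is the maximum allowed deviation of the spline
from the raw polyline, in mm; its default is half the median raw segment
length, i.e. the scale of the mesh-induced noise the smoothing is meant to
remove. The spline flexibility (equivalent degrees of freedom) is chosen
adaptively as the stiffest fit meeting that bound, falling back to an
interpolating spline when nothing stiffer qualifies.

Fascicle length is the chord sum over the 100 resampled points by
default; the raw polyline remains available for users who prefer the
unsmoothed measure.
The pennation angle at a seed is `mean(asin(|(p_k − p_1)·n̂| / |p_k − p_1|))`
for `k = 2..6` — five inter-point steps of a 100-point tract, i.e. 5% of
the fascicle — in degrees, clipped to [0, 90].

The tangent-plane normal `n̂` is the normalized average of the outward unit
normals of the seed face and its vertex-adjacent boundary faces
**restricted to the seed face's own patch**. Averaging across the
attachment rim onto belly faces would tilt the plane at rim seeds (a corner
seed on a box end wall would report ~45–63° instead of 90°); the tangent
plane belongs to the tendon surface, so same-patch averaging is the
default, with `same_patch = FALSE` and edge-adjacency available as options.

## Synthetic geometries and what green tests establish

The bundled generators are parameterized archetypes of architectural
classes, not replicas of any anatomical outline: parallel strip
(`make_rect2d`), fanned trapezoid with asymmetric attachments
(`make_fan2d`), curved annulus sector (`make_annulus_sector2d`), and the
3D box (`make_box3d`, Kuhn 6-tet split) used as the uniform-field
verification case. Default demo dimensions (strip 10×1 mm, fan 4→1×3 mm,
sector r∈[1,2] mm over a quarter turn, box 10×4×4 mm) are desk-scale
stand-ins; anatomical meshes run ~300k elements and are out of scope. The
radial "pectoral diaphragm"-like class is covered by the annulus archetype,
whose closed form `φ = c·θ`, `v = (c/r)ê_θ` provides the analytic oracle;
the exact per-face flux is the integral `c·log(r₂/r₁)` over each radial
edge face. An internal-tendon (bipennate) archetype is not provided; the
multi-patch boundary API supports such cases when a tagged mesh is
supplied.

These geometries have structured meshes, exact patch boundaries and (for
box and strip) fields with zero discretization error. A green test
establishes correctness of the solver and tracer machinery and the claimed
invariants; it does not establish anatomical fidelity, behavior on
unstructured anisotropic meshes with graded attachment resolution, or the
realism of the uniform-flux hypothesis for any particular muscle.

Convergence order in the refinement study is measured against the actual
maximum element diameter of each mesh, not the nominal target `h`: the
generators treat `h` as a target edge length (`ceiling` division), and the
arc cells at the outer radius are ~1.33× nominal, so nominal `h` neither
matches nor scales exactly with the true mesh size across levels.

## Known limitations

* Two outer-loop engineering constants (`max_outer = 50`, the adaptive
  inner-tolerance factor 0.1) are engineering defaults; highly
  non-orthogonal meshes may need a larger `max_outer` (a warning, not
  silent failure, results otherwise).
* The scheme is first-order in the element orientation vectors on skewed
  meshes; attachment-area refinement (as practiced for anatomical meshes)
  is the intended mitigation and is the user's responsibility.
* Tracing assumes a conservative flux field; raw measured (e.g. DT-MRI)
  vector fields are not valid input.
* STL input is accepted for display only: it carries no patch tags and is
  never meshed or solved on.
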