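---
title: "Estimating centre of mass: suspension, scales and volumetric modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating centre of mass: suspension, scales and volumetric modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commass)
```

`commass` implements the three classical whole-body centre-of-mass (CoM)
methodologies — suspension, reaction-board scales and digital volumetric
modelling — plus the machinery needed to compare them fairly: rigid
registration of repeated marker captures, reference geometric centres,
error and repeatability metrics, and a synthetic-specimen generator whose
true CoM is known in closed form. This vignette explains the models behind
each pipeline, the parameters that matter, the numerical choices, and what
the synthetic experiments do and do not demonstrate about real data.

## Suspension

A rigid body hanging freely from a string comes to rest with its CoM on the
string's line: the weight vector and the string tension are collinear at
equilibrium. Repeated hangs from different attachment points therefore
triangulate the CoM. Each capture contributes one infinite 3D line,
reconstructed from two markers on the string; since every hang is recorded
in its own frame, the specimen markers are first registered into a common
frame (`fit_rigid_transform()`), and the string markers are carried through
the fitted transform.

Two lines in 3D almost never intersect. For each unordered pair of lines we
compute the *closest point of approach* — the unique pair of mutually
closest points, whose connecting segment is perpendicular to both lines —
and take their midpoint as that pair's CoM estimate. The overall estimate
`CoM_Su` is the unweighted mean of all `choose(n, 2)` pair midpoints.

Numerical choices:

* **Parallel pairs.** The skew-line solution is singular for parallel
  lines. Pairs whose unit-direction cross product has norm below `1e-8` are
  excluded with a warning and counted in the result, never silently
  dropped. Physically such a pair carries no information about the position
  along the lines.
* **No outlier rejection.** All pair midpoints enter the mean, however
  large their gap; an optional inverse-gap weighting (`weighted = TRUE`,
  weight `1/(gap + 1e-6)`) is provided as an opt-in variant but is off by
  default, matching the plain experimental protocol.
* **Marker-radius offset.** Markers glued to a string sit one marker radius
  (6.35 mm for 12.7 mm spheres) off the string axis. The default leaves the
  line through the raw marker centres — reproducing the usual lab protocol
  and its documented one-sided bias — because the offset direction is
  unobservable from two collinear markers. `line_from_string_markers()` can
  apply the correction when the caller supplies the offset normal.
* **Minimum marker separation.** String markers closer than 10 mm are
  rejected: the direction error of a line through two jittered points
  scales inversely with their separation.

## Scales (reaction board)

The specimen lies on a tared plank spanning two supports, each on a scale.
Torque balance about the proximal support gives the 1D coordinate of the
CoM from the proximal plank edge:

$$\mathrm{CoM_{Sc}} = \frac{W_2 \, L}{W_1 + W_2} + \Delta L$$

with $W_1, W_2$ the proximal and distal readings (kg), $L$ the distance
between supports (mm) and $\Delta L$ the distance from the plank edge to
the proximal support. The output always lies in $[\Delta L, \Delta L + L]$.

Placing the specimen "flush" against the plank edge is subject to a
systematic offset: if the body actually sits $\delta$ mm beyond the edge,
every forward measurement is biased by exactly $+\delta$. The remedy is the
*reversed repeat*: flip the specimen end-for-end and measure again. The
combination rule is not standardised in the experimental literature, so the
package defines the symmetric estimator

$$c = \tfrac{1}{2}\left(c_\mathrm{fwd} + (\ell - c_\mathrm{rev})\right)$$

with $\ell$ the specimen length along the axis. This is the unique
symmetric linear combination that cancels an additive placement offset
exactly, for any $\delta$ — a property the test suite verifies over
$\delta \in [-20, 20]$ mm. Within each orientation, repeats are averaged
before combining.

Per-axis coordinates are fused into 3D by `assemble_3d()` from an explicit
proximal reference point; a single measured axis (the typical case for
birds, where only the cranio-caudal axis is practical) yields an
axis-tagged 1D estimate, and error reports against 3D references are then
restricted to that axis and flagged. Capture-frame alignment uses the
plank/ruler markers: `build_world_frame()` takes the plank direction as the
first axis, the Gram–Schmidt-orthogonalised ruler direction as the second,
and their cross product as the third, rejecting plank/ruler angles within
5° of parallel. Per-axis runs are fused after registration to the common
specimen frame rather than in the measurement frame, since only registered
coordinates are comparable across runs.

## Volumetric modelling

For a watertight, consistently oriented triangle mesh, volume and CoM are
integrated exactly by signed-tetrahedron decomposition: each face forms a
tetrahedron with a common apex, contributing signed volume
$V_i = \det(a, b, c)/6$ and centroid $(o + a + b + c)/4$. For a closed
surface both quantities are independent of the apex — verified in the tests
by moving the apex to random points. Validation is strict: every undirected
edge must be shared by exactly two faces and every directed half-edge must
appear exactly once. The only auto-repair is flipping a globally inward
winding (total signed volume negative, warned); holes always fail loudly,
because silently filled geometry changes mass properties.

Composite bodies combine as

$$\mathrm{CoM_D} = \frac{\sum \mathrm{CoM}_f m_f - \sum \mathrm{CoM}_a m_a}
                        {\sum m_f - \sum m_a}$$

where $f$ indexes flesh components and $a$ internal air cavities. Air
subtracts at the density of the flesh segment displacing it, so under the
conventional uniform 1000 kg m⁻³ assignment the cavity's *net* density is
zero. Cavity containment inside a flesh component is checked by ray-casting
a sample of cavity vertices and warns (rather than fails) on marginal
overlaps, which are common in segmented anatomical models.

Seven density sets ship in `inst/extdata/density_sets.yaml`: D1 (uniform
1000, air 0), D2/D3 (uniform bird-flesh maximum 1069 / minimum 536.8) and
D4–D7 (per-segment assignments from bird/archosaur, human and horse
sources; limb values stored as single per-limb averages). Segment
resolution tries the exact label, then plural per-limb labels, then the
aggregated `head_and_neck`/`limbs` groupings, then a uniform `flesh`
fallback, and errors on anything unresolvable. `density_sensitivity()`
reports the CoM shift of each set against a baseline; uniform sets can
never shift the CoM of a fixed geometry (density cancels), which the tests
assert to machine precision.

As an independent cross-check of the integrator, the package exports a
Monte-Carlo estimator (`mesh_mass_properties_mc()`) that samples the
bounding box and classifies points with a ray-casting parity test
(`point_in_mesh()`). The two share no algorithmic machinery, so agreement
(0.2 % on volume, hundredths of a mm on CoM at 10⁶ samples) validates both.

## Registration and references

Registration is the closed-form least-squares rigid fit over shared marker
labels (covariance SVD): correspondence is by label only, never by nearest
neighbour, matching how labelled physical markers are actually matched.
Reflections are excluded — if the optimal orthogonal matrix has determinant
−1 the smallest-singular-value axis is flipped with a warning, since a
physical capture cannot be mirrored. Inputs with fewer than three shared
labels, or collinear configurations (second singular value below `1e-9`
times the first), raise typed errors. The minimiser of this objective is
unique for non-degenerate inputs, so an iterative global optimiser over the
same objective must agree with it; the tests confirm this against a
multi-start numerical minimiser over Euler angles.

For box-like calibration objects, the reference truth is the *geometric
centre*: per axis, the mean coordinate of the two markers on opposite
faces, combined into 3D (`geometric_centre()`). Under marker jitter of
per-axis sd $\sigma$, each coordinate is a two-point mean with sd
$\sigma/\sqrt 2$ — a dispersion the tests verify by simulation. For
bird-like synthetic bodies the geometric centre is meaningless, and the
generator's analytic composite CoM serves as the reference instead.

Posture change between captures is quantified as the summed absolute change
in inter-marker distances over all pairs — exactly zero for rigid motion,
positive for genuine deformation such as a joint rotation.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the comparative experiment runs.

* **Bricks** (`make_brick()`): homogeneous boxes with six face-centre
  markers (pairs E/F, C/D, A/B along x, y, z; corner ADE at the origin).
  The default 216 × 99 × 67 mm, 3.13 kg brick matches a typical engineering
  brick used as a calibration object.
* **Birds** (`make_birdlike()`): a segmented composite — ellipsoidal head
  and trunk, box neck, two folded-wing boxes, two hanging hindlimb boxes,
  and a cranially placed ellipsoidal air cavity inside the trunk — with
  seven surface markers in the standard avian scheme. True CoM and mass
  come from closed-form primitive volumes and centroids, deliberately
  *not* from the mesh pipeline, so the analytic and mesh routes are mutual
  oracles. All ellipsoids share one icosphere discretisation (default 3
  subdivisions, 1280 faces): an ellipsoid mesh is a linear image of the
  icosphere, so every curved part carries the same relative volume deficit
  and the deficit largely cancels in the composite CoM, keeping the
  mesh-vs-analytic disagreement below 0.1 mm at the default resolution.
  Adjacent segments may overlap slightly; overlaps are double-counted
  identically by both routes, so the mutual-oracle property is unaffected.
* **Noise model** (`noise_model()`): marker jitter (default 1.32 mm,
  applied as a per-axis Gaussian sd, the calibration-level error of a
  multi-camera infrared capture volume), string angular error (degrees,
  free parameter — no instrument value exists for it), lateral attachment
  offset, scale reading noise, scale quantisation (default 0.1 g, the
  resolution of the balances such set-ups use) and the systematic proximal
  placement skew. `noise_model_zero()` disables everything, including the
  quantiser, for exact-closure tests.
* **Suspension captures** (`simulate_suspension_capture()`): attachment
  points are sampled on the specimen's bounding surface, stratified so each
  plane is visited; the ideal line runs from the attachment through the
  true CoM; perturbations and jitter are applied; and *each capture is
  returned in its own random rigid frame*, so the estimation pipeline must
  register — the multi-capture matching step is exercised, not
  short-circuited.
* **Scales captures** (`simulate_scales_capture()`): ideal readings come
  from torque balance of the specimen placed with its proximal face at the
  plank edge plus the skew; noise and quantisation are applied; plank/ruler
  markers are emitted in a random capture frame. A CoM outside the support
  span (the specimen would tip) is an error.
* **Posture changes** (`simulate_posture_change()`): rigid rotation of
  named segments (meshes, centroids, markers) about a joint pivot, with the
  truth recomputed analytically and mass conserved exactly.

Everything is a deterministic function of its seed; the experiment runner
derives per-cell seeds as `(master * 1009 + counter) mod (2^31 - 1)` and
records them, so any report row can be replayed in isolation.

What the synthetic experiments do **not** show: real specimens deform
(thawing, feather compression), strings sag, markers can be misidentified,
and CT-derived meshes carry segmentation error — none of which the
generator models. Passing the closure and ranking tests demonstrates that
the *estimation machinery* is exact and that the methods' relative
behaviour under instrument-level noise matches expectation, not that any
real measurement achieves these error levels.

## The comparative experiment

`run_comparison()` crosses specimens × methods × repeat arms × replicates,
simulates each cell from its derived seed, and reports the 3D error to the
analytic truth in a tidy tibble (`summarise_comparison()`, `autoplot()`,
`improvement_summary()` build on it). Under instrument-pinned noise
(1.32 mm markers, 1° string noise, 0.1 g quantisation, 5 mm proximal skew)
the replicated study reproduces the qualitative ranking seen with physical
calibration objects: scales-with-reversed-repeats and volumetric modelling
are both accurate to well under a millimetre and nearly indistinguishable,
suspension is an order of magnitude worse and by far the most variable, and
going from 3 to 10 hangs improves its median error without fixing the
spread. The forward-only scales arm is biased by exactly the injected skew
(√3·δ in 3D), which is why reversed repeats matter.

Problem sizes throughout (replicate counts of 50–200, 10⁶ Monte-Carlo
samples, icosphere subdivision 3) were chosen so the full suite and the
acceptance script each run in a few minutes on one CPU while leaving the
Monte-Carlo standard errors far below the tolerances being asserted.

## Known limitations

* The volumetric pipeline computes volume and CoM only; inertia tensors are
  out of scope.
* Dorso-ventral scales measurements of irregular bodies (requiring custom
  cradles) are not modelled, mirroring their absence from standard lab
  practice.
* The reversed-repeat combination assumes the placement skew is additive
  and orientation-independent; a skew that depends on which face leads
  would only partially cancel.
* Mesh auto-repair is limited to winding flips; meshes with holes must be
  fixed upstream.
* String-line angular error has no instrument-derived default; simulation
  studies should report the value they assume.
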