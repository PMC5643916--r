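# commass

Centre of mass (CoM) is a fundamental anatomical and biomechanical
parameter: it governs posture, stability and the mechanics of locomotion,
and it is a primary input to forward and inverse dynamic models of living
and extinct animals. Three families of methods dominate the literature for
measuring it on whole bodies or body segments — suspending the specimen from
a string, balancing it on a plank across two scales, and integrating a
digital volumetric model — yet their accuracy and repeatability are rarely
quantified or compared.

`commass` implements all three methodologies end to end, together with the
registration, reference-centre, error and repeatability machinery needed to
compare them, and a seeded synthetic-specimen generator that produces
virtual bricks and segmented bird-like bodies whose true CoM is known in
closed form. That makes the full comparative experiment runnable on a desk:
simulate the captures, run each pipeline, and measure every method's error
against analytic truth.

The package is written tidyverse-style: marker captures, scales runs, body
components and reports are tibbles; estimation results support `tidy()`,
`glance()` and `autoplot()`.

## The three estimators

**Suspension.** A hanging body comes to rest with its CoM on the line of the
string. Each capture contributes one 3D line (reconstructed from two string
markers after rigid registration of the specimen markers into a common
frame). Two lines in 3D almost never intersect, so for every unordered pair
of lines the *closest point of approach* is computed — the unique pair of
mutually closest points on two skew lines — and their midpoint is that
pair's CoM estimate. With *n* lines there are *C(n, 2)* pairwise estimates
(3 from 3 lines, 45 from 10), and

&nbsp;&nbsp;&nbsp;&nbsp;CoM_Su = mean of all pairwise midpoints.

**Scales (reaction board).** The specimen lies on a tared plank spanning two
scales. Torque balance about the proximal support gives the 1D CoM
coordinate measured from the proximal plank edge:

&nbsp;&nbsp;&nbsp;&nbsp;CoM_Sc = W₂·L / (W₁ + W₂) + ΔL,

with W₁, W₂ the proximal/distal readings (kg), L the support span (mm) and
ΔL the edge-to-support offset (mm). Placement against the plank edge carries
a systematic proximal skew; repeating the run with the specimen reversed
end-for-end and combining as (c_fwd + (length − c_rev))/2 cancels any
additive placement offset exactly. Three axes assemble into a 3D CoM.

**Volumetric modelling.** For a closed triangle mesh, volume and CoM are
integrated exactly by signed-tetrahedron decomposition (divergence theorem).
Multi-component bodies combine as

&nbsp;&nbsp;&nbsp;&nbsp;CoM_D = (Σ CoM_f·m_f − Σ CoM_a·m_a) / (Σ m_f − Σ m_a),

flesh components adding and internal air cavities subtracting at the density
of the flesh they displace. Seven published density sets (D1–D7, uniform and
per-segment) ship with the package for sensitivity analysis.

Units are mm, kg and kg·m⁻³ throughout; the single mm³→m³ conversion lives
inside the mass-property computation.

## Worked example

```r
library(commass)

brick <- make_brick(dims = c(216, 99, 67), mass_kg = 3.13)
brick
#> Synthetic specimen 'brick': 1 component(s), mass 3.13 kg
#>   true CoM (mm): (108.000, 49.500, 33.500)

noise <- noise_model(marker_sigma = 1.32, string_angle_sigma = 1,
                     proximal_skew_delta = 5)

# suspension: 10 simulated hangs, each in its own capture frame
caps <- simulate_suspension_capture(brick, n_positions = 10,
                                    noise = noise, seed = 42)
est <- estimate_com_suspension_from_captures(caps, reference = brick$markers)
est
#> CoM estimate (suspension, 10 runs): (107.220, 50.650, 32.978) mm

com_error(est, brick$true_com, reference_length = 216)
#> # A tibble: 1 × 8
#>   method     n_runs dist_mm     dx    dy     dz dimensionality normalised
#> 1 suspension     10    1.48 -0.780  1.15 -0.522 3d                0.00687

# scales with reversed repeats: the 5 mm placement skew cancels exactly
runs <- simulate_scales_runs(brick, reversed = TRUE, noise = noise, seed = 42)
sc <- assemble_3d(axis_coms_from_runs(runs),
                  proximal_reference_point = brick$bbox["lo", ])
sc
#> CoM estimate (scales, 6 runs): (108.000, 49.500, 33.500) mm
```

The suspension estimate lands 1.48 mm from the true CoM (0.7 % of the
brick's longest side) with the marker and string noise above, while the
reversed-repeat scales estimate recovers the truth to machine precision —
the same qualitative ranking the methods show on real calibration objects.

Density sensitivity on a synthetic bird (trunk air cavity included):

```r
bird <- make_birdlike()
density_sensitivity(bird$components)[, 1:5]
#> # A tibble: 7 × 5
#>   set   shift_mm        dx        dy        dz
#> 1 D1    0         0         0         0
#> 2 D2    2.84e-14  2.84e-14  2.86e-20  0
#> 3 D3    2.93e-14  2.84e-14 -1.83e-19  7.11e-15
#> 4 D4    8.87e+ 0  8.63e+ 0  1.99e-16 -2.04e+ 0
#> 5 D5    1.52e+ 0  1.50e+ 0 -9.80e-17 -2.62e- 1
#> 6 D6    1.94e+ 0 -1.90e+ 0 -8.25e-17  3.79e- 1
#> 7 D7    2.08e+ 0 -2.08e+ 0 -1.83e-16  4.83e- 2
```

Uniform sets (D1–D3) cannot move the CoM of any fixed geometry; the
low-density head/neck of D4 shifts it caudally by ~9 mm, far more than the
other segmented sets — the characteristic signature of that density source.

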