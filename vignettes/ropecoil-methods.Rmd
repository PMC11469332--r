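---
title: "Models and estimators in ropecoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in ropecoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ropecoil)
```

ropecoil models the deposition of open-porous silicone coatings by the
liquid rope-coil (LRC) effect and reimplements the morphometric and
stereological pipelines used to quantify such coatings and the tissue
response around coated implants. This vignette explains the underlying
models, the calibration constants and their provenance, the numerical
choices, and the limits of what the synthetic validation can show.

## The coiling model

A viscous filament extruded from a nozzle at height $h$ onto a substrate
moving at velocity $V$ buckles into characteristic patterns governed by the
ratio $\rho = L/V$, where $L$ is the extruded filament length per unit
time. For an incompressible filament of nozzle diameter $d$,
$L = Q / (\pi (d/2)^2)$ with $Q$ the volumetric flow; measured calibration
tables can replace this identity where volumetric extrusion becomes
nonlinear at high flow. With increasing $\rho$ the trace passes through
straight, meandering and alternating-loop regimes before reaching a steady
coil at $\rho \approx 2.2$. Beyond the onset, loop shape is fixed and
additional flow only increases the overlap of consecutive loops, the
*frequency* $F = \rho / 2.2$ ($F = 1$ at onset, 2 when doubly overlapped,
0.5 for a sparse coil). The onset value is a measured property of the
silicone ink; the two lower regime boundaries (defaults 1.0 and 1.6) are
approximate and configurable, and the boundary membership convention puts
$\rho = 1.0$ with the straight regime but $\rho = 2.2$ with the steady
coil, since coiling is already established at the onset.

Loop amplitude grows near-linearly with nozzle height. The bundled
calibration $A(h) = 0.45\,h + 0.8$ (mm) is anchored so that the standard
coating setting $h = 6$ mm yields $A = 3.5$ mm, and is considered valid
over deposition heights 3–9 mm. The inverse map is used by the planners to
choose the standoff that realises a target amplitude.

### The trochoid centerline and its calibration

The deposited centerline of a steady coil is modelled as a translated
coiling circle (a prolate trochoid),

$$c(t) = \left(V t + R \sin 2\pi f_c t,\; R \cos 2\pi f_c t\right),
  \qquad R = A/2,$$

the simplest closed form consistent with steady coiling on a moving
substrate. Its geometry is fixed by the advance per coil period
$p = V / f_c$. Two natural calibrations of $p$ exist and are *mutually
inconsistent* for a pure trochoid: (i) mass conservation with
$L/V = 2.2$ at $F = 1$, and (ii) the measured single-loop along-travel
width of 2.2 mm at $A = 3.5$ mm. The geometry implied by (ii) deposits
arc length at $3.94\,V$ per unit time, not $2.2\,V$. ropecoil treats the
measured loop geometry as authoritative: $p$ is solved numerically (to
$10^{-12}$) so that the closed lobe of the frequency-1 loop has the
specified width, which is self-similar in $A$ ($p = 0.80965\,A$ at
$F = 1$, giving width $0.6286\,A$); frequency divides the advance,
$p(F) = p_1/F$. The generated curve then reports the effective filament
rate its own geometry implies (`filament_rate`), and mass conservation is
asserted against that rate. The regime and frequency laws keep the
measured $\rho = 2.2$ onset; the discrepancy reflects the idealisation of
the trochoid, not a property of the data.

Loop metrics are recovered from a centerline by detecting polyline
self-intersections. The pinch point of a lobe joins curve parameters less
than one coil period apart, while crossings between *neighbouring* loops
are always more than one period apart, so a single threshold at one
period separates the two families at any overlap; this makes the
measure–generate round trip exact to sampling error (tested at 2% over
$A \in [0.8, 5]$ mm, $F \in [0.5, 3]$).

## Toolpath planning

Planar coatings deposit parallel nozzle rows at each layer's angle
(default cycle 0°/45°/135°, six layers replicating the cycle twice), with
row spacing defaulting to the amplitude so adjacent loop rows touch. Rows
are placed on both region edges (a 21 mm span at 3.5 mm spacing gives 7
rows); a half-spacing first-row offset is available via `convention`.
Layers rise by one filament diameter (0.2 mm) per layer.

Height-map surfaces (the digital form of a laser surface scan) are coated
by vertical projection: the planar pattern is sampled along each row and
the nozzle z follows the local surface height plus the standoff,
matching a 3-axis machine with z-follow. Surfaces are assumed
single-valued; geodesic wrapping is out of scope. Spray passes use a
serpentine raster at the atomizer standoff (85 mm).

Rotary mandrels are coated as continuous helixes, one helix per layer with
a configured number of turns ("lines"). Rotational rate follows the
constant-linear-velocity rule $\omega(z) = v/\rho(z)$ so the substrate
surface speed under the nozzle is constant (within 1% including the helix
pitch contribution). The per-point standoff is found by measuring the
meridional gap to the neighbouring helical line and inverting the
amplitude law so that printed loop rows touch; gaps outside the calibrated
amplitude range are clamped with a warning.

G-code is RepRap-style: one linear move per point, `F` in mm/min,
cumulative `E` in mm³ computed as segment length × flow/feed, rotary `A`
in degrees, with layer and standoff changes recorded as structured
comments. The bundled parser inverts the writer exactly to the emitted
decimal precision (default 4 places); flow is recovered from `E`
increments, so its round-trip precision scales with segment length.

## Deposition simulation

Filaments are rigid tubes swept along draped centerlines — no sag,
spreading or fusion mechanics, consistent with a high-viscosity ink that
holds its extruded form. Contact overlaps are unioned. Consecutive layers
interpenetrate by a configurable fraction of the filament radius (default
25%) to mimic contact fusion; the degree of fusion in real coatings is
not quantified, so this is exposed as a parameter. A voxel is occupied
iff its center lies within the filament radius of a centerline (default
voxel 0.05 mm, near micro-CT scan resolutions; a guard requires voxel ≤
radius/2).

Surface meshes are extracted as the zero levelset of the signed Euclidean
distance transform of the binary volume (negative inside; exact 3D EDT by
the separable lower-envelope algorithm), using marching tetrahedra on the
Kuhn 6-tetrahedra cube decomposition with vertices deduplicated on grid
edges, which guarantees watertight, consistently oriented meshes. The
binary-grid EDT carries half-voxel quantisation ripple that inflates the
area of oblique surfaces by up to ~18%; one pass of a separable 3-tap
binomial filter on the signed field removes the ripple while moving the
surface by well under a voxel (sphere area then converges within 1%,
enclosed volume within 0.5%). Validation: voxelized sphere area within 3%
of $4\pi R^2$ at 0.02 mm voxels, cube within 5%, and a mesh→volume parity
resampling round trip with Dice ≥ 0.97 at voxel = radius/5.

## Morphometry

**Curvature.** Per-vertex principal curvatures come from a quadric height
fit over an n-ring neighbourhood in the local tangent frame, taking the
eigenvalues of the shape operator $-G^{-1}B$; mean curvature is
$H = (\kappa_{min} + \kappa_{max})/2$, positive for convex surfaces under
outward orientation. The default 2-ring neighbourhood matches clean
meshes (cylinder $H = 1/2r$ within 10%, sphere $H = 1/R$ within 5%, plane
$|H| < 0.05$/mm). Meshes extracted from voxel data carry sub-voxel ripple:
a 4-ring neighbourhood recovers sphere curvature within 5% at 0.04 mm
voxels, but at filament scale (radius comparable to a few voxels) the
ripple dominates the quadratic sag and curvature from voxelized filaments
should be treated as distributional rather than pointwise — the package
reports quantile summaries (quartiles/deciles/ventiles) for exactly this
use.

**2D voids.** Thin coatings (three layers under 1.3 mm) do not admit
meaningful 3D porosity, so the volume is collapsed by a maximum intensity
projection and voids are 8-connected background clusters in the 2D image.
Background touching the image border is excluded by default, restricting
voids to the coating footprint; the original protocol does not state its
border rule, so the choice is exposed (`exclude_border`).

**Micropores.** SEM-style images are window/levelled (linear ramp,
defaults W = 88, L = 141), binarized at mid-grey, labelled 8-connected,
and filtered by area ≥ 0.38 µm² and circularity $4\pi A/P^2 \in
[0.10, 1.00]$. The perimeter estimator matters at the circularity cutoff:
ropecoil uses Moore boundary tracing with the Vossepoel–Smeulders
corrected chain code, $P = 0.980 N_e + 1.406 N_o - 0.091 N_c$, which is
near-unbiased on digital disks; circularity is capped at 1 (digital disks
can slightly exceed it). Equivalent diameters are $2\sqrt{A/\pi}$;
summaries report per-ROI medians, the median and s.d. of medians, and
pores per area.

## Stereology

Capsule thickness uses the orthogonal-intercept method: at every
intersection of the tissue–device interface with a test line of a square
grid (both orientations), a chord is drawn perpendicular to the local
interface tangent (5-point window — perpendicular to the interface, not
to the grid line) to the far capsule edge. Chord ends are located to
sub-pixel precision by bisecting the bilinear interpolation of the mask
across the 0.5 level, which makes the estimator exact on parallel bands
at any grid orientation. The report is the arithmetic mean of intercepts,
as is conventional; the classical true-thickness correction
($\tfrac{8}{3\pi}\times$ harmonic mean) is available behind
`correction = TRUE` but off by default. Volume fractions use point
counting (target hits over reference hits, the Delesse principle).
Vessel metrics apply the standard identities $L_v = 2 N_A$ for isotropic
sections and radial diffusion distance $r = 1/\sqrt{\pi L_v}$; the
maturity ratio is the flagged fraction of profiles. Region areas use the
shoelace formula with a self-intersection guard.

## Formulation arithmetic

Blend HLB is the weight-fraction-weighted mean of component HLB values
(bundled constants: Span 85 = 1.8, Tween 40 = 15.6; the 3:7 blend gives
11.46 ≈ 11.5). The emulsion recipe resolves to overall mass fractions.
"Diluted 1:3 by weight in heptane" is read as 1 part silicone : 3 parts
heptane (the alternative reading is selectable). Under that reading the
aqueous-phase : silicone-solids ratio of the stated recipe is 1.33:1,
which disagrees with the separately stated 2:1 process target; the
composition report computes the ratio, states the target, and flags the
disagreement rather than silently adopting either number.

## Synthetic data: what it shows and what it cannot

The generators provide every fixture the validation needs, each with
stored ground truth and byte-identical output under a fixed seed.

* `gen_coating_volume` plans, drapes and voxelizes a coating (default:
  three layers, amplitude 3.5 mm, frequency 1, spacing = amplitude,
  filament 0.2 mm, 20×20 mm region, 0.05 mm voxels — the standard coating
  conditions). Optional lateral row jitter mimics deposition variability.
  It emulates geometry only: no slumping, die swell, filament fusion
  necking, or scanner noise, so its void statistics test the *analysis
  chain*, and agreement of its mean 2D void with the measured value
  (within the stated 30% band) additionally supports the geometric model,
  not the physics.
* `gen_pore_image` draws non-overlapping dark ellipses (aspect 1–2, so
  the circularity filter is exercised but rarely binding) on a bright
  low-frequency-textured background; diameters are lognormal with median
  4.1 µm and sdlog 0.3 by default, 120 pores on a 225 µm field as typical
  of a 200× SEM region of interest. Real SEM pores are irregular, partly
  merged, and shaded; recovery of the generator median within 2% shows
  the pipeline is unbiased for resolvable, separated pores, not that it
  segments arbitrary micrographs correctly.
* `gen_capsule_section` sweeps a band of smoothly varying thickness along
  a wavy interface. The normal-offset construction is only a valid band
  while the interface curvature radius exceeds the local thickness; the
  generator warns when the band would fold. Estimator recovery within
  10% over true means 50–500 µm covers tortuosity and thickness
  variation, not staining artefacts or broken capsule boundaries.
* `gen_flared_mandrel` produces a C¹ raised-cosine flare on a cylinder.

Problem sizes used throughout the validation (20×20 mm coatings at
0.05 mm voxels, 0.02 mm voxels for closed-form solids, seven 900-pixel
pore fields, twenty capsule sections) were chosen as the smallest sizes
at which the estimators' sampling error is clearly below the tolerances
being checked.

## Known limitations

* The trochoid is a kinematic, not fluid-dynamic, model; transient
  regimes (meander, alternating loops) are emitted only as flagged
  approximations.
* Filament cross-sections stay circular; real filaments flatten against
  the substrate and neck at contacts, which slightly changes void shapes
  and coating height.
* Curvature from voxelized filament-scale geometry is noisy (see above);
  prefer quantile summaries over pointwise values.
* The 2D void border rule and the ImageJ perimeter estimator are stated
  conventions, not uniquely determined by the original protocol;
  cutoff-adjacent particles may classify differently under other
  estimators.
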