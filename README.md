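# ropecoil

Design, simulation and quantification tools for multi-scale porous
silicone implant coatings deposited by the **liquid rope-coil (LRC)
effect** — the buckling of a viscous filament falling onto a moving
substrate. Soft-tissue implants with smooth surfaces provoke a foreign
body response that walls them off in dense avascular capsule; open-porous
coatings with macropores (0.8–5 mm loops) for tissue ingrowth and
micropores (1–20 µm, from salt-leached sprayed emulsions) for cell
attachment can modulate that response. ropecoil is for engineers planning
such coatings on direct-ink-writing hardware and for analysts quantifying
the resulting structures and the peri-implant tissue.

## What it implements

**Coiling model.** With filament length rate $L = Q/(\pi (d/2)^2)$ (flow
$Q$, nozzle diameter $d$) and print-head velocity $V$, the buckling regime
is a step function of $\rho = L/V$, reaching a steady coil at
$\rho = 2.2$; beyond onset extra flow raises only the loop overlap
("frequency", $F = \rho/2.2$). Loop amplitude follows the nozzle height
near-linearly, $A(h) = 0.45h + 0.8$ mm (so $A(6\,\mathrm{mm}) =
3.5\,\mathrm{mm}$). The deposited centerline is a prolate trochoid
$c(t) = (Vt + R\sin 2\pi f_c t,\ R\cos 2\pi f_c t)$, $R = A/2$, with the
advance per period calibrated so a frequency-1 loop at $A = 3.5$ mm is
2.2 mm wide.

**Toolpath planning.** Multi-layer planar coatings (0°/45°/135° cycle,
row spacing = amplitude so loop rows touch), z-follow coating and spray
passes over laser-scanned height maps, helical mandrel coatings under
constant linear velocity ($\omega = v/\rho(z)$) with per-point standoff
from inverting the amplitude law, feature embossing, and round-trippable
RepRap-style G-code.

**Deposition simulation.** Rigid-tube filament sweeps voxelized onto
isotropic grids (the in-silico analogue of segmented micro-CT data) and
levelset isosurface meshes via a signed 3D Euclidean distance transform
and marching tetrahedra.

**Morphometry.** Mesh principal curvature by quadric fitting (mean
curvature $H = (\kappa_{min}+\kappa_{max})/2$ with quantile summaries),
maximum-intensity-projection 2D void analysis, coating height maps, and
the SEM micropore pipeline: window/level (W = 88, L = 141), 8-connected
particle analysis with chain-code perimeters, area ≥ 0.38 µm² and
circularity 0.10–1.00 filters, equivalent diameters $2\sqrt{A/\pi}$.

**Stereology.** Orthogonal-intercept capsule thickness (perpendicular
chords at grid/interface intersections, arithmetic mean), point-count
volume fractions, vessel metrics ($L_v = 2N_A$, radial diffusion distance
$1/\sqrt{\pi L_v}$, maturity ratios), and polygonal area measurement.

**Formulation.** Surfactant blend HLB (weighted mean) and sprayable
emulsion phase composition.

**Synthetic data.** Seeded generators with stored ground truth for
coating volumes, SEM-like pore fields, capsule sections and flared
mandrel profiles.

## Worked example

```r
library(ropecoil)

# steady-coil loop at the standard coating setting
cv <- generate_loop_centerline(loop_spec(3.5), path_length = 30)
measure_loop_metrics(cv)[c("amplitude", "width", "frequency")]
#> loop: amplitude 3.50 mm, width 2.20 mm, frequency 1.00

# simulate the default three-layer coating and quantify it
g   <- gen_coating_volume(region = c(20, 20), seed = 1)
hm  <- compute_height_map(g$volume)
mip <- max_intensity_projection(g$volume)
vs  <- analyze_voids(mip$mask, mip$pixel_size)
#> coating: max height 0.55 mm, 684 voids, mean void 0.335 mm^2

# micropore pipeline over seven synthetic SEM fields
stats <- lapply(1:7, function(i) {
  p <- gen_pore_image(seed = i)
  analyze_pore_image(p$image, p$pixel_um)
})
summarize_pores(stats)$median_of_medians
#> micropores: median of per-ROI medians 4.11 um (sd 0.13)

blend_hlb(c("Span 85" = 3, "Tween 40" = 7))
#> 11.46
```

The loop is 3.5 mm tall and 2.2 mm long per coil — the geometry that
leaves interconnected macropores between touching rows. The three-layer
coating stays 0.55 mm thin (well under the 1.3 mm design bound) yet its
projection contains hundreds of sub-mm² voids. The sprayed-membrane
micropore model recovers its calibrated 4.1 µm median through the full
window/level + particle-filter chain, and the 3:7 Span 85/Tween 40 blend
lands at HLB 11.5 (one decimal), the oil-in-water emulsifying balance the
ink needs.

A command-line interface over the same functions lives at
`inst/cli/ropecoil.R` (`plan`, `synth`, `analyze`, `stereology`,
`formulation` subcommands, each emitting a JSON summary).

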