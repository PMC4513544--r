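---
title: "Unfolding image-stack surfaces onto 2D maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unfolding image-stack surfaces onto 2D maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackmap)
```

## The problem

Confocal and widefield microscopes image translucent, roughly spheroidal
specimens — vesicles, yeast cells, nuclei — as z-stacks: series of 2D
planes along the optical axis. Signal that lives on the *surface* of such
an object (membrane dyes, cell-wall deposits, nuclear envelope markers)
is scattered across many planes, and conventional displays (single
slices, maximum projections, galleries) either hide part of it or break
its spatial connectivity. `stackmap` treats the labeled surface like the
Earth's surface in cartography: it fits an axis-aligned reference
ellipsoid to the signal, pulls every pixel of a 2D map raster back to a
direction on the sphere, samples the stack radially along that direction,
and so produces a single, structurally connected 2D image of the whole
surface — together with a per-pixel provenance table that lets every
map-space measurement be carried out on the original voxel data.

## The model and its assumptions

The pipeline assumes one closed, roughly convex surface per stack that is
star-shaped around the fitted ellipsoid center: every central ray must
cross it once. Undulations (protrusions/indentations) are handled as
radial displacements; deeply folded or multi-lobed shapes violate the
assumption and are out of scope, as is fitting a *rotated* ellipsoid —
the unfold axis is always one of the stack axes X, Y, Z, mirroring how
such data are acquired and browsed.

The stages are:

1. **Segmentation** (`extract_surface_points`): voxels above an Otsu (or
   user-fixed) threshold become intensity-weighted points at their
   voxel-center physical coordinates; a largest-connected-component
   filter (26-connectivity) removes debris.
2. **Ellipsoid fit** (`fit_ellipsoid`): weighted linear least squares on
   the quadric $Ax^2 + By^2 + Cz^2 + Dx + Ey + Fz = 1$, converted to
   center/semi-axes. The fit is linear, deterministic, and exact on
   noiseless data; under radial noise of $\sigma = 0.25\,\mu m$ it
   recovers parameters of $5$–$40\,\mu m$ ellipsoids to well under 2 %.
   The quadric is an ellipsoid whenever each $S/A$, $S/B$, $S/C$ is
   positive (with $S$ the completed-square constant); note the raw
   coefficients $A, B, C$ are legitimately *negative* when the center is
   far from the coordinate origin, so positivity of the semi-axes — not
   of the raw coefficients — is the degeneracy test.
3. **Projection** (`forward_project`, `inverse_project`): nine standard
   cartographic projections on the unit sphere (equirectangular,
   Mercator, Braun, Miller, Lambert cylindrical, sinusoidal, Mollweide,
   Wagner VI, Bonne), each with an exact analytic inverse used to
   rasterize maps.
4. **Unfolding** (`unfold_intensity`, `unfold_height`): each map pixel
   center is pulled back to $(\varphi, \lambda)$, converted to a 3D unit
   direction under the chosen unfold axis, and the stack is sampled at
   radii $r \in [r_{lo} R, r_{hi} R]$ around the local ellipsoid radius
   $R(\varphi, \lambda)$ in steps of half the smallest voxel dimension.
   The ray is reduced by a statistic (`max` by default), and the radius
   of the maximum, $r^\ast$, localizes the surface; the signed elevation
   $r^\ast - R$ gives the height map.
5. **Cross-referencing** (`roi_to_voxels`, `measure_roi_timeseries`):
   polygons drawn in map coordinates select map pixels (even-odd rule),
   which resolve through the cross-reference table to stack voxels;
   intensity statistics are always computed on the original voxel
   values, never on rendered map values.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `radial_window` | (0.5, 1.5) | fraction of $R$ | wide enough to catch undulating surfaces and haloes around the ellipsoid; symmetric about 1 so the baseline is centered |
| `radial_step` | min voxel / 2 | µm | Nyquist-style: two samples per voxel ensure the peak is never stepped over |
| `ray_statistic` | `max` | — | the surface is the radial intensity *peak*; mean/sum serve volume-integrating applications |
| `interpolated` | `TRUE` | — | trilinear sampling gives smooth maps; `FALSE` (nearest voxel) keeps map values bit-identical to stack values, which cross-reference auditing relies on |
| `lat_clamp` | 85° | rad | Mercator/Braun grow unbounded/strongly stretched poleward; 85° is the common truncation convention |
| `bonne_parallel` | 45° | rad | no canonical value exists; 45° gives a balanced heart-shaped outline, and the parameter is exposed |

Argmax ties along a ray break toward the smallest radius — a
deterministic, conservative (innermost-surface) rule. Sub-sample peak
refinement was deliberately left out: the argmax rule keeps
`interpolated = FALSE` maps exactly equal to stack values, a property
the test suite asserts literally.

## Geometric conventions

Voxel indices are 0-based; voxel $(z, y, x)$ occupies the half-open box
$[x\,dx, (x{+}1)dx) \times [y\,dy, (y{+}1)dy) \times [z\,dz, (z{+}1)dz)$,
so its center is at $((x{+}0.5)dx, \ldots)$ µm and nearest-voxel lookup
is a floor division. Longitude is normalized to $(-\pi, \pi]$ with the
map seam fixed at the $-\pi$ side, making cross-references
deterministic. Under pole axis $P \in \{X, Y, Z\}$, latitude $\pm\pi/2$
points along $\pm P$ and $(\varphi{=}0, \lambda{=}0)$ points along the
first remaining axis in X < Y < Z order.

Two numerical choices deserve note:

* **Bonne origin shift.** The textbook Bonne formulas place the standard
  parallel, not the equator, at $y = 0$. A constant $+\varphi_1$ shift
  is added to $y$ so that $(0,0)$ maps to the plane origin like every
  other projection here; a constant shift leaves the equal-area property
  untouched, and the inverse removes it first.
* **Mollweide auxiliary angle.** $2\theta + \sin 2\theta = \pi
  \sin\varphi$ is solved by Newton iteration from $\theta_0 = \varphi$
  to a residual below $10^{-12}$; the poles, where the derivative
  vanishes, are short-circuited analytically. Round-trip identity is
  assessed as *angular* (great-circle) distance, since at the point-like
  poles of the pseudocylindrical projections longitude is not
  recoverable componentwise.

## The synthetic phantoms

`make_spheroid_stack` renders an ellipsoidal shell with a Gaussian (or
binary) radial profile, multiplied by a surface pattern — uniform,
checkerboard, disjoint bright rings (the sparse "bud-scar" scenario), or
graticule — optionally displaced by Gaussian bumps/indentations, with
additive noise and per-z-slice multiplicative jitter emulating
slice-to-slice acquisition variability. Every phantom returns its ground
truth (true ellipsoid, pattern equations, bump list), which the tests
consume as oracles instead of re-deriving geometry.

`simulate_photoactivation_series` evolves a scalar field on the sphere
by explicit finite differences of the Laplace–Beltrami operator in a
regular $(\varphi, \lambda)$ grid (conservative flux form in $\varphi$,
periodic in $\lambda$, rows poleward of 80° zonally averaged), with a
constant influx inside a source cap — an idealized continuous
photoactivation experiment. The explicit scheme carries a CFL stability
bound that the function enforces with an informative error; frames may
integrate several internal steps (`steps_per_frame`) so realistic
diffusion times remain reachable at stable step sizes. The source cap
indicator is anti-aliased by 5×5 sub-pixel sampling so the discrete cap
area tracks the analytic $2\pi(1 - \cos r)$ to about 0.1 %, which is
what makes the 1 % conservation check meaningful.

What the phantoms deliberately do *not* model: point-spread-function
blur, photon shot noise, spherical aberration, depth-dependent
attenuation. Passing tests therefore demonstrate the correctness of the
geometry, sampling, bookkeeping and statistics of the pipeline — not
robustness to optical artifacts of real micrographs, which users should
assess on their own data.

## Problem sizes used in validation

The test suite and the acceptance script validate on: $48^3$–$96^3$
voxel stacks at 0.5 µm isotropic spacing with 7.5–15 µm spheres; map
rasters of 48–128 px width; a 181 × 361 graticule for projection
round-trips; 50 Monte-Carlo ellipsoid fits of 1200 points each; and 20
seeded diffusion series of 6 frames on a 36 × 72 surface grid. These
sizes were chosen as the smallest at which every geometric feature under
test spans several voxels *and* several map pixels, so pass/fail
reflects correctness rather than resolution.

## Known limitations

* One surface per stack; star-shaped around the ellipsoid center.
  Multi-object scenes need per-object cropping upstream.
* Sampling runs along central rays, not along ellipsoid normals; for
  mildly eccentric ellipsoids the difference is small, but strongly
  flattened objects would bias elevation estimates near the equator of
  the long axes.
* Near the poles of the map raster many pixels reference few voxels; ROI
  statistics de-duplicate shared voxels by default to avoid oversampling
  bias, and the pattern-resolution limit there is set by the *stack*,
  not the map.
* Map pixels are rasterized from pixel centers; features narrower than
  two map pixels (or two voxels on the sphere) may alias, exactly as in
  any raster reprojection.
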