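---
title: "Modelling root reinforcement in direct shear: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling root reinforcement in direct shear: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootshear)
```

## The physical picture

A cylindrical soil specimen containing live roots is sheared across a
horizontal plane between two tube halves. Roots crossing the plane are
dragged into an inclined position across the shear band, stretch, and
mobilise tension. That tension raises the soil's shearing resistance in
two ways: its component along the shear direction acts directly, and its
component normal to the plane increases the frictional resistance
through `tan(phi')`. Per root, the model evaluates

- inclination `beta = arctan(u_x / Z)`,
- bond factor `k = sqrt(4 tau' Z E / D)`,
- contribution `dS_i = a_r_i k (sec beta - 1)^0.5 (sin beta + cos beta tan phi')`,

and sums over roots. The controlling unknowns are the shear-zone
thickness `Z` (geometry) and the limiting interface stress `tau'`
(friction plus anchorage by lateral branches). Both are hard to measure;
the package's two main additions address them: a changepoint estimator
that extracts `Z` maps from volumetric displacement data, and a
back-analysis that fits `tau'` to a measured stress record.

### Model assumptions

Roots are initially perpendicular to the shear plane, linearly elastic,
and neither break nor pull out; there is always enough root length on
either side of the band to anchor the mobilised tension. Breakage and
pull-out are deliberately not modelled: `assumption_check()` instead
*flags* roots whose axial stress exceeds a configurable fraction
(default 80%) of a supplied tensile strength, or whose stressed length
exceeds a supplied available length, so the user can see when the
predictions leave the model's domain of validity rather than having
outputs silently truncated.

## Non-uniform thickness and growth

Measured shear zones in cylindrical direct shear are not uniform: the
band forms a double cone, thickest at the specimen centre and pinched at
the wall to the physical gap between the tube halves. `local_shear_zone()`
interpolates linearly between `Z_max` (centre) and `Z_min` (wall) with
the root's radial distance. The defaults — `Z_min = 2` mm (tube gap),
`Z_max = 30` mm, `D_tube = 103` mm — are the reference apparatus values.

The band also develops progressively. `growth_factor()` is a
piecewise-linear schedule: 0 at zero displacement, 80% of peak at the
displacement of the third loading step (where a band first becomes
clearly resolvable), 100% at the final step, constant beyond. Two
consequences needed decisions:

- **Zero-displacement singularity.** A literal `Z -> 0` at `u_x = 0`
  makes `beta = arctan(u_x / Z)` ill-defined in the limit. The grown
  thickness is therefore clamped from below at `Z_floor = Z_min`: the
  physical tube gap exists at any displacement. The clamp is
  configurable in `shear_zone_model()`.
- **`beta` under growth.** The inclination is evaluated pointwise as
  `arctan(u_x / Z(u_x))` with the *current* grown thickness, because the
  growth schedule is itself indexed by displacement; no history integral
  is attempted.

The default schedule displacements (8.15 mm, 19.83 mm) are one
specimen's loading schedule and should be set per specimen.

## Units

All interfaces use the field's customary mixed units — mm, kPa for soil
and interface stresses, MPa for root stiffness and axial stress, degrees
for friction angle. Internally every stress is put on kPa before
evaluating `k`, so `k = sqrt(4 tau'[kPa] Z[mm] E[kPa] / D[mm])` is a
stress in kPa and the summation is dimensionally consistent. One caveat
follows from this: the stressed-length expression
`l = k (sec beta - 1)^0.5 D / (2 tau')` then yields lengths of order
1 m for willow-like parameters at 20 mm displacement, an order of
magnitude above values sometimes quoted from mixed-unit evaluations of
the same expression (stiffness in MPa against interface stress in kPa).
The package keeps the consistent-unit evaluation — it is the one under
which the predicted reinforcement magnitudes are self-consistent — and
reports `l` as computed; users comparing against literature values
should check the unit convention of the source. Degree/radian and unit
conversions happen once at parse/construction time and are covered by
round-trip tests.

## Tri-linear thickness estimation

Each (x, y) position of a displacement field gives a column of
x-displacement versus depth. The idealised profile is tri-linear:
constant displacement below the band (the moving half), constant above
(the fixed half), and a linear ramp across it; the knee separation is
the local thickness. `fit_trilinear()` minimises the sum of squared
residuals over the two knee depths and two plateau values, with
continuity enforced at the knees by construction.

Numerical design:

- For *fixed* knees the model is linear in the plateaus, so they solve a
  2×2 normal system in closed form. The knees are found by exhaustive
  search over pairs of observed depths (globally optimal on that
  lattice, deterministic), followed by Nelder–Mead refinement of the two
  knee depths with the closed-form inner solve. Ties in residual break
  towards the smallest thickness.
- The fit contains no randomness: identical input and settings give
  bit-identical maps.
- Quality flag: a column is marked `ok = FALSE` when the plateau
  separation falls below three times the configured displacement-noise
  level (no resolvable band — this also catches rigid translations of
  the whole column), or when a knee lands at the profile boundary (the
  band is not contained in the observed depth range). Flagged columns
  propagate as `NA`/`NaN`; one bad column never aborts a map.
- Exhaustive-stage cost is quadratic in profile length; profiles longer
  than 80 samples are thinned evenly for candidate generation only (the
  refinement and the residual always use all samples).

Against noiseless tri-linear profiles the estimator recovers knees to
better than 1e-6 mm, including knees between depth samples; at the
reference displacement-noise level (5.4 µm per correlation step,
accumulated linearly over seven steps) the median absolute thickness
error on a 12 mm band is about 0.02 mm over 100 noise draws.

## Synthetic data generators

No volumetric measurement data are deposited with the reference study,
so every stage is validated against synthetic fixtures with known ground
truth.

- `generate_field()` builds the displacement field of an idealised
  direct-shear step: lower half translated by the step displacement,
  upper half fixed, transition across a zone whose local thickness is
  the double cone plus optional Gaussian "root bumps", with i.i.d.
  Gaussian noise of standard deviation `noise_sd * step` added per
  component (linear accumulation over correlation steps). Defaults
  mirror the reference measurement: 0.37 mm pitch, 103 mm tube, 2–30 mm
  zone, 5.4 µm noise, one specimen's step schedule. The ramp is
  tri-linear by default; a cubic-smoothstep variant exists to emulate
  smooth (bent, not kinked) deformation — its fitted thickness is
  slightly below the nominal width, so thickness-recovery guarantees are
  stated for the tri-linear ramp. Spatially correlated noise is not
  modelled.
- `generate_root_map()` draws root positions uniform-in-area with a
  configurable fraction (default 60%) placed within 20 mm of the wall —
  pot-grown systems concentrate roots near the boundary — and diameters
  from a lognormal truncated to 0.1–4 mm (many fine roots, a few
  coarse). Roots are drawn until the target root area ratio is reached
  and the last diameter is adjusted so the achieved RAR lands within 5%
  of target; the achieved value is reported exactly.
- `generate_root_path()` produces deformed root centrelines with either
  sharp knees (the model's idealisation) or tangent circular arcs at the
  knees. Arc paths with the same endpoints are strictly shorter, which
  is exactly why the tri-linear extension formula `dl = Z (sec beta - 1)`
  overestimates measured root extension; moderate bend radii put the
  overestimate in the 10–30% range.

What passing these tests shows — and does not. The generators share the
analysis' own geometric idealisation, so round-trip recovery validates
the estimator's correctness and noise robustness, not the idealisation
itself. Real fields add spatially correlated noise, partially decorrelated
subsets near roots and boundaries, and band shapes that are only
approximately tri-linear; flagged-column rates on real data will be
higher than on fixtures.

## Back-analysis of the interface stress

`fit_tau_prime()` exploits that `dS` is strictly increasing in `tau'`
(it enters only through `k` as `sqrt(tau')`), so matching the measured
stress at one displacement is a bracketed scalar root-finding problem
(bisection bracket 0.01–50 kPa, well beyond the physically plausible
0.5–5 kPa range) with a unique solution. A full-curve least-squares mode
minimises over the same interval; on noisy records it has visibly lower
variance than the single-point mode and is the pipeline default. Both
modes are deterministic, and both recover the forward-model `tau'` to
1e-6 kPa on noiseless synthetic records.

## Problem sizes and defaults used in the shipped checks

The test suite and pipeline run on deliberately small instances chosen
to exercise every code path at interactive speed: fixture fields of
1 mm pitch over 12–24 mm windows (the full 0.37 mm / 80 mm study-scale
grid remains the generator default), thickness maps of ~100–500 columns,
100 noise draws for the fitter robustness study and 50 for the `tau'`
recovery study, and a pipeline demo at 1.85 mm pitch with every second
column mapped. These sizes are the package's own validation choices;
all are parameters, and study-scale runs use the same code paths.

## Known limitations

- Progressive failure (fibre-bundle behaviour), root elasto-plasticity,
  slippage mechanics and load redistribution between roots are out of
  scope; violations of the elastic no-failure assumptions are flagged,
  not simulated.
- The positional thickness model is axisymmetric; real maps show
  azimuthal structure near large roots that only enters through
  user-supplied bumps in the generator, not the model.
- `tau'` and `Z_max` are weakly identified jointly from a single stress
  record; the package fits `tau'` with `Z_max` fixed from the thickness
  map, and deliberately does not offer a default joint fit.
- The smooth-ramp generator's nominal width is not bias-corrected to the
  tri-linear fit's plateau-to-plateau thickness.
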