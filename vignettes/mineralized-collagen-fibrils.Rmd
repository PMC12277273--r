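---
title: "Mesoscopic mechanics of graded mineralized collagen fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscopic mechanics of graded mineralized collagen fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

The ligament insertion (enthesis) anchors soft, collagen-rich ligament to
stiff, mineral-rich bone through a millimetre-scale transition in which the
mineral volume fraction (MVF) of the tissue rises roughly linearly from
about 9.4% at the ligament limit to about 65.2% at the bone limit. At the
fibril scale this gradient is realized by hydroxyapatite (HAp) deposited
both *inside* collagen fibrils (intrafibrillar: ellipsoidal crystals in the
gap zones and platelets in lattice planes) and *around* them
(extrafibrillar: shell-like blocks on the fibril surface), with roughly
75% of the mineral extrafibrillar. `mcfibril` builds a coarse-grained
bead-spring model of a single fibril at any position along this gradient,
runs tensile molecular dynamics on it, and extracts the mechanical
properties (Young's modulus, offset yield, ultimate point) whose gradient
the insertion exploits to smooth load transfer.

## The model

### Energy function

Total energy is a sum of three terms, `E = E_inter + E_bond + E_angle`:

* **Nonbonded (radial cohesion).** 12-6 Lennard-Jones between all
  non-bonded bead pairs, `E(r) = 4ε[(σ/r)^12 − (σ/r)^6]`, with
  species-pair parameters: Col–Col ε = 6.87 kcal/mol, σ = 14.72 Å;
  HAp–HAp ε = 137.1, σ = 9.88; Col–HAp ε = 106.7, σ = 10.28. Col–HAp
  adhesion is *only* nonbonded — mineral restrains collagen sliding
  through these wells, not through covalent links.
* **Bonded (axial stretching).** Consecutive beads of a chain interact
  through a bilinear, breakable force law: harmonic with stiffness `KT0`
  about `r0` up to the critical distance `r1`, then a stiffer
  "hyperelastic" branch `KT1·(r − r̄1)` up to the breaking distance `rb`,
  zero beyond. `r̄1` is not a free parameter: it is derived from force
  continuity at `r1` (`derive_r1bar()`), giving 17.4633 Å for collagen
  (r0 = 14.00, r1 = 18.20, rb = 21.00 Å, KT0 = 17.13, KT1 = 97.66
  kcal/mol/Å²) and 11.0440 Å for HAp. The energy stored in one collagen
  bond at rupture, `0.5·KT1·(rb − r̄1)²`, evaluates to 610.8 kcal/mol;
  the literature's printed 613.7 reflects rounding of r̄1 before
  squaring. Because this far exceeds the 106.7 kcal/mol Col–HAp well,
  mineral adhesion saturates (molecules slide) before collagen chains
  scission — the mechanism behind the ultimate point.
* **Angular (bending).** Harmonic in the radian deviation,
  `E = KΘ(θ − θ0)²`, KΘ = 14.98 kcal/mol/rad². Molecules are built
  straight and no direction change between gap and overlap regions is
  modeled, so θ0 = 180° for every triplet (configurable per angle).

Numerical choices: the LJ potential is truncated at 2.5σ per pair type and
shifted so the energy is zero at the cutoff (forces are truncated,
unshifted); separations below 0.5σ are clamped before evaluation as a
safety net against pathological overlaps — placement rejection during
mineralization should make the clamp unreachable. Bond energy is
referenced to `E(r0) = 0`. Bond rupture is tested on the minimum-image
distance and is permanent; bonds never re-form.

### Geometry

A collagen molecule is a chain of 218 beads (1,316 Da each, 287 kDa per
molecule) spanning 3,011 Å, i.e. a bead spacing of 13.876 Å — slightly
below the 14.00 Å bond equilibrium; the small compressive pre-strain is
released during relaxation. Molecules sit on a triangular lattice
(constant 16.52 Å, exactly the Col–Col LJ minimum 2^(1/6)σ) with all sites
within a 215 Å diameter populated: 151 molecules, 32,918 beads. Axially,
each molecule is offset by `s·D` where `D = gap + overlap = 400 + 282 =
682 Å` and the stagger class `s = (i + 2j) mod 5` of its integer lattice
coordinates; any five consecutive sites along a lattice row carry all five
classes (a Hodge–Petruska-compatible coloring). The simulation cell is
5 D-periods (3,410 Å), periodic along the fibril axis only; x/y are open
with vacuum padding. The resulting structure shows the expected five
gap-zone density minima per cell (one stagger class absent in each).

Two stated source inconsistencies are resolved in favour of the
self-consistent parameter table: gap 400 Å / overlap 282 Å / D 682 Å /
cell 3,410 Å (the prose "36 nm gap" and a quoted gap/D ratio of 0.54
match no consistent combination; the config allows overriding). On the
151-site disk no linear 5-coloring can balance classes better than
{29,29,29,32,32} (151 = 5·30 + 1), which is what the implemented coloring
gives; this is recorded in the tests.

Desk-scale work uses `microfibril_preset()` — 7, 19 or 37 molecules
(1–3 hexagonal shells) with identical lattice, stagger, D-period and bead
spacing — so every test exercises the same construction code as the full
model.

### Mineralization

`mineralize()` deposits HAp inclusions one at a time until the model's
MVF first reaches the target, which `mvf_at_position(x)` sets from the
linear insertion gradient (9.4% at x = 0 to 65.2% at x = 1; note the
printed intermediate value 22.3% at x = 0.25 differs from the linear
rule's 23.35% — the package follows the linear rule). Three kinds:

* **Gap ellipsoids** (intrafibrillar): long diameter 20–340 Å along the
  fibril axis, short diameter 20–40 Å, centered uniformly in a gap band
  and in the fibril cross-section.
* **Platelets** (intrafibrillar): thickness 20–40 Å × width 50–100 Å ×
  length 50–400 Å, lying in one of the three symmetry-equivalent lattice
  plane families that contain the fibril axis.
* **Shell blocks** (extrafibrillar): cylindrical sectors just outside the
  fibril surface, thickness (radial) 20–40 Å × width (arc) 0–400 Å ×
  length (axial) 150–1,000 Å; the arc is capped at a full ring.

All inclusion long axes (the crystal c-axis) are parallel to the fibril
axis. Each inclusion is realized as beads on a simple-cubic lattice at
10.00 Å (the HAp bond equilibrium); candidate beads closer than the
rejection distance (0.8·σ_Col–HAp = 8.22 Å) to any existing bead are
discarded — this keeps minerals in the adhesive LJ well and out of the
repulsive core. Surviving HAp beads within 12 Å are bonded (HAp–HAp law).
Intrafibrillar inclusions are clipped at the fibril surface.

Kind scheduling holds the 75/25 volume split by deficit rather than by
count probability: an extrafibrillar shell is drawn whenever the
realized extrafibrillar volume share is at or below 0.75, an
intrafibrillar kind (ellipsoid or platelet, equal odds) otherwise. A
count-probability scheme cannot hold a *volume* share when shell blocks
are one to two orders of magnitude larger than gap ellipsoids. Endgame
rule: once less than a typical shell volume of mineral is missing, only
the small intrafibrillar kinds are drawn (unless the extra share has
fallen more than 5 points low), so the closing inclusion can neither
blow the share nor overshoot the target badly. At full scale this holds
the realized share within 0.75 ± 0.05; at desk scale single inclusions
are large relative to the whole budget and the share is necessarily
coarser.

Two conventions the source leaves open, chosen once: **(1)** MVF is
measured as `V_hap/(V_hap + V_col)` with each bead contributing a fixed
spherical volume at its species' equilibrium spacing (14 Å / 10 Å) —
cheap, monotone in bead count, and swappable; **(2)** HAp beads take the
collagen bead mass (1,316 Da), since no HAp bead mass is stated; masses
only set the thermostat time scales, not the quasi-static mechanics.

### Dynamics

Velocity-Verlet with a 10 fs step. Temperature control is a Langevin
thermostat (damping 1,000 fs by default; the source names only the
ensembles, not the coupling), applied as a post-force friction+noise term
once per step; noise comes from a package-internal xoshiro256++ stream so
runs are bit-reproducible for a given seed regardless of R's RNG state.
Relaxation is two-stage: NVT plus a proportional axial box-length
controller steering the mean axial virial stress to zero (the NPT
surrogate — only the axial direction is periodic, so only the axial
residual stress matters), then plain NVT. Tensile deformation defaults to
`BOX_STRAIN`: the axial cell length grows at the engineering strain rate
with affine remapping, reconciling "velocity constraint on both ends" with
"longitudinal periodic boundaries"; an `END_CLAMP` mode (end slabs driven
at ±v/2 with transverse freedom) is provided rather than guessing a
hybrid. The default strain rate is 1e-7/fs (1e8/s), typical for
coarse-grained fibril pulling; it is not stated in the source.

Axial stress is the tension-positive virial estimator
`σ_zz = −(Σ m v_z² + Σ r_z f_z)/V` (kinetic term included by default,
configurable), converted via 1 kcal/mol/Å³ = 6.9477 GPa. The **fibril
volume** convention matters: the volume is a cylinder `π R² Lz` with
`R = max(R_hex, R_p95)`, where `R_hex` is the radius of the circle
whose area equals the hexagonal cells tiled by the molecule columns
(106.6 Å for the full fibril, matching its nominal 107.5 Å radius) and
`R_p95` the 95th-percentile radial distance of the *collagen* beads.
Two choices are deliberate. First, a percentile radius alone excludes
the outer half-cells and inflates stress by ~30% on a 19-molecule
microfibril, contradicting the analytic spring-chain bound below —
hence `R_hex`. Second, the reference cylinder excludes extrafibrillar
mineral: at 65% MVF the shell annulus more than doubles the geometric
cross-section, so a mineral-inclusive volume would make the apparent
modulus fall several-fold along the insertion — incompatible with the
flat (±3%) modulus the gradient is known to show. Engineering stress on
the fixed collagen-fibril cylinder is the convention that reproduces
that observation; the percentile is configurable.

## Mechanics extraction

Recorded curves are smoothed by a centered moving average (default window
51 records ≈ 5.1% strain at default settings) because raw MD stress
fluctuates by a few megapascals, enough to fake yield under an offset
criterion. The five properties:

* **Young's modulus**: OLS slope of stress vs strain on [0, 10%].
* **Yield (1% offset)**: `DROP` mode — first crossing where the curve
  falls onto the offset line `E(ε − 0.01)` from above (onset of
  intermolecular sliding); if none occurs before the ultimate strain,
  `LIFT` mode — first strain where the curve exceeds the elastic line by
  `E·0.01` (strain-hardening departure, seen at high MVF where mineral
  blocks sliding and the hyperelastic bond branch engages). The source
  describes the lift qualitatively; the symmetric 1% threshold is the
  least arbitrary quantification. Aggregates always carry the
  DROP/LIFT/NONE tally because replicate sets at high MVF mix modes.
* **Ultimate point**: argmax of smoothed stress (ties to smaller
  strain); the unsmoothed peak is reported alongside in the detail
  output. Smoothing precedes extraction by default (the alternative
  order is available by passing `window = 1`).

Replicate studies (`run_insertion_study()`) use seeds `base + replicate`,
with mineralization, velocity initialization and thermostat noise on
independent derived streams so changing one stage does not shift
another's draws. Per-position aggregates are elementwise min/max/mean.

## What the synthetic world does and does not establish

The generator's defaults *are* the stated world: Table-level geometry
(218 beads, 16.52 Å lattice, 682 Å D-period, 151 molecules), the linear
9.4→65.2% MVF gradient, the 75/25 mineral split, the stated inclusion
size ranges, 300 K, 10 fs. Desk-scale runs shrink only the cross-section
(19 molecules) and the relaxation length (1e4 steps), not the physics.
Consequences to keep in mind:

* A 19-molecule fibril has a much larger surface fraction than the
  151-molecule model; its modulus and especially its ultimate strength
  carry finite-size bias (the acceptance checks use a ±20% band on the
  modulus and a factor-2 band on strength for exactly this reason).
* The stated extrafibrillar shell ranges are full-scale morphology; one
  such block holds more mineral than a microfibril's entire budget, so
  desk-scale *graded* studies pass scaled-down shell ranges to
  `run_insertion_study()` (the study script and CLI do this for the
  micro presets). At 7 molecules the shells roughly double the
  stress-normalization radius, which dilutes stress faster than the
  mineral adds load — a finite-size artifact to keep in mind when
  reading microfibril trends.
* The fibril is cross-link free by construction; absolute stresses sit
  below tissues with enzymatic cross-links, trends are unaffected.
* The model says nothing about macro-scale fiber orientation, crystal
  axis disorder, or mineralization kinetics — inclusions are final
  placements.
* A green trend test at microfibril scale (UTS increasing ligament→bone,
  flat modulus) supports the mechanism — mineral adhesion restraining
  sliding — not the full-scale numbers; quantitative replication of the
  full property table needs the shipped 151-molecule configuration
  (`scripts/insertion_study.R --full`, cluster-scale).

## Known limitations

* The axial box controller is a proportional surrogate, not a barostat;
  transverse directions are open and uncontrolled.
* The force cutoff truncation leaves a small force discontinuity at
  2.5σ (energy is shifted, forces are not).
* Degenerate straight triplets (θ = 180°) take the zero-transverse-force
  limit of the angle gradient.
* END_CLAMP mode measures strain as rate·t against the initial cell
  length; for chains whose free length differs appreciably from the cell
  the nominal modulus picks up the ratio of the two.
* Whether molecules crossing the periodic boundary should be wrapped or
  trimmed is unstated in the source; they are wrapped (minimum-image
  bonds), which preserves the bead census.
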