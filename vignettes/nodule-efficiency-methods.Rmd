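---
title: "Multi-scale quantification of nodule symbiotic efficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale quantification of nodule symbiotic efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodusym)
```

## The problem

Rhizobia inside legume root nodules differentiate into bacteroids, the
endosymbiotic form that reduces N~2~ to ammonia for the host. Two bacteroid
fates exist: terminally differentiated, swollen bacteroids (induced by host
NCR peptides in IRLC legumes such as pea) and undifferentiated, rod-shaped
bacteroids that can regenerate outside the nodule (bean, soybean). Whether
these lifestyles differ in symbiotic efficiency is only answerable if
fixation is expressed on comparable physiological scales — a whole-plant
rate says nothing about per-cell efficiency when hosts differ in size,
nodule number, nodule density, bacteroid size and packing.

`nodusym` implements that multi-scale comparison as a reusable pipeline:
geometric nodule-volume models from 2-D sections, a bacteroid packing census
from 3-D electron-microscopy segmentation, rate normalization across eight
scales (plant, shoot dry weight, nodule volume, nodule dry mass, infected
volume, bacteroid, bacteroid protein, bacteroid volume), and Hi3/top3
absolute proteome quantification with five copy-number denominators.
A synthetic-data generator emulates every raw measurement table from a
ground-truth parameter set, so each stage is testable end to end and
parameter recovery can be asserted against planted truth.

## Geometric models

**Spherical (determinate, bean-type) nodules.** A central longitudinal
section of a sphere has area $A = \pi r^2$ and Feret diameter $F_d = 2r$,
so the solid volume is recoverable as

$$V = \tfrac{2}{3} A F_d .$$

`sphere_volume_from_section()` defaults to this diameter convention because
Feret's diameter is a caliper diameter, not a radius; the variant
$V = \tfrac{4}{3} A F_d$ (exact only if $F_d$ were a radius) is retained
behind `convention = "radius"`. The two differ by exactly a factor of two,
and published cohort volumes are consistent with the true-sphere
(diameter) form. Maximum- and minimum-Feret volumes are computed separately
and averaged afterwards.

**Cap-plus-cylinder (indeterminate, pea-type) nodules.** The uninfected
distal cap is a spherical cap measured by chord $c$ and sagitta $h$. The
textbook cap volume with base radius $a$ is
$V_c = \tfrac{\pi h}{6}(3a^2 + h^2)$. A section chord spans the full base,
so $a = c/2$; `cap_volume()` therefore defaults to `chord_mode =
"half_chord"`. The check that settles the convention: at $c = 2r, h = r$
the half-chord form returns the hemisphere $\tfrac{2}{3}\pi r^3$, the
full-chord form does not. The literal full-chord evaluation is retained as
an option. The body (and the infected zone inside it) is a cylinder of
average width $d = A/l_c$, giving $V = A d \pi/4 = \tfrac{\pi}{4}A^2/l_c$;
the whole nodule is $V_n = V_c + V_b$.

**Infected volume.** In both models the fractional colonization density is
the area ratio $f_c = A_i / A_{iz}$ of bacteroid-occupied to infected-zone
area, and $V_i = V_{iz} \cdot f_c$. A property test verifies the half-chord
cap against numerical quadrature of the cap cross-section over 50 random
shapes (agreement is machine precision; the test bound is 0.5%).

## Bacteroid census

Per-bacteroid volumes and surface areas come from 3-D segmentation of
serial block-face scanning electron microscopy stacks; the packing fraction
is measured by segmenting every bacteroid in defined 8 × 8 × 2 µm
subvolumes. Two conventions matter:

* the surface-area:volume ratio is the **mean of per-bacteroid ratios**,
  not the ratio of cohort means — the published cohort value (7.44 for
  bean) is only consistent with the former;
* flow-cytometry gates (forward scatter > 0, side-scatter aspect ratio
  > 0.4, fluorescence > 3,000 FI) are **strict** inequalities, so boundary
  events are excluded.

The census cascade is exact by construction: total bacteroid volume is
$V_i \times$ packing; bacteroids per nodule is that volume divided by the
mean single-cell volume (exact $10^9$ µm³/mm³ factor); protein density times
cell volume returns the protein content identically.

## Fixation rates and the scale cascade

Atom percent excess subtracts the ¹⁵N natural abundance (0.36782%).
The working formula for fixed N per fraction under 20% ¹⁵N₂ is
$(\mathrm{APE}/100)\cdot N_\mathrm{tot}\cdot\tfrac{5}{4}$; the correction
factor scales as $1/(4\,g)$ with the labeled-gas fraction $g$. The default
(`mode = "literal"`) evaluates exactly this; `mode = "strict"` divides by
the incubation time as a separate, auditable step rather than folding it
into the constant, and the molar conversion (28.0134 g/mol N₂) is explicit
in `plant_fixation_rate()`. Shoot, root and nodule fractions are summed per
plant; a natural-abundance water control yields an identically zero rate.

`normalize_rate()` expresses one plant-level rate on all eight scales with
exact unit conversions, so the cascade identities
(per-bacteroid = per-bacteroid-volume × $\bar v$;
per-protein = per-bacteroid / $\bar p$) hold to machine precision. The
published bacteroid-scale rows are mutually cascade-consistent at the ~1%
level (per-replicate averaging in the original cohorts prevents exact
reconstruction of the per-bacteroid rows from the per-plant rows, so only
ratio-consistent quantities are asserted numerically).

## Absolute proteome quantification

The top3 rule quantifies a protein as the mean intensity of its three most
intense qualifying peptides: unique, zero missed cleavages, unmodified or
methionine-oxidized only; when a sequence is observed both unmodified and
oxidized the two intensities are summed first. Scaling by the spiked Hi3
standard (12.5 fmol of rabbit glycogen phosphorylase, accession P00489)
converts intensity to fmol, and $6.0221413\times10^8$ copies/fmol converts
to absolute copies. Five denominators re-express copies per bacteroid
(B~D~ = 1,202,531 bean / 608,974 pea bacteroids per 380 ng load), per
bacteroid volume (0.93 / 4.50 µm³), per nodule (5.28 / 1.63 × 10⁸
bacteroids), per nodule volume (6.07 / 4.61 mm³) and per pg bacteroid
protein (0.32 / 0.62 pg). B~D~ is taken as an explicit constant: deriving
it from 380 ng / 0.32 pg gives 1,187,500, so the published value reflects
an unrounded protein content, and re-deriving it would silently shift every
per-bacteroid figure.

Because the five scales differ per host only by constant factors, fold
changes obey exact identities, e.g.
$\mathrm{FC}_{vol} = \mathrm{FC}_{bact}\times B_{vol}^{bean}/B_{vol}^{pea}$.
Only the bacteroid-volume scale is asserted against published fold changes
to printed precision; the per-nodule and per-unit-protein columns of the
published table depart slightly from the constant-ratio identity
(per-replicate averaging again), which the tests acknowledge rather than
paper over. Welch's two-sample t-test on untransformed per-replicate copy
numbers flags differential proteins at p < 0.05 (a log-scale option
exists; no multiple-testing correction is applied by default, matching the
original analysis, with Benjamini–Hochberg available). The optional
replicate normalization is a documented median-ratio (size-factor)
procedure, off by default.

## The synthetic-data generator

The generator defines the study conditions: cohort sizes default to the
published design (11 plants per host, 8 sectioned nodules, 240/246
segmented bacteroids, 6 protein isolations, 3 proteomic replicates), means
default to the published cohort means, and dispersions are recovered from
the published standard errors via $\mathrm{CV} = \mathrm{SE}\sqrt{n}/\mu$.
Strictly positive measurements use a lognormal noise model (the published
tables give only means ± SE; lognormal is an assumption, chosen because
every measured quantity is positive and biological CVs here reach ~75%);
counts are Poisson. A zero CV collapses each draw to its mean exactly,
which the zero-noise round-trip tests exploit.

Design choices worth stating:

* **Section construction is exactly invertible.** Sections are built from a
  drawn solid (sphere, or 8% cap + cylinder of aspect ratio 6 with the
  infected zone an inner cylinder spanning 90% of the body length), so the
  geometry module recovers the drawn volume to machine precision at zero
  noise and noise enters only through the drawn volume.
* **Colonization density** $f_c$ is not published (only the infected-volume
  proportions 24.2%/26.2% are); defaults are 0.65 (bean) and 0.80 (pea),
  reflecting denser colonization of indeterminate nodules. $f_c$ cancels
  out of every downstream identity, so this choice affects no asserted
  quantity.
* **Packing subvolumes** default to 6 per host (the published table does
  not state the SBF-SEM sample count; 6 is a realistic census size).
* **Surface areas** are generated as shape factor × the sphere-minimum
  surface $(36\pi V^2)^{1/3}$, guaranteeing the isoperimetric inequality
  record-by-record, with the lognormal moment $E[V^{2/3}]$ corrected
  analytically so cohort means are unbiased.
* **Peptide tables** plant true copy numbers (pea = bean × published fold
  change, so planted fold changes are recoverable ground truth), include
  the Hi3 standard at its known amount, split one peptide per protein into
  an unmodified/oxidized pair that must be summed, and carry loud decoy
  rows (missed cleavage; disallowed modification) that any filter failure
  would surface immediately.
* **Seed fan-out.** One master seed derives per-table child seeds by fixed
  offsets, so adding a table to the bundle never perturbs existing draws.

What the generator does **not** emulate: raw images and spectra (generation
starts at the measurement-table level), between-peptide ionization structure
beyond a single response factor, correlated measurement error between
scales, and the per-replicate averaging idiosyncrasies of the original
cohorts. Passing tests therefore demonstrate correctness of the arithmetic
and recoverability of planted parameters under the stated noise model — not
that the noise model is the true generative process of the original data.

## Numerical choices and degenerate inputs

All unit conversions are exact factors in one registry. Negative APE values
(controls) are floored at zero with a warning. Strict top3 errors on
proteins with fewer than three qualifying peptides; a flagged
average-available fallback exists. The cap-height inversion in the
generator solves the monotone cubic by `uniroot` at 1e-12 tolerance. The
cumulative-mass rank treats an exact tie at the target percentage as
reached (1e-12 relative tolerance). Fold changes default to ratio of group
means (the published table-footnote convention); mean-of-ratios is
available for paired designs.

## Problem sizes

The test suite and acceptance script run at the study-condition sizes above
plus a 1,000-plant law-of-large-numbers check and 500-sample parameter
recovery runs; everything completes in well under a minute on one CPU.

## Worked example

```{r example}
# derived-row closure from the published raw means
t1 <- build_table1(reference_raw_means())
t1[t1$provenance != "raw", ]

# a full synthetic run at the study-condition sizes
res <- run_pipeline(seed = 1)
res$summary$bacteroids_per_nodule
```

## Limitations

The pipeline consumes measured tables; image preprocessing, mesh
segmentation, spectral search and RNA-Seq read processing are out of scope.
Published per-bacteroid rate rows cannot be reconstructed exactly from the
per-plant rows (per-replicate averaging), so the package asserts
ratio-consistent quantities there. Whether the original bean analysis used
Feret's diameter as a radius or diameter is not decidable from printed
values alone; both conventions are exposed and the geometric one is the
default.
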