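---
title: "Analysing multivariable NMR peaklist series with nmrcube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing multivariable NMR peaklist series with nmrcube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrcube)
```

## The problem

A modern protein NMR study rarely consists of one spectrum.  A ligand is
titrated in seven steps, each construct and each point mutant is measured
separately, and paramagnetic samples are paired with diamagnetic
controls — quickly producing tens of curated 2D peaklists whose joint
analysis is tedious and error-prone by hand.  `nmrcube` organises such a
dataset as a dense three-axis grid: the **x axis** holds a continuous
perturbation (ligand concentration, temperature), the **y axis** discrete
sample identities (constructs, sequence variants) and the **z axis**
spectroscopic toggles (diamagnetic/paramagnetic).  Every cell of the grid
is one peaklist; ordered slices along one axis at fixed coordinates of
the other two are *series*, and the first element of every series is its
reference experiment.

Some operations only make sense along particular axes, and the package
enforces this before any computation: paramagnetic comparisons run along
z only, fitting of continuous data along x only, and differing protein
sequences are legal only across y labels.  Mixing two sequences along x
or z (detected as conflicting residue types at the same residue number)
is a configuration error.

## Peaklist input

Four text dialects are parsed: Sparky list files, NMRPipe `.tab` tables,
CCPN Analysis v2 tabular exports and NmrView `.xpk` files.  None of
these formats is formally specified, so the package freezes one concrete
golden file per dialect in its test suite and guarantees behaviour only
for files shaped like those goldens; anything else fails loudly with a
line number rather than guessing.  Assignment strings are accepted in
the forms `T103N-H`, `Gly45HN` and the per-dimension `Thr103N`; an
unrecognised token is a parse error naming the token, because silently
misassigning a residue is the worst possible failure mode for downstream
mapping.  The fixed-width Ansig format is detected but deliberately
unsupported (the reader is a stub that raises "unsupported dialect").
Parsers never invent values: a column a dialect does not carry stays
empty, and all downstream code treats empty as absent.

The canonical on-disk representation is a CSV with a fixed fourteen-column
header (residue number and type, the two atom names, two shifts, height,
volume, two linewidths, three free-text annotation fields and a status
column), followed by any derived columns.  Parsing a canonical file
reproduces the table exactly, which is the round-trip property the test
suite asserts for every golden.

## Curation

Before any arithmetic, each x-axis series is scanned so that every
residue of the universe has a status in every table:

* **measured** — the peak is present in that spectrum;
* **missing** — the peak was observed at an earlier series point but has
  disappeared (exchange broadening); the label of the last point where
  it was measured is recorded;
* **unassigned** — never observed up to that point.

A residue that only appears from, say, the third point onward is classed
*unassigned* at the earlier points rather than *missing*: "missing"
deliberately requires a prior observation, since its diagnostic meaning
is *disappearance*, and there is no earlier value to carry.  The residue
universe is the union of observed residue numbers, or — preferably — a
user-supplied sequence, which additionally lets prolines (invisible in
an amide correlation spectrum) be created as labelled placeholders
rather than anonymous gaps.

After scanning, all tables of a series are padded to one backbone row
per universe residue.  The default fill policy, `carry_last`, copies the
observables of a missing residue from its last measured point — this is
causal (never from a later point) and is what bar plots expect so a
disappeared residue still shows its last value in red.  The alternative
`blank` policy leaves missing observables empty, which is the safer
choice when derived values feed statistics, because an empty value
propagates as empty instead of as a stale number.  Padding is
idempotent.  Sidechain NH2 rows (atom names ending `a`/`b`, e.g.
ND2a/HD2a) are segregated before scanning so the one-row-per-residue
invariant refers to backbone amides only.

## Derived parameters

All parameters compare each table of a series against the series
reference (the first table).

**Combined chemical shift perturbation.**  For amide ¹H/¹⁵N pairs the
two shift changes are collapsed into the weighted Euclidean norm

$$\mathrm{CSP} = \sqrt{\tfrac12\left(\Delta\delta_H^2 +
(\alpha\,\Delta\delta_X)^2\right)}$$

with the standard heteronucleus weight α = 0.14 for all residue types
and α = 0.2 for glycine.  The weights are configurable per residue type;
the defaults follow the usual ¹⁵N scaling recommended in the CSP
literature.

**Intensity ratios.**  Height or volume ratios target/reference guard
against zero or absent reference values (the ratio is left empty and
counted in a warning, never infinity).

**ΔPRE.**  Paramagnetic relaxation enhancement is measured as the
paramagnetic/diamagnetic intensity ratio along z.  The observed profile
is compared with the profile predicted for a random coil (supplied as a
two-column table, e.g. computed externally by an ensemble model):
`dpre = predicted − observed` by default, so positive values mark
residues *more* broadened than a random coil — transient structure or
contacts.  Since the opposite convention also circulates and the
defining publication does not settle it at formula level, the sign is a
configuration switch recorded in the output.

**Gaussian smoothing.**  ΔPRE profiles are noisy per residue, so a
running Gaussian filter with weights $w_j = e^{-j^2/2\sigma^2}$,
$j \in [-h, h]$, is applied along the sequence.  Defaults σ = 3 residues
and $h = \lceil 4\sigma\rceil$ were chosen as a reasonable compromise
between noise suppression and the ~10-residue width of typical contact
regions; no published kernel parameters exist for this procedure.  The
weights are renormalised at profile edges and across gaps (residues
without a value get no weight), which makes the filter exactly
constant-preserving and keeps its output inside the range of its input.

**Shift normalisation.**  Referencing drift between spectra moves every
peak of a spectrum by one global (¹H, X) offset.  Given a residue known
to be unperturbed, that offset is estimated from it and subtracted from
the whole spectrum; the operation is idempotent and the reference
residue's CSP becomes exactly zero.

## Fitting binding curves

Along a numeric x axis, per-residue responses are fitted by least
squares.  The default model is the Hill curve
$y(x) = y_{max} x^n/(K_d^n + x^n)$; with $n = 1$ it reduces to the
one-site fast-exchange isotherm, and a quadratic ligand-depletion model
is available when the total protein concentration is known.  The
functional form is a package choice — standard practice for CSP
titrations — and the model registry accepts user models.

Numerical choices: parameters are optimised on a log scale (enforcing
positivity without constrained optimisation), starting from
$y_{max,0} = $ max response, $K_{d,0} = $ the x at half-max by linear
interpolation and $n_0 = 1$; the sign of a negative response is factored
out before fitting and restored afterwards.  A BFGS run and a
Nelder-Mead run from the start are followed by polish steps from the
best point (Brent line search for one-parameter models); the best RSS
wins.  This recovers noiseless synthetic parameters to ~1e-12 relative.
Failures — too few measured points (fewer than four), optimizer
breakdown — are reported per residue in the result table, never thrown.
Residues whose maximal response is below a floor (default three times a
robust noise estimate: the median absolute response at the first
non-reference point, where true responses are smallest) are reported
unfitted rather than fitted to noise.

## Comparative (stacking) analysis

A parameter computed along one axis is often best read along another:
ΔPRE computed along z for ten sequence variants becomes a residues ×
variants matrix (a heat map), and a PRE ratio computed along z at every
titration point becomes per-residue PRE-versus-concentration curves.
Stacking is pure re-indexing — each matrix cell is copied from exactly
one source cell and the provenance is kept, so the operation is
invertible and value-preserving by construction.  Residue sets that
differ between columns (legal across y) are outer-joined with empties
and the mismatch is logged; alignment is by author residue numbering,
never by sequence alignment — reconciling numbering schemes is the
user's curation duty.

## Output and plots

Results live in a hierarchical tree `output_root/<z>/<y>/<analysis>/`
mirroring the cube's coordinates, with a `manifest.csv` listing every
file.  Eight figure templates are provided (three bar variants, a shift
map and a peak-trajectory scatter, a heat map, a ΔPRE profile overlay
and a per-residue evolution grid with fitted-curve overlay).  Bar
colours encode status — black measured, red missing, grey unassigned —
prolines are labelled "P", and an optional significance threshold is
drawn as a red line; the threshold is a plain user-set constant, since
no principled default exists.  Every figure is accompanied by a sidecar
CSV holding exactly the plotted values: the sidecar, not the pixels, is
the testable and reusable surface.  UCSF Chimera attribute files map any
per-residue column onto a 3D structure; values are printed as
shortest-round-trip decimals at six significant digits.

## Synthetic data

The package ships generators rather than canned fixtures.

`simulate_titration()` emulates a seven-point ligand titration
(0–800 µM) of a 100-residue protein in fast exchange: 30 responding
residues with $K_d$ drawn from 50–300 µM and plateau shift changes of
0.05–0.30 ppm (¹H) / 0.3–1.5 ppm (¹⁵N) of either sign, one residue
(22, a phenylalanine) disappearing from point 4 onward, five prolines
never observed, two Asn/Gln sidechain NH2 rows, Gaussian shift noise of
0.002 ppm (¹H) / 0.02 ppm (¹⁵N) and 2 % log-normal intensity noise.
The noise magnitudes are typical of well-resolved HSQC data — roughly
2 % of a typical plateau CSP — and are the package's single definition
of "realistic noise" throughout the tests.

`simulate_pre_pair()` emulates a paramagnetic/diamagnetic pair: the
random-coil part of the intensity-ratio profile is a Gaussian
broadening well (depth 0.9, width 8 residues) around the probe site on
a 0.95 baseline, and configurable deviation regions add extra
broadening the random-coil prediction does not contain — that extra
signal is exactly the ΔPRE ground truth.

What the generators do **not** emulate: peak overlap, assignment
errors, intermediate-exchange lineshape effects, field-dependent
referencing drift, or physically modelled PRE (no Solomon–Bloembergen
distance dependence).  A green test therefore establishes the
correctness of the bookkeeping and arithmetic on well-behaved input,
not robustness to pathological spectra.

On the null PRE fixture (no deviation regions) the per-residue ΔPRE
noise is ~√2 × 2 % ≈ 2.8 % of the ratio, and the acceptance check that
the profile is "quiet" is asserted on the *smoothed* profile against
this analytic floor: the maximum of ~100 raw noise values is itself a
≈3σ order statistic, so a raw-value 3σ bound would be a coin flip
rather than a test, while the smoothed maximum sits far below it.

## Known limitations

* Cubes are dense; absent cells are rejected rather than tolerated.
* No global (shared-$K_d$) fits across residues, no exchange-regime
  modelling, no bootstrap errors on fitted parameters.
* Intensity ratios are not converted to Γ₂ rates or distances.
* Alternative-assignment swapping (annotated pairs in the input) is
  surfaced via the annotation columns but never applied automatically.
* The Ansig dialect is recognised but not parsed.
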