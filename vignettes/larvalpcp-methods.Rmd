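---
title: "Models and methods behind larvalpcp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind larvalpcp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvalpcp)
```

# The biological setting

Each abdominal segment of the *Drosophila* larva's ventral epidermis is a
fixed file of seventeen cell rows — denticulate rows 0–6, three interspersed
tendon (muscle attachment) rows T1–T3, and undenticulate rows 7–11, −2 and
−1 — whose planar cell polarity (PCP) is set entirely by the Dachsous/Fat
(Ds/Ft) system. Ds in one cell binds Ft in its neighbour; by comparing the
Ds activity presented by its anterior and posterior neighbours, each cell
points its denticles towards the neighbour with the higher activity, and
the myosin-related protein Dachs accumulates on the opposite side (the face
whose own Ds is not excluded by neighbouring Ft). `larvalpcp` packages this
neighbour-comparison model together with the quantitative analyses used to
probe it: membrane-fluorescence quantification of Ds levels, circular
statistics on the growth directions of EB1-labelled microtubules, and exact
tests on predenticle-orientation contingency tables. Because the original
microscopy data are not deposited, a first-class synthetic-data module
generates all inputs with known ground truth.

# The segment model

`build_landscape()` assigns one Ds-activity scalar per row. The activities
are *ordinal*: every model claim is a sign comparison, so only the ordering
matters and any monotone re-scaling gives identical predictions. The
wild-type defaults (0.40, 0.30, 0.20, 0.35, 0.40, 0.45, 0.25, 0.50, 0.55,
0.60, 0.65, 0.70, 0.80, 1.00, 0.85, 0.60, 0.50 for rows 0…−1) were chosen
once to satisfy all qualitative constraints — single-cell troughs at T1 and
T2, a profile rising through the A compartment, a unique maximum in row 10,
high values at T3 and row 11 — and are configuration, not measurements. The
polarity-modified scenario (ectopic active Ds driven in tendon rows) simply
raises T1 and T2 to 1.20, above all their neighbours.

Design choices that were genuinely open:

* **Compartment assignment of rows 0–1.** The P compartment is taken to be
  rows −2, −1, 0, 1 (four rows between the last A row and the next
  segment's T1), inferred from the compartment marker's extent and the
  P-mode polarity of rows 0–1; nothing in the package depends on the label
  beyond bookkeeping.
* **Fj is folded into the single Ds-activity scalar.** The kinase modulates
  both partners of the heterodimer, but the operative quantity in every
  comparison is one effective activity per cell, so a separate Fj field
  would be redundant configuration.
* **Row 11's mixed behaviour** (about half of cells localize Dachs
  posteriorly, the rest are mixed) is modelled as a deterministic anterior
  call from the default landscape; stochastic scatter belongs to the
  synthetic samplers (`gen_dachs_records()`'s `noise`), never to the
  deterministic core.

`predict_polarity()` evaluates every membrane *region* (face × abutting
neighbour), so an atypical cell whose face touches two different neighbours
receives two independent calls and multipolarity is representable. Tendon
cells return `no-call` and cytoplasmic Dachs. With the default landscape
the model reproduces the full direction map (rows 0, 1, 4, 11, −2, −1
anterior; 2, 3, 5–10 posterior), the four reversals (rows 1, 2, 4, 5) of
the polarity-modified scenario, and the four qualitative atypical-cell
outcomes (wild-type row 2 monopolar posterior, modified row 2 multipolar,
wild-type row 4 multipolar, modified row 4 monopolar posterior).

## Propagation

The interdependence of membrane-bound Ds and Ft lets polarity changes relay
from cell to cell. Published descriptions of this relay are qualitative, so
`propagate()` is an explicit, deliberately replaceable formalization: each
cell's activity is split into anterior/posterior face pools, and per round
a fraction `gain` of the pool re-equilibrates towards an allocation in
which the anterior-face share equals the posterior facing activity divided
by the sum of the two facing activities — Ds moves away from the face whose
neighbour presents more. The update conserves each cell's total exactly,
is the identity at zero rounds, converges instead of saturating, and a
lone activity peak on an otherwise flat landscape polarizes one further row
per round, which is the relay behaviour the model needs. After
propagation, polarity is read from each cell's own face asymmetry (the
depleted face marks the pointing direction), which reduces to the plain
neighbour comparison at round zero.

*Known limitation:* with strong coupling (`gain` well above the default
0.2) and several rounds, the two faces presented to the watershed row
(row 10) can cross order, reversing its call. The operation is intended
for the weak-coupling regime, and the wild-type sign-stability test pins
`gain` ≤ 0.2 over five rounds.

# Synthetic data

The generators define the study conditions for every downstream test.

* **Images** (`gen_segment_image()`): a strip of rows along x
  (anteroposterior), 30 µm high, 0.25 µm pixels, with punctate membrane
  signal at each internal interface — Gaussian puncta of σ 0.3 µm at 2
  puncta/µm of interface, per-punctum peak brightness equal to the
  interface's specified intensity (so total interface signal scales
  linearly with density), lognormal amplitude jitter (CV 0.3), constant
  background (20) and Gaussian pixel noise (SD 8). With `noise_sd = 0`
  the image is *fully deterministic* (evenly spaced puncta, fixed
  amplitudes): a calibration mode in which recovered interface rankings
  must equal ground truth exactly. The y axis is treated as periodic when
  rendering so edge clipping cannot bias per-interface totals. The
  emulation of the quantification experiments uses a flat intensity map
  (100 a.u.) with the two interfaces flanking T3 raised 1.5×, matching the
  reported finding of a local Ds peak with no segment-wide gradient.
* **Comet tracks** (`gen_comet_tracks()`): each comet draws a net growth
  direction from a von Mises mixture, then advances at constant speed
  (default 0.15 µm/s; reported protocols do not constrain comet speed, and angle
  extraction is speed-invariant) with 5° per-step angular jitter, sampled at 5.16 s
  intervals, default six steps. Right-hemisegment tracks are stored
  y-mirrored, exercising the flip in `track_to_angle()`. Angle convention
  throughout: x increases posteriorly, y medially; 0° = posterior, 90° =
  medial, counterclockwise, degrees in [0, 360).
* **Predenticles** (`gen_predenticles()`): per-cell Poisson predenticle
  counts (mean 3, minimum 1), a neighbour class per predenticle, a
  class-specific anterior-pointing probability and an `unclear` rate.

What the generators do *not* emulate: microscope optics, photobleaching,
larval movement and registration artefacts, comet detection or tracing
errors, denticle occlusion, and irregular row geometry in images. Passing
tests therefore demonstrate that the statistical machinery recovers known
structure under idealized punctate/directional noise, not that the
upstream image processing of a real microscope pipeline is validated.

# Ds quantification

Following the imaging protocol: ten lines parallel to the anteroposterior
axis, 4 µm wide, at uniform random heights (lines may overlap — the
protocol does not forbid it); per-line intensity profiles; peak detection;
manual peak-to-interface assignment replaced by nearest-interface matching;
per-image interface means only where at least three lines contributed; and
normalization by the image's mean of interface means, which makes the
per-image normalized values average to exactly 1 and the whole pipeline
invariant to any positive rescaling of an image (this is also why
denticulate and undenticulate image sets can be normalized independently
and then pooled).

Numerical choices: peaks are local maxima with topographic prominence at
least 10% of the profile's range (the original analysis delegated this to
an interactive routine without recorded parameters; the threshold is an
exposed argument); assignment tolerance defaults to half the minimum
interface spacing; when two peaks of one line land on one interface the
higher wins. Group comparisons use a one-way layout with the interface as
group and each image's normalized mean as one observation (pooling raw
per-line maxima would pseudo-replicate lines within images), Tukey's HSD
for all pairwise contrasts, and a compact letter display built by
insert-and-absorb; per-row asymmetries are the Tukey contrasts between the
two flanking interfaces of each row, flagged when the 95% interval
excludes zero.

# Microtubule statistics

Comet directions are the first-to-last-point displacement angles of the
tracks. The analyses mirror the published battery:

* **Rose bins** of 4° and **quadrant counts** in four half-open 90° sectors
  centred on the axes (anterior [135, 225), posterior [315, 45), medial
  [45, 135), lateral [225, 315)); boundary angles belong to the sector they
  open, a tie-handling convention that published figures leave unstated.
* **Sison–Glaz simultaneous intervals** for the quadrant proportions,
  implemented from the published construction (truncated-Poisson
  representation with an Edgeworth-corrected central term; the largest
  half-width `c` with joint coverage below 1 − α, interpolated towards
  `c + 1`). At n = 175 and four categories the approximation's true joint
  coverage sits slightly below nominal (≈ 0.941 at the observed
  proportions) — a property of the method itself, visible in the package's
  coverage simulations.
* **Per-cell bootstrap**: the observed statistic is the mean over cells of
  the within-cell difference of opposite quadrant fractions; cells are
  resampled 10 000 times and the 0.025/0.975 quantiles give the interval.
  The printed p-value recipe of the source figure ("frequency of resampled
  differences greater than the observed") hovers near 0.5 by construction,
  so the package reports it verbatim as `p_literal` *alongside* a
  conventional two-sided sign-based `p_sign`; neither is asserted to be
  the original intent. Percentile intervals with only ten cells undercover
  mildly (≈ 92% rather than 95%), the familiar small-sample behaviour of
  the percentile bootstrap.
* **Sector scan**: 22.5° sectors, eight opposite pairs, exact binomial
  two-sided test of equal splitting per pair. Whether the original scan
  slid continuously is not stated; fixed sectors are used, by default
  centred on 0°/90°/180°/270° so one pair contains the PCP axis
  (edge-anchoring is available).
* **Model selection**: maximum likelihood over a five-model ladder —
  uniform; von Mises; axial bimodal (antipodal modes, equal weights,
  shared κ); weighted axial bimodal; free two-mode von Mises mixture —
  ranked by AIC (2k − 2 logL; with ~2000 angles per dataset the AICc
  correction is negligible). This subset of the cited ten-model circular
  catalogue expresses every conclusion the original analysis draws. Fitting uses
  Nelder–Mead on transformed parameters (log κ capped at 500 to forbid
  degenerate spikes, logit weights), 20 random restarts plus
  moment-based starts, and each nested solution seeds the next model up,
  so fitted log-likelihoods respect the nesting to optimizer tolerance.
  One intrinsic caveat: on truly uniform data AIC still prefers a
  2-parameter competitor with probability ≈ e⁻² per competitor (the
  classical overfit rate), so the uniform model heads the ranking in only
  ~50–60% of uniform replicates under this family — no AIC-ranked family
  can do better than ≈ 86% even with a single competitor.
* **Mode deviation**: signed angular distance of each fitted mode from the
  nearest mediolateral direction (90°/270°), positive towards the anterior
  semicircle: 100° → +10, 80° → −10, 270° → 0.

# Contingency tables

`build_table()` turns per-predenticle records into 2×2 tables and resolves
`unclear` observations by the footnote conventions of the published
tables: split equally (odd remainders placed to weaken association),
all-to-the-null-favouring cell (the cell minimizing |log odds ratio|, with
a Haldane correction for zeros), or all to a named cell.
`fisher_exact_2x2()` uses the probability-ordering two-sided definition by
direct hypergeometric enumeration, with a 1 + 10⁻⁷ relative tolerance on
the probability comparison — the convention under which the published
values (p = 1, p = 0.068, p < 2.2 × 10⁻¹⁶) reproduce exactly.
`table1_fixtures()` stores the four printed post-adjustment tables; the
one typographically ambiguous block was resolved by requiring consistency
with its printed p-value, its null-favouring footnote, and the described
wild-type region behaviour simultaneously.

# Pipeline and reproducibility

`run_pipeline()` drives the stages in dependency order from a single
config (R list, YAML or JSON), rejects unknown keys, and refuses a
user-configured stochastic stage without an explicit seed. All stage
outputs are CSV; a JSON report records package version, full
configuration, seeds and summary statistics. Fixed seeds give
byte-identical result CSVs. Every generator takes one integer seed and
restores the caller's RNG state, so no hidden global state leaks between
stages.

# Problem sizes used in the test-suite and acceptance script

Simulation sizes match the originally reported conditions where stated: 175
comets per cell (inside the 150–200 protocol range), 10 cells per
compartment, B = 10 000 bootstrap resamples, 10 lines of 4 µm per image,
12 images per quantification pool, 2000 angles per model-selection
dataset, 10⁴ multinomial draws for interval coverage, and 100–500
replicates for the rate estimates.
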