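---
title: "Designing and quantifying retron-expressed DNA aptamers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying retron-expressed DNA aptamers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrodna)
```

Bacterial retrons reverse-transcribe part of their non-coding RNA (the
*msd* region) into abundant single-stranded DNA in vivo. Encoding a
functional sequence — here a fluorogenic DNA aptamer that lights up the
GFP-chromophore mimic DFHBI-1T — inside the *msd* turns the retron into an
intracellular ssDNA expression platform. `retrodna` implements the four
computational stages of that workflow: structure-guided insertion design,
qPCR-based abundance quantification, equilibrium binding analysis, and
dilution-corrected half-life estimation, together with seeded synthetic-data
generators so each stage can be exercised and validated offline.

## Folding engine and insertion design

The design question is where in the *msd* a cargo can be inserted without
disrupting the scaffold's native fold. The package answers it with a
deliberately simple folding model: **weighted base-pair maximisation**
(Nussinov-style dynamic programming) over non-crossing pairs, with default
weights `GC = 3`, `AT = 2`, `GT = 1` (the G·T wobble is stable in DNA) and a
minimum hairpin loop of 3 nt. The score is a dimensionless stability
surrogate, not a free energy: a full nearest-neighbour thermodynamic model
for DNA — let alone for the branched RNA–DNA hybrid a retron actually makes —
is out of scope, and no algorithm models mixed RNA–DNA molecules joined by a
2'–5' bond. What matters for insertion design is the *topology* of the
predicted structure (which positions are paired, which runs are single
stranded), and the weighted-maximisation optimum is a reasonable proxy for
that. Users who want thermodynamic folding can pass any external engine as a
callable to `fold_mfe(engine = )`; its output is validated against the same
structural invariants (non-crossing, loop length, mask compliance) before
use.

Numerical choices:

* **Tie-breaking.** Co-optimal structures are common in base-pair
  maximisation. The traceback always prefers the pair with the smallest
  opening index, then the smallest closing index, so the reported structure
  is deterministic.
* **The msr-overlap mask.** The 5' end of the *msd* is base-paired with the
  *msr* RNA in the branched RT-DNA and must not be folded intramolecularly.
  The default treatment is a *hard pairing mask* (`dna_sequence(mask = )`):
  the region stays in the sequence — preserving coordinates for insertion
  design — but is forbidden from pairing. Trimming the region off before
  folding is equally valid and supported by simply slicing the sequence; we
  default to the mask because downstream gap indices then refer to the full
  construct.
* **Site ranking.** Candidate sites are midpoints of maximal unpaired runs
  of length ≥ `min_run` (default 3). Runs are ranked longer-first, then by
  class (`hairpin_loop` > `exterior` > `internal_or_bulge`), then leftmost.
  No experimental ranking rule exists — only that loop/single-stranded
  regions are suitable — so the ranking is a reported heuristic, not a
  biological claim: longer single-stranded stretches simply give the cargo
  more room. The `fold_preservation()` score (fraction of scaffold pairs
  that reappear, index-shifted, in the refolded fusion) is the
  operationalisation of "does not interfere with the native fold"; a
  pairless scaffold is vacuously preserved (1.0).
* **Stem truncation.** Fluorogenic aptamers tolerate shortening of their
  terminal (P1) stem; `truncate_stem()` removes outer pairs symmetrically
  from both strands, supporting the 4/8/11-bp P1 variant series used for
  cargo length exploration.

## qPCR abundance

Quantification uses the comparative-CT method with an inside/outside primer
design: the inside amplicon templates on RT-DNA *and* plasmid, the outside
amplicon on plasmid only. Technical replicate CTs are averaged before
ΔCT = CT(inside) − CT(outside); fold enrichment is
`efficiency^(−ΔΔCT)` per biological replicate and summarised as mean ± SD.
The amplification efficiency is fixed at 2.0 per cycle (the classic
`2^−ΔΔCT`), exposed as a parameter for assays with calibrated efficiencies.

Because `fold = (N_rt + N_p) / N_p`, per-cell copy number follows as
`N_rt = (fold − 1) · N_p`; this back-calculation is the unique one
consistent with the amplicon template counts. Copy numbers convert to molar
concentration via Avogadro's constant (6.02214076e23/mol, the exact SI
value) and a cytoplasmic volume of 7e−16 L for *E. coli*. A fold below 1 is
legitimate in uninduced samples and is clamped to 0 copies with a warning
rather than an error. Gel densitometry and plate-reader helpers normalise
band intensity by RT-DNA length and fluorescence by undiluted-equivalent
OD600 respectively.

## Equilibrium binding

At the concentrations used in fluorogen titrations, ligand depletion is not
negligible, so the bound fraction is the exact root of the binding
quadratic (the *tight-binding isotherm*):

F(At) = C1 · [(At + Bt + Kd) − sqrt((At + Bt + Kd)² − 4·At·Bt)] / (2·Bt) + C0

with lower plateau `C0`, amplitude `C1`, total fluorogen `Bt` and
dissociation constant `Kd`. The radicand is clamped at zero to absorb
floating-point negatives at the saturation boundary.

`fit_global()` fits several titration series at once with **shared**
`C0`, `C1`, `Bt` and a **per-series** `Kd`, by bounded Levenberg–Marquardt
least squares:

* `Bt` is boxed to ±20% of its nominal value by default. The fluorogen
  stock concentration is uncertain but not free; "strong constraints" is
  not a number, and ±20% is a defensible stock-error bound. The box width
  is a user parameter.
* `Kd` is fitted on a log10 scale (bounded 1e−4 to 1e4 µM), which both
  enforces positivity and conditions the optimisation across the four
  decades the presets span.
* The isotherm is weakly identifiable when `Kd` greatly exceeds the
  titrated range, so the fit is multi-started 8 times with `Kd` drawn
  log-uniformly from 0.01–100 µM (seeded, hence reproducible); plateaus
  start at `min(F)` and `max(F) − min(F)`, `Bt` at nominal. Lowest residual
  sum of squares wins; ties go to the earliest start.
* A fitted amplitude that is numerically zero makes `Kd` meaningless; such
  series are flagged `kd_unidentifiable` instead of erroring.

Confidence intervals come from a **residual-resampling bootstrap**
(`bootstrap_ci()`, percentile intervals, default B = 1000, seeded). The CI
method used for the published Kd estimates is unstated, so bootstrap
intervals here are this package's choice and are not expected to match any
published interval numerically.

## Half-life estimation

After inducer washout, the RT-DNA fold change declines through dilution by
growth and, possibly, active degradation. Growth is fitted first —
logistic `OD(t) = OD_max / (1 + exp(−r(t − t0)))` — and then substituted
into the decay model

C(t) = 1 + A · exp(−k·t) · OD(t_ref) / OD(t)

fitted over `(A, k)` with `k ≥ 0`. The fits are sequential, not joint,
mirroring how the substitution is defined. Two interpretation points the
model makes explicit:

* The `t_ref` inside the OD dilution ratio is the *first sampling time of
  the decay series*, a different quantity from the logistic midpoint `t0`,
  even though both are conventionally written t₀.
* The `+1` floor is read as the plasmid contribution to the inside
  amplicon: fold change cannot drop below the plasmid-only background.

A fitted `k` below 1e−6/min reports a half-life of `Inf` ("beyond the
detection limit"); the threshold is far below 1/(10 × doubling time) for
any realistic culture, so no real decay is masked. `fixed_k_refit()`
re-fits with `k` pinned at `ln 2 / half-life` — the amplitude is then linear
and solved in closed form — so free and fixed-half-life models can be
compared by residual sum of squares, the standard check that a
pure-dilution fit is genuinely better than, say, a 15- or 30-min half-life.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of (parameters, seed) — the session RNG
is never touched — and every generator has a noise-free mode that
round-trips *exactly* through its fitter, which anchors the test suite.

Noise models and defaults: additive Normal noise on CT values
(SD 0.15 cycles, a typical technical spread), multiplicative Normal noise
on fluorescence (2%), OD (2%) and decay-series fold change (5%), because
those errors scale with signal. The qPCR generator's CT intercept (35
cycles for one template) cancels in ΔΔCT by construction, which a test
asserts. Presets carry the study conditions: `FL` (Kd 0.12 µM) and `4LEv4`
(Kd 6 µM) titrations at Bt = 1 µM on a 12-point log grid from 0.05 to
40 µM, and `eco2_default` (17 plasmid copies, 120 RT-DNA molecules,
7e−16 L). The fluorescence plateaus are not published quantities; they are
fixed once at C0 = 100 and C1 = 4000 arbitrary units, a typical
plate-reader scale, and Kd recovery is invariant to that choice.

`gen_scaffold()` stands in for real *msd* sequences (which live in
supplementary material, not reproduced here): GC-clamped stems with A-only
loops, stem orientation alternating so that cross-stem pairings cannot tie
the designed structure — the ground-truth pair set is the *unique* maximum
under the default weights, which enumeration verifies on small cases. All
generated scaffolds are labelled synthetic.

What the generators do **not** emulate: real *msd* sequence content and its
RNaseH-processed heterogeneous ends, amplification-efficiency differences
between primer sets, plate position effects and pipetting drift, lag phases
or diauxie in growth, and promoter leakiness after washout (acknowledged as
possible ongoing RT-DNA production, expected minor, unmodelled). Passing
parameter-recovery tests therefore demonstrates correctness of the
estimators under the stated error models, not robustness to every real-data
pathology.

## Problem sizes and verification

The test suite checks the DP engine against brute-force enumeration on
random sequences up to 18 nt (500 cases in the end-to-end suite), recovers
Kd across 0.12–6 µM from 100 seeded noisy titrations per preset (median
within 25% of truth; in practice within a few percent), recovers half-lives
of 15/30/60 min within 20% in the median over 50 noisy replicates, and
confirms that pure-dilution data yield the infinity sentinel or a
half-life far beyond the doubling time in ≥ 90% of replicates. These sizes
were chosen to make the recovery distributions stable while keeping the
whole suite fast.

## Limitations

The folding engine ranks structures by pair weight, not free energy;
pseudoknots and the 2'–5'-branched hybrid topology are not modelled; the
insertion-site ranking is a reported heuristic; bootstrap CIs assume
exchangeable residuals across a titration; and all acceptance-style results
are on synthetic data by necessity — the wet-lab gels and in-vivo
fluorescence they echo are not computationally reproducible.
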