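---
title: "Isotope-tracing computations in tracemid: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-tracing computations in tracemid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracemid)
```

# Scope

`tracemid` implements the computational core of a stable-isotope-tracing
workflow for tumor metabolism studies: correction of measured
mass-isotopologue distributions (MIDs) for natural isotope abundance and
tracer impurity, labeling metrics, serum normalization of in vivo
enrichments, deconvolution of the NADPH active-hydride labeling fraction
from the NADP+/NADPH pair, the arithmetic of the accompanying bench assays,
and a forward simulator that generates complete cohorts with known ground
truth. It does not model chromatography, raw spectra, absolute fluxes, or
any downstream hypothesis testing.

# The correction model

A metabolite with elemental formula $F$ and a tracer on element $E$ (C or H)
with $n$ label-capable atoms is observed as intensities over nominal mass
shifts $0..k$. The *correction matrix* $M$ has one column per true labeling
state $j \in \{0..n\}$:

$$M_{\cdot j} = \underbrace{\mathrm{Bin}(j,\ \pi)}_{\text{tracer impurity}}
\ast \underbrace{\mathrm{nat}(E,\ c_E - j)}_{\text{unlabeled tracer-element atoms}}
\ast \underbrace{\mathrm{nat}(\text{other elements})}_{\text{nominal mode only}}$$

where $\ast$ is discrete convolution over mass shifts, $\pi$ is the
per-atom isotopic purity of the tracer, $c_E$ is the count of element $E$ in
$F$, and $\mathrm{nat}(\cdot)$ is the natural-abundance shift distribution
obtained by convolving per-atom isotope distributions. Note the second term
uses *all* unlabeled atoms of the tracer element, not only the designated
ones: same-element heavy isotopes sit at (nearly) the same exact mass as the
tracer isotope and cannot be resolved away at any practical resolution.

Two resolution modes are provided. `high_res` (the default, appropriate for
Orbitrap-class instruments resolving e.g. ¹³C from ²H isotopologues) drops
the hetero-element term; `nominal` keeps it, for unit-resolution data.
Which setting a given dataset needs is a property of the instrument method,
so it is a configuration choice, never inferred from the data.

Columns are truncated at the largest measured shift and deliberately *not*
renormalized: the truncated tail is signal the detector genuinely does not
see, and renormalizing would silently redistribute it.

Given raw intensities $y$, the corrected MID solves

$$\min_{x \ge 0} \| M x - y \|_2, \qquad \hat m = x / \textstyle\sum_i x_i .$$

The non-negativity constraint is what makes the inversion robust at low
signal; the solver is the Lawson–Hanson active-set NNLS
(`pracma::lsqnonneg`). Numerically, the solve is performed on the
sum-normalized intensity vector and rescaled afterwards — NNLS is
scale-equivariant, and keeping the right-hand side at unit scale keeps the
active-set iteration well conditioned across the six orders of magnitude
of intensity encountered in practice. The residual norm is reported on the
original intensity scale. An all-zero intensity vector is an error; a
missing isotopologue row in an input table is treated as intensity zero
with a warning (absent peaks are common exports, all-zero compounds are
not).

## Isotope constants

The natural-abundance table ships IUPAC/CIAAW-style values (¹³C 0.0107,
²H 0.000115, ¹⁵N 0.00364, ¹⁷O 0.00038, ¹⁸O 0.00205, ³³S 0.0075, ³⁴S
0.0425; ¹⁸O counts as shift 2 in nominal bookkeeping). ³²S is set to 0.95
so per-element abundances sum to exactly 1 (³⁶S, abundance ~1e-4, is
dropped). The table is a plain data frame, replaceable per call or loadable
from CSV, because published abundance values are revised occasionally and
enriched-matrix experiments may need custom tables.

# Labeling metrics and serum normalization

From a corrected MID $m_0..m_k$ the package always reports both

* the **labeled fraction** $1 - m_0$, and
* the atom-weighted **fractional enrichment** $\sum_i i\, m_i / n$,

because plotted "labeling fractions" in the literature are usually the
former while flux interpretation needs the latter; reporting both removes
the ambiguity. Figure-style pipeline outputs use $1 - m_0$ by default,
switchable per track (`metric: fractional_enrichment`).

In vivo ¹³C readouts are normalized per mouse by the serum tracer
enrichment: tumor metric divided by the serum [U-¹³C₆]-glucose enrichment
of the same animal. Whether that denominator should be the serum glucose
M+6 fraction or its atom-fraction enrichment is genuinely ambiguous in
practice; both are supported (`denominator: fractional_enrichment`, the
default, or `mplus_fraction`) and neither is asserted as canonical. For an
infusion where serum glucose is essentially a mixture of unlabeled and
fully labeled molecules the two coincide, which is exactly how the
simulator generates serum glucose.

For saponified fatty acids under D₂O tracing, the enrichment denominator
defaults to the full hydrogen count of the free fatty acid (e.g. 32 for
C16:0). Exchangeable-H counts are debatable and instrument-dependent, so
the count is overridable (`n_atoms=`). Essential fatty acids (C18:2) carry
an `essential` flag through to outputs; they cannot be synthesized de novo
and their labeled fraction is the internal zero control of any D₂O
experiment.

# NADPH active-hydride deconvolution

NADPH carries one redox-active hydride that NADP+ lacks. Under ²H tracing
the corrected NADPH MID is a two-component mixture of the corrected NADP+
MID $a$:

$$b = (1-p)\,[a; 0] + p\,[0; a],$$

where $p$ is the fraction of active hydrides carrying ²H. The mixture is
linear in $(1-p, p)$ with the weights summing to one, so the least-squares
problem reduces to one scalar parameter with the closed form

$$p^\* = \frac{\langle b - c_1,\ c_2 - c_1\rangle}{\lVert c_2 - c_1 \rVert^2},
\qquad c_1 = [a;0],\ c_2 = [0;a],$$

clipped to $[0,1]$. Clipping is flagged (`clipped`) and reported, never
silent: with true $p$ near zero, measurement noise makes slightly negative
unconstrained optima *expected*, and hiding the event would bias any
downstream averaging silently. Whether to constrain at all is a judgment
call; the package constrains (a labeling fraction is physical), keeps the
unconstrained value in `p_unconstrained`, and the test suite verifies the
closed form against brute-force grid search. Inputs must be corrected MIDs;
the pipeline enforces that ordering. Shorter vectors are zero-padded, and
$p$ is invariant to trailing zeros.

`active_h_cohort()` fits every NADP+/NADPH pair and summarizes $p$ per
group as mean ± SEM (SEM is `NA` for single-sample groups). No hypothesis
testing is attached — group statistics belong to the analysis layer, not
the estimator.

# Bench-assay arithmetic

These functions encode the exact published formulas, with units enforced at
the boundary (amounts µg, concentrations mg/L, volumes mL, fluorescence
arbitrary units, confluence percent):

* serine consumption: $(A_0 - A_t) / ((C_t - C_0)/10^6)$ µg per
  10⁶-cell increase; wells without growth are an error, not a negative
  rate, because the formula presumes proliferation. `medium_amount_ug()`
  converts medium composition to well amounts (30 mg/L in 2 mL = 60 µg).
  Duplicate wells per timepoint are combined by the mean in the pipeline
  (the obvious choice where none is stated).
* ROS: background-subtracted CM-H₂DCFDA fluorescence per 10⁶ cells;
  a stained reading below background returns the negative value with a
  warning.
* redox ratios: plain pool ratios (NADPH/NADP+, GSH/GSSG).
* proliferation: OLS slope of percent confluence vs time (%/h), at least
  three points.
* relative proliferation: treated counts over the untreated control mean.

# What the simulator emulates — and what it does not

`simulate_cohort()` forward-simulates a two-group (WT vs G6PD-KO) mouse
cohort through the *identical* forward model the correction inverts:
true binomial labeling MIDs, convolution with natural abundance and tracer
impurity via the correction matrix, a per-sample intensity scale drawn
log-uniformly over $[10^5, 10^8]$, and multiplicative lognormal noise
applied to intensities (where measurement noise physically enters), never
to fractions.

Default conditions (chosen once; each is a parameter of `sim_config()` /
`sim_group()`):

| parameter | WT | KO | rationale |
|---|---|---|---|
| active-H labeling $p$ | 0.05 | 0.15 | KO relies more on serine-driven one-carbon NADPH |
| serum glucose M+6 | 0.35 | 0.35 | shared infusion exposure |
| serine ¹³C enrichment (per C) | 0.15 | 0.08 | impaired serine biosynthesis in KO |
| C16:0 newly-synthesized fraction | 0.30 | 0.10 | impaired de novo lipogenesis in KO |
| per-H ²H incorporation | 0.045 | 0.045 | ~body-water D₂O enrichment of an infusion |
| C18:2 synthesis | 0 | 0 | essential fatty acid, zero by definition |
| NADP+ background ²H enrichment | 0.02 | 0.02 | low passive labeling of the ring sites |
| `n_per_group` | 8 | 8 | typical cohort size for such tracing arms |
| `noise_cv` | 0.02 | — | LC-MS peak-intensity repeatability |
| tracer purity | 0.99 | — | typical commercial isotopic purity |
| `bio_cv` | 0.05 | — | mild between-mouse biological spread |

Glycine shares the serine glucose-derived enrichment parameter (the two
move together downstream of 3-phosphoglycerate; one parameter keeps the
generator minimal). Bench-assay magnitudes (consumption 12 vs 25 µg/10⁶
cells, ROS 3000 vs 6000 a.u./10⁶ cells, slopes 0.75 vs 0.45 %/h,
NADPH/NADP+ 1.2 vs 0.6, GSH/GSSG 8 vs 4) are realistic invented values
with the group effect directions of the biology they emulate.

The simulator does **not** emulate: chromatographic peak shape or
integration error, co-eluting isobars, ion suppression, missing peaks,
compartment-specific (cytosolic vs mitochondrial) labeling, non-binomial
positional isotopomer structure (a `custom` MID escape hatch exists), or
correlated noise across isotopologues. Passing recovery tests on simulated
cohorts therefore demonstrates that the *computations* are correct and
unbiased under realistic noise — not that real LC-MS artifacts are
handled; those must be dealt with upstream at peak curation.

All randomness flows from the single `seed` in `sim_config()`; identical
configurations produce byte-identical output files.

# Numerical choices

* NNLS on the sum-normalized right-hand side, rescaled after (conditioning;
  see above). Exact forward simulations yield residual norms at machine
  precision.
* Convolutions are truncated at the measured shift during accumulation;
  truncation at shift $s$ can never change entries $\le s$, so this is
  exact for the retained rows.
* Purity 1 collapses the impurity binomial to a point mass (column $j$
  starts with $j$ structural zeros) — tested explicitly.
* The active-H closed form guards the degenerate case
  $\lVert c_2 - c_1\rVert = 0$, unreachable for valid MIDs.
* Metric clamping: labeling metrics are clamped to $[0,1]$ against
  floating-point dust; an enrichment genuinely exceeding 1 (wrong
  `n_atoms`) additionally warns.
* Pipeline compound `n_label` defaults to
  `min(measured shifts - 1, element count)` — for fully measured compounds
  this equals the atom count, and for tall molecules measured over few
  shifts (NADP+ over M+0..M+2) it keeps the system determined.

# Tested problem sizes

The test suite verifies: oracle equivalence of `natural_mid` and the
correction matrices against exhaustive multinomial enumeration for random
formulas of up to 12 atoms; noise-free round trips across intensity scales
$10^5$–$10^8$; recovery of $p$ over the grid $\{0, 0.02, \ldots, 0.6\}$
with 200 replicates per point under 2% multiplicative noise (bias < 0.01,
RMSE < 0.03); a full simulated cohort of 8 mice per group for the
essential-fatty-acid zero control; and byte-level determinism of the
simulate-and-run path. These sizes keep the default suite fast while
covering every code path; all scale linearly if enlarged.

# Known limitations

* Single tracer element per run; simultaneous ¹³C/²H interference is out of
  scope.
* No resolution-dependent partial merging of near-isobaric species — the
  mode switch is binary.
* No absolute flux estimation or isotopomer spectral analysis; the package
  stops at labeling fractions and enrichments.
* The fatty-acid hydrogen denominator ignores exchange-site subtleties
  unless overridden.
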