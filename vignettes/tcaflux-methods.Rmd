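---
title: "tcaflux: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tcaflux: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcaflux)
```

## The isotopomer model

`tcaflux` simulates 13C label propagation through a reduced mitochondrial
network: pyruvate (3C), acetyl-CoA (2C, the acetyl unit), oxaloacetate
(4C), citrate (6C), alpha-ketoglutarate (5C), glutamate (5C), succinate
(4C) and malate (4C). Each pool carries a probability vector over
*positional* labeling states — length $2^c$ for a $c$-carbon pool — rather
than a mass-only distribution. Positional resolution is not a luxury: the
isocitrate- and alpha-ketoglutarate-dehydrogenase steps each release a
specific, oxaloacetate-derived carbon, which is what makes acetyl carbons
survive the first turn and produces the canonical first-turn signatures
(citrate M+2 from glucose or palmitate entering as acetyl-CoA; citrate
M+4 from glutamine entering via glutamate and alpha-ketoglutarate).
Mass-only bookkeeping cannot reproduce those carbon fates. The largest
pool (citrate) needs only 64 states, so the state space stays tiny.

Carbon conventions: citrate positions 1–4 derive from oxaloacetate,
positions 5–6 from the acetyl unit; both decarboxylations remove the
lowest-numbered (oxaloacetate-derived) position. Succinate and fumarate
are symmetric intermediates: every state formed is averaged with its
carbon-reversed twin, the standard treatment of molecular symmetry.
Glucose enters as [13C3]pyruvate oxidized to [13C2]acetyl-CoA with
pyruvate as a pass-through pool (no pyruvate carboxylase); palmitate
enters as a lumped [13C2]acetyl-CoA enrichment rather than eight
sequential acetyl units — with identical acetyl-pool enrichment the
distinction is invisible downstream, so the lumped form is used.
Anaplerosis is modeled generically as unlabeled entry at
alpha-ketoglutarate plus unlabeled exchange dilution at acetyl-CoA and
oxaloacetate.

For a balanced network, each pool's state vector obeys

$$\frac{dx_P}{dt} \;=\; \frac{1}{C_P}\sum_{i \in \mathrm{in}(P)}
  v_i\,\bigl(s_i(t) - x_P\bigr),$$

where $C_P$ is the pool size, $v_i$ the inflow fluxes and $s_i$ the
inflow state distributions (a carbon-map projection of the source pool, a
condensation outer product for citrate synthase, an unlabeled delta, or
the plasma input mixture). `build_tca_network()` closes the mass balance
before simulation starts by computing a balancing efflux for every pool
and rejecting configurations that would need a negative one.

### Plasma input function

Infusion enrichment follows a mono-exponential approach to plateau with a
priming step,
$e(t) = E\,(1-(1-f)e^{-kt})$, $f = \min(\text{prime}\cdot k, 1)$ — the
kinetics of a one-compartment pool primed with a bolus of `prime` times
the per-minute infusion rate. The experimental design fixes only the 3x prime
ratio, not plasma kinetics, so the rate constant defaults to
$k = 0.3\,\mathrm{min^{-1}}$ (plasma tracer turnover of a few minutes,
typical for rodent infusions) and the plateau to 0.5 (endogenous
production dilutes an infused tracer well below 1). In vitro media-switch
experiments are represented by plateau 1 with the same near-instant
primed onset. Relative V_CS normalizes the plateau away.

### Integration

A fixed-step classical Runge–Kutta (RK4) scheme, default step 0.05 min
(capped at 0.1 min), integrates the balance equations. Fixed-step
integration keeps outputs bit-deterministic across platforms — no
adaptive-solver dependence in golden files — and the tests verify the
integrator against a closed-form two-pool cascade to 1e-6. A state
component falling below −1e-6 aborts with advice to reduce the step;
distributions are renormalized nowhere, so conservation (each pool
summing to 1) is itself a correctness check, asserted to 1e-6 in tests.

## Default kinetic parameters

Pool sizes are expressed in minutes of turnover at the reference
citrate-synthase flux `vcs = 1 min^-1`. Two presets cover the two
experimental regimes:

* **`"infusion"`** (default): pyruvate 8 (lumped with the large, rapidly
  exchanging cytosolic lactate pool), acetyl-CoA 0.2, oxaloacetate 2,
  citrate 6, alpha-ketoglutarate 4, glutamate 10, succinate and malate 2.
  These were fixed, once, so that the two kinetic facts characteristic of
  primed tumor infusions hold simultaneously: citrate label accumulation
  approximately linear over 0–30 min (relative RMS deviation from the
  least-squares line 4.2%) and isotopic steady state by 60 min (the
  60-min enrichment is 96.3% of the 150-min value). A single well-mixed
  pool cannot satisfy both — an exponential that saturates by 60 min is
  visibly curved before 30 — so the precursor delay supplied by the large
  pyruvate pool, which makes the citrate curve sigmoid, is essential.
* **`"linear_range"`**: all pools enlarged (citrate 150) so that the
  0–30 min window lies deep inside the pre-steady-state linear phase even
  at several-fold the reference flux. Slope-based flux estimation is only
  *valid* in that regime: once citrate saturates, the slope measures the
  plateau rather than the flux. Parameter-recovery benchmarks therefore
  use this preset.

Default fluxes: `ana = 0.25` (anaplerosis a quarter of citrate-synthase
flux), dilution exchanges 0.1 at acetyl-CoA and oxaloacetate, glutamate
exchange 0.5, glycolysis 2 (half of pyruvate turnover leaving as
lactate), and an even acetyl-CoA split between pyruvate dehydrogenase and
beta-oxidation (`acetyl_from_pdh = 0.5`), reflecting media in which
glucose, glutamine and fatty acids are all supplied.

The linearity criterion above is operationalized as the RMS residual of
the ordinary least-squares line divided by the fitted enrichment range
over the window; the observation is qualitative and names no
metric.

## Enrichment measures and flux estimation

Because plotted "enrichment" in this assay family is rarely defined
algebraically, both pool-average measures are exposed:
`atom_fraction` $=\sum_i (i/n) M_i$ (default — the natural measure for a
flux-slope interpretation) and `labeled_fraction` $=1-M_0$. A third
response, a single isotopologue channel (e.g. [13C2]citrate under
uniformly labeled glucose), is available in `fit_label_slope()` via
`isotopologue =`.

`vcs_fit()` fits each condition's slope constrained through the origin by
default (label is zero at infusion start) over the 0–30 min window (the
in vitro convention) or as the single-point origin ratio at 60 min (the
in vivo convention). The unconstrained fit is available and matters for
noisy data: the measurement layer clamps negative noise excursions at
zero, which leaves a small positive apparent baseline in every channel;
measured t = 0 samples expose that baseline and an intercept absorbs it.
The end-to-end benchmark `vcs_recovery_benchmark()` accordingly reads the
[13C2]citrate channel (single-channel noise instead of the accumulated
noise of a pool-average) with an unconstrained fit, and recovers a true
twofold flux ratio within a few percent at MID noise sd 0.01 with five
replicates.

The steady-state check mirrors the 60 vs 150 min comparison: a pooled
two-tailed t test whose *failure to reject* declares steadiness. This is
not an equivalence test — low replication can pass simply through low
power — and the documentation flags it as such.

The dilution index $1 - E_{\mathrm{met}}/E_{\mathrm{ref}}$ is one
reasonable operationalization of "label dilution through the cycle,
reflecting anaplerosis"; there is no canonical formula, so
outputs label it explicitly. Citrate is the reference for the
acetyl-entry tracers and glutamate for the glutamine tracer (the first
labeled TCA-proximal metabolite of each scheme).

## The measurement layer

Natural 13C (default `p13 = 0.0107` per carbon) converts a true MID into
the observed one by binomial convolution over the unlabeled carbons;
correction solves the triangular linear system exactly, clamps small
negatives and renormalizes. Only skeleton carbons are convolved — the
derivatization chemistry of the assay is not modeled, so no
derivatization-atom correction is attempted. Measurement noise is
additive truncated Gaussian on fractions (default sd 0.01), not Poisson
on ion intensities, because the pipeline consumes fractional
distributions, never raw spectra.

## Synthetic cohorts, growth curves and their limits

`generate_expression_cohort()` draws a leukocyte-fraction covariate from
a Beta(2, 5) quantile transform of a latent standard normal (mean
infiltrate ~0.29, support [0, 1]), log-normal expression (log-scale sd
0.4), planted genes whose latent shares the target correlation with the
covariate's latent, and `GZMA`/`PRF1` sharing that latent (r = 0.6) so
CYT correlates positively with infiltration. Default cohort size is 369
samples, matching the melanoma leukocyte-fraction cohort being emulated;
the default planted lists are the amino-acid transporter/enzyme symbols
reported for that screen. Growth curves are logistic — counts visibly
approach a horizontal asymptote by 72 h — with three replicate wells and
three counting measurements at 24/48/72 h and multiplicative log-normal
noise (CV 5%).

What passing tests on these generators do **not** show: real cohorts have
heavy-tailed, covarying expression, batch effects and dropout; real MIDs
carry correlated, intensity-dependent noise and derivatization artifacts;
real tumors are multi-compartment (immune and stromal cells contribute).
The generators plant exactly the structure the estimators look for, so
the tests validate the *pipeline's correctness*, not the biology.

## Immunogenomic conventions

* CYT uses linear-scale expression (log-space is a documented option in
  the literature; linear is the default here) and errors loudly on zeros
  unless a pseudocount (suggested 0.01) is supplied.
* The DE gate reads the conventional "log2 fold change > 2 or <= 2"
  phrasing as the evident intent >= 2 / <= −2, i.e. |log2FC| > 2,
  applied after BH adjustment across the whole table (p < 0.01).
* The Z-to-p convention is one-sided upper-tail, fixed by the anchor
  z = 3.09 <-> p = 0.001; `classify_prognostic()` partitions at ±3.09.
* Correlation screens default to Pearson (when only a
  "correlation coefficient" is asked for); Spearman is a flag. Screen gates
  default to raw p < 0.05, with a BH-adjusted option, since
  multiplicity handling varies across published screens.
* Row clustering z-scores each row, uses Euclidean distance and average
  linkage (the default of the common heatmap tools), with ties resolved
  by lowest original index for deterministic leaf order.

## Problem sizes and numerical tolerances

The test and acceptance suites run at deliberately desk-sized scales: 150
minutes of simulated infusion at step 0.05 min, 1000-MID round-trip
checks (max abs error < 1e-8), 500 random vectors for the BH oracle, 100
random group sets for the Tukey domination check, cohorts of 200 genes x
200 samples for the correlation screens, and the twofold-flux recovery at
5 replicates x 13 time points. MID validity uses 1e-6 tolerances; file
readers renormalize sums within 1e-3 of 1 and reject worse.

## Known limitations

No compartmentation beyond a single mitochondrial pool set; no CO2
refixation; no pyruvate carboxylase flux; no genome-scale network or
gradient-based isotopically-nonstationary flux fitting — relative V_CS is
a slope ratio, not an absolute flux in µmol/g/min. PRECOG-style survival
Z scores and DESeq2-style DE tables are consumed as inputs, never
recomputed. The number of TCA turns the first-turn schemes approximate in
real data is not identifiable from MIDs alone; the simulator supports both
the severed first-turn mode and full multi-turn recycling, and reports
whichever the caller requests.
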