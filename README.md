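# tcaflux

Stable-isotope tracing of TCA-cycle fluxes, with an immunogenomic scoring
arm, for tumor-metabolism studies.

## The problem

How much of a tumor's oxidative metabolism is fed by glucose, glutamine or
fatty acids — and does that partitioning track the tumor's immunogenicity?
The experimental answer comes from uniformly 13C-labeled tracers
([U-13C6]glucose, [U-13C5]glutamine, [U-13C16]palmitate) delivered either
as labeled culture media or as a primed (3x)-continuous infusion, followed
by LC-MS/MS measurement of the mass-isotopologue distributions (MIDs) of
TCA-cycle intermediates. Two readouts summarize the biology:

* **Relative citrate-synthase flux** `V_CS`: the slope of 13C citrate
  enrichment versus time, normalized to a reference condition,

  `V_CS(rel) = slope(E_cit vs t) / slope_ref`,

  fitted over the linear 0–30 min accumulation window in vitro, or as the
  single-point origin ratio `E(60)/60` in vivo;
* **Anaplerotic dilution**: unlabeled carbon entering the cycle downstream
  of citrate dilutes the label in distal intermediates, quantified here as
  the dilution index `1 − E_met / E_cit` at isotopic steady state.

The companion immunogenomic analyses relate tumor metabolic gene
expression to immune infiltration: cytolytic activity
`CYT = sqrt(GZMA × PRF1)` per sample, gene–covariate correlation screens,
differential-expression gating (|log2FC| > 2, BH-adjusted p < 0.01), and
prognostic survival-Z classification (detrimental if z > 3.09, i.e.
one-sided p < 0.001; beneficial if z < −3.09).

Because the underlying cohort and LC-MS/MS datasets are not publicly
deposited, the package ships a bespoke generator for every input it
consumes: a deterministic positional-isotopomer simulator of 13C label
propagation through a reduced TCA network (with carbon-correct
decarboxylations and succinate/fumarate symmetry), a measurement layer
(natural-abundance convolution, additive MID noise), and seeded expression
cohorts, DE tables, prognostic Z tables and deprivation growth curves with
planted, recoverable structure.

## Worked example

Simulate a "cold" and a "hot" condition whose true citrate-synthase fluxes
differ twofold, push both through the measurement layer, correct natural
abundance back out, and estimate relative V_CS:

```r
library(tcaflux)

net_ref  <- build_tca_network(network_config("linear_range", acetyl_from_pdh = 1))
net_test <- build_tca_network(network_config("linear_range", vcs = 2, acetyl_from_pdh = 1))
tr <- tracer_spec("glucose_U13C6", plateau_enrichment = 1)

tc <- label_timecourse(rbind(
  as.data.frame(synth_tracer_dataset(net_ref,  tr, seq(0, 30, 5), 5,
                noise_model(sd_mid = 0.002, seed = 1), condition = "cold")),
  as.data.frame(synth_tracer_dataset(net_test, tr, seq(0, 30, 5), 5,
                noise_model(sd_mid = 0.002, seed = 2), condition = "hot"))))

fit <- vcs_fit(correct_timecourse(tc), reference = "cold")
fit
#> Relative citrate-synthase flux (citrate atom_fraction, window slope over [0, 30] min)
#> Reference condition: cold
#>   condition        tracer    slope        se  n relative_vcs
#> 1      cold glucose_U13C6 0.001715 2.182e-05 35        1.000
#> 2       hot glucose_U13C6 0.003306 3.127e-05 35        1.927
```

The `hot` condition's citrate labels 1.93x faster than the reference —
recovering the simulated twofold flux difference from noisy MIDs. Under
the full measurement-noise benchmark (MID noise sd 0.01, natural
abundance, 5 replicates) the dedicated estimator reads the
[13C2]citrate channel:

```r
vcs_recovery_benchmark(true_ratio = 2, seed = 1)$estimate
#> [1] 1.979165
```

Anaplerotic dilution at steady state (default infusion kinetics, glucose
tracer, 60 min):

```r
net <- build_tca_network(network_config())
tc60 <- simulate_timecourse(net, tracer_spec("glucose_U13C6"), times = 60,
                            metabolites = c("citrate", "glutamate",
                                            "succinate", "malate"))
dilution_profile(tc60)
#>   metabolite enrichment dilution_index clamped
#> 1    citrate     0.1381          0.000   FALSE
#> 2  glutamate     0.0452          0.672   FALSE
#> 3     malate     0.1045          0.243   FALSE
#> 4  succinate     0.1049          0.240   FALSE
```

About a quarter of the malate-pool label has been replaced by unlabeled
anaplerotic carbon relative to citrate. See `vignettes/tcaflux-methods.Rmd`
for the model, its assumptions and the design decisions.

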