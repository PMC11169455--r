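# thiamsim

Kinetic modelling of vitamin B1 (thiamin) biosynthesis and in-silico
enzyme-overexpression scanning, packaged for metabolic engineers and
systems biologists who want to rank biofortification strategies before
touching a transformation vector.

Rice grains are thiamin-poor, and raising B1 vitamers in the endosperm
requires knowing which enzyme limits flux. `thiamsim` builds small kinetic
models of the pathway — the pyrimidine branch (THIC: AIR + SAM → HMP-P),
the thiazole branch (THI1: NAD + glycine → HET-P), the bifunctional TH1
(HMP-P → HMP-PP kinase and HMP-PP + HET-P → TMP synthase), TH2, TDPK and
THiM salvage — and asks what happens to TMP when enzyme abundances change.

## What the package does

* **Declarative models.** Metabolite/reaction tables (TSV or CSV; one
  reaction per row, stoichiometry as `-1:HMP_PP,+1:TMP` token lists) load
  into validated model objects; SBML Level 3 export/import round-trips
  them exactly.
* **Rate laws.** Irreversible Michaelis–Menten
  `v = Vmax·S/(Km+S)`, two-substrate
  `v = Vmax·A·B/((KmA+A)(KmB+B))` (ternary-complex default, ping-pong
  variant per reaction), mass action and constant flux.
* **Stiff ODE simulation.** `dC/dt = N·v(C)` integrated with LSODA
  (rel 1e-8 / abs 1e-12) over 10,000 s by default, with trailing-window
  plateau detection and quadratically refined peak annotation.
* **Overexpression scans.** `f`-fold enzyme changes scale Vmax
  (`Vmax = kcat·[E]`; Km untouched; `f = 0` is a knockout); bifunctional
  enzymes scale all their reactions together; scenarios are ranked by
  sustained target concentration, peak or AUC.
* **Flux-balance gap-fill.** Reactions without literature kinetics get
  fluxes from an LP over `N·v = 0` with box bounds, back-solved into MM1
  laws that reproduce the predicted flux at the initial state.
* **Growth-curve analysis.** Exponential-phase growth rates from OD600
  series (nonlinear least-squares logistic/exponential fit by default, a
  transparent log-linear window method as an option), one-way ANOVA +
  Tukey HSD group comparison.
* **Synthetic data.** Generators for analytic MM chains, a reduced
  thiamin network with the co-substrate-limitation phenomenology, and
  noisy logistic growth tables — everything the tests need, built in code.

The shipped 34-reaction / 29-metabolite rice network
(`inst/extdata/thiamin_rice_synthetic/`) is a **synthetic reconstruction**:
canonical pathway topology with plausible placeholder kinetics, intended to
exercise the full workflow, not to predict measured rice concentrations.

## Worked example

```r
library(thiamsim)

toy <- make_thiamin_toy()
scan <- run_scan(toy, enumerate_standard_scenarios(
  toy, c("THIC", "THI1", "TH1"), fold = 100))
scan$report[, c("rank", "scenario", "final", "v_peak", "t_peak", "plateau")]
```

```
 rank                       scenario      final     v_peak   t_peak plateau
    1 THIC x100, THI1 x100, TH1 x100 2.00003624 2.84824877    42.11    TRUE
    2                      THI1 x100 0.01698491 0.03273947   467.16    TRUE
    3                      THIC x100 0.01017855 0.01528191  1374.03   FALSE
    4                       TH1 x100 0.01005317 1.24163162    12.03    TRUE
    5                       baseline 0.01002121 0.01014481    79.91    TRUE
```

Read bottom-up: the baseline TMP plateau sits at 0.0100 nmol/L.
Overexpressing THIC alone changes nothing (the thiazole branch limits);
THI1 alone gives a modest sustained 1.7-fold gain; TH1 alone produces a
dramatic transient — a peak of 1.24 nmol/L at 12 s, over a hundred times
its own final value — but relaxes back to baseline once the stored
HMP-PP/HET-P pools are spent. Only overexpressing all three enzymes
sustains a high plateau (2.0 nmol/L, a 200-fold gain in this toy). That
asymmetry — TH1 as the single most consequential lever, but only the
combination sustainable — is the pathway's engineering lesson.

The full workflow on the shipped network lives in `analysis/`:

```sh
Rscript analysis/01_build_model.R        # census, FBA gap-fill
Rscript analysis/02_baseline_simulation.R
Rscript analysis/03_overexpression_scan.R
Rscript analysis/04_growth_curves.R      # yeast-style growth comparison
```

Each step prints what it found and writes tables under `results/` (for
example, step 2 reports the baseline cytosolic TMP plateau of the
gap-filled network at 1.637 nmol/L).

## Package layout

* `R/` — model types and I/O, rate laws, simulator, perturbation scan,
  flux balance, growth analysis, synthetic-data generators.
* `inst/extdata/thiamin_rice_synthetic/` — the synthetic reference tables
  plus the flux-balance bounds/objective configuration.
* `analysis/` — the numbered workflow scripts.
* `vignettes/thiamin-kinetics.Rmd` — model assumptions, parameter
  semantics, numerical choices and limitations.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles (fixed-step RK4, LP vertex enumeration, permutation
  tests).
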