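---
title: "Kinetic modelling of thiamin biosynthesis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of thiamin biosynthesis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thiamsim)
```

## The modelling problem

Vitamin B1 (thiamin) is synthesised de novo in plant plastids from two
moieties: a pyrimidine branch (THIC converts AIR + SAM to HMP-P) and a
thiazole branch (THI1 produces HET-P from NAD and glycine). The bifunctional
enzyme TH1 first phosphorylates HMP-P to HMP-PP (kinase site) and then
condenses HMP-PP with HET-P into thiamin monophosphate (TMP; synthase site).
TMP is dephosphorylated to free thiamin by TH2 and activated to the cofactor
TDP by thiamin pyrophosphokinase (TDPK); THiM salvages free thiazole back
into HET-P. Rice endosperm — the polished grain — is thiamin-poor, so the
engineering question the model addresses is: *which enzyme abundances limit
TMP accumulation, and which overexpression strategy raises it sustainably?*

`thiamsim` represents such networks as declarative tables (metabolites with
compartments and initial concentrations; reactions with stoichiometry and
rate laws), simulates them as stiff ODE systems, scans enzyme
overexpression scenarios, and gap-fills missing kinetics from a
stoichiometric flux-balance model.

## Model structure and rate laws

The state is a concentration vector $C$ (nmol/L) obeying
$\dot C = N\,v(C)$, with $N$ the stoichiometric matrix and $v$ the
reaction-rate vector. Supported rate laws:

* **MM1** — irreversible single-substrate Michaelis–Menten,
  $v = V_{max} S/(K_m + S)$.
* **MM2** — two-substrate law (used for TH1 synthase, THIC and THiM). The
  default is the random-order ternary-complex (double-hyperbolic) form
  $v = V_{max}\,A B / ((K_{mA}+A)(K_{mB}+B))$; a ping-pong form
  $v = V_{max} A B/(K_{mB}A + K_{mA}B + AB)$ is selectable per reaction
  (`variant` column). The mechanism underlying each two-substrate enzyme is
  rarely documented, so the smallest-assumption default is used and the
  alternative is one configuration field away; on toy problems the two
  forms differ only quantitatively, not in any ordering the package
  asserts.
* **mass_action** — $v = k \prod_i S_i$, used for transport and turnover.
* **constant_flux** — a fixed rate, used for precursor supply from
  unmodelled metabolism.

Compartments (plastid, cytosol, mitochondrion, external) are labels only:
no volumes are modelled, all concentrations share one unit (nmol/L), and
transport between compartments is an ordinary reaction. Boundary species
(cofactor pools such as ATP, external reservoirs) are clamped at their
initial concentration by zeroing their time derivative; they still enter
rate laws and stoichiometries.

Overexpression semantics: an $f$-fold change in enzyme abundance is an
$f$-fold change in $V_{max}$ (since $V_{max} = k_{cat}[E]$), with $K_m$
untouched; $f = 0$ is a knockout. All reactions sharing an enzyme label
scale together — for bifunctional TH1 a single gene dosage drives both
active sites.

## Simulation, plateau and peak annotation

Time courses are integrated with the adaptive stiff/non-stiff switching
LSODA integrator (`deSolve::lsoda`), relative tolerance `1e-8`, absolute
tolerance `1e-12` nmol/L, over a default horizon of 10,000 s (2 h 47 min)
with 1000 uniformly spaced output points; outputs are dense-output
interpolants, so refining the grid does not change the trajectory. States
in $(-10^{-9}, 0)$ nmol/L — ordinary stiff-solver excursions — are clamped
to zero before rate evaluation; anything below $-10^{-9}$ aborts with a
diagnostic naming the metabolite.

"Plateau" has no standard definition, so the package uses a reproducible,
scale-free one: a series has plateaued when the relative spread
(max − min over the window, divided by the window mean magnitude) of the
trailing 10 % of the time course is below $10^{-3}$; both the window mean
and the terminal value are reported, since for a genuine plateau they
coincide and for a still-drifting series they do not. Window fraction and
tolerance are configuration fields.

Peaks are located as the global maximum on the output grid, refined by the
vertex of the quadratic through the three surrounding points (ties break to
the earliest time); peak times are also rendered as "Xm Ys".

## Flux-balance gap-fill

Reactions without literature kinetics are flagged `needs_fba`. A
stoichiometric model is built over the *internal* (unclamped) metabolites
— clamped species act as unbalanced reservoirs — with finite box bounds
(defaults $[0, 1000]$, $[-1000, 1000]$ for reversible reactions; finiteness
is required by the simplex formulation) and a linear objective. The LP is
solved with the two-phase simplex method after shifting fluxes by their
lower bounds. Infeasibility is a reported status, not an error.

Each flagged reaction then receives a law whose rate at the initial
concentrations equals its predicted flux $J$: by default an MM1 law over
the reaction's first substrate with a configured $K_m$ and
$V_{max} = J\,(K_m + S_0)/S_0$ (keeping the step responsive to substrate
depletion), or `constant_flux` on request. Zero predicted flux always
becomes `constant_flux` 0; positive flux through a substrate starting at
zero is reported as unsatisfiable.

The objective and bounds of a flux-balance model are genuinely open
choices. For the shipped network the configuration (a plain TSV next to the
model tables) maximises the TMP synthase flux — the pathway's committed
biosynthetic step — under uptake caps on the precursor supplies of the same
order as their kinetic rates, plus small minimum demand fluxes on the
TDP/thiamin utilisation steps representing cofactor consumption. Note that
maximising *net* production of an internal metabolite is degenerate (it is
identically zero at steady state), which is why the synthase flux is the
objective.

## The shipped reference network is synthetic

The full rice thiamin network is distributed as plain-text tables
(`inst/extdata/thiamin_rice_synthetic/`): 34 reactions and 29 metabolites
across the four compartments, covering the de novo branches, TH1, TH2 in
cytosol and mitochondrion, TDPK, THiM salvage, inter-compartmental
transport, precursor supply and slow turnover, with four transport or
utilisation steps left to the flux-balance gap-fill. Its *topology* follows
the canonical plant pathway; its *parameters are plausible placeholders* on
an nmol/L scale, chosen for a stable baseline with a TMP plateau, and are
not measured constants. Analyses on this network therefore demonstrate the
workflow and the mechanism, not rice-specific quantitative predictions, and
no literature concentration is asserted against it.

## The reduced thiamin network

`make_thiamin_toy()` is a six-reaction distillation built to isolate the
dynamic phenomenon that makes TH1 the interesting target. Its calibration
encodes two facts and is fixed in code (the seed argument exists only for
interface uniformity — the generator is deterministic):

* **branch asymmetry** — the thiazole branch (HET-P supply,
  ~0.01 nmol L⁻¹ s⁻¹) is slower than the pyrimidine branch (~0.02), so
  HET-P is the limiting co-substrate;
* **large stored pools** — HMP-PP and HET-P pools (50 and 30 nmol/L) are
  two to three orders of magnitude larger than the branch fluxes, with the
  condensation $K_m$ values (100 nmol/L) well above the pools' quasi-steady
  levels, and a slow pyrimidine turnover leak gives HMP-PP a finite steady
  state. The initial state is the baseline steady state, so the
  unperturbed model plateaus immediately.

Four behaviours follow, and are asserted by the test suite: THIC
overexpression alone changes nothing (the other branch limits); THI1 alone
gives a modest sustained increase (until the pyrimidine side limits); TH1
alone burns the stored pools into a pronounced TMP transient — peak two
orders of magnitude above its own final value, on a minutes timescale set
by pool size over boosted flux — that relaxes back to the supply-limited
baseline; and only the triple overexpression sustains a high plateau. These
are orderings, not concentrations: the toy makes no claim to reproduce any
measured value.

## Growth-curve analysis

The yeast-complementation module estimates specific growth rates from
OD600 series and compares groups. The estimator question is subtler than
it looks. The classical recipe — log-transform, select the exponential
phase, fit a line — is implemented as `method = "window"`: the exponential
phase is the longest contiguous run whose ln(OD) linear fit reaches
R² ≥ 0.99 with positive slope (ties to the higher R²), and the rate is
that slope. But with additive OD noise of realistic size (σ = 0.01 on a
culture inoculated at OD 0.05), the true exponential region is
noise-dominated *in log space*, so the only windows reaching R² 0.99 sit
late on the curve where growth has begun to saturate; on simulated logistic
curves with rate 0.4 h⁻¹ this underestimates by roughly 25 %. The default
(`method = "nonlinear"`) therefore fits the growth model itself by
nonlinear least squares in OD space, where the noise is homoscedastic: a
logistic $OD(t) = K/(1 + ((K - x_0)/x_0)e^{-rt})$ (start values from the
logit linearisation, a small multi-start ladder on $r$), falling back to a
pure exponential when the series shows no saturation to identify $K$. On
the same simulations this recovers the rate to within ~2 %, and on
noiseless exponentials it is exact to solver precision. The exponential
window (fitted curve below $K/4$) is still reported for audit. A culture
with no detectable growth yields `found = FALSE`, never an error.

Group comparison is one-way ANOVA (`stats::aov`) followed by Tukey's HSD,
with tiers at p < 0.05 (significant) and p < 0.01 (very significant);
all-identical input is reported as p = 1 rather than NaN.

## Synthetic data: what it does and does not emulate

`make_mm_chain()` builds linear influx/MM1 chains whose nodes have the
analytic steady state $S^* = k K_m/(V_{max} - k)$ (parameters drawn from
[1, 10], influx at half the smallest $V_{max}$), used to check the
integrator against closed forms. `make_growth_curves()` emits logistic
OD600 tables (72 h, readings every 30 min, start OD 0.05, carrying capacity
1.5) with i.i.d. Gaussian noise. All generators are pure functions of their
arguments and seed and leave the caller's RNG stream untouched.

What passing tests show: the numerics (integration, LP, estimation) are
correct on systems with known behaviour, and the network logic reproduces
the qualitative overexpression phenomenology. What they do not show:
agreement with measured rice metabolite concentrations (the shipped
parameters are synthetic); behaviour under regulation absent from the
model (see limitations); robustness to real plate-reader artefacts
(drift, lag phases, evaporation) that the growth-curve generator does not
emulate.

## Numerical choices and test problem sizes

* Solver tolerances rel `1e-8` / abs `1e-12` nmol/L; negative-excursion
  clamp at `1e-9` nmol/L.
* Plateau: trailing 10 % window, relative spread < `1e-3`.
* Peak ties break earliest; quadratic refinement only away from grid ends.
* LP: two-phase simplex, feasibility tolerance `1e-10`; equality rows with
  negative right-hand sides are sign-flipped for the solver.
* Oracle cross-checks run fixed-step RK4 (dt `1e-3` s) against the stiff
  solver on small networks over 10 s horizons, agreement within `1e-5`
  relative — short horizons keep the deliberately naive oracle fast while
  still covering the transient dynamics. Flux-balance solutions are checked
  against exhaustive vertex enumeration on networks of up to four
  reactions, and growth-rate recovery uses 100 simulated replicates.

## Known limitations

* No regulatory feedback: the THIC riboswitch (TDP-sensing control of THIC
  mRNA stability) and any product inhibition are not modelled, so the model
  overstates the benefit of flooding the pyrimidine branch under high TDP.
* No cooperativity (Hill), no inhibition terms, deterministic dynamics
  only.
* Compartment volumes are not modelled; transport rates absorb the
  geometry.
* The flux-balance objective and bounds are assumptions, prominently
  configurable but still assumptions.
* Tissue-level trafficking (source leaves to endosperm sink) is outside
  the model: it describes a single well-mixed cell.
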