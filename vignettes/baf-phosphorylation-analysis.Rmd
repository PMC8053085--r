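---
title: "Quantifying BAF phosphorylation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying BAF phosphorylation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bafphos)
```

## The biological problem

Barrier-to-autointegration factor (BAF) is an 89-residue, obligately
dimeric protein that cross-bridges double-stranded DNA and couples
chromatin to the nuclear envelope through the emerin LEM domain and the
lamin A/C Ig-fold domain. The vaccinia-related kinase 1 (VRK1)
phosphorylates BAF on two adjacent N-terminal residues — Ser4 first,
then Thr3 — and this di-phosphorylation collapses BAF's affinity for
dsDNA by three to four orders of magnitude while leaving its nuclear
envelope interactions intact. `bafphos` implements the quantitative
analyses behind that characterisation as a reusable, tested pipeline:

1. **Chemical-shift-perturbation (CSP) mapping** between two ¹H–¹⁵N
   HSQC peak lists (`compute_csp()`, `classify_csp()`,
   `fraction_shifted()`, `intensity_loss_filter()`).
2. **Real-time NMR phosphorylation kinetics**: deconvolution of the
   non-, mono- and di-phosphorylated species from time-resolved peak
   intensities and fitting of a consecutive two-step kinetic model
   (`species_fractions()`, `site_occupancy()`,
   `fit_consecutive_kinetics()`).
3. **¹⁵N relaxation**: mono-exponential R1/R2 fitting, heteronuclear
   nOe ratios, and classification of backbone dynamics
   (`fit_rate()`, `compute_noe()`, `classify_dynamics()`).
4. **Binding affinities**: hyperbolic saturation fluorescence fits,
   single-site ITC isotherm fits with thermodynamic decomposition,
   replicate aggregation and fold changes (`fit_saturation()`,
   `fit_itc_one_site()`, `aggregate_replicates()`, `fold_change()`).
5. **Synthetic data** with known ground truth for every input
   (`generate_kinetics_series()`, `generate_relaxation()`,
   `generate_binding()`).

No raw instrument data are consumed: inputs are picked, assigned peak
lists (Sparky-style text or CSV), tabulated intensities, titration
tables and injection heats.

## Chemical shift perturbation

For each backbone amide present in both states the combined
perturbation is

$$\Delta\delta = \sqrt{(\delta_{HN,A}-\delta_{HN,B})^2 +
  (\delta_{N,A}-\delta_{N,B})^2/25},$$

the standard weighting that compresses the ~5-fold wider ¹⁵N dispersion
onto the ¹H scale. Records are classified against ordered thresholds
(defaults 0.15, 0.5, 1.0, 2.0 ppm) with **strict** inequalities — a
residue sitting exactly on a threshold falls into the lower class,
matching the "larger than" wording these cut-offs come from.

Two deliberate conventions:

* Residues observed in state A but not in state B (typically exchange
  broadened at the measurement pH and temperature, as for BAF residues
  2–5) are classified `missing`, and `fraction_shifted()` excludes them
  from its denominator. Imputing 0 ppm for a residue whose peak
  *vanished* would systematically understate the perturbation.
* Side-chain NH peaks (the Trp84 indole is an important kinetics
  reporter) are carried with `atom_group = "sc"` and excluded from
  backbone summaries unless requested.

The summary criterion "half of the signals shift by more than
0.15 ppm" is taken to use the same combined formula; the package
applies one formula for all cut-offs.

Peak matching pairs assigned peaks by residue (assignments are trusted
over distance, since genuine perturbations can far exceed any matching
box), then greedily pairs unassigned query peaks to the nearest free
reference within a tolerance box, ranked by
$\sqrt{\Delta\delta_H^2 + (\Delta\delta_N/5)^2}$. Default tolerances
(0.05 ppm ¹H, 0.5 ppm ¹⁵N) are typical 700-MHz linewidths; no
instrument-specific value was available, and both are exposed as
arguments.

For ternary-complex mapping, `intensity_loss_filter()` flags residues
whose peaks lose more than 80% intensity (configurable) after partner
addition; peaks that disappear outright count as a loss of 1, and
zero-intensity reference peaks are skipped with a warning rather than
producing infinities.

## Consecutive phosphorylation kinetics

The reaction is modelled as irreversible and sequential,

$$\mathrm{BAF} \xrightarrow{k_1} \mathrm{BAF\text{-}pSer4}
  \xrightarrow{k_2} \mathrm{BAF\text{-}pSer4pThr3},$$

with closed-form fractions $f_A = e^{-k_1 t}$,
$f_B = \frac{k_1}{k_2-k_1}(e^{-k_1 t}-e^{-k_2 t})$,
$f_C = 1-f_A-f_B$. Pseudo-first-order kinetics are justified by the
catalytic kinase ratio used in the monitored reaction (0.1% molar
versus substrate), and no dephosphorylation term is included because
no phosphatase is present in vitro. Michaelis–Menten saturation and
the minor Thr2 site seen only in a T3A mutant are out of scope.

Numerical care at the degeneracy: the intermediate term is evaluated
as $k_1 e^{-k_1 t}\,(1-e^{-(k_2-k_1)t})/(k_2-k_1)$ via `expm1`, and
below a switch at $|k_1-k_2| < 10^{-6}\max(k_1,k_2)$ the analytic
limit $k_1 t e^{-k_1 t}$ with its first two series corrections in
$(k_2-k_1)t$ is used. The two branches agree to well below $10^{-8}$
at the switch, and $f_A+f_B+f_C = 1$ holds exactly on both branches.
The intermediate maximum has the closed form
$(k_2/k_1)^{k_2/(k_1-k_2)}$ (`intermediate_maximum()`), which the test
suite checks against numerical maximisation.

Species deconvolution (`species_fractions()`) follows the intensities
at each reporter residue's three peak positions, normalises the
triplet to its sum at each time point, and averages fractions over
residues **unweighted** (the source analysis averages over three
reporters without stating weights). A residue whose triplet is
entirely below detection at a time point is dropped from that time
point's average rather than contributing zeros.

`fit_consecutive_kinetics()` fits all three traces simultaneously by
least squares with the rates parameterised on the log scale (which
enforces positivity without active box constraints); standard errors
come from the linearised covariance by the delta method. The initial
unphosphorylated fraction is fixed at $a_0 = 1$ (reactions start from
unmodified protein). Because the dead time between kinase addition and
the first spectrum is unknown in general, an optional time offset `t0`
can be fitted (`fit_t0 = TRUE`); it defaults to 0.

Site-occupancy traces (`site_occupancy()`) are normalised to a plateau
defined as the mean of the **last two** time points of the di-phospho
traces — more robust than the final point alone. The transient
mono-pSer4 trace cannot be normalised to "its own" plateau (that
plateau is ~0 by construction); it is normalised to the di-pSer4
plateau, i.e. the same spin in the final species, whose intensity is
directly comparable. This is a convention choice: the original
percentages could equally have been anchored to a reference peak, and
nothing downstream depends on which is used beyond an overall scale.

## ¹⁵N relaxation and dynamics classes

R1 and R2 are obtained by nonlinear least squares of
$I(\tau)=I_0 e^{-R\tau}$ per residue, with replicates pooled as
repeated observations rather than pre-averaged, so the replicate
scatter propagates into the rate SE through the residual variance. A
log-linear regression provides starting values (and serves as the
independent oracle in the tests, where both must agree to $10^{-8}$
relative on noiseless data). The nOe is the mean over replicates of
the saturated/reference intensity ratio, with SE = SD/√n; values above
the ~1.1 theoretical ceiling trigger a warning. Only mono-exponential
decays are modelled — no CPMG dispersion analysis (refocusing
frequencies are not part of the inputs) and no model-free analysis.

`classify_dynamics()` operationalises the qualitative relaxation
signatures:

| class | rule (defaults) |
|---|---|
| `unobservable` | residue yields no cross-peak |
| `slow_exchange` | R2 > cohort mean + 2 SD |
| `fast_flexible` | R1 > cohort mean + 2 SD **and** nOe < 0.65 |
| `rigid` | nOe ≥ 0.75, no exceedance |
| `unclassified` | everything else |

in that precedence order. Cohort baselines use 10%-trimmed means and
SDs over observed residues so that the flexible tail does not inflate
its own detection threshold. The 2-SD exceedance and the 0.65/0.75
nOe cut-offs are this package's quantitative reading of qualitative
statements ("significantly increased", "mostly close to 0.8"); all
four numbers are arguments. A consequence worth knowing: under pure
measurement noise a 2-SD rule will flag ~2% of a genuinely
homogeneous cohort, so `slow_exchange`/`fast_flexible` calls in real
data should be read against replicate SEs, not as certainties.

## Binding models

**Fluorescence saturation.** The immobilised-DNA assay flows analyte
continuously over the chip, so the free concentration equals the total
and no depletion term is needed:
$S(c) = S_0 + (S_\mathrm{max}-S_0)\,c/(K_d+c)$, with $K_d$ fitted on
the log scale. The instrument's own fitting model is unpublished; the
hyperbola is an explicit assumption. Fits require ≥ 4 concentrations
spanning ≥ 1 decade; a fitted $K_d$ above the top concentration
triggers a poorly-constrained-plateau warning, and gross outliers
(>5 residual SDs) are rejected once with a warning.

**ITC.** `fit_itc_one_site()` fits the standard single-site Wiseman
isotherm: running cell/titrant concentrations with the
displaced-volume dilution correction, cumulative heat from the 1:1
binding quadratic, per-injection differences plus a constant
dilution-heat offset. Fitted parameters are $n$, $K_d$, $\Delta H$ and
the offset; the first injection is excluded by default (the classic
syringe-diffusion artifact) but can be kept. $\Delta G = RT\ln K_d$
(R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹) and $-T\Delta S = \Delta G - \Delta H$
are derived at the experiment temperature, so the thermodynamic
identity holds to machine precision by construction. A Wiseman
c-value $nM_0/K_d$ outside [1, 1000] flags the fit as unreliable
without suppressing it.

**Replicates.** `aggregate_replicates()` uses the arithmetic mean and
the *sample* (n−1) standard deviation — the only convention consistent
with published two-replicate SDs of the form $|x_1-x_2|/\sqrt2$ — and
leaves the SD undefined for single measurements. `fold_change()`
propagates relative standard errors of the two means in quadrature.
The packaged replicate table (`baf_affinity_replicates()`) ships the
printed values verbatim; one cell was printed with a missing exponent
sign ("3.00E09"), and since only 3.00E−09 reproduces its row mean, the
loader adopts that reading and flags the row. Dissociation constants
are reported in molar units throughout (the original table's caption
says M⁻¹, but the quantities are unambiguously Kd values in M).

## What the generators emulate — and what they do not

`generate_kinetics_series()` emits unassigned peaks at three
well-separated positions per reporter residue, intensities
proportional to the model fractions with **multiplicative lognormal
noise** (unit mean; peak heights are positive, so additive Gaussian
noise would be the wrong error model), a 2% detection floor that makes
near-baseline species drop out of the picked list, and optional
exchange-broadened residues that never appear. Defaults: reporters
Ala12, Gly27 and the Trp84 side chain; spectra every 30 min over 4 h;
k₁ = 10 h⁻¹ and k₂ = 1.4 h⁻¹. The default rates were chosen
analytically from the closed forms before any test was run, to realise
the qualitative milestones of the monitored reaction — the mono
species peaks at $(k_2/k_1)^{k_2/(k_1-k_2)} = 0.73$ near 0.23 h, most
molecules are mono-phosphorylated at 0.5 h ($f_B = 0.57$), and
di-phosphorylation passes 90% by 2 h ($f_C = 0.93$). They are stated
world, not fitted constants.

`generate_relaxation()` uses the published acquisition design as
defaults (R1: 10 delays over 10–1500 ms in triplicate; R2: 11 delays
over 18.5–185 ms in quadruplicate; nOe pairs in triplicate; 3%
intensity noise). `generate_binding()` evaluates the corresponding
forward model on the experimental schedule (two-fold dilution series
1.6–200 nM at 10 °C; or 25 × 10 µL injections of 100 µM titrant into
20 µM at 15 °C) with additive Gaussian noise.

What a green round-trip test establishes is that the estimators
recover the parameters of their own generating model at realistic
noise. It does **not** establish robustness to what real spectra add:
peak overlap and lineshape distortions, chemical-exchange broadening
during the reaction, baseline drifts in titrations, or heat spikes in
ITC. The generators share their forward models with the fitters by
design (that is what a closed loop means); independence in the test
suite comes from separate oracles — an RK4 integration of the rate
equations, log-linear regression for decays, hand-evaluated formulas,
and mass-balance checks on ITC heats.

A note on stochastic tolerances: at 2% signal noise on the 8-point
titration grid the Kd error distribution has a median near 12% but a
90th percentile near 35% (the grid carries only two points below Kd).
Stochastic recovery checks therefore assert the *median* error over a
fixed set of seeds rather than a single draw, mirroring how the
kinetics recovery criterion is phrased.

## Worked example

```{r example}
g <- generate_kinetics_series(kinetics_sim_spec(k1 = 2, k2 = 0.5,
                                                noise_cv = 0.02, seed = 42))
fr <- species_fractions(g$series, g$triplets)
fit_consecutive_kinetics(fr)
```

```{r binding}
sums <- baf_affinity_summaries()
sums[sums$ligand == "48 nt dsDNA", ]
reps <- baf_affinity_replicates(quiet = TRUE)
wt <- aggregate_replicates("BAF WT", "fluorescence", "48 nt dsDNA",
                           reps$kd_M[reps$label == "BAF WT" &
                                       reps$method == "fluorescence"])
pb <- aggregate_replicates("pBAF", "fluorescence", "48 nt dsDNA",
                           reps$kd_M[reps$label == "pBAF" &
                                       reps$method == "fluorescence"])
fold_change(pb, wt)
```

## Known limitations

* Intensities are taken as given; no peak-height interpolation or
  volume integration is attempted, and no frequency-domain data are
  touched.
* The dynamics classifier is a screening rule, not a model-free
  analysis; it reports classes, not order parameters or exchange
  rates.
* Single-site models only: no cooperativity, no multi-site binding,
  and the dsDNA length dependence of affinity is tabulated but not
  modelled.
* The consecutive model assumes a clean start from unmodified protein
  (`a0 = 1`); partially phosphorylated starting material would need
  the generalised initial condition, which is not implemented.
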