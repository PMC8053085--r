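# bafphos

Quantitative analysis of BAF phosphorylation by VRK1 from solution NMR
and binding data.

Barrier-to-autointegration factor (BAF) is an 89-residue dimeric
protein that cross-bridges double-stranded DNA and tethers chromatin to
the nuclear envelope via emerin and lamin A/C. The vaccinia-related
kinase 1 (VRK1) phosphorylates BAF sequentially — Ser4 first, then
Thr3 — which rigidifies the N-terminal region and collapses the DNA
affinity by ~3–4 orders of magnitude. `bafphos` packages the analyses
needed to characterise this system from tabulated instrument output
(picked peak lists, intensity tables, titrations, injection heats), for
NMR spectroscopists and biophysicists who want the number-crunching
reproducible and testable:

* **CSP mapping** — per-residue combined shift perturbation
  Δδ = √(Δδ_HN² + Δδ_N²/25), classified against ordered thresholds
  (0.15 / 0.5 / 1.0 / 2.0 ppm, strict inequalities), plus an
  intensity-loss filter (>80%) for complex-formation mapping.
* **Real-time phosphorylation kinetics** — species deconvolution from
  time-resolved HSQC peak intensities and weighted least-squares
  fitting of the consecutive first-order scheme
  A →(k₁) B →(k₂) C, with closed forms
  f_A = e^(−k₁t), f_B = k₁/(k₂−k₁)·(e^(−k₁t) − e^(−k₂t)),
  f_C = 1 − f_A − f_B.
* **¹⁵N relaxation** — mono-exponential R1/R2 fits with pooled
  replicates, heteronuclear nOe ratios, and rule-based backbone
  dynamics classes (rigid / fast_flexible / slow_exchange /
  unobservable).
* **Binding** — hyperbolic saturation fits (fluorescence on
  immobilised DNA, no depletion), single-site Wiseman ITC isotherms
  (n, K_d, ΔH, dilution offset; ΔG = RT ln K_d; −TΔS = ΔG − ΔH),
  replicate aggregation with sample SDs, and fold changes with
  propagated uncertainty. The published replicate K_d table ships as a
  fixture (`baf_affinity_replicates()`).
* **Synthetic data** — deterministic generators for every input with
  known ground truth, so each stage has closed-loop tests.

## Worked example

```r
library(bafphos)

# simulate a phosphorylation time course (HSQC spectra every 30 min,
# 2% intensity noise) and fit the consecutive model
g  <- generate_kinetics_series(kinetics_sim_spec(k1 = 2, k2 = 0.5,
                                                 noise_cv = 0.02, seed = 42))
fr <- species_fractions(g$series, g$triplets)
fit_consecutive_kinetics(fr)
#> <kinetic_fit> consecutive A -> B -> C
#>   k1 = 2.025 +/- 0.017 h^-1 (Ser4)
#>   k2 = 0.5002 +/- 0.0025 h^-1 (Thr3)
#>   RSS = 0.0007289 over 9 time points
```

The generating rates (2.0 and 0.5 h⁻¹) are recovered within ~1% here;
`k1` is the fast first phosphorylation of Ser4, `k2` the slower second
step on Thr3.

```r
reps <- baf_affinity_replicates(quiet = TRUE)
wt <- aggregate_replicates("BAF WT", "fluorescence", "48 nt dsDNA",
        reps$kd_M[reps$label == "BAF WT" & reps$method == "fluorescence"])
pb <- aggregate_replicates("pBAF", "fluorescence", "48 nt dsDNA",
        reps$kd_M[reps$label == "pBAF" & reps$method == "fluorescence"])
wt
#> <affinity_summary> BAF WT / fluorescence / 48 nt dsDNA: Kd = 2.54e-09 M (SD 1.05e-09, n = 5)
pb
#> <affinity_summary> pBAF / fluorescence / 48 nt dsDNA: Kd = 1.07e-05 M (SD 1.84e-06, n = 2)
fold_change(pb, wt)$ratio
#> [1] 4212.598
```

The mean affinities (2.54 nM unphosphorylated, 10.7 µM
di-phosphorylated) give the ~4×10³-fold affinity loss caused by
phosphorylation.

A thin CLI over the same functions lives at `inst/cli/bafphos`
(subcommands `csp`, `kinetics`, `relax`, `bind-fit`, `itc-fit`,
`bind-summary`, `simulate`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the pipeline end to end against the installed package: it
aggregates the shipped replicate affinity table and reports the
phosphorylation fold change, maps CSPs on a synthetic state pair,
simulates and refits a phosphorylation time course, fits and
classifies a planted relaxation cohort, and closes the
fluorescence/ITC round trips, writing the JSON result file to the
path given by `--out`. All randomness derives from `--seed`.

## Package layout

```
R/                 implementation (peak lists, series, CSP, kinetics,
                   relaxation, binding, affinity table, simulators)
inst/extdata/      published replicate Kd table (CSV)
inst/cli/bafphos   command-line wrapper
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (models, conventions, limitations)
scripts/           acceptance script
```

The methods vignette
(`vignettes/baf-phosphorylation-analysis.Rmd`) documents the models,
every tunable default and the reasoning behind the package's
conventions.
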