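# emsacoop

Quantitative analysis of EMSA (electrophoretic mobility shift assay)
titrations of a DNA probe carrying **two** protein binding sites — the
design used to measure whether two Notch transcription complexes load
cooperatively onto a sequence-paired site (SPS) or independently onto
tandem CSL sites. It is written for anyone who has densitometry values
for the free-probe, single-shift and supershift bands of a titration
ladder and wants dissociation constants and a cooperativity estimate
with honest uncertainty.

## The model

A lane at complex concentration `[NTC]` is summarized by the statistical
weight `α = [NTC]/Kd`. The probabilities that a probe carries 0, 1 or 2
complexes follow the two-site binding polynomial `1 + 2α + Cα²`:

    P0 = 1/(1+2α+Cα²),  P1 = 2α/(1+2α+Cα²),  P2 = Cα²/(1+2α+Cα²)

where the cooperativity factor `C` rescales the second-site affinity
(`Kd,2nd = Kd/C`; `C = 1` independent sites, `C > 1` positive
cooperativity). Because the single-shift band persists at saturating
protein, a fraction `1 − f` of probes is modelled as able to bind only
one complex, giving the mixture used for fitting:

    P0 = f/(1+2α+Cα²) + (1−f)/(1+2α)
    P1 = 2αf/(1+2α+Cα²) + 2α(1−f)/(1+2α)
    P2 = Cα²f/(1+2α+Cα²)

`(Kd, C, f)` are estimated by bounded multistart nonlinear least squares
on the normalized band fractions; uncertainty comes from a percentile
bootstrap (default 5,000 resamples, 95%) that redraws every
(concentration, band) cell from its replicate mean and SD. A
synthetic-data generator reproduces the titration design (4-fold ladder
2.5–640 nM, replicate lanes, fraction-scale Gaussian noise) so the whole
pipeline is testable without laboratory data.

## Worked example

```r
library(emsacoop)

lanes <- simulate_titration(preset_scenarios()$wt_sps)  # cooperative preset
fit   <- fit_titration(lanes)
fit
#> <emsa_fit> condition: wt_sps
#>   Kd = 43.39 nM, C = 5.624 (second-site Kd = 7.715 nM), f = 0.8434
#>   SSR = 0.01007 over 45 residuals; converged: TRUE; starts: 24

boot <- bootstrap_titration(fit, n_boot = 500, seed = 7)
tidy(boot)
#> # A tibble: 3 × 4
#>   term  estimate  lower  upper
#>   <chr>    <dbl>  <dbl>  <dbl>
#> 1 kd_nM   43.4   40.9   46.5
#> 2 C        5.62   5.09   6.23
#> 3 f        0.843  0.830  0.855
```

The simulated wild-type/SPS condition (true `Kd = 40` nM, `C = 5`,
`f = 0.85`, noise SD 0.02 on fractions) is recovered as `Kd ≈ 43` nM and
`C ≈ 5.6` — a roughly 5-fold tighter second site (`Kd,2nd ≈ 7.7` nM) —
with a 95% bootstrap interval for `C` well above 1, i.e. clearly
cooperative. `autoplot(fit)` draws the observed and fitted mean
sites-filled curve; `run_simulate()`, `run_fit()`, `run_bootstrap()`
and `run_report()` drive the same steps from a config list or file, and
`inst/cli/emsacoop.R` exposes them as a command line.

Real gel tables enter through `read_titration()` (CSV with columns
`condition, conc_nM, replicate, band0, band1, band2`) or
`read_titration_xlsx()` for spreadsheet exports.

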