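---
title: "Quantifying binding cooperativity from EMSA titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying binding cooperativity from EMSA titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsacoop)
library(dplyr)
```

## The measurement and the model

An electrophoretic mobility shift assay (EMSA) titrates a fixed, small
amount of fluorescent DNA probe against increasing concentrations of a
DNA-binding protein complex. A probe carrying two binding sites runs as
three bands: free probe, a single shift (one complex bound) and a
supershift (two complexes bound). Densitometry of each lane gives three
intensities whose normalized fractions estimate the probabilities that a
probe carries 0, 1 or 2 complexes at that concentration.

In the Notch pathway this design distinguishes *cooperative* loading of
two Notch transcription complexes (NTCs) onto a sequence-paired site
(SPS) from independent loading onto two tandem CSL sites. The package
models a lane at complex concentration $[\mathrm{NTC}]$ through the
statistical weight $\alpha = [\mathrm{NTC}]/K_d$, where $K_d$ is the
single-site dissociation constant. The four microstates of a two-site
probe (empty, either single site, both) carry Boltzmann weights
$\{1, \alpha, \alpha, C\alpha^2\}$, so

$$P_0 = \frac{1}{1+2\alpha+C\alpha^2},\qquad
  P_1 = \frac{2\alpha}{1+2\alpha+C\alpha^2},\qquad
  P_2 = \frac{C\alpha^2}{1+2\alpha+C\alpha^2}.$$

The cooperativity factor $C$ rescales the second-site dissociation
constant, $K_{d,2} = K_d / C$: $C = 1$ is independent binding, $C > 1$
positive cooperativity, $C < 1$ negative.

Because the single-shift band is never depleted even at saturating
protein, a fraction $1-f$ of probes is allowed to bind at most one
complex (a one-site species with polynomial $1 + 2\alpha$):

$$P_0 = \frac{f}{1+2\alpha+C\alpha^2} + \frac{1-f}{1+2\alpha},\quad
  P_1 = \frac{2\alpha f}{1+2\alpha+C\alpha^2} +
        \frac{2\alpha(1-f)}{1+2\alpha},\quad
  P_2 = \frac{C\alpha^2 f}{1+2\alpha+C\alpha^2}.$$

The three fitted parameters are $K_d$ (nM), $C$ (dimensionless) and
$f \in [0,1]$. The mean number of sites filled, $P_1 + 2P_2$, rises
monotonically with concentration and saturates at $1 + f$.

```{r occupancy-curve, fig.width = 5, fig.height = 3.5}
library(ggplot2)
curve <- tidyr::expand_grid(C = c(1, 5), conc = 10^seq(-0.5, 3.5, 0.05)) |>
  mutate(filled = purrr::map2_dbl(conc, C,
                                  ~ mean_sites_filled(.x / 40, .y, 0.85)))
ggplot(curve, aes(conc, filled, colour = factor(C))) +
  geom_line() + scale_x_log10() +
  labs(x = "complex (nM)", y = "mean sites filled", colour = "C") +
  theme_minimal()
```

### Assumptions worth stating

* **Equilibrium, nominal concentrations.** $\alpha$ uses the nominal
  titrated protein concentration; no free/total or ligand-depletion
  correction is applied, even though the probe (1.75 nM in the standard
  design) is comparable to the lowest titration point (2.5 nM). The
  uncorrected model is the one fitted throughout; users needing a
  depletion correction must apply it upstream.
* **Three probe states.** The free, single-shift and supershift bands
  map onto the 0-, 1- and 2-complex states. Gels containing additional
  species must be pre-aggregated into these three classes before import.
* **Per-lane normalization.** Fractions are each lane's band intensities
  divided by their three-band sum (probe conservation within a lane); no
  cross-lane loading correction. All downstream statistics live on this
  fraction scale.
* **Units.** All concentrations are nM everywhere.

## Fitting

`fit_titration()` minimizes the unweighted sum of squared residuals
between observed and predicted fractions, pooled over all lanes and all
three bands (each lane contributes three residuals; replicate lanes
enter as separate points, switchable to replicate means with
`use_means = TRUE`; inverse-variance weighting by replicate SD is
available with `weighted = TRUE` but off by default, since the
replicate SDs from three lanes are too noisy to be reliable weights).

Numerical choices:

* **Parameterization.** The optimizer works on
  $(\log_{10} K_d, \log_{10} C, f)$, which conditions the search across
  the ladder's dynamic range, with box bounds
  $K_d \in [10^{-3}, 10^{6}]$ nM, $C \in [10^{-3}, 10^{3}]$,
  $f \in [0, 1]$, via Levenberg–Marquardt (`minpack.lm::nls.lm`).
* **Multistart.** A fixed deterministic start grid: $K_d$ at every
  decade spanned by the ladder, $C \in \{0.1, 1, 10\}$,
  $f \in \{0.5, 0.9\}$ (24 starts on the standard ladder). The best
  final SSR wins; numerical ties break toward the $C$ closest to 1, the
  conservative no-cooperativity reading. Identical inputs always give
  identical fits.
* **Diagnostics.** Estimates within $10^{-6}$ (transformed scale) of a
  box bound are flagged in `at_bound`; `converged` records the
  optimizer's own status. A design with fewer than 3 distinct
  concentrations cannot constrain 3 parameters and is rejected as
  unidentifiable rather than fitted.
* **Degenerate inputs.** All-zero lanes are rejected at validation with
  their row numbers; $\alpha = 0$ returns exactly $(1,0,0)$ without
  forming $C\alpha^2$, so extreme $C$ cannot produce 0/0.

`grid_oracle()` brute-forces the SSR on a finite
$(\log K_d, \log C, f)$ grid. It exists to *check* the optimizer — its
argmin SSR is an upper bound the fit must beat — and is not an
estimator.

## Bootstrap confidence intervals

Uncertainty follows a parametric percentile bootstrap: for each
(concentration, band) cell, the replicate mean and SD of the normalized
fractions are taken as a Gaussian, synthetic lanes are drawn with the
observed lane structure, truncated at zero and renormalized per lane,
and the model is refit to each of the `n_boot` resamples (default
5,000); the 95% interval (default) is the 2.5–97.5 percentile range of
the resampled estimates. Design choices, since "same mean and SD" leaves
them open:

* Noise is independent across cells and Gaussian — the minimal reading;
  the mean/SD are taken on the *normalized-fraction* scale, the same
  scale the fit consumes, so simulation, fitting and resampling are
  mutually consistent.
* Lanes are renormalized after resampling, keeping every synthetic lane
  a valid composition.
* Refits start from the point estimate (the resampled objective is a
  small perturbation of the original, so the full multistart grid is
  ~20× the cost for no observed change in the intervals;
  `refit_multistart = TRUE` restores it).
* One master seed; resample $i$ gets the derived seed
  $(s + 1000003\,i) \bmod (2^{31}-1)$, so enlarging `n_boot` extends the
  resample sequence instead of reshuffling it.
* A summary built from single replicates has no estimable SD; the
  resampler refuses it unless an explicit `sd_override` is given.

With three replicates the cell SDs are themselves noisy and biased low
(the sample SD of $n=3$ Gaussian draws underestimates $\sigma$ by
~11% on average), so the intervals tend to run slightly narrow and
empirical coverage sits a little below nominal. The coverage simulation
below quantifies this; it is a property of the published resampling
protocol, not of its implementation here.

## The synthetic-data generator

`simulate_titration()` emulates the assay's statistical structure: a
geometric concentration ladder (`make_ladder(2.5, 4, 5)` reproduces the
standard 4-fold design from 2.5 to 640 nM), `n_reps` replicate lanes per
concentration, mixture-model fractions plus independent Gaussian noise
(SD `noise_sd`) on the fraction scale, truncation at zero, per-lane
renormalization, and a constant lane total of 10,000 arbitrary units so
raw and normalized representations interconvert exactly.

The four `preset_scenarios()` mirror the assay conditions: a cooperative
wild-type complex on the paired-site probe (`wt_sps`, $C = 5$), the
dimerization-deficient point mutant on the same probe (`ra_sps`,
$C = 1$), and both complexes on the tandem two-site probe (`wt_2xcsl`,
`ra_2xcsl`, $C = 1$). The presets share $K_d = 40$ nM — mid-ladder,
where the titration is maximally informative — $f = 0.85$, consistent
with a persistent single-shift band, and noise SD 0.02, a realistic
densitometry repeatability for clean gels. These are synthetic defaults
chosen once for identifiability; the laboratory $K_d$ and $f$ are not
published values and the presets do not claim to be them.

What the generator does *not* emulate: gel-image artifacts (smearing,
background, saturation), lane-to-lane loading variation, correlated
densitometry errors between neighbouring bands, or probe depletion at
low protein. Passing recovery and coverage tests therefore demonstrate
correctness of the estimator under the model's own noise assumptions,
not robustness to every failure mode of real gels.

## Validation performed by the test suite

All empirical statements below are computed by `tests/testthat/` and
`scripts/acceptance.R` at run time; problem sizes were fixed in advance
as the package's validation design.

* **Microstate oracle.** Occupancies agree to $10^{-12}$ with an
  independent enumeration of Boltzmann weights over the four
  microstates; $10^6$ random parameter draws normalize to 1 within
  $10^{-10}$.
* **Optimizer vs brute force.** On 20 random synthetic series the fitted
  SSR never exceeds the best point of a $40\times40\times20$ grid over
  $(\log K_d, \log C, f)$ by more than $10^{-9}$.
* **Recovery.** Over 200 synthetic titrations ($K_d$ log-uniform
  10–160 nM, $C \in \{1, 5\}$, $f \in [0.6, 1]$, noise SD 0.02, standard
  ladder, 3 replicates) the median relative error of $\hat C$ is below
  15% and the $\hat C$ distributions for $C=1$ vs $C=5$ have disjoint
  interquartile ranges.
* **Coverage.** 500 synthetic datasets with 200 resamples each at
  nominal 95% measure the empirical coverage of $C$; see the caveat
  above on narrow intervals from 3-replicate SDs.

One check requires data the package cannot ship: refitting the original
laboratory band intensities. Users with the supplementary workbook can
convert it to the CSV lane schema, place per-condition files under
`inst/extdata/s1_data/`, and the acceptance suite will fit them and
check the headline cooperativity ($\hat C$ rounding to 5 for the
wild-type/SPS condition, bootstrap CIs for $C$ covering 1 elsewhere).

## Limitations

* Exactly two sites, one shared $K_d$; no $n > 2$ generalization, no
  heterogeneous per-site affinities, no kinetics.
* Percentile intervals only; no profile likelihood or posterior.
* The no-cooperativity call reported by `run_fit()`
  ($\hat C \in [0.8, 1.25]$ by default, printed alongside the call) is a
  descriptive band, not a hypothesis test.
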