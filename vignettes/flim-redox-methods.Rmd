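---
title: "Quantifying yeast redox state from NAD(P)H fluorescence lifetimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying yeast redox state from NAD(P)H fluorescence lifetimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(flimredox)
library(dplyr)
```

## The measurement and the model

NAD(P)H autofluorescence decays bi-exponentially: free NAD(P)H relaxes fast
(τ~free~ ≈ 0.4 ns) while protein-bound NAD(P)H relaxes slowly (τ~bound~
typically 1–4 ns, depending on the binding partner). A time-correlated
single-photon counting (TCSPC) acquisition histograms photon arrival times
after each laser pulse; per region of interest (ROI, here one cell) the
pooled histogram is modelled as

$$ I(t) \;=\; A\,\big[a_1 e^{-t/\tau_{free}} + a_2 e^{-t/\tau_{bound}}\big]
   \circledast \mathrm{IRF}(t) \;+\; b, \qquad a_1 + a_2 = 1, $$

where $a_1$ and $a_2$ are the amplitude fractions of the free and bound
pools, IRF is the instrument response, and $b$ a flat background. The
per-cell redox readout is the amplitude-weighted mean lifetime

$$ \tau_{mean} = a_1\,\tau_{free} + a_2\,\tau_{bound}, $$

which lengthens — and $a_1/a_2$ falls — as the NAD(P)H pool becomes more
oxidized. The companion chemical readout is the NAD(P)H/NAD(P)⁺
concentration ratio (`compute_redox_ratios()`), which decreases under
oxidative stress.

Because no raw image data are available for this analysis, the package pairs
the estimator with a fully specified TCSPC simulator, so that every stage —
model, fit, segmentation, statistics — is testable against known ground
truth, and published summary statistics can be turned into generative
parameters whose recovery the pipeline must demonstrate.

## The decay model and its numerics

`model_decay_curve()` evaluates the convolution of each exponential
component with a Gaussian IRF in closed form (the exponentially modified
Gaussian), computed on the log scale so small lifetimes cannot overflow the
$e^{\sigma^2/2\tau^2}$ prefactor, and wraps it over the laser repetition
period (circular convolution) by summing a dozen prior pulses — exact to
double precision since $e^{-P/\tau} \le e^{-12.5/6} \approx 0.12$ decays
geometrically across terms. There is no pile-up or afterpulsing model: at
the simulated count rates and $\tau \ll P$ these are negligible by
construction, and real-data corrections of that kind belong upstream of this
package.

Amplitudes, not areas: the mixture weights $a_1, a_2$ multiply the
*pre-exponential* amplitudes, so the photon (area) fraction of the free
component is $a_1\tau_{free} / (a_1\tau_{free} + a_2\tau_{bound})$ — for the
*K. marxianus* parameters only ≈ 23% of photons, even though $a_1 = 0.69$ of
molecules, which is why high photon budgets are needed to pin $a_1$.

Acquisition defaults (`acquisition_config()`): 80 MHz repetition (12.5 ns
period), 250 bins × 50 ps, Gaussian IRF of 150 ps FWHM centred at 1.0 ns,
background 0.02 counts/bin/pixel — typical commercial two-photon TCSPC
settings; all overridable.

## The simulator as a study-condition generator

`cell_preset()` describes a cell population: per cell,
$a_1 \sim N(a_{1,\mathrm{mean}}, a_{1,\mathrm{sd}})$ clipped to (0.01, 0.99)
and $\tau_{bound} \sim N(\cdot)$ clipped to (0.5, 6.0) ns. The built-in
species presets invert the published summaries: from the reported
$a_1/a_2 = r$, $a_1 = r/(1+r)$; from the reported $\tau_{mean}$,
$\tau_{bound} = (\tau_{mean} - a_1 \tau_{free})/(1 - a_1)$:

```{r presets}
species_preset("kmarxianus")
species_preset("scerevisiae")
```

Per-cell $\tau_{bound}$ is drawn from a normal truncated to the
physiological bound-lifetime range [1.2, 6.0] ns by resampling, with the
location shifted so the truncated mean still equals the derived
$\tau_{bound}$ mean. Two things motivated the truncation, both found during
the one-time calibration simulations. Biologically, protein-bound NAD(P)H
does not relax at near-free lifetimes, and the generator is meant to emulate
a 1–4 ns bound pool. Statistically, cells whose true $\tau_{bound}$
approaches $\tau_{free}$ make the amplitude split unidentifiable: with the
free lifetime fixed at 0.4 ns and the background free, the fit then rides a
likelihood ridge and inflates $a_1$ (measured: $\hat a_1 \approx 0.93$ for a
true 0.77 at $\tau_{bound} = 1.0$ ns), and a single such cell's
$a_1/a_2$ can exceed 100 and dominate a 100-cell mean. A hard clip — the
obvious alternative — piles an atom of cells exactly at the boundary and
makes that failure mode routine.

The between-cell SDs are constrained only through the SD of $\tau_{mean}$
(0.27 and 0.19 ns for the two species); that one constraint does not fix the
split between variability in $a_1$ and in $\tau_{bound}$. The split was
calibrated once by simulation (100 fitted ROIs × 3 seeds per candidate,
seeds disjoint from the test suite's) and frozen:
$a_{1,\mathrm{sd}} = 0.02$ (0.01 for *S. cerevisiae*) and
$\tau_{bound,\mathrm{sd}} = 0.85$ (0.835) ns. The split leans on
$\tau_{bound}$ because $a_1/(1-a_1)$ is convex: population spread in $a_1$
inflates the mean per-cell $a_1/a_2$ above the published value it must
round-trip to (by ≈ $\sigma_{a_1}^2/(1-a_1)^3$), whereas $\tau_{bound}$
spread leaves it untouched.

For conditions where only mean ± SD of $\tau_{mean}$ was published (30 °C /
45 °C, H₂O₂, and the heterologous-protein strains), presets carry a target
$\tau_{mean}$ distribution with a nominal $a_{1,\mathrm{mean}} = 0.70$, and
each cell's $\tau_{bound}$ is solved from its drawn $\tau_{mean}$; those
$a_1$ values are invented plumbing and are documented as such. The day-1
empty-vector control of the low-expression strain has no published
$\tau_{mean}$ at all; its preset (1.02 ± 0.10 ns) is a synthetic stand-in.

`simulate_field()` renders elliptical cells (semi-axes 5–9 px by default) on
a dark background, spreads each cell's photon budget (default 5×10⁴, enough
for < 2% relative error on $\tau_{mean}$ per pooled ROI) over its footprint
with a centre-bright radial profile, and draws every pixel × bin count as
Poisson. Cells are placed by rejection sampling with a 1.5 px clearance
margin so footprints never touch — without the margin, adjacent cells merge
under 8-connected labelling, which is a segmentation property, not a
biological one. What the simulator deliberately does **not** emulate:
vacuoles and internal lifetime structure, out-of-focus light, detector
afterpulsing and pile-up, spatial IRF variation, and touching/budding cells.
Passing tests therefore demonstrate estimator correctness under the stated
noise model, not robustness to every real-microscope artefact.

## Fitting

`fit_biexponential()` maximizes the Poisson likelihood (correct at low
counts, unlike unweighted least squares) over $(\mathrm{logit}\,a_1,
\log\tau_{bound}, \log A, \log b)$ with L-BFGS-B, $\tau_{bound}$ bounded in
[0.5, 6.0] ns — the physiological 1–4 ns range widened for robustness.
$\tau_{free}$ is fixed at 0.4 ns by default (the standard choice for
NAD(P)H) and can be freed. Initialisation: $a_1 = 0.7$, $\tau_{bound} =
2.5$ ns, amplitude = total counts; one restart from a coarse grid-search
optimum on non-convergence. Background is fitted, not fixed, since real
instruments drift. Components are reported in canonical order (component 1 =
shorter lifetime), so relabelling the generative components never changes
the result. Goodness of fit is the Pearson reduced χ² over bins with
positive expectation, df = usable bins − free parameters. Histograms under
500 photons are rejected outright rather than fitted: ROI pooling (all
photons of a cell in one histogram, the design choice here, matching
one-lifetime-per-cell reporting) makes this floor easy to clear.

Two independent checks guard the optimizer. `fit_gridsearch_oracle()`
exhaustively scores $a_1 \in \{0, 0.01, \ldots, 1\} \times \tau_{bound} \in
\{0.5, 0.52, \ldots, 6.0\}$ ns with the amplitude profiled analytically —
transparent, assumption-free, and required to agree with the MLE within the
grid resolution. `phasor_transform()` maps a histogram to its first Fourier
coefficients $(g, s)$ with IRF-phase correction; mono-exponential decays
must land on the universal semicircle $g^2 + s^2 = g$. One caveat
discovered while specifying the tests: the *phase* lifetime $s/(g\omega)$
of a mixture is a $g$-weighted mean of component lifetimes, which for a
strongly bi-exponential NAD(P)H decay differs from the intensity-weighted
mean by tens of percent as a matter of algebra; the phasor-vs-fit
consistency check is therefore asserted on (near-)mono-exponential decays,
where the two coincide.

```{r fit-example}
h <- simulate_histogram(model_decay_curve(0.690, 0.4, 3.02), 5e4,
                        background = 4, seed = 7)
fit <- fit_biexponential(h, fix_tau_free = 0.4)
generics::tidy(fit)
```

## Segmentation and lifetime maps

`segment_cells()` thresholds the total-intensity image with Otsu's method,
labels 8-connected components (deterministically, in raster order of first
pixels), and discards components outside 30–5000 px or touching the border.
Hand-drawn ROI selection is replaced by this reproducible rule; a label
matrix can also be supplied directly to `pool_roi_histogram()` for manual
masks. Touching cells merge — no watershed splitting — and whole-component
masks are used (no vacuole exclusion). `render_lifetime_map()` colours each
cell by its fitted $\tau_{mean}$ through a fixed 256-entry
blue→green→yellow→red ramp over 1.5–4.0 ns (clamped), the conventional
display range for NAD(P)H FLIM.

## Group statistics

`choose_and_run_test()` encodes the test-selection rule: Shapiro–Wilk
normality per group at α = 0.05; if either rejects (or a group is constant),
a two-sided Mann–Whitney U — exact by full enumeration of labelings when the
pooled sample is ≤ 20 (with midrank ties; this is what makes
identical-sample comparisons return exactly p = 1), normal approximation
with tie and continuity correction otherwise; if both pass, median-centred
Levene at α = 0.05 decides between the pooled-variance t-test and Welch's
t-test. All tests are two-sided; the normality/homogeneity procedures are
conventional choices, since only the rule structure, not the exact
procedures, is documented for the original analysis. Significance labels
follow the GraphPad convention (ns > 0.05 ≥ \* > 0.01 ≥ \*\* …). No
multiple-testing correction is applied, matching the unadjusted pairwise
reporting this reproduces. Group summaries are mean ± sample SD (n − 1) over
converged fits, and $a_1/a_2$ is the mean of per-cell ratios — not the ratio
of means — consistent with per-cell violin summaries; for skewed per-cell
ratios the two differ, which is why the convention is pinned down here.

The NAD(P)H/NAD(P)⁺ ratio from the chemical arm is computed per replicate as
the pooled sum $(\mathrm{NADH} + \mathrm{NADPH}) / (\mathrm{NAD}^+ +
\mathrm{NADP}^+)$; whether the original combined ratio pooled sums or
averaged the two pair ratios is not stated, so the alternative is exposed as
`combined = "mean_of_ratios"`.

## The pipeline and the reproduction suite

`run_experiment()` chains simulate → segment → fit → compare for two
conditions under one seed (all draws from a single stream in documented
order), writing per-cell CSVs, comparison JSON, lifetime-map PNGs and a
manifest with per-file checksums; the manifest is written on failure too.
Identical config + seed reproduces every CSV/JSON byte-for-byte.

`reproduce_paper_suite()` runs the five published two-group experiments at
the published group sizes (101 vs 52; 68 vs 112; 66 vs 69; day-1
94/105/104/78; day-3 91/79/96/102) and tabulates recovered mean ± SD
lifetimes and significance labels next to the published values. Problem
sizes throughout (100-ROI recovery runs, 50-repetition significance
medians, 1000-repetition type-I-error check, ~20-cell unit-test fields)
were chosen as the smallest sizes at which the Monte-Carlo error is well
inside each tolerance.

## Known limitations

* The simulator's noise model is idealized (see above); recovery results
  bound estimator error, not end-to-end microscope accuracy.
* $a_1$ values for the stress/strain presets are nominal, since only
  $\tau_{mean}$ summaries were published for those conditions; their
  $a_1/a_2$ comparisons are internally consistent but not anchored to
  published numbers.
* The exact Mann–Whitney enumeration is $\binom{n}{n_1}$ and is capped at a
  pooled n of 20; beyond that the corrected normal approximation is used.
* Per-pixel fitting, triple-exponential models, global fitting across ROIs,
  and time-series tracking are out of scope.
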