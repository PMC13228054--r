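---
title: "Quantifying macrocolony structure and mutation supply with macromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macrocolony structure and mutation supply with macromorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macromorph)
```

# Scope

`macromorph` quantifies two complementary aspects of bacterial phenotypic
diversification on solid media: the *spatial structure* of macrocolony
biofilms (wrinkling, surface relief) read from stereomicroscope images, and
the *mutation supply* of strains measured by rifampicin fluctuation assays.
It also handles two small companion analyses — fluorescence competition
assays with monoculture normalization, and descriptive tallies of
peripheral-outgrowth screens — and ships seeded synthetic-data generators
so that every stage can be validated against known ground truth without any
raw images or plate counts.

# Image analysis: the normalized pair-correlation function

Macrocolony photographs are split into channels (the green channel carries
the most structural contrast in practice), background-subtracted, and
reduced to a table of non-background pixels `(x, y, I)`. The structural
summary is the normalized radial pair-correlation

$$\gamma(r) \;=\; \frac{\langle I(x)\,I(y)\rangle_{|x-y| \approx r}}
                       {\langle I^2 \rangle},$$

the average product of intensities of pixel pairs at distance $r$, divided
by the average squared intensity. Distances are Euclidean in pixel units and
binned with width $\Delta r$ (default 1 px); bin 0 holds exactly the
self-pairs, so $\gamma(0) = 1$ identically. Cross pairs are assigned to bin
$\max(1, \lfloor d/\Delta r \rfloor)$ — the `max` clause only matters for
$\Delta r > 1$, where the floor rule alone would let distance-1 pairs
contaminate the self-pair bin and break the $\gamma(0)=1$ guarantee.
Unordered pairs are counted once; the default maximum distance is half the
diameter of the pixel cloud's bounding box.

Two implementations share this contract. `pair_correlation_bruteforce()`
enumerates every pair and is the reference definition (above 20,000 pixels
it falls back to seeded uniform pair subsampling unless forced exhaustive —
the exact path is $O(N^2)$). `pair_correlation_fft()` obtains the per-bin
pair sums from the zero-padded autocorrelation of the masked intensity
field, and the per-bin pair counts from the autocorrelation of the binary
mask; it is exact, fast at full-image scale, and is required to agree with
the brute force to $10^{-9}$ in the test suite. Bin 0 of the FFT path is
filled analytically from $\sum I^2$ so that $\gamma(0) = 1$ holds to the
last bit rather than to FFT roundoff.

## Centering

As written above, $\gamma$ does **not** subtract the mean intensity. For a
spatially uncorrelated field with mean $\bar{I}$ the uncentered $\gamma(r)$
therefore settles at $\bar{I}^2/\langle I^2\rangle$ for $r > 0$ — not at
zero. The familiar reading "random images decay rapidly to zero" only holds
for (near-)mean-zero fields. Both variants are provided: `centered = FALSE`
is the literal definition and the default; `centered = TRUE` replaces $I$ by
$I - \bar I$ and the normalizer by the variance, and is required by
`correlation_summary()`, whose decay interpretation needs a zero baseline.
The package asserts the uncentered plateau on fixtures rather than hiding
the distinction.

## Decay and oscillation summaries

`correlation_summary()` reduces a centered curve to three numbers: the
correlation length (smallest binned $r$ with $\gamma < 1/e$), the
oscillation period ($r$ of the first local maximum after the first local
minimum, after a 3-point running mean; `NA` when no rebound reaches the
amplitude threshold, default 0.05), and the amplitude at that maximum.
Structured, wrinkled colonies give long correlation lengths and a clear
oscillation; unstructured noise gives a correlation length of one bin and
no oscillation.

One geometric subtlety, visible in the validation suite: for a concentric
sinusoidal relief of wavelength $\lambda$, pairs at separation $r$ average
the phase difference over orientations, so the centered correlation follows
a Bessel-like profile whose first rebound maximum sits near $1.12\lambda$
rather than $\lambda$ exactly. The period estimate for a 20 px wavelength
is consequently ~22 px — within the 10% recovery band the package promises,
and a bias worth remembering when comparing absolute wavelengths between
instruments.

# Surface metrology

Pixel intensity is treated as a height proxy (`z = calibration * I`,
brighter = more protruding). Over the colony mask the package reports the
standard areal texture statistics — Ra, Rq, skewness Rsk, kurtosis Rku,
peak-to-valley Rt — and a surface-area ratio SA: each fully-masked 2x2
pixel block is split along a fixed diagonal into two triangles lifted to
their pixel heights, and SA is developed area over projected area (flat
field: exactly 1). On a flat field the dimensionless moments are undefined
and flagged rather than returned as NaN. The intensity-to-height
calibration is a user-supplied scalar with default 1: published Rt values
in millimetres require the original instrument calibration, which is why
absolute agreement with published surface numbers is out of scope while
scaling behaviour (amplitudes linear in calibration, dimensionless metrics
invariant) is fully tested.

# Fluctuation analysis

The mutation-supply model is the classical Lea-Coulson formulation of the
Luria-Delbruck distribution: mutations arise as a Poisson process with mean
$m$ per culture, and each mutation founds a resistant clone whose final
size follows $P(J = j) = 1/(j(j+1))$ (constant mutant fitness, full
plating). The pmf is computed by the exact compound-Poisson recursion

$$p_0 = e^{-m}, \qquad
  p_n = \frac{m}{n} \sum_{j=1}^{n} \frac{p_{n-j}}{j+1},$$

implemented in C++ because it sits inside the likelihood optimizer's inner
loop. The forward simulator draws clone sizes as $\lfloor 1/U \rfloor$,
$U \sim \mathrm{U}(0,1)$ — exact for this law since
$P(J \ge k) = 1/k$ — truncated at the final population size $N_t$; the
simulator and the analytic pmf are cross-checked against each other by
chi-square goodness of fit, which is the package's oracle-equivalence
anchor for everything downstream.

`fit_mutation_rate()` maximizes the count likelihood over $\log m$
(derivative-free bracketed optimization started from the zero-class
estimator $-\log \hat p_0$ when defined, else a fixed-point pass on the
median relation), converts to a per-cell rate $\hat\mu = \hat m / N_t$ with
$N_t$ the mean final population size, and profiles the likelihood for a 95%
interval ($\chi^2_1$ drop). Counts above a cap (default $10^4$) are pooled
into a single tail category with probability $1 - \sum_{n \le cap} p_n$:
jackpot cultures then contribute through the tail mass instead of forcing
an enormous pmf support, without discarding or winsorizing them. Mutant
fitness, phenotypic lag, death, and partial plating are deliberately not
modelled — the estimates are interpretable exactly under the constant-
fitness, full-plating assumptions stated above.

`lrt_mutation_rate()` compares two strains: the null model drives both
experiments with one per-cell rate ($m_A = \mu N_{t,A}$,
$m_B = \mu N_{t,B}$), the alternative fits each separately, and
$-2\Delta\ell$ is referred to $\chi^2_1$. `rate_table()` composes per-strain
fits with all pairwise tests; raw p-values are reported without multiplicity
correction, matching how pairwise fluctuation comparisons are conventionally
presented.

## Simulation study sizes

The validation and acceptance suites use the study-scale design throughout:
84 cultures per experiment, 200 replicate experiments per condition for
rate-recovery means, 1000 simulated null pairs for type-I calibration, and
100 pairs for power at a 10-fold rate separation. The per-cell rates used as
simulation ground truth span $4.9\times10^{-10}$ to $2.06\times10^{-7}$; the
mutator-control condition is simulated at $N_t = 10^8$ so its expected
mutations per culture ($m \approx 21$) stays in the regime where the
recursion cap is rarely binding.

# Competition and screening

Competition assays mix two fluorescently labelled strains 1:1 and read the
integrated density (summed channel intensity over the colony mask) of the
GFP and mKate channels. Because the two reporters differ in brightness,
coculture densities are divided by monoculture densities channel by channel
and then renormalized:

$$a' = \frac{co_A}{mono_A}, \quad b' = \frac{co_B}{mono_B}, \quad
  \mathrm{pct}_A = 100\,\frac{a'}{a' + b'}.$$

This is gain-invariant by construction (rescaling one channel rescales its
coculture and monoculture readings alike) and recovers the true mixing
fraction exactly on noiseless synthetic quartets with arbitrarily unequal
expression factors. Total integrated density (not per-area density) is the
adopted reading of monoculture normalization; the choice is documented
rather than claimed to be the only one.

Outgrowth screens are tallied descriptively: per strain (and per experiment
— experiments are not pooled by default, since screening conditions vary
between replicates), the number screened, the number of outgrowths, the
frequency, and the morphotype-class breakdown. No statistical test is
attached; the records' structural invariant (a morphotype class is present
exactly when an outgrowth was observed) is validated on input.

# Synthetic data: what it does and does not emulate

The generators provide every input the pipeline consumes, with known truth:

* `sim_wrinkled_colony()` — a disk with concentric sinusoidal relief of
  chosen wavelength/amplitude plus clipped Gaussian noise. Real wrinkles
  are labyrinthine and anisotropic; the concentric simplification is chosen
  precisely because it has a single controllable wavelength, making
  oscillation recovery a sharp test. Passing the recovery test demonstrates
  the estimator, not that real colonies are sinusoidal.
* `sim_random_colony()` — the unstructured control (i.i.d. noise disk).
* `sim_fluctuation()` — the Lea-Coulson forward model described above.
* `sim_competition_quartet()` and `sim_screening_records()` — noiseless or
  lognormal-noise density quartets and Bernoulli screening records.

All generators are bit-reproducible under a fixed seed and restore the
caller's RNG state.

# Numerical choices and edge cases

* $\gamma(0) = 1$ is enforced structurally (bin 0 = self-pairs; analytic
  bin-0 sums; normalizer computed with the same expression as the bin-0
  mean), not left to floating-point luck.
* All-zero (or zero-variance, when centered) intensity fields raise a
  "degenerate field" error instead of returning NaN curves.
* An all-zero count vector gives $\hat m = 0$ at the boundary with a
  one-sided profile interval; a flat height field flags Rsk/Rku undefined.
* The likelihood bracket on $\log m$ auto-expands if the optimum lands on
  an edge; profile roots bracket outward before `uniroot`.
* Image intensities are validated against the declared bit depth; the
  8-bit/16-bit round trip through PNG and TIFF is tested.

# Limitations

* Absolute surface values in physical units need a calibration the user
  must supply; only relative/dimensionless behaviour is verifiable here.
* The correlation summary reports the rebound-maximum distance, which for
  radially periodic structure overestimates the wavelength by ~12% (the
  Bessel bias above).
* The fluctuation machinery fixes plating efficiency and mutant fitness at
  1; strains violating those assumptions need the richer two-parameter
  models of dedicated fluctuation packages.
* Pipeline reports embed the full configuration and seed for
  reproducibility, not a content hash.
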