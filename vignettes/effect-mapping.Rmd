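---
title: "Mapping oscillatory DBS effects to clinical outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping oscillatory DBS effects to clinical outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephysmap)
```

## The problem

Pallidal deep brain stimulation (DBS) improves cervical dystonia, but
outcomes vary widely across patients and the electrophysiological
mechanism is only partly understood. A leading hypothesis is that
effective stimulation suppresses pathologically enhanced low-frequency
(6–12 Hz) oscillations in motor cortical areas while engaging
compensatory activity elsewhere. `ephysmap` implements the analysis
chain that tests this hypothesis at the whole-cortex level: it takes
source-reconstructed oscillatory activity recorded ON and OFF
stimulation, turns it into per-subject maps of stimulation-induced
band-power change, and asks where in the cortex those changes track the
clinical benefit.

The package operates from the source level onward. Sensor-space
cleaning, beamforming and anatomical processing are upstream of its
data contract: inputs are source time series sampled at 250 Hz with a
3 Hz high-pass already applied, or precomputed vertex × frequency power
spectra, on a common source space (triangle mesh or volumetric grid).

## The model

For subject $i$ and vertex $v$, let $P^{ON}_i(v)$ and $P^{OFF}_i(v)$ be
normalized band power in a frequency band of interest. The subject's
**Δ-map** is

$$\Delta_i(v) = P^{ON}_i(v) - P^{OFF}_i(v),$$

positive where stimulation synchronizes activity and negative where it
suppresses it. Three analyses follow:

1. **Group t-map.** A one-sample t-test of $\{\Delta_i(v)\}$ against
   zero at every vertex (algebraically the paired ON-vs-OFF test),
   df $= n-1$, two-tailed uncorrected p. Regions of interest are the
   largest adjacency-connected cluster of vertices with $p < 0.05$,
   split by the sign of t and tie-broken by peak $|t|$; the mean Δ in
   the ROI is then correlated with clinical improvement
   (two-tailed Spearman, Bonferroni-corrected with an explicit
   comparison count $m$, fixed at ROIs × outcome scores $= 4$ in the
   replication recipe).
2. **R-map.** At every vertex, the correlation across subjects between
   $\Delta_i(v)$ and the clinical improvement. The map of
   coefficients is the cohort's "optimal" response signature.
3. **Cross-validated outcome estimation.** The R-map is rebuilt
   excluding each held-out subject (or fold); the held-out subject's
   **spatial similarity** — the correlation across vertices between
   their Δ-map and the training R-map — is their estimated outcome.
   Pooled estimates are correlated with the empirical improvements
   using a one-sided (right-tailed) Spearman test, since only positive
   estimate–outcome correlations are meaningful.

Clinical improvement is the TWSTRS motor percentage improvement
$100(\mathrm{OFF}-\mathrm{ON})/\mathrm{OFF}$ (larger scores are worse,
so positive change is benefit). UPDRS-III bradykinesia subitems (3.4,
3.5, 3.7, 3.8 summed) use $100(\mathrm{ON}-\mathrm{OFF})/\mathrm{ON}$,
since stimulation-induced slowness makes the ON score the reference.

## The spectral chain

Raw source time series become normalized band-power maps through a
fixed pipeline order:

z-score → Welch PSD → spatial smoothing (per frequency bin) →
spectral Hampel filter → reference-band normalization → band averaging.

* **Welch PSD**: Hann-tapered 4 s windows with 50% overlap, giving a
  0.25 Hz grid at 250 Hz sampling; all full windows are averaged,
  partial trailing windows dropped. The taper and detrending are
  conventional defaults; the method choice itself only fixes the
  estimator's variance, not the downstream contrasts.
* **Spectral Hampel filter**: active DBS leaves narrow-band electrical
  artifact lines at subharmonics and aliases of the stimulation
  frequency. A sliding window (half-width 2 Hz) moves along the
  frequency axis of each vertex's spectrum; bins exceeding the local
  median by more than 3 scaled MADs (×1.4826) are replaced by the
  local median. Optionally the replacement is restricted to declared
  artifact frequencies. The filter is applied to power spectra rather
  than reconstructing cleaned time series: all downstream analysis
  consumes spectra, and the two approaches are indistinguishable at
  the level of band-power outputs.
* **Normalization**: each vertex's spectrum is divided by its mean
  power across 55–95 Hz. This removes per-recording scale so that ON
  and OFF conditions are comparable. The pipeline order matters and is
  enforced: an artifact line *inside* the reference band biases the
  normalization of every bin, so the Hampel step must precede it (the
  filter refuses normalized input). Smoothing precedes normalization
  too; smoothing and band averaging are linear and commute, division
  does not.
* **Bands**: low frequency 6–12 Hz (the primary band; its lower border
  keeps distance from the 3 Hz high-pass), beta 13–30 Hz, and a 4–12 Hz
  sensitivity variant. Band edges are inclusive on both sides, making
  bin counts deterministic (25 bins for 6–12 Hz at 0.25 Hz).

## Geometry and smoothing

Maps live on a `source_space`: vertex coordinates in millimetres, with
adjacency derived from shared triangle edges (surfaces) or from a
distance threshold (volumetric grids). Indices are 1-based throughout,
the R convention. Smoothing is a Gaussian kernel on Euclidean
inter-vertex distance with $\sigma = \mathrm{FWHM}/2.3548$, truncated
at $3\sigma$, weights renormalized over unmasked vertices. The 6 mm
default matches the kernel used on dense cortical meshes
(15k vertices, 2–3 mm spacing). Geodesic smoothing is out of scope: at
this kernel scale the chord-vs-surface distance difference is
negligible.

One geometric consequence deserves emphasis: on the package's *synthetic*
icospheres (642 vertices at 80 mm radius, 11 mm minimum spacing) a 6 mm
kernel reaches no neighbour within its $3\sigma$ truncation and is
exactly the identity. That is correct behaviour — a kernel below the
mesh resolution should do nothing — and it is asserted as a property in
the tests; smoothing-dependent tests therefore use mesh-spanning
kernels (≥ 30 mm) on the synthetic spaces.

## The clinical cohort

The bundled table (`load_cohort_table()`) carries the 15-patient
GPi-DBS cervical dystonia cohort: TWSTRS motor scores pre-operatively,
stimulation OFF, under an experimental bipolar setting (used during
recordings to reduce stimulation artifacts) and under the chronic
monopolar setting, plus AIMS item 7, disease type (cervical vs
segmental), symptom side and durations. Percent-change columns are
always derived, never stored. Bipolar improvement is referenced to the
same-day OFF score; monopolar improvement to the pre-operative
baseline (monopolar assessments were rated from archival videos, for
which the pre-operative score is the matching reference — this
reproduces all printed per-patient percentages to 2 d.p.).

Statistics on the table: paired t-test with the paired-sample effect
size $d = \bar{d}/s_d$ (this definition, not the pooled-SD variant,
reproduces the cohort's printed $|d| = 0.81$); Shapiro–Wilk as a
normality precondition — note that on this cohort the OFF-vs-bipolar
differences *fail* the check (p ≈ 0.004, driven by one 22-point
improvement), so `paired_t_test()` warns; responder classification by
≥ 20% improvement, with the ≥ 3-point minimal clinically important
difference as a second rule (the two partition this cohort
identically, 10 responders / 5 non-responders); one-way ANOVA of
improvement by disease type, df (1, 13); and OLS covariate models on
standardized variables, where a single predictor's standardized
coefficient equals its Pearson correlation with the outcome.

The sensitivity power analysis uses the Fisher transform:
$z = \operatorname{atanh}(\rho)$, SE $= 1/\sqrt{n-3}$, giving
$\rho_{\min} = \tanh\!\big((z_{1-\alpha} + z_{\mathrm{power}})/\sqrt{n-3}\big)$
— 0.616 at $n=15$, 80% power, one-sided $\alpha = 0.05$. The same
closed form gives 94% power for $\rho = 0.73$ at $n = 15$; a published
figure of 84% for this quantity is not reproducible by this (or any
standard Fisher-z) closed form, so the package reports the closed-form
value and flags the discrepancy rather than matching it.

## The synthetic cohort generator

Because the underlying recordings are not publicly available, every
pipeline stage is validated on synthetic cohorts whose statistical
structure is exactly what the analysis assumes:

$$\Delta_i = g\,(y_i - \bar{y})\,\pi + \varepsilon_i,$$

where $\pi$ is a unit-norm ground-truth pattern (sum of signed
Gaussian blobs), $y_i$ the outcomes, and $\varepsilon_i$ spatially
smooth Gaussian noise. Defaults and their rationale:

* **Outcomes** default to the bundled cohort's actual bipolar
  percent-improvement column (mean 27.78, SD 29.22, including negative
  values), anchoring simulations to the real cohort's spread.
* **Pattern**: two negative blobs (motor/SMA-like suppression) and two
  positive blobs (prefrontal- and cerebellar-like synchronization),
  σ = 30 mm on the 80 mm sphere. Response signatures of this kind are
  lobe-scale, smooth fields covering much of the cortex, not isolated
  points; at sub-lobe blob widths the pattern support would be so
  sparse that per-vertex sampling noise of a 15-subject correlation
  (SD ≈ 0.27) dominates the map and no method could recover it — the
  default deliberately sits in the recoverable regime that the real
  analysis presumes.
* **Noise**: white Gaussian fields smoothed with a 20 mm FWHM kernel
  (controllable correlation length, reusing the tested smoothing code)
  and rescaled so the per-vertex SD equals `noise_sd` (default 0.5)
  times the across-subject SD of the planted effect at the pattern
  peak. Under the null (`effect_gain = 0`) that reference degenerates,
  so the generator falls back to the unit-gain scale; all downstream
  correlations are scale-invariant, so only degeneracy is at stake.
* **Time-series mode** generates, per vertex, a 1/f background plus a
  band-limited 6–12 Hz oscillator whose ON-vs-OFF power contrast
  realizes the target Δ, with optional pure-sinusoid artifact lines in
  the ON condition (defaults 65 and 120 Hz — one inside the 55–95 Hz
  reference band, where an uncleaned line biases normalization, and
  one alias-like line). An artifact-free copy of the ON series (same
  noise realization) is returned so the Hampel step can be judged
  against a line-free ground truth.

What the generator does *not* emulate: realistic anatomy, volume
conduction and source leakage (which correlates neighbouring vertices'
estimates in real data), condition-order effects, or non-linear
Δ–outcome relations. Passing the recovery tests therefore shows the
chain is correct and well-calibrated under its own assumptions, not
that real MEG cohorts will reach the same effect sizes.

## Numerical and design choices

* Vertex-wise R-map correlations are Spearman by default (the cohort
  statistics are uniformly Spearman); spatial similarity is Pearson by
  default (the convention for "spatial correlation" in network
  mapping). Both are flags; neither choice is asserted to be what any
  particular study used.
* k-fold estimates are pooled across folds before a single outcome
  correlation; folds are equal-sized (±1) seeded shuffles,
  re-randomized (≤ 20 tries) if a training set has constant outcomes.
  Fold seeds should be independent of simulation seeds.
* One-sided Spearman p-values use the t-approximation (df $= n-2$).
  An exact permutation option exists for small n: full enumeration up
  to $n = 8$ (40320 permutations), seeded Monte-Carlo (2 × 10⁵ draws)
  for $n = 9, 10$, where full enumeration buys nothing at R speeds.
* Bonferroni corrections always use an explicit comparison count m;
  nothing is inferred from object shapes.
* Rounding against printed values is half-away-from-zero
  (`round_half_up()`), matching how clinical tables are printed;
  base R's banker's rounding would disagree at exact .5 ties.
* Masks propagate: zero-variance vertices (z-scoring), zero
  reference-band power (normalization), degenerate Δ variance
  (t-maps, R-maps) are masked, not errors; similarity computations
  exclude masked vertices pairwise and require ≥ 10 shared vertices.

## Known limitations

* **Pooled-CV p-values are mildly anti-conservative.** With pure-noise
  Δ-maps (no planted effect), the one-sided p of the pooled 4-fold
  cross-validation rejects at ≈ 12% instead of 5% (measured over 1000
  replicates at the default conditions): held-out subjects within a
  fold share a training R-map built from the same outcome vector that
  the final correlation tests, so the pooled estimates are not an
  i.i.d. sample. The standard permutation-style null — shuffling the
  outcome labels of an otherwise structured cohort — is calibrated to
  ≈ 7–9%. For confirmatory use, a full permutation test around
  `cross_validate()` is the rigorous option.
* **The noiseless limit saturates.** With `noise_sd = 0` every
  vertex's Δ is an exact monotone function of outcome, training R-maps
  collapse to a ±1 sign map of the pattern, and held-out similarities
  become two-valued; the CV rank correlation is then bounded by the
  tie structure (≈ 0.87 with the default outcomes), not 1. Recovery
  should be assessed at non-zero noise.
* Spectral estimates at 120 s records have finite-window noise: a
  robust Hampel filter will occasionally trim legitimate stochastic
  peaks (a few percent of bins); restricting it to declared artifact
  frequencies avoids this entirely.
* The bundled table's printed summary row is not fully
  self-consistent (its monopolar-change and AIMS means do not match
  the printed per-patient values); per-patient values are
  authoritative, and the package derives all summaries from them.

## Problem sizes

The test-suite and acceptance-script experiments run on icospheres of
162–642 vertices with the 15-subject default cohort: 20-seed recovery
experiments, 200–400-replicate calibration experiments, and 120 s
two-condition time-series simulations on 42 vertices. These sizes were
chosen to characterize the estimators well (Monte-Carlo SEs of a few
percent) while staying desk-scale; the pipeline itself is
vertex-count-agnostic.
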