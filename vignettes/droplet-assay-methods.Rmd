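---
title: "Models and methods behind dropgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dropgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropgate)
```

`dropgate` models a droplet-microfluidic single-cell RNA profiling workflow:
live cells are encapsulated into picoliter droplets together with isothermal
amplification (RT-LAMP) reagents, target transcripts amplify to a fluorescent
endpoint, and droplets stream past a laser at a few hundred per second while
photodetectors record multi-channel time traces. The package covers the
computational layer of such an instrument — everything between the raw trace
and the biological answer — plus a generative simulator so every stage can be
exercised against known ground truth without instrument data.

## The generative droplet model

`assay_model()` describes an experiment. Its assumptions, and what they do
and do not capture:

* **Cell loading is Poisson.** Dilution loading puts $k \sim
  \mathrm{Pois}(\lambda)$ cells in a droplet. The default $\lambda = 0.105$
  gives $P(k \ge 1) = 1 - e^{-0.105} \approx 0.0997$, i.e. one occupied
  droplet in ten — the loading regime this assay family runs at. Doublets are
  simulated and recorded in the ground truth; a doublet's marker state is the
  OR of its cells' states, which inflates positive fractions by a few parts
  per thousand at this $\lambda$. Analyses that assume "one droplet, one
  cell" should condition on singlets (the ground-truth table makes that
  possible).
* **Marker amplification is Bernoulli.** A cell of class $c$ amplifies
  marker $m$ with probability $c_m$ — the assay's per-cell true positive
  rate when $c$ truly expresses $m$ (97.1% for the calibrating ERBB2
  experiments). An *empty* droplet registers positive with probability
  `fpr_per_marker` (default $2\times10^{-4}$, the assay's estimated 0.02%
  false positive rate). There is no kinetic model of the amplification
  chemistry: positivity is binary at endpoint, which is exactly the
  abstraction the detectability model downstream needs.
* **Fluorescence is plateau + linear optics.** An event's true per-channel
  signal is `empty_baseline` plus `amp_signal` per amplified marker (plus
  the stain on the stain channel); observed signal is the crosstalk matrix
  times the true vector plus Gaussian noise. The default `amp_signal` is
  10x the empty baseline so a 2.8-fold-over-median threshold separates the
  populations cleanly; shrink it to study overlapping populations.
* **Nucleus-spike artifacts** (a cell nucleus crossing the laser lights up
  an intercalating dye) are short transients of amplitude 5x the
  amplification signal on the detection channel. The artifact's *rate* is
  a model parameter, default 0: the false positive rate is already carried
  explicitly by `fpr_per_marker`, and enabling both by default would count
  the same phenomenon twice. Turn `spike_rate` up to study the mechanism —
  at event level a spike adds its full amplitude to the droplet mean, while
  in traces it is a ≤3-sample transient, so trace-derived means are diluted
  by the duration; the two views deliberately bracket the artifact's
  severity.
* **Durations are lognormal** (mean 100 samples, CV 0.1 at a 100 kHz
  detector and 300 droplets/s): strictly positive and right-skewed, with
  droplet-to-droplet variability as a calibration knob, not a physical
  claim. Oil gaps fill the remaining time budget.

What the simulator does **not** emulate: baseline drift, droplet merging or
shredding, partial amplification (dim positives), autofluorescence spectra,
or day-to-day instrument variation. Tests passing on simulated data
demonstrate the *pipeline's* correctness under the stated statistical
structure — not that real instrument data obeys that structure.

## Event detection

`detect_events()` implements single fixed-threshold detection: an event is a
maximal run of samples with detection-channel value strictly above the
threshold, at least `min_width` (default 3) samples long. Conventions chosen
for testability: samples equal to the threshold are oil; runs are 0-based,
half-open. There is no hysteresis and no peak-shape fitting; spikes inside a
droplet raise its mean rather than splitting it — spike rejection belongs to
gating, not detection. The suite checks the implementation against a
brute-force per-sample scan on traces up to $10^5$ samples, and checks the
exact round trip `detect_events(simulate_traces(m, n))` on noiseless traces.

## The gating cascade

`run_pipeline()` fixes the stage order:

1. **Compensation** — multiply by the inverse spillover matrix. Negative
   compensated values are retained so medians stay unbiased.
   `estimate_compensation()` builds the matrix from single-positive
   controls (median ratio of off-channel to on-channel signal).
2. **Size gate** — rank by duration, remove `floor(0.08 n)` events from
   each tail (ties broken by droplet id, so the gate is deterministic).
3. **Cell gate** — an event is a cell iff its stain mean exceeds 2.8x the
   median stain of all size-gated events. This replaces manual gating with
   a reproducible fold-over-median rule, reusing the same constant as the
   amplification rule.
4. **Amplification thresholds** are computed from the stain-negative
   (empty) survivors of the size gate, *before* the cells are
   down-sampled: thresholds must not depend on the down-sampling draw.
   Threshold = 2.8 x median empty fluorescence, per marker channel.
5. **Down-sample** the cell population to 10,000 events (uniform, seeded)
   for cross-sample comparability.
6. **Classify** — strict `>` against each threshold; percent positive,
   quadrant counts, and optionally a per-droplet logic-circuit readout.

Every constant above is a named `gate_config()` default, never hard-coded;
the report logs the count removed at each stage and those counts sum to the
input count.

## Rare-cell detectability

The detectability model asks: screening $n$ cells of which a fraction $p$
are true positives, does the positive count distinguish the sample from a
pure negative population? With per-cell rates TPR and FPR,

$$\mathbb{E}[\text{positives}] = n(1-p)\,\mathrm{FPR} + np\,\mathrm{TPR},$$

and the null is $X \sim \mathrm{Binom}(n, \mathrm{FPR})$. The expected count
is rounded half-up to an integer $k$ (the model tests an expected value, so
a deterministic rounding rule is needed; half-up is the documented
convention) and the p-value is the exact upper tail $P(X \ge k)$ — detection
means an *excess* of positives, so the test is one-sided by default with a
two-sided variant behind a flag. No approximation is used; a
continuity-corrected normal tail is kept as a cross-check (they agree within
0.01 once the null mean reaches 20).

At the assay's operating point (TPR 0.971, FPR $2\times10^{-4}$): a 0.1%
mixture among 10,000 cells gives $k = \mathrm{round}(11.708) = 12$ against a
null mean of 2 ($p \approx 1.4\times10^{-6}$), while 1-in-10,000 needs
100,000 cells ($k = 30$ against a null mean of 20, $p \approx 0.022$) — the
decade grid `min_detectable_prevalence()` searches is $10^{-6}\dots10^{-2}$.
Whether the original analysis used simulation replicates or the
deterministic expected count is ambiguous; `detection_pvalue()` is the
deterministic mode and `simulate_mixture_series()` the stochastic one, so
both readings are available.

```{r rarecell}
lod_grid(c(1e4, 1e5), 10^(-5:-3))
```

## Molecular logic

Strand-displacement gates (YES, NOT, OR, AND, AND-NOT) are evaluated at two
levels. Boolean semantics are exact and exhaustively testable
(`truth_table()`). The signal level is a deliberately *phenomenological*
equilibrium model — sums, thresholds and floors, no kinetics, because the
chemistry's rate laws are not part of this package's scope:

* a transducer emits `on_level` (default 1.0) when its LAMP input is
  present, `leak` (0.05) otherwise;
* OR sums its branches; AND subtracts the threshold strand
  (`max(0, x + y - 1.1)`); NOT inverts (`on_level - x`); AND-NOT is
  `max(0, x - y)`;
* every gate output saturates at `on_level` — a fluorogenic reporter cannot
  exceed its fully-displaced signal. Without saturation an OR feeding an
  AND-NOT would mis-fire: OR(1,1) would reach $2\cdot$`on_level` and
  overwhelm the inverting branch, calling ON where the Boolean answer is
  OFF.
* `and_threshold` = 1.1 sits above one active transducer plus the other's
  leak (1.05), so a lone input is fully sequestered, yet low enough that
  two-level cascades (AND of ANDs) stay above the 0.5 detect cutoff. A
  margin analysis: at depth 2 the weakest true output is
  $0.9 + 0.9 - 1.1 = 0.7$ and the strongest false output is an OR of two
  leaks, $0.1$ — both clear of the cutoff.

**Known limitation:** levels attenuate through depth. At three or more
levels of AND nesting the true output can fall below the cutoff, so
signal/Boolean agreement is guaranteed (and tested) for single gates and
depth-2 circuits such as `(KRT19 OR VIM) AND-NOT PTPRC` — the
circulating-tumor-cell classifier that distinguishes epithelial or
mesenchymal cells from leukocytes — not for arbitrarily deep cascades. The
wet chemistry's measured ON/OFF ratios are not fitting targets; parameters
were chosen once for Boolean fidelity.

```{r logic}
circ <- parse_logic_expression("(KRT19 OR VIM) AND-NOT PTPRC")
truth_table(circ, signal = TRUE)
```

## Efficiency-corrected enrichment

Sorting validation compares target (X) to reference (R) transcript levels
before and after sorting via RT-qPCR. With poor amplification efficiencies
the classical $2^{-\Delta\Delta C_t}$ rule misstates fold changes, so the
per-gene efficiency enters the base:

$$E = (1+E_R)^{C_{t,R,\mathrm{sorted}} - C_{t,R,\mathrm{initial}}}
      \cdot (1+E_X)^{C_{t,X,\mathrm{initial}} - C_{t,X,\mathrm{sorted}}}.$$

Efficiencies live on the 0–1 scale (a perfect doubling chemistry has
$E = 1$; the calibrating experiments measured 0.36 for GAPDH and 0.17 for
KRT19). `efficiency_from_dilution()` estimates $E$ from a serial dilution
series by OLS of $C_t$ on $\log_2(\text{concentration})$:
$E = 2^{-1/\text{slope}} - 1$, clipped to $[0,1]$ with a warning. Replicate
averaging happens upstream (`mean_ct()`), never inside `fold_enrichment()`.

## Problem sizes and numerical conventions

The test suite simulates $2\times10^4$–$2\times10^5$ droplets per
statistical check — enough that three-binomial-SD bounds are tight (a few
parts per thousand) while the whole suite runs in seconds. Convergence
checks use 3-SD binomial bounds around closed-form expectations; end-to-end
mixture recovery adds a +0.01 allowance for the Poisson-doublet OR effect
described above. Medians of even-sized sets are the mean of the two central
values; all randomness descends from explicit integer seeds, and rerunning
any simulation or pipeline with the same configuration is bit-identical.

Known limitations, collected: no kinetic model of amplification or strand
displacement; linear-only spectral unmixing; no baseline drift or
instrument artifacts beyond nucleus spikes; signal-level logic degrades
with circuit depth; enrichment assumes pooled replicate Cts and does not
model the auxiliary assumptions behind sorting-efficiency inequalities.
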