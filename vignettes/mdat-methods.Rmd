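---
title: "Methods: single-sensor EMG magnitude discretization, simulated"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-sensor EMG magnitude discretization, simulated}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdatsim)
```

## The control scheme

A single sEMG channel reports muscle activity as integers on a 0–1023 scale.
A *flex* is one contraction episode: once the conditioned signal rises
strictly above a user-set resting threshold, samples are accumulated until it
dips strictly below again; the running maximum is the contraction's *peak*.
The axis above resting is divided into *zones* — intervals
`[minimum_i, minimum_{i+1})`, the top zone extending to 1024 — and the zone
containing the peak selects the gesture. Users with 1, 3 or 5 zones must
therefore grade contraction *strength*, not pattern, which is the regime this
package simulates.

## Signal conditioning

The conditioning chain is `rectify() -> filter_and_smooth() -> quantize()`.

- **High-pass**: order-2 Butterworth at 2 Hz (causal `signal::filter`). A
  2–1000 Hz band-pass at a 1000 Hz sampling rate cannot be realized as
  stated — the upper edge sits at the Nyquist frequency — so the upper edge
  is left to the sampling itself and only the 2 Hz lower edge is implemented.
  Filter family and order are declared package choices, not measured device
  properties. The causal form mirrors a real-time device; its transient means
  streams need a warm-up (about 1 s at 2 Hz) before DC is fully rejected,
  and large bursts are followed by a small opposite-sign ringing lobe. That
  lobe can re-cross a low resting threshold and emit a small artifact event;
  downstream consumers take the largest event per attempt, which is also the
  robust choice against baseline noise.
- **Smoothing**: a causal moving-average envelope, default 50 ms. At 1000 Hz
  this shrinks baseline noise SD by ~1/√50, which is what makes a resting
  threshold of ~23 counts essentially impenetrable to default resting noise.
- **Quantization**: multiply by the calibration scale, round half away from
  zero (a fixed, testable convention; base R's `round()` is banker's), clamp
  to [0, 1023]. Amplification is folded into the calibration scale; there is
  no separate gain stage.

Packets arrive at ~60 Hz and are consumed in arrival order at each 30 Hz
frame tick (`buffer_frames()`), so the processing interval is
1000/30 ≈ 33.3 ms and no samples are dropped.

## Detector boundary semantics

A sample exactly equal to resting neither opens nor closes a contraction:
opening requires strictly greater, closing strictly less. Equality is
undefined in the scheme's informal description ("above" / "below"), so the
narrowest reading is fixed and tested. A contraction still open at
end-of-stream emits nothing in batch mode (`flush = TRUE` force-emits for
interactive use), because a peak is only defined after the dip below resting.
No refractory period is imposed after a dip.

One tested caveat: "raising the resting threshold never increases the event
count" holds for physiological envelopes (unimodal bursts over a low
baseline, where the above-threshold set of each burst is an interval) but not
for adversarial streams, where a higher threshold can split one run into two.
The property test generates burst-shaped envelopes accordingly.

## Zones and calibration

Equal initial segmentation puts the first minimum at `resting + 1` — so every
detected flex lands in some zone — and gives consecutive minimums a width of
`round((1024 − first) / n_zones)`, the top zone absorbing the rounding
remainder. Minimums are integers on the device scale; boundary membership is
closed at the minimum. Calibration "zooms" the envelope so an observed
maximum voluntary contraction (MVC) lands at a target fraction of full scale:
`global_scale = target_fraction × 1023 / mvc_peak`. Thresholds always live on
the post-scale axis.

## The assessment engine

A trial is `n_cues` (default 15) randomized cues; the participant has exactly
one attempt per cue and no time limit; an attempt succeeds iff the attempt's
peak falls in the cued zone; the score is the success count. Cues are i.i.d.
uniform over zones by default — "randomized" admits several readings and
i.i.d. uniform is the minimal one — with a balanced mode (equal counts,
shuffled) exposed rather than silently chosen. Cohort schedules: A1 = (1,1,1)
zones across three trials, A2 = (3,3,3), A3 = (5,5,5), B1 progressive
= (1,3,5), with a 60 s rest between trials, right arm then left as
independent repeats with separate derived seeds.

Because the scheme treats any above-resting peak in single-zone mode as a
success, single-zone trials have a hard ceiling: any user whose contractions
exceed resting scores 15/15 with zero variance. This is structural, and the
suite asserts it over 100 simulated trials.

## The simulated participant

The generator stands in for human participants; no participant-level data is
distributed with the package, only cohort summary tables (means, SDs, sizes)
in `inst/extdata/`.

- **Aim model**: for a cued zone the processed peak is
  `Normal(zone center, aim_sd)`, rounded and clipped to [0, 1023]. `aim_sd`
  is the single skill parameter, in counts on the post-scale axis.
- **Raw-signal path**: `synth_contraction()` embeds a raised-cosine burst
  between resting-noise segments and solves the burst amplitude so the
  *processed* peak equals the drawn target exactly (the chain is linear for
  nonnegative signals, so the amplitude solve is a two-step fixed point).
  `run_trial(use_signal_path = TRUE)` routes attempts through this path and
  the fast path agrees with it to ±1 count; the suite checks both.
- **Resting noise**: Gaussian raw baseline (default mean 10, SD 4 counts).
  After envelope smoothing this cannot cross a resting threshold of 23; the
  spurious-event rate grows with noise SD, which is tested by Monte Carlo.
- **Population default**: per-participant `aim_sd` is log-normal with median
  190 counts (sdlog 0.25). Chosen once from the closed-form hit probability
  `2Φ(w / 2σ) − 1` at equal zone widths: at σ ≈ 190 it yields per-cue hit
  rates near 1, ~0.6 and ~0.45 for 1/3/5 zones — a ceiling at one zone and a
  falling gradient thereafter, the qualitative pattern the study design
  anticipates. Per-zone human accuracies are not published, so the generator
  is *not* calibrated to reproduce observed cohort means, and matching them
  is deliberately not a test.
- **Inverse estimator**: `estimate_aim_sd()` maximizes the Bernoulli
  likelihood of per-cue hits under the closed-form zone-hit probability; at
  200 simulated participants it recovers a true `aim_sd` within 10%
  (asserted in the suite).
- **Surveys**: integer item responses from clipped Gaussians around cohort
  item-mean profiles. Default profiles encode the expected cohort patterns
  (usability lowest for the static 5-zone cohort, perceived performance
  highest for single-zone); EHI tallies make the population uniformly
  right-handed (LQ > 40); grip strength is Gaussian by self-reported gender
  around 44.0/27.3/21.3 kg (SD 11.2/4.6/0.6).

What the generator does **not** model: fatigue (the protocol handled it with
rest breaks), learning across trials, non-Gaussian aim error, electrode
shift. Passing tests therefore certify the machinery — detector, zones,
scoring, statistics — under a clean stochastic participant, not human
performance.

## Statistics

- Within-cohort trial contrasts: paired two-sided t (df = n−1), paired
  `d = mean(diff)/sd(diff)`, Hedges g; when Shapiro–Wilk on the differences
  gives p < .05 a Wilcoxon signed-rank result is attached as a sensitivity
  analysis rather than replacing the t test.
- Between-cohort contrasts: Welch t with Welch–Satterthwaite df (variances
  are not assumed equal); effect sizes use the conventional definitions —
  pooled-SD Cohen d on `df = n_a + n_b − 2` even though the test is Welch,
  `g = d(1 − 3/(4df − 1))` (the exact gamma-ratio correction is available via
  `exact_hedges = TRUE` and cross-checked), and
  `d_av = Δmean / ((sd_a + sd_b)/2)`. The progressive cohort is compared
  trial-by-trial against the static cohort with the same zone count and the
  same exposure time (B1 trial 1 vs A1 trial 1, etc.).
- Ordinal/multilevel factors: tie-corrected Kruskal–Wallis; associations:
  Spearman with average ranks; gender contrasts: Mann–Whitney U with
  rank-biserial `r = 1 − 2U/(n_a n_b)` (U is the a-side pair count, ties one
  half; exact p for tie-free samples with both n ≤ 8, tie-corrected normal
  approximation otherwise).
- Everything is two-sided at α = .05 and *nothing* is adjusted for multiple
  comparisons; the report tables contain no adjusted columns by design.
- SDs everywhere are the n−1 sample SD. The TLX composite is the unweighted
  mean of the six 0–100 subscales with the inversely-oriented performance
  subscale entered as `100 − performance`; it is a convenience summary, not
  an instrument-defined score, and is labelled accordingly.

Kruskal–Wallis, Mann–Whitney and Spearman delegate their p-values to base R
(`kruskal.test`, `wilcox.test`, `cor.test`); the suite checks the statistics
against brute-force rank/pair-count oracles on small fixtures (n ≤ 12), so
the package's own effect-size layer is validated independently of the
delegated machinery. One degenerate case is fixed by convention: when every
observation across groups is tied there is no rank variation and H is
reported as 0 with p = 1.

## Problem sizes and numerical choices

The shipped tests run the detector oracle on 10^4 random streams, the zone
oracle on all 1024 peaks × 50 random threshold sets, Monte-Carlo hit rates at
10^5 draws (3-SE tolerance), and parameter recovery at 200 simulated
participants — sizes chosen so the full suite completes in about a minute on
one core while keeping binomial standard errors well below the tolerances
they gate. Seeds are fixed inside tests; user-facing functions accept a
`seed` and restore the caller's RNG state (`with_seed` internally), so
library calls never perturb reproducibility of surrounding code.

## Known limitations

- The simulated participant is a proxy; absolute cohort means depend on the
  chosen `aim_sd` population and are not validated against humans.
- The causal Butterworth choice introduces ringing artifacts after large
  bursts (handled by max-event selection, documented above).
- Zone minimums of 1024 are accepted by the container (the scheme permits
  them) but describe an empty top zone; equal segmentation never produces
  one.
- The CLI (`inst/cli/mdat.R`) is a thin driver over the exported functions;
  it adds no behavior of its own.
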