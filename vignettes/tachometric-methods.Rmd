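---
title: "Tachometric analysis of urgent decisions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tachometric analysis of urgent decisions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In urgent-decision paradigms a response deadline (1,000 ms) starts at a
Go-signal, and a variable *gap* (0–950 ms in 11 levels) separates the
Go-signal from target onset. Long gaps leave little time to see the target
before the deadline, forcing responses that range from pure guesses to fully
stimulus-driven decisions. The analysis variable is the **raw processing
time**,

$$ \mathrm{rPT} = \mathrm{RT} - \mathrm{gap} - \mathrm{SOA}, $$

the time the target was visible before the response was committed (the SOA
term applies when flankers precede the target). Plotting the proportion of
correct responses against rPT yields the **tachometric function**: flat at
chance for negative and short rPTs, then rising to an asymptote. In conflict
tasks (incongruent flankers) the function can dip *below* chance in a window
where the irrelevant stimulus dimension drives the response. Whether such a
dip exists, how deep it is, and whether it is statistically credible is what
this package quantifies.

## The estimation pipeline

1. **Window**: only trials with $-200 \le \mathrm{rPT} \le 1000$ ms are
   analyzed (closed interval; beyond 1,000 ms a response is outside the
   deadline even at gap 0). Practice trials are dropped. Both exclusion
   counts are reported.
2. **Binning**: accuracy is aggregated per 1-ms bin (rPT rounded to the
   nearest ms). Empty bins carry no information and are dropped before
   smoothing rather than treated as zeros.
3. **Smoothing**: the per-bin proportions are locally regressed on the bin
   centers with `stats::loess`, span 0.2, tricube weights, local polynomial
   degree 2, and evaluated on the full 1-ms grid. Defaults mirror `loess`
   itself, which is the procedure the analysis scheme is built on. Bins are
   unweighted by default (a count-weighted mode is available); the smoothed
   curve is clipped to $[0, 1]$.
4. **Minimum**: the dip statistic is the minimum of the smoothed curve over
   rPT > 0 — negative-rPT responses precede target onset and cannot be
   stimulus-driven, so minima there are uninterpretable. Ties break toward
   the smallest rPT.

### Numerical choices

* `surface = "interpolate"` (the `loess` default) is the package default and
  is used inside all resampling loops; `surface = "direct"` computes the
  exact tricube weighted least squares at every grid point
  (neighborhood $q = \lfloor \text{span} \cdot n \rfloor$, support
  $d < d_{(q)}$) and is the reference the test suite validates against an
  independently coded per-point WLS oracle. Under the interpolated surface
  the curve is evaluated only within the range of nonempty bins.
* Smoothing needs at least $\max(\text{degree} + 2, \lceil 2/\text{span}
  \rceil)$ nonempty bins; fewer is an estimation-infeasible error. At the
  default span 0.2 this is the usual "at least 10 bins" rule; larger spans
  admit the small exactly-enumerable instances used for validating the
  permutation machinery.
* p-value tie comparisons use a $10^{-9}$ tolerance so that floating-point
  noise in exactly tied statistics cannot flip a count.

## Inference

**Minima difference (two conditions).** The statistic is
$\min_A - \min_B$, each computed through the full bin → smooth → minimum
pipeline. The null relabels the pooled trials into groups of the original
sizes (per trial, on the aggregated table) and re-runs the entire pipeline —
smoothing included — per replicate. With random relabelings the two-sided
p-value uses the add-one convention $p = (1 + \#\{|t^\ast| \ge
|t|\})/(1 + B)$, so $p > 0$ always; when the number of distinct relabelings
is at most `n_perm` the test switches to exhaustive enumeration and returns
the exact p-value.

**Minimum versus chance.** The procedure is named after testing the minimum
against the chance level 0.5; its null here regenerates every trial's
correctness as an independent fair coin while keeping all rPTs fixed, and
recomputes the restricted minimum. This is the natural one-sample null that
reuses the full pipeline: it represents an observer whose responses carry no
stimulus information at any rPT. The p-value is lower-sided. Under this
construction the test is exactly calibrated when the data themselves are
fair coins (the suite verifies the rejection rate at $\alpha = 0.05$ over
200 replicate datasets of roughly 2,000 trials, with 199 permutations per
replicate — sizes chosen to keep the study a few minutes long while leaving
the test exact at any permutation count).

**Bootstrap SE.** Trials are resampled with replacement within condition and
the restricted minimum recomputed; the reported SE is the standard deviation
of the bootstrap minima.

**Chance band.** Per grid point, $0.5 \pm 1.96\sqrt{p(1-p)/n}$ with
$p = 0.5$ and $n$ = the number of trials inside the local smoothing
bandwidth at that grid point (`n_local`) — the count the smoothed value is
effectively based on. Points with no local trials are flagged undefined.

**Bayes factors.** Accuracy is re-aggregated in 100-ms rPT bins. For each
bin with $n$ trials and $k$ correct, evidence for "below chance" (and
separately "above chance") versus "exactly at chance" is the marginal
likelihood ratio under a logistic prior on the log-odds, centered at
$\mathrm{logit}(0.5)$ with scale 0.5 and truncated to the tested side:

$$ \mathrm{BF} = \frac{\int \binom{n}{k} p(\omega)^k (1-p(\omega))^{n-k}\,
\pi(\omega)\, d\omega}{\binom{n}{k} 0.5^n}, \qquad p(\omega) =
\mathrm{logit}^{-1}(\omega). $$

The integral is computed by adaptive quadrature on the log scale (the peak
is factored out, so large $n$ cannot overflow), reported as $\log_{10}$ BF,
with 0 and $\infty$ preserved as sentinels. The tests validate three fixed
$(k, n)$ cases against a brute-force trapezoid quadrature on $10^6$ grid
points to $10^{-6}$ in $\log_{10}$.

**Dip classification.** A condition is reported as exhibiting a below-chance
dip only when both signals agree: the smoothed curve leaves the chance band
downward somewhere in the interpretable range (rPT > 0) *and* the
minimum-vs-chance permutation test is significant at 0.05. The band alone is
deliberately not trusted: with tens of thousands of trials the band is a few
hundredths wide, and the smoothed curve's own sampling noise produces
transient crossings with no inferential meaning. The joint rule recovers the
qualitative reading "the function remains within the band until it rises"
for dip-free data while never missing a real dip, which is also flagged by
both signals at once.

## The synthetic-data generator

The generator exists so every stage is testable end to end with known ground
truth. It reproduces the three bundled designs exactly — 6 participants;
5 sessions of 9 × 132 trials (`exp1`, `exp2`; 5,940 per participant) or
4 × 264 trials (`exp3`; 5,280); 11 gap levels 0–950 ms; fixation 350/400/500
ms; SOA 0 or 0/120 ms; 1,000-ms deadline; the first block of session 1 is
practice. Within each block the full factorial of gap × congruency × target
× SOA × fixation is replicated exactly and shuffled.

The observer's accuracy curve is

$$ p(\mathrm{rPT}) = p_{\mathrm{floor}} + (p_{\mathrm{asym}} -
p_{\mathrm{floor}})\, S\!\left(\tfrac{\mathrm{rPT} - m - \delta\,[inc]}{s}\right)
- d\, e^{-\frac{(\mathrm{rPT} - c)^2}{2w^2}}[inc], $$

a logistic rise from the guessing floor (0.5) to the asymptote, shifted
right by the congruency delay $\delta$ for incongruent flankers, minus an
optional Gaussian dip (incongruent only), clipped to $[0.001, 0.999]$. An
optional linear late decline (off by default) mimics the slight accuracy
drop at very long rPTs; none of the reported statistics needs it.

Defaults: floor 0.5, asymptote 0.95 (0.93 for the letter-stimulus presets),
half-rise 350 ms, rise scale 60 ms, congruency delay 50 ms — values placing
the rise above the band near 200 ms rPT and the congruent–incongruent offset
at the canonical ~50 ms flanker delay. The `exp3` asymmetry scenario uses a
150-ms delay (the conflict must be resolved first), a dip centered at 400 ms
with 80-ms width, and a depth *calibrated at load time* so the generative
incongruent curve bottoms out at exactly 0.16 (`calibrate_dip_depth()`
solves for the depth on the 1-ms grid).

Response times are truncated-normal, mean 800 ms, SD 150 ms, bounds
[100, 1300] ms, independent of the gap — chosen so realized rPTs cover the
full −200..1,000 ms window across the 11 gaps. Responses with rPT below 0
are guesses: the dominant-hand response is chosen with probability
`hand_bias` (0.5 = unbiased); with balanced targets this yields chance
accuracy regardless of the bias.

**What the generator does not emulate.** Real RT distributions are anchored
to target onset for short gaps and to the deadline for long gaps, are
right-skewed, and differ across participants and sessions; the generator's
single gap-independent truncated normal produces a much flatter rPT density
than real data. Two consequences matter for interpreting the tests. First,
low-rPT coverage is dense, so the chance band is narrow there and transient
band crossings occur — one reason the dip classification requires the
permutation test to agree. Second, in the 120-ms SOA condition the rPT
distribution shifts left and the 900–1,000-ms bins hold only straggler
trials; under the fair-coin null the degree-2 boundary fit occasionally
swings low at the right edge, which inflates the one-sample p-value for that
condition (to about 0.01 where the dense-coverage single-SOA equivalent
reaches 1/1001). This is a boundary-variance property of the degree-2
local fit under this RT law, not of the dip itself; the dip-detection checks
therefore use the single-SOA design, and the SOA-split analysis reports its
own honest values. Passing tests demonstrate correctness of the machinery
and recoverability of known ground truth under these conditions — not that
real data meet them.

## Problem sizes used in the checks

Design counts are verified on complete 6-participant builds. Phenomenology
checks run at full single-experiment scale (35,640 simulated trials,
1,000 permutations per test). The calibration study uses 200 replicate
datasets of ≈2,000 trials with 199 permutations each. Exhaustive-enumeration
equivalence uses 12-trial (924 relabelings) and 10-trial (1,024 coin
vectors) instances with wider spans and degree 1, where every relabeling
remains smoothable.

## Known limitations

* The analysis aggregates across participants by design (the tachometric
  analysis needs very large trial counts); there is no random-effects layer.
* The smoothed curve is only evaluated inside the observed bin range under
  the default surface; no extrapolation is attempted at the window edges.
* The band's `n_local` depends on the smoothing span; it is an effective
  count, not an independent-sample size, so the band is approximate by
  construction.
* `exp2` differs from `exp1` only in its observer asymptote; stimulus-level
  differences (colors vs letters) are outside the generator's scope, as are
  eye movements and stimulus rendering.
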