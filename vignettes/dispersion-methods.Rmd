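---
title: "Quantifying intra-individual variability in operant behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-individual variability in operant behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operantiiv)
library(dplyr)
```

## The problem

Subjects with attention-deficit/hyperactivity phenotypes are not just
more active, more impulsive or less attentive on average — their
behavior is more *inconsistent* from moment to moment. This
within-subject inconsistency (intra-individual variability, IIV) is a
phenotype in its own right, distinct from the between-subject
differences that ordinary group comparisons measure. `operantiiv`
quantifies IIV in operant-conditioning data: rats pressing levers for
water reinforcement on a variable-interval (VI) schedule, with every
lever press, door opening and reinforcer time-stamped by the chamber
controller.

## The dispersion statistic

A session of duration $T$ (default 5400 s) is partitioned into $J$
equal half-open segments (default $J = 5$, 1080 s each; an event
exactly on a boundary belongs to the later segment, so the segments
partition $[0, T)$). For rat $i$ with per-segment counts $X_{ij}$ of
some trait, the session's **phenotypic dispersion** is the mean
absolute deviation

$$
\mathrm{PD}_i \;=\; \frac{1}{J}\sum_{j=1}^{J}\,\bigl|\,X_{ij}-\bar X_{i}\,\bigr|,
\qquad \bar X_{i} = \frac{1}{J}\sum_j X_{ij},
$$

one value per rat per session per trait (`pd_session()`,
`dispersion_table()`). The plain divisor $J$ is used — this is the
average of absolute deviations, not an $n-1$-corrected estimator. The
statistic is zero exactly when all segments are equal, is invariant to
permutation and translation of the segment values, and scales like
$|c|$ under multiplication by $c$; the test suite asserts all three
symmetries against a brute-force implementation at $10^{-12}$ relative
tolerance. Dispersion is computed on raw counts, not rates: segment
durations are equal, so the two differ by a constant factor only.

For the within-session trend analysis a segment-resolved companion is
needed: one dispersion-like value per rat per *segment*. We define it
as $|X_{ij} - \bar X_i|$ averaged over sessions
(`segment_deviation_table()`). Averaging these over segments recovers
the rat's mean per-session $\mathrm{PD}_i$, so the two views are
algebraically consistent (a tested invariant). This is a deliberate
interpretive choice: a session-level average cannot also be
segment-resolved, and this is the only reading that yields one value
per segment while preserving the session-level totals.

Sessions here have five 18-minute segments. The segment count and
duration are configurable through `session_structure()` rather than
hard-coded, because descriptions of this design vary (six-minute bins
are sometimes used); the default follows the explicit five-segment
session description, and all statistics are parameterized by
`n_segments`.

## Trait operationalization

Three traits are extracted per segment (`extract_traits()`):

* **Impulsiveness** — correct lever presses whose inter-response time
  (IRT, the time since the previous *correct* press of the same
  session) is defined and below 0.67 s. Incorrect presses neither
  carry an IRT nor reset the clock; the first press of a session has
  no IRT and is never impulsive; IRTs never span sessions, but segment
  boundaries are not breaks — a press pair straddling a boundary
  yields an IRT credited to the later press's segment (events belong
  where they occur).
* **Hyperactivity** — total lever presses (correct + incorrect by
  default; `hyperactivity_levers = "correct"` restricts it), *minus*
  the impulsive presses. This short-IRT exclusion decouples the
  activity measure from burst responding: without it, the dispersion
  of hyperactivity and impulsiveness would partly count the same
  events. With the exclusion on, impulsiveness + hyperactivity equals
  total lever presses in every segment — an identity asserted on all
  simulated data. The exclusion can be disabled
  (`short_irt_exclusion = FALSE`); a test demonstrates that disabling
  it raises the across-rat correlation between the two traits'
  dispersions when only burst propensity varies.
* **Inattention** — incorrect openings of the reinforcer-cubicle door
  (openings with no water present). Correct-door and reinforcer events
  are parsed and retained but feed no statistic.

Every rat-session observed in the event stream contributes exactly
$J$ rows, with explicit zeros for empty segments — dispersion of a
quiet session is a meaningful 0, not a missing value.

## Inference

Dispersion distributions are strongly right-skewed, so the strain
comparison (`compare_strains()`) avoids normality assumptions on the
raw scale:

* **Kruskal–Wallis** rank test on dispersion, by default on per-rat
  session-averaged values — one value per rat, not per rat-session, so
  rats are the independent units and sessions are not pseudo-replicated
  (`kw_unit = "rat_session"` exposes the laxer unit). With two groups
  the tie-corrected $H$ is $\chi^2_1$-distributed under the null; the
  all-tied input, where the tie-correction denominator vanishes, is
  defined as $H = 0, p = 1$.
* **Linear model on log dispersion**: $y = \log(\mathrm{PD}_i + 1)$,
  averaged per rat, then a one-way model $y \sim \text{strain}$,
  giving the strain $F$ test with $(1, N-2)$ df and fitted strain
  means with pooled-$t$ 95% CIs, reported on the log and
  back-transformed scales. The offset of 1 is needed because constant
  sessions give $\mathrm{PD}_i = 0$ exactly; it is configurable
  (`log_offset`) and echoed in every result object.
* **Variance proportion** $\eta^2 = SS_{\text{between}}/SS_{\text{total}}$
  from the same per-rat log-averages — the fraction of dispersion
  variance attributable to strain.

Temporal structure is tested with univariate repeated-measures ANOVA,
rat as subject (`aov` with an `Error(rat)` stratum), on
log-transformed values, without a sphericity correction (the classical
univariate test; with $J = 5$ levels and these sample sizes the
correction changes little, and the uncorrected test is what the
simulation calibration checks):

* `among_sessions_model()` — between factor strain, within factor
  session day (categorical), plus their interaction: does dispersion
  drift across days, and differently by strain?
* `within_sessions_model()` — the same machinery on the
  segment-deviation table: does dispersion drift across segments
  within the session?

Both models also report per-strain (and pooled) linear slopes of
dispersion on the session/segment index. The slope machinery treats
the rat as the repeated unit: one ordinary-least-squares slope per
rat, then mean, $SE = sd/\sqrt{n}$ and a two-sided $t$ test across
rats — a paired-style summary that needs no mixed-model assumptions.
Within-session slopes are reported on the raw count scale by default
(counts per segment; `slope_scale = "log"` switches), because that is
the natural reporting scale for trend magnitudes; among-session slopes
are on the log scale, matching the model they accompany. If every rat
shares one exact slope the SE is 0; the p-value is then reported as
`NA` with a warning rather than 0.

Two-sided p-values are used throughout and no multiple-testing
correction is applied across the three traits; the traits are
complementary descriptions, not a family of interchangeable
hypotheses.

## The synthetic generator

No raw dataset accompanies the design this package targets, so
`simulate_experiment()` generates event streams with the statistical
structure the analysis assumes. Defaults reproduce the canonical
design: 16 SHR-like and 15 WKY-like rats, five daily 90-min sessions,
VI 180 s.

The generative mechanism, per rat:

1. A rat-level log-rate effect $a_i \sim N(0, \sigma_{\text{rat}}^2)$,
   drawn once.
2. Per session segment $k$ (0-based), a multiplicative disturbance
   $m_{k} = \exp\!\bigl(N(0, \sigma_k^2)\bigr)$ with
   $\sigma_k = \max(0,\ \sigma_{\text{seg}} + \delta k)$. The level
   $\sigma_{\text{seg}}$ (`segment_dispersion_sd_log`) is the IIV
   knob — it is what downstream $\mathrm{PD}_i$ detects — and $\delta$
   (`dispersion_trend_per_segment`) is the within-session trend knob.
3. Lever presses as a renewal process whose IRTs come from a
   two-component exponential mixture (`r_irt_mixture()`): with
   probability `burst_prob` a short burst IRT (mean < 0.67 s),
   otherwise a long IRT whose mean is solved so the mixture mean
   equals $60/\text{rate}$ — the marginal press rate is thus matched
   regardless of burstiness. If the solved non-burst mean would fall
   below 0.67 s (very high target rates), both component means are
   rescaled proportionally instead, preserving the target mean while
   keeping the components on opposite sides of the impulsiveness
   threshold. Each press lands on the wrong lever with probability
   `incorrect_lever_frac`; wrong-lever presses are on extinction (no
   scheduled consequence).
4. Incorrect door openings as a Poisson process at
   `incorrect_door_rate` times the same segment multiplier — so door
   and lever dispersion share the segment-level disturbance, as they
   would for a rat whose arousal fluctuates.
5. A VI schedule: after each reinforcer, the next availability is an
   exponential wait of mean `vi_mean_s` clipped to
   $[1\,\text{s}, 3 \times \text{mean}]$ (the clip avoids degenerate
   near-zero intervals and unrealistically long droughts); the first
   correct press at or after availability fires a `reinforcer` event
   and, after a log-normal latency (median 1.5 s, log-SD 0.4), one
   `correct_door` event. These reinforcement events affect no
   statistic; they make the streams structurally complete.

Each rat runs on its own RNG substream, derived by hashing the
(seed, strain, rat) triple through Lehmer-style multiplicative rounds
modulo $2^{31}-1$: identical seed and configuration give bit-identical
event tables, and adding rats to a strain leaves existing rats'
streams untouched. The caller's RNG state is restored on exit.

The shipped presets (`shr_like_params()`, `wky_like_params()`, also in
`inst/extdata/default-sim-config.yml`) encode the qualitative contrast
the analysis should detect — the SHR-like strain has a higher press
rate (18 vs 10 per min), more burst responding (0.35 vs 0.15), more
incorrect door openings (3 vs 0.8 per min), larger segment-level
dispersion (0.35 vs 0.15 log-SD) and a positive within-session
dispersion trend (+0.04 vs −0.02 per segment). These are design
choices for a plausible preparation, **not** estimates fitted to any
published table; the package claims directional and structural
emulation only.

### What the generator does and does not emulate

It reproduces: burst-like IRT structure straddling the 0.67 s
threshold, strain differences in level and in segment-to-segment
dispersion, a strain-specific within-session dispersion trend,
VI-schedule reinforcement bookkeeping, and count-valued traits with
realistic magnitudes. It deliberately omits: learning/acquisition
dynamics across days (no among-session trend is injected),
satiety/warm-up within sessions beyond the dispersion trend,
post-reinforcement pausing, and any contingency on the wrong lever.
Passing simulation tests therefore show that the pipeline detects the
injected structure at realistic sample sizes — they cannot show that
real rats contain no structure the generator lacks.

## Calibration by simulation

The acceptance suite measures operating characteristics at the
canonical design (16 + 15 rats, five sessions), with a moderate
baseline parameter set (8 presses/min, burst probability 0.2,
segment log-SD 0.2, 1 door opening/min):

* **Type-I error**: 500 experiments with identical strain parameters;
  the per-trait Kruskal–Wallis rejection rate at $\alpha = 0.05$ must
  fall in $[0.03, 0.07]$. (The exact level of the $\chi^2$ cutoff at
  $n = 16/15$ is 0.0494.)
* **Dispersion-difference recovery**: doubling one strain's segment
  log-SD (0.2 → 0.4) must give that strain the higher mean dispersion
  in ≥ 95% and a rank-test rejection in ≥ 80% of 200 experiments, for
  every trait.
* **Trend-sign recovery**: injecting a positive within-session
  dispersion trend (+0.06/segment) in one strain must yield a positive
  fitted slope for that strain in ≥ 90% of 200 experiments, while the
  flat strain's slope stays non-significant in ≥ 90%.
* 10,000-replicate null calibration of the rank test alone, oracle
  equivalence of the dispersion kernel (1000 inputs, $10^{-12}$) and
  of $\eta^2$ (100 datasets, $10^{-10}$), the trait-accounting
  identity on simulated streams, and bit-level determinism of the
  full pipeline from seed to report.

These problem sizes keep the full suite to a few minutes on one core
while leaving the binomial noise of each rate estimate well inside its
acceptance band.

## Numerical and edge-case policy

* Dispersion requires ≥ 2 finite segment values; fewer is an error,
  not an `NA`.
* A missing segment row is an error naming the rat and session —
  silent imputation would bias dispersion downward.
* Event times live in the half-open $[0, T)$; a time equal to the
  session duration is rejected at parse time with its line number.
* Ties in event time are kept in file order (stable sorts
  throughout), making IRT computation deterministic.
* `strain` is an open label set — the generator and trait/dispersion
  stages accept any number of groups; the inference functions enforce
  exactly two, matching their contracts.

## Limitations

Printed historical estimates for this preparation (specific $\chi^2$,
$F$ and mean values) are not reproducible from first principles
because no raw dataset is available; this package reproduces the
*qualitative* findings (direction and detectability of strain
differences and trends) under its own generator. The repeated-measures
ANOVA is the classical univariate form without sphericity correction;
with strong non-sphericity its within-subject p-values are
approximate. The per-rat-slope summary weights rats equally regardless
of their residual variance, which is robust but not efficient.
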