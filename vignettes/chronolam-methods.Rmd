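---
title: "Methods: chronobiological analysis of beam-break activity recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chronobiological analysis of beam-break activity recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronolam)
```

# The problem

Small insects such as *Anopheles* mosquitoes are monitored for spontaneous
locomotor activity in tube-based infrared activity monitors: every time the
animal crosses the beam, a count is registered, and counts are accumulated
per minute over about a week. The resulting "activity score" series carry a
rich chronobiological signal: entrained daily rhythms under a light:dark
(LD) cycle, free-running circadian rhythms under constant darkness (DD),
secondary ultradian components, and between-individual differences
(chronotypes) that shift with physiological state — insemination and blood
feeding in the case of mosquito females. `chronolam` implements the full
analysis chain for such recordings: parsing and QC, chi-square
periodograms, rhythmicity classification, chronotype barcoding with Shannon
diversity, activity endpoints, and group-level inference, together with a
generative simulator used to validate every estimator against known ground
truth.

# Time conventions

Clock time is mapped to Zeitgeber time (ZT, under LD) or circadian time
(CT, under DD) by `to_reference_time()`. The package anchors ZT0 at lights
off (18:00 by default, so lights on at 06:00 is ZT12); some laboratories
anchor ZT0 at lights on instead, and `light_schedule(zt0_anchor =
"lights_on")` flips the convention. The default schedule is LD 12:12 with
1-h linear twilight ramps: dusk 17:00-18:00 and dawn 05:00-06:00, leaving
11 h of full light and 11 h of full darkness. DD keeps the same nominal
clock anchors so that "subjective" dusk remains defined.

Timestamps are treated as naive local clock times (no daylight-saving
arithmetic); monitor files are parsed with a fixed English month table so
results do not depend on the session locale.

# Quality control

Three filters are applied before any analysis, in `apply_cohort_filters()`
and `trim_days()`:

* **Day trimming.** The first recording day is an acclimation period and
  the last a period of declining activity; both are removed. Days are
  counted as consecutive 24-h blocks from the first reading, since
  recordings start mid-day; a trailing partial block is discarded with the
  last day. Seven recorded days yield five analysis days, labelled 2-6.
* **Dead rule.** An individual showing 24 h of continuous inactivity (a run
  of 1440 consecutive zero minutes) is considered dead and discarded. The
  rule is evaluated on the *untrimmed* series, so a death during the final
  day still removes the individual; whether the boundary days should count
  is genuinely open, and the stricter pre-trim choice is deliberate and
  logged in the QC report.
* **Controls and sperm checks.** Empty control tubes are removed (flagged
  as potential artifacts when they carry counts), as are inseminated-arm
  females whose post-hoc sperm check failed.

# The chi-square periodogram

`chi_square_periodogram()` computes the Sokolove-Bushell statistic. Counts
are re-binned to 5-min bins (the 1-min recording is noisier than the
statistic needs; the bin is configurable) and, for each trial period of
`K` bins, the first `N = floor(T/K)` complete cycles are folded into an
`N x K` array. With column means `M_h` and grand mean `M`,

$$ Q_p = \frac{N^2 K \sum_h (M_h - \bar M)^2}{\sum_i (x_i - \bar M)^2} $$

which is asymptotically $\chi^2_{K-1}$ under the null of no rhythm at that
period. The incomplete final cycle is truncated because the statistic
assumes complete rows. `Q_p` is invariant under shifting or positively
scaling the counts, and the implementation is verified against a naive
double-loop evaluation of the same formula to $10^{-10}$.

**Multiplicity.** The period grid (default 5-32 h in one-bin steps, about
325 trial periods over five days) is scanned with a Bonferroni-corrected
threshold at family-wise $\alpha = 0.05$ by default. Chronobiology
software often tests each period at uncorrected $\alpha = 0.05$;
`correction = "none"` restores that convention. Under the default, i.i.d.
noise series are called rhythmic in well under 7% of cases (checked on 500
simulated individuals).

**Calls.** An individual is *arrhythmic* when no trial period anywhere in
the scanned range is significant — arrhythmic individuals therefore carry
the all-zero chronotype barcode. Among significant peaks (one per
contiguous super-threshold run, at the run's maximum of
$Q_p - \text{threshold}$), the *fundamental* free-running period $\tau$ is
the peak inside the acceptance window 21-25 h ($23 \pm 2$ h, the plausible
range for *Anopheles*) with the largest margin; ties go to the shorter
period. A rhythmic individual whose circadian-band peaks all fall outside
that window (e.g. a lone 27.5-h component) is flagged *atypical*, carries
no fundamental, and is excluded from period-length analyses. The atypical
band is 19-29 h by default, excluding peaks that map to a canonical
secondary period; the bounds are configurable because no sharp definition
exists.

# Chronotype barcodes and diversity

Secondary periodic components at 6, 8, 12, 16, 18, 20 and 30 h are scored
present when a significant peak lies within ±0.5 h of them
(`map_to_canonical()`; nearest assignment, ties to the shorter period —
at the default tolerance a tie cannot arise, but wider tolerances make the
rule observable). The per-individual *barcode* is the ordered 8-bit vector
of these seven flags plus presence of the fundamental.

`shannon_diversity()` computes $H = -\sum_k p_k \ln p_k$ over the
frequencies of *distinct barcodes* within a group — combinations, not
per-period marginals, so `H` measures how heterogeneous a group's
chronotype repertoire is. Natural logarithms are the default (group-level
values of 1-2 nats are typical at group sizes of 14-36); a `base` switch
is provided. Arrhythmic individuals are included as the all-zero barcode
class.

# Activity endpoints

* **Nightly activity** (`nightly_activity()`): 5-min sums over the night
  window 16:00-07:00 (ZT10-ZT1), 180 bins per night; partial nights at the
  series edge are omitted and reported. Nights are labelled by the day
  they start.
* **Onset of activity** (`onset_time()`): the first minute in the dusk
  search window from which the individual scores at least one beam break
  per minute for three consecutive minutes. The search window is
  17:00-19:30 — from the start of the artificial dusk ramp through the end
  of the peak window, since onsets can be delayed past lights-off in some
  groups; the upper bound is a package choice and configurable.
* **Peak time** (`peak_time()`): the clock minute of the maximum 1-min
  count within the dusk peak window, 17:30-19:30 under LD and 16:30-19:30
  under DD (the free-running peak drifts earlier). Ties resolve to the
  earliest minute; an all-zero window yields a missing value. Missing
  onsets and peaks propagate as missing values, never zeros.

# Group statistics

* **Rhythmicity composition**: `williams_g_test()` computes the
  likelihood-ratio G statistic with Williams' correction,
  $G_{adj} = G/q$, referred to $\chi^2_{(r-1)(c-1)}$.
* **Nightly activity** (`rate_ratio_nightly()`): per-5-min counts are
  modelled with a log-link negative-binomial regression on group
  (dispersion by maximum likelihood, Poisson fallback when the dispersion
  estimate diverges, which is logged in the method tag). Because the
  single-factor log-link MLE of the rate ratio is the ratio of group mean
  counts, the 95% CI is obtained by a cluster bootstrap that resamples
  individuals within group and recomputes that ratio — this respects the
  repeated-measures structure without a mixed-model engine, and is the
  package's deliberate simplification of random-slope GLMMs with
  Tukey-adjusted marginal means: the estimand (RR) is preserved, the
  machinery is not. Every result carries its method tag, bootstrap size
  and seed.
* **Period lengths** (`compare_periods()`): least-squares cell-means fit
  of $\tau$ on meal x insemination, pairwise mean differences with t-based
  CIs and Holm-adjusted p-values. LD and DD are analysed separately.
* **Onset** (`compare_onset()`): two-stage — per-individual mean onset
  across days, then a group contrast with a percentile bootstrap over
  individuals, reported in minutes of delay.

# The synthetic actogram generator

`simulate_cohort()` emulates the data structure the analysis assumes, with
full ground truth. The expected rate (counts/min) of a rhythmic individual
is

$$ \lambda(t) = b\,\bigl[1 + A_{dusk} e^{-\Delta t_{dusk}/s}
  + A_{dawn} \mathbf{1}_{LD}\, e^{-\Delta t_{dawn}/s}
  + (P - 1)\,\mathbf{1}_{scoto}\bigr]\cdot \text{supp}(t) $$

with one-sided exponential dusk/dawn bursts and a night plateau. Under LD
the anchors recur every 24 h at the schedule's clock times; under DD the
dusk anchor recurs every $\tau$ hours (so it drifts earlier each
subjective day when $\tau < 24$) and the dawn burst is absent, making LD
profiles bimodal and DD unimodal. The dusk anchor is shifted by the onset
delay $\delta$; the subjective scotophase in DD is the half-period
following each dusk anchor. Counts are negative-binomial around
$\lambda(t)$ (size parameter 2 by default; `Inf` gives Poisson), because
beam-break counts are overdispersed.

Defaults were fixed once as the study conditions the package is tested
under: 7-day recordings starting mid-day (13:00); daytime baseline
$b = 0.05$ counts/min (daytime activity is near-nil in this system); dusk
burst $A_{dusk} = 60$ decaying with $s = 30$ min (a burst lasting 1-2 h
that dominates the actogram); dawn burst $A_{dawn} = 30$ (LD only); night
plateau $P = 10$ (0.5 counts/min of sustained night activity); DD
free-running period $\tau \sim N(23, 0.3^2)$ h truncated to 21-25 h;
blood-fed groups suppressed to 0.2 of their rate for 72 h, then linearly
recovering over 24 h (the ramp length is a package choice — only the 72-h
horizon is anchored in mosquito physiology); inseminated groups delayed by
$\delta = 4$ min; arrhythmic probability 0.03, elevated to 0.25 for
inseminated DD groups; 25 individuals per group in the 2 x 2 x {LD, DD}
factorial. Arrhythmic individuals emit flat baseline activity.

Monitors hold up to 30 experimental channels plus two all-zero control
tubes and never mix light regimens; `simulate_cohort(dir = ...)` writes
monitor files, channel metadata, ground truth and the study configuration
for exact re-runs.

**What the simulator does and does not emulate.** It reproduces the data
*structure*: grid, dialect, burst phenomenology, free-run drift, blood
suppression, onset delays, arrhythmic subpopulations, overdispersion.
It does not model burst amplitude in physical units (the source
observations are figure-level), activity decay with age, temperature or
humidity covariates, or within-individual autocorrelation beyond what the
intensity function induces. Passing parameter-recovery tests therefore
demonstrates estimator correctness under the stated generative model, not
performance on any particular real colony.

# Numerical choices and problem sizes

Degenerate constant series yield a flagged all-zero periodogram rather
than NaNs. Periodogram trial periods need at least two complete cycles.
The bootstrap CIs are percentile intervals; p-values for bootstrap-based
contrasts use a normal approximation on the log (RR) or raw (onset) scale.
Validation experiments in the test suite use: 200 random series against
the brute-force periodogram oracle; 500 noise-only individuals for the
false-positive calibration; 20 individuals for DD period recovery; 25 per
group for onset recovery; and 100 replicates x bootstrap size 200 for
rate-ratio CI coverage — sizes chosen to make Monte-Carlo error small
relative to each tolerance.

# Known limitations

* The negative-binomial + cluster-bootstrap route gives slightly
  different (typically wider) intervals than a random-slope GLMM would;
  it trades efficiency for robustness and simplicity.
* The periodogram's Bonferroni correction is conservative for the highly
  correlated neighbouring trial periods; power at short series lengths
  suffers accordingly.
* Diversity indices are not rarefied; groups of very different sizes
  should be compared with care.
* Onset detection is threshold-based and will register pre-dusk bursts of
  activity as onsets if they meet the 3-min rule within the search window.
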