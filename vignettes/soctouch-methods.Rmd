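---
title: "Modeling cortical single-unit activity during social facial touch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cortical single-unit activity during social facial touch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soctouch)
```

## The problem

During naturalistic social facial touch, rats repeatedly align snouts and
palpate each other's faces. The behavior has no imposed trial structure:
touch episodes have a median duration of about 1.33 s but span two orders
of magnitude, and inter-touch intervals (median about 4.68 s, IQR spanning
1.2--24 s) are often as short as the touches themselves, so classical
PSTH analysis mixes "baseline" windows that are contaminated by adjacent
touches with post-stimulus windows that mix very different touch
durations. `soctouch` implements a point-process regression treatment of
this problem, the population-level analyses built on top of it, a spiking
microcircuit simulation of candidate neuromodulatory mechanisms, and
spike-shape classification of units into putative excitatory/inhibitory
classes. Because raw recordings of this kind are rarely deposited, the
package ships calibrated generators that produce sessions with the
behavioral and spiking statistics the analysis assumes; every stage is
exercised against synthetic data with known ground truth.

## The point-process model

Spike trains are discretized into 1-ms bins (`binSpikes()`); bins whose
centers are more than 5 s from the nearest touch episode are dropped from
the likelihood (`trimBaseline()`). Counts in retained bins are modeled as
Poisson with rate

$$\lambda_i = \exp(P_i \cdot \beta),$$

where the row $P_i$ contains a constant, eleven spike-history terms
(counts in the five preceding 1-ms bins and in six 25-ms windows covering
the preceding 5--155 ms, capturing refractoriness and burstiness),
$n_\mathrm{rec}-1$ recording-block indicators (baseline drift between
recordings), a touch indicator, and optionally a partner-sex indicator.
The full log likelihood (including the $\sum_i y_i\log\Delta -
\sum_i\log y_i!$ constants, so model variants are comparable on an
absolute scale) is maximized by Newton iterations with step-halving; the
Poisson log-link likelihood is concave, so the optimum is global. The
convergence rule accepts either a small score (relative tolerance
`1e-8`) or a stalled likelihood; the latter occurs when a history column
separates (no spike pair at some lag), which drives that coefficient to a
plateau without affecting the touch and sex terms.

Two details are worth flagging.

* **History across trimmed gaps.** History features are computed on the
  original timeline: spikes inside trimmed spans still feed the history
  of retained bins (the spikes existed); only the likelihood rows of
  trimmed bins are dropped. The alternative -- pretending trimmed spans
  are silent -- fabricates refractory evidence.
* **The sex column is gated by touch.** A per-bin indicator that is 1
  during touch episodes with a male partner and 0 otherwise. The source
  material is ambiguous between this and a recording-constant partner-sex
  column; with one partner per recording block, a block-constant column
  lies exactly in the span of the recording indicators, making
  $\beta_\mathrm{sex}$ unidentifiable. The touch-gated form is also the
  one under which the fold-modulation formulas are exact: female-touch
  modulation $= e^{\beta_\mathrm{touch}}$, male-touch modulation
  $= e^{\beta_\mathrm{touch}+\beta_\mathrm{sex}}$, both against the
  baseline $e^{\beta_0}$. Sex is coded 0 = female, 1 = male.

## Shuffle nulls and unit classification

Touch significance compares the touch-only model's log likelihood with
models refitted after circularly permuting the touch column along the
retained-bin axis (preserving episode durations and autocorrelation), with
shifts of at least 1 s. The p value is the plus-one permutation estimate
$(1+\#\{LL_\mathrm{shuf}\ge LL_\mathrm{obs}\})/(n+1)$.

Sex significance permutes the male/female labels at the partner-animal
level (each partner keeps one label across all its episodes). Because a
session has few partners, the assignment space is small; the test
enumerates the distinct non-identity assignments and caps the number used
at the combinatorial maximum, drawing without replacement when the space
exceeds the requested count. Re-drawing the same few assignments with
replacement would fabricate precision the design cannot support and
badly inflates the false-positive rate (verified during development).
A consequence worth knowing: with the minimal 2+2-partner design there
are only $\binom{4}{2}-1 = 5$ non-identity assignments, so the p value
saturates at $1/6$ and a sex-touch call at $\alpha = 0.05$ is impossible;
about 8 partners (70 assignments) are needed before the nominal 5% level
is meaningful.

Units are labeled `sex_touch` if $p_\mathrm{sex} < 0.05$, `touch` if
$p_\mathrm{sex}\ge 0.05$ and $p_\mathrm{touch} < 0.05$, else
`nonsignificant`.

## Information per spike

Over a stimulus-category set (baseline plus per-partner touch episodes, or
baseline/female-touch/male-touch), with occupancy probabilities $p_i$ and
category rates $\lambda_i$ (estimated as total spikes over total occupancy
time),

$$I_\mathrm{per\,spike} = \frac{1}{\lambda}\sum_i \lambda_i
\log_2\!\frac{\lambda_i}{\lambda}\,p_i, \qquad
\lambda=\sum_i p_i\lambda_i,$$

with $0\log 0 := 0$. Algebraically this equals the Kullback--Leibler
divergence between the spike-triggered category distribution and the
occupancy distribution; it is bounded by $\log_2(1/\min_i p_i)$, not by
the entropy of the occupancy distribution (a rare category with a high
rate can yield several bits per spike). Significance uses circular shifts
of the category timeline (occupancies are shift-invariant). The
sex-versus-identity comparison computes, per unit, the information over
the three situations minus its value under partner-label permutations and
fits `deltaI ~ 1 + (1 | unit)` (repeated shuffles per unit are
dependent); with one observation per unit this degenerates to a paired
one-sample t test, which is then used directly.

## Population geometry: bias versus potentiation

Per unit, the touch+sex fit yields female and male fold modulations.
After removing units with more than a 32-fold change on either axis, the
mixed model

`male ~ 1 + female + subjectSex + female:subjectSex + (1 | subject)`

is fitted by REML on the log2 fold-change scale (symmetric for increases
and decreases, matching the 32-fold filter; the ratio scale is
selectable). A slope CI excluding 1 indicates potentiation (responses to
one partner sex scaled in magnitude); an intercept CI excluding 0
indicates bias (an additive shift). Area-wise label proportions are
compared with a chi-square test plus standardized Pearson residuals;
female-versus-male modulations are summarized with tie-adjusted Kendall
correlations.

## Synthetic sessions

The generator is the analysis run forward. Durations and inter-touch
intervals are log-normal: the distributions are heavy-tailed across
orders of magnitude on a log axis, and a log-normal is the simplest law
matching the printed median and IQR (`meanlog = log(median)`,
`sdlog = (log q75 - log q25)/(2 \times 0.6745)`); no distributional form
is prescribed by the source material, only these quantiles. Episodes are
tiled into blocks (one partner per block, cycling the partner list) by
alternating interval and duration draws. Spike trains are simulated bin
by bin from the same predictor encoding the fitter uses -- a single
source of truth that precludes encode/decode mismatch -- with Poisson
counts of mean $\Delta\exp(\eta_i)$. Default unit: 5 spikes/s baseline
and a relative refractory profile on the five 1-ms history terms
(`-4, -2, -1, -0.5, -0.2`), window terms zero.

Null-calibration sessions (for the type-I checks) use a densified timing
law (interval median 3 s, log-sd 0.6; duration median 1.33 s, log-sd
0.5). The paper-calibrated law has a *mean* inter-touch interval of about
51 s (heavy tail), so populating 8 partners with episodes would need
roughly 20-minute sessions per null unit; the densified law keeps null
sessions near 100 s with every partner observed, while leaving rates,
model structure and the shuffle machinery untouched. The population-table
generator draws female-side modulations from a centered normal (sd 1 in
log2 units) and builds male-side modulations with configurable bias,
slope, subject-sex effect, interaction, per-subject intercepts (sd 0.1)
and residual noise (sd 0.3) -- magnitudes in the range of the fold
changes the single-unit model produces.

What the generators do *not* emulate: correlated noise across units,
slow nonstationarities within a block, overlapping multi-partner bouts,
imperfect spike sorting, and individual-partner (as opposed to
partner-sex) rate structure unless constructed explicitly. Passing tests
therefore certify the statistical machinery, not robustness to these
real-data complications.

## The microcircuit

Eight cortical leaky integrate-and-fire populations (excitatory and
inhibitory pairs of layers 2/3, 4, 5, 6; 77,169 neurons at full scale)
plus 902 thalamic inputs. Pairwise synapse counts follow
$K = \log(1-p_\mathrm{conn})/\log(1-1/(N_\mathrm{pre}N_\mathrm{post}))$;
synapses are assigned uniformly with replacement (multapses and autapses
permitted). Membrane and exponential-synapse dynamics are integrated
exactly (per-step propagators of the linear system) at 0.1-ms steps;
threshold $-50$ mV, reset/leak $-65$ mV, $\tau_m = 10$ ms, $C_m = 250$
pF, 2-ms refractory clamp, $\tau_\mathrm{syn} = 0.5$ ms. Excitatory
weights are Normal(87.8, 8.8) pA (L4e to L2/3e doubled; redrawn if
non-positive), inhibitory weights $-4\times$ the excitatory draw; delays
Normal(1.5, 0.75) ms (excitatory, thalamic included) and Normal(0.8,
0.4) ms (inhibitory), truncated below at one step. Background drive is a
constant per-population current $b \times 0.3512$ pA. Trials are 1000 ms
baseline, 700 ms touch (thalamic rate 0 to 30 Hz), 300 ms post;
modulated and non-modulated trials alternate in one continuous
simulation. The two neuromodulations act only during the touch window of
modulated trials: the inhibitory reset/leak potential is raised by 0,
+0.5 or +1.0 mV, and the excitatory membrane time constant is scaled by
1.0, 1.1 or 1.2 (an input-resistance increase, which also amplifies the
background current, as physics requires). Ambiguities resolved here: the
typographically garbled L5e-to-L2/3i connection probability is taken as
0.0755 (the value consistent with the upstream microcircuit model;
either reading leaves the 0.3-billion synapse total unchanged at one
significant figure), and the inhibitory depolarization is confined to
the touch window, mirroring the explicit statement for the time-constant
manipulation; both are configurable.

**Desk scale.** The default scale is 0.1 (7,717 cortical neurons, about
30 million synapses) with in-degree preservation: per-pair synapse
counts scale with the target population so expected synapses per target
neuron -- hence single-neuron input statistics -- are approximately
invariant. Full scale is available by setting `scale = 1`.

**A known desk-scale limitation.** Per-neuron touch coefficients
$\beta = \log(r_\mathrm{touch}/r_\mathrm{base})$ estimated from 700-ms
count windows carry sampling noise of roughly $\mathrm{var} \approx
1/n_\mathrm{base}+1/n_\mathrm{touch}$ per condition. At scale 0.1 the
across-neuron spread of *true* coefficients (variance about 0.1) is
comparable to this noise at 10--20 trials per condition, so the ordinary
least-squares regression of modulated on non-modulated responses is
attenuated (slope below 1 even with modulation off -- the classical
errors-in-variables effect), and BIC tends to prefer the full model: the
attenuation itself manufactures a spurious intercept
$\bar{x}(1-\mathrm{reliability})$. Because both this intercept and the
residual variance shrink at the same rate with trial count, the BIC
preference is not fixable by feasible trial counts. The trial-level
permutation test is immune to this (modulated and non-modulated trials
are exchangeable under the null), and the directional effects are robust:
inhibitory depolarization lowers the regression slope well below the
null configuration's attenuation level (response potentiation), and the
time-constant manipulation changes responses detectably. At this reduced
scale the excitatory-resistance manipulation *suppresses* L2/3e while
boosting L4e/L5e/L6e, so its network-mean effect is not the uniform
upward shift seen at full scale; the package reports what its
simulations produce.

**Response-pattern selection.** From 2000 randomly sampled neurons
(excluding those with fewer than 3 spikes across trials or any
zero-count window), three least-squares models compare modulated against
non-modulated coefficients: bias (slope fixed at 1), potentiation (no
intercept), full. `BIC = n log(RSS/n) + k log(n)` with `k` the number of
free mean parameters; lowest BIC wins.

## Spike-shape classification

Mean waveforms are oversampled at twice the sampling rate by cubic
splines; features are the width at half of the peak amplitude (ms) and
the post-positivity, the trapezoid integral of the waveform 0.375--0.75
ms after the peak normalized by the peak voltage (reported per ms so the
value is order 1). Both are invariant to amplitude scaling. Features are
z-scored and a two-component full-covariance Gaussian mixture is fitted
by EM (k-means initialization; 0.1 added to the covariance diagonals on
the standardized scale each M-step -- the stated regularization,
interpreted additively). The thin-spiked component is labeled
`putative_I`; assignment is by posterior responsibility. When the
mixture degenerates (an effectively empty component), a single 2-d
Gaussian is fitted and cut through its mean along the shortest axis,
i.e., units are split by the sign of their projection on the
largest-variance principal axis; an exactly isotropic cloud leaves the
axis undefined (first principal direction used, with a warning). The
labels are "putative" deliberately: spike shape is a weak proxy for
cellular identity.

## Numerical choices and problem sizes

* Bins are half-open `[t, t + 1 ms)`, zero-based; times are seconds in
  double precision (the microcircuit uses ms/mV/pA/pF internally).
* Baseline trimming measures from bin centers to episode boundaries
  (center versus edge is unspecified in the source; centers are
  symmetric). The PSTH baseline window is -2500..0 ms by default with
  -2000..0 selectable, and the causal alpha kernel
  `f(x) = (x/tau) exp(1 - x/tau)`, `tau = 75` ms, peaks at 1.
* Newton tolerance `1e-8` (relative to total spikes); shuffle-test LL
  comparisons use a `1e-6` equality guard; permutation estimators use the
  plus-one form throughout.
* Test-suite problem sizes: 600-s sessions for coefficient recovery (20
  seeds); 200 null units per shuffle-test calibration on ~30--100-s dense
  sessions with 100 shuffles; 100 null units for the information
  statistic; 20 seeds per population regime; microcircuit grid at scale
  0.1 with 10+10 trials per configuration.
* Bit-reproducibility: R-side randomness follows `set.seed()`; the
  microcircuit uses its own splitmix64/Box-Muller streams (separate
  seeds for connectivity, initial state + thalamic spiking, and neuron
  sampling) so results do not depend on the C++ standard library's
  distribution implementations.

## Known limitations

* With only two partners per sex the sex-shuffle p value cannot fall
  below 1/6 (combinatorial limit of the partner-level permutation).
* The desk-scale microcircuit reproduces directional modulation effects
  but not the full-scale OLS/BIC response-pattern classification, for the
  attenuation reasons above.
* The log-normal behavioral law matches the printed medians and IQRs but
  is otherwise an assumption; bout structure beyond the interval law is
  not modeled.
* Information estimates use naive (plug-in) rates with no bias
  correction, as in the method being implemented; values on short
  sessions are upward-biased, which the circular-shift null accounts for.
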