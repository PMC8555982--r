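---
title: "Methods: analyzing economic choice under variable action costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing economic choice under variable action costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and the data model

`costchoice` analyzes behavior and single-neuron activity from a two-juice
economic choice task in which each offer carries an action cost. On every
trial a monkey sees two offers — a juice type (A or B), a quantity in
drops, and a binary saccade cost (low = short saccade, high = long
saccade) — placed on opposite sides of fixation. After a delay, two
saccade targets appear in opposite hemifields on small-radius (low cost)
and large-radius (high cost) rings, and the animal reports its choice with
a saccade. The spatial location of an offer is dissociated from the
saccade that obtains it, so the cost of an option is known before any
action can be planned.

A *trial* is one completed choice (`as_cc_trials()` validates the
structural invariants: complementary costs, opposite sides, a binary
hemifield for the target). An *offer type* is a pair of offers (e.g.
`1A+:3B-`); a *trial type* adds the choice (`enumerate_trial_types()`).
Target angle, when given, is reduced to a hemifield at ingestion; the raw
angle plays no further role. Analyses assume completed trials only —
aborted trials are expected to be removed upstream, and the previous-trial
indicators therefore refer to the previous completed trial.

# The behavioral choice model

Choices are fit per session by logistic regression (no intercept):

$$ P(\text{choose } B) = \frac{1}{1 + e^{-X}} $$
$$ X = a_0 q_B - a_1 q_A + a_2(\delta_{B,+} - \delta_{A,+})
     + a_3(\delta_{n-1,B} - \delta_{n-1,A})
     + a_4(\delta_{\mathrm{cost}B} - \delta_{\mathrm{cost}A})
     + a_5(\delta_{B,\mathrm{left}} - \delta_{A,\mathrm{left}})
     + a_6(\delta_{tB,\mathrm{left}} - \delta_{tA,\mathrm{left}}) $$

where the indicators mark, per juice: offered at low cost; chosen and
received on the previous trial; carrying the same cost as the previously
chosen offer; offered on the left; and its target in the left hemifield.
Dividing by the steepness $a_0$ expresses every effect in units of juice
B: relative value $\rho = a_1/a_0$, action cost $\xi = a_2/a_0$, juice
hysteresis $\eta = a_3/a_0$, cost hysteresis $\varphi = a_4/a_0$, and the
offer- and target-side biases $\delta = a_5/a_0$, $\varepsilon = a_6/a_0$.

Estimation (`fit_session()`) is plain unpenalized maximum likelihood via
iteratively reweighted least squares; the log-likelihood is concave, so no
multi-start is needed. Near-deterministic sessions (complete or
quasi-complete separation) produce diverging coefficients: these are
capped at ±50 and flagged `converged = FALSE`. A fitted $a_0 \le 0$ is
flagged as non-identifiable. First trials of a session have all
previous-trial indicators set to 0. `split_choice_pattern()` refits the
simplified model (only $a_0, a_1, a_2$) separately summarized by the cost
condition of juice A; the indifference ratio at the reference quantity
$q_A = 1$ is $\rho + \xi$ (A low cost) and $\rho - \xi$ (A high cost).

# The candidate-variable panel

`compute_variables()` evaluates 21 candidate decision variables per trial
(see `cc_variables()`), spanning juice-based (offer value A/B, chosen
juice), cost-based (offer value −/+, chosen cost), spatial (offer value
L/R, location indicators), and action-based (offer value target L/R,
chosen target location) reference frames, plus chosen value, value ratio,
spatial congruence and cost/benefit conflict. Offer values include the
action-cost term: offer value A $= \rho q_A + \xi \delta_{A,+}$, offer
value B $= q_B + \xi \delta_{B,+}$, with $\rho$ and $\xi$ taken from the
session's behavioral fit. Variables are computed once per trial and
reused across all time windows. A chosen value of 0 (possible only with
zero-quantity offers) makes the value ratio undefined; such trials are
excluded pairwise from regressions involving the value ratio only.

Two binary covariates accompany the panel: the chosen offer location and
chosen target location, coded 1 = contralateral to the recorded
hemisphere, which is supplied per session rather than inferred. By
convention juice B is the lower-valued juice ($\rho$ in units of B);
this is a labeling convention of the inputs, not something the code
infers.

# Windowed responses and the task-relatedness screen

Firing rates are computed in nine 0.5-s windows aligned to behavioral
events (`cc_windows()`, `window_rates()`); windows are half-open
`[start, start + 0.5)` so a boundary spike is counted exactly once. A
*response* is one neuron in one window as a function of the trial.

Each response enters two 3-way ANOVAs on trial firing rates — factors
(trial type × offer A location × target A location) and (trial type ×
chosen offer location × chosen target location) — main effects only, with
type-II sums of squares (each factor tested against the model containing
the other two). Main-effects-only type II decomposition was chosen
because the factor lists carry no interactions and pseudo-random
counterbalancing leaves mild imbalance. Trial-type levels with fewer than
2 trials are dropped; a factor constant in the session gets p = 1 with a
warning. A response is *task related* if any factor reaches p < 0.001 in
either ANOVA; only task-related responses enter the tuning analyses. The
screen is invariant to rescaling rates by a positive constant.

# Tuning classification by ANCOVA

Each task-related response is fit against every panel variable with the
*parallel lines* model: `rate ~ variable + group`, no interaction, where
the group is the chosen offer location for windows up to pre-target
(pre-offer included by the early convention) and the chosen target
location from post-target on. A variable *explains* the response if its
slope is significant (p < 0.05); the recorded $R^2$ is the total $R^2$ of
the two-regressor model, bookkept as 0 for non-explaining variables. The
interaction ("separate lines") model is deliberately out of scope.

Data points are per-(trial type × covariate level) mean rates, each cell
requiring at least 2 trials — matching how such responses are plotted and
fit against trial-type means; `level = "trials"` switches to trial-level
fitting (this affects p-values far more than the $R^2$ ordering).

The two location-only variables use the *horizontal lines* model
(`rate ~ group`). Because that group is one of the two regressors of
every parallel model on the same data points, the horizontal $R^2$ can
never exceed the $R^2$ of any explaining parallel fit — so a location-only
variable can provide the best fit only when it provides the sole
explanation. To preserve exactly this nesting in every window, the
horizontal model always uses the window's epoch covariate, and each
location-only variable is assessed in its matching epoch (chosen offer
location only in early windows, chosen target location only in late
windows); in the other epoch it is recorded as not explaining. The best
variable for a response is the explainer with the highest bookkept
$R^2$, with exact ties broken in panel-index order.

`count_matrices()` tallies, per (window, variable), the number of
responses explained (a response may count for several variables) and the
number best-fit (each response counts at most once), plus the split of
explained counts by group-effect significance.

# Variable selection

The *explanatory power* of a variable subset is the number of task-related
responses collectively explained by it, pooled across all nine windows.
Two procedures are provided:

* `stepwise_select()` picks, at each step, the variable with the highest
  number of best fits within any single time window (the maximum over
  windows; a sum-over-windows criterion is available), removes every
  response it explains, and repeats on the residual data. Selection stops
  when the marginal explanatory power of the would-be next variable falls
  below 2% of the task-related responses — the threshold is interpreted
  as a fraction so that it scales with population size; absolute counts
  are reported alongside. Count ties break by higher marginal power, then
  panel order.
* `best_subset_select()` enumerates all subsets up to `max_size` (≤ 8
  keeps enumeration tractable over 21 variables) and is therefore
  guaranteed optimal at each size. Equal-power ties prefer the subset
  whose members best-fit the most responses, then the smallest index set.

Because the panel variables are strongly correlated by construction (the
chosen value is always one of the two offer values; cost-frame values are
the juice values re-routed by the cost assignment), explained sets
overlap heavily and the cumulative coverage of optimal subsets saturates
quickly. Consequently the marginal-gain stop applied to the best-subset
trace can terminate at a smaller size than the stepwise procedure even
when both would select the same signals. The package therefore supports
the comparison protocol in which best-subset verifies the stepwise
result: `best_subset_select(tab, size = length(stepwise$selected))`
returns the guaranteed-optimal subset at the stepwise size, and agreement
of the two sets is the meaningful check. On synthetic populations built
from the five signals this protocol recovers exactly the generating set
(see the test suite); the standalone marginal-gain stop remains the
default and its trace is always reported.

# Dimensional integration of the chosen value

Two variants of the chosen value are compared per response
(`chosen_value_variants()`): *cost-affected* (the panel's chosen value,
including the $\xi$ term) and *cost-independent* ($\xi$ forced to 0). A
response qualifies as chosen-value coding only when **both** variants
explain it (p < 0.05, the assigned $R^2$ being the maximum of the two),
so that the test does not pre-favor either variant; responses where only
one variant explains are excluded and counted. Each qualifying response
contributes $\Delta R^2 = R^2_{\text{cost-affected}} -
R^2_{\text{cost-independent}}$, one value per qualifying window.
Responses aggregate into an early epoch (post-offer to pre-target) and a
late epoch (post-target to post-juice); the pre-offer window belongs to
neither. Per epoch the package reports mean and median $\Delta R^2$ and a
two-sided Wilcoxon signed-rank test against 0; the epochs are compared
with a Wilcoxon rank-sum test. With $\xi$ of realistic size the two
variants correlate above 0.99, so individual $\Delta R^2$ values are
small (order 0.01) and inference is population-level — matching the
magnitudes this analysis is known to produce.

# Population statistics

`session_param_tests()` reports per-parameter medians across sessions and
two-sided Wilcoxon signed-rank tests against 0 for $\xi, \eta, \varphi,
\delta, \varepsilon$ ($\rho$ is summarized by its median only). Tests are
exact for n ≤ 25 without ties and use the normal approximation with
continuity correction otherwise; sidedness is two-sided throughout
because the direction of the spatial biases is not constrained a priori.
`area_comparison()` contrasts encoding percentages between two areas per
(window, variable) with a Pearson chi-square on the 2×2 table (df = 1, no
continuity correction); expected cells below 1 trigger a warning and a
Fisher exact p alongside. Counts for the comparison area are user-supplied
inputs, never recomputed. No multiple-testing correction is applied
anywhere: the analysis uses raw thresholds (0.001 screen, 0.05 explain)
by design. `build_report()` assembles the factor-count table, the
explained/best-fit matrices, per-window encoding percentages, the epoch
summary and the behavioral tests, leaving explicit gaps for missing
stages.

# The synthetic generator

`generate_session()` draws sessions from the choice model itself:
offer types (default: eight pairs spanning quantity ratios 1:3 to 8:1
around indifference) and the eight cost × offer-side × target-side
configurations are assigned in shuffled counterbalanced blocks (every
configuration within ±1 of its expected count), and choices are drawn
sequentially so hysteresis indicators reflect the realized history.
Generating parameter defaults are the session medians this task family
produces: $a_0 = 2$, $\rho = 2$, $\xi = 0.27$, $\eta = 0.16$,
$\varphi = -0.008$, $\delta = -0.03$, $\varepsilon = 0.017$. The relative
value and steepness are not published quantities; $\rho = 2$ and
$a_0 = 2$ were fixed once as typical of two-juice sessions.

`generate_neuron()` mirrors the additive structure the parallel-lines
model assumes: per trial,
`rate = max(0, baseline + slope * variable + location_offset * covariate)`,
with the epoch covariate (chosen offer location early, chosen target
location late), and spike counts Poisson with mean `rate × 0.5 s`.
Untuned cells have slope 0; location-only cells have positive
`location_offset` only; mixed tuning is possible but not part of the
default recipe. The default population recipe mixes chosen-value
(slope 2 spikes/s per unit value), chosen-cost and chosen-juice (8
spikes/s steps), location-only (8 spikes/s offset) and untuned cells on
baselines of 4–5 spikes/s, yielding cell-level $R^2$ in the 0.6–0.9 range
typical of well-tuned cortical responses in this task.

What the generator does *not* emulate: trial-to-trial rate
autocorrelation, overdispersion beyond Poisson, drift, mixed selectivity
beyond one variable plus a location offset, and correlated noise across
neurons. Passing recovery tests on this synthetic population therefore
demonstrates correctness of the pipeline's bookkeeping and statistics
under the assumed model, not robustness to real-data pathologies.

# Numerical choices and problem sizes

* ANCOVA cells need ≥ 2 trials; value-ratio-undefined trials drop
  pairwise. Aliased or constant regressors make a variable non-explaining
  rather than erroring.
* Coefficient cap ±50 for separable sessions; likelihood evaluated with
  probabilities floored at machine epsilon.
* Best-subset enumeration is limited to subsets of size 8; beyond that the
  procedure errors with guidance rather than silently approximating.
* The test suite and the acceptance script simulate sessions of 250–1000
  trials and populations of ~50 neurons; recovery analyses use 56/85/141
  sessions to match the published session counts, with 1000-trial
  sessions keeping the Monte-Carlo error of across-session medians well
  below the printed precision of the target values.

# Known limitations

Hierarchical (pooled) behavioral fitting, probit links, interaction
ANCOVA models, information-criterion selection, sliding-window analyses
and spike-level preprocessing (sorting, LFP) are out of scope. The
value-ratio variable is undefined for zero-value choices; sessions with a
deterministic animal yield capped, flagged behavioral estimates rather
than confidence statements.
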