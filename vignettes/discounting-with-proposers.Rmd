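---
title: "Modeling discounting behavior with proposers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling discounting behavior with proposers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trustdisc)
```

## The scientific problem

People devalue rewards that are delayed or uncertain. Under the hyperbolic
model the subjective value of a delayed reward of amount $A$ at delay $D$
days is

$$V = \frac{A}{1 + kD},$$

and the subjective value of a probabilistic reward at win probability $p$
is

$$V = \frac{A}{1 + h\Theta}, \qquad \Theta = \frac{1-p}{p},$$

where $\Theta$ is the odds against winning. The individual rates $k$ and
$h$ index how steeply the person discounts: larger values mean stronger
preference for the smaller immediate (or certain) option.

`trustdisc` implements the full analysis for a repeated-measures design in
which every choice item is presented once per *proposer condition*: a
baseline block with no proposer, plus six blocks crossing the proposer's
gender (female, male) with their apparent trustworthiness (trustworthy,
neutral, untrustworthy). The scientific questions are (1) whether an
untrustworthy proposer increases discounting relative to baseline, (2)
whether decisions are faster when a face is present and when the
smaller-sooner/certain option is chosen, and (3) whether the size of the
untrustworthy effect in a participant relates to percent DNA methylation
at CpG sites of the oxytocin receptor (OXTR) gene.

## Instruments

The delay task is the standard 27-item monetary choice questionnaire:
nine small, nine medium and nine large delayed rewards, engineered so the
27 indifference values $k^* = (A/A_s - 1)/D$ fall on a nine-step ladder
(about 0.00016 to 0.25 per day) with one item per step and magnitude.
The probability task has 30 items in three blocks of fixed amounts
(20 vs 80, 40 vs 100, 40 vs 60 currency units) whose win probabilities
place ten indifference values $h^*$ per block on a shared ladder (about
0.08 to 6 per odds unit).

The delay bank is a transcription of the published instrument. For the
probability bank the source instrument's per-item probabilities are not
reproduced in full anywhere we can bundle, so the packaged table is a
**documented reconstruction**: the block amounts and two published example
items (20 for sure vs 10% of 80, i.e. $h^* = 1/3$; 40 vs 60 at 50%, i.e.
$h^* = 0.5$) are exact, and the remaining probabilities were chosen once
to form a strictly increasing, block-aligned ladder. Analyses that only
use rank structure (everything in this package) are unaffected by the
exact rungs; users comparing against published $h$ norms should swap in
their own table via the same CSV format (`inst/extdata/pdq_items.csv`).

Currency is treated as a unitless positive number. Ties in indifference
values within a group are an error rather than broken arbitrarily; the
packaged banks have none.

## Consistency scoring

Binary choices are scored per participant and condition by consistency
maximization. Rank groups (items sharing a rank across magnitude groups
or blocks) get a group indifference value — the geometric mean of their
items' values, $v_1 < \dots < v_G$. Candidate rates are the lower edge
$v_1$ (an always-larger responder), the geometric means
$\sqrt{v_r v_{r+1}}$ of adjacent groups, and the upper edge $v_G$
(always-smaller). Each candidate predicts "larger" exactly on the rank
groups above its position; the assigned estimate is the geometric mean of
all candidates attaining maximal agreement with the observed choices, and
that maximal agreement is reported as the consistency. Edge responders
therefore get finite rates (and finite logs) with consistency 1.

Design choices worth noting:

* No minimum-consistency exclusion is applied; consistency is surfaced
  for the user to filter on if desired.
* Natural logarithms are used for `log_value`. The base only shifts
  model coefficients by a constant factor.
* Per-magnitude sub-scores are available (`score(..., subscores = TRUE)`)
  but the condition-level models use the overall estimate.

```{r score-demo}
bank <- mcq_bank()
always_larger <- data.frame(item_id = bank$item_id, choice = 1L)
score(always_larger, bank)
```

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
participant data. It emulates, with one seeded RNG stream:

* **Discount rates.** $\log k_{ic} = \mu + u_i + \delta_c +
  \gamma z_i \mathbf{1}[c\ \text{untrustworthy}] + \varepsilon_{ic}$,
  with participant intercepts $u_i$, condition offsets $\delta_c$,
  standardized site-3 methylation $z_i$ and residual noise; analogously
  for $\log h$. Defaults take $\mu$ and $\delta_c$ from published
  mixed-model coefficient tables for this design ($\mu_{\log k} = -3.768$;
  untrustworthy offsets 0.6–0.73 log units, neutral 0.09–0.33,
  trustworthy slightly negative), the residual SD from the printed
  contrast standard errors under balanced-design algebra
  ($0.139\sqrt{59/2} \approx 0.755$ for $k$, $0.49$ for $h$) and the
  between-participant SD from the intercept SEs (1.15 and 0.87).
* **Methylation.** Four beta-distributed percent values per participant
  (bounded in [0, 100] like pyrosequencing output), site means 35–50%
  with SD near 10 points. $\gamma$ is calibrated in closed form so that
  the large-$n$ correlation between site-3 percent and the untrustworthy
  log-shift (mean of the two untrustworthy cells minus baseline) equals
  the configured coupling — defaults 0.361 for $\Delta k$ and 0.431 for
  $\Delta h$, the reported effect sizes for this design. The shift's
  noise variance is $1.5\sigma_\varepsilon^2$, so
  $\gamma = \sqrt{1.5}\,\sigma_\varepsilon\,\rho/\sqrt{1-\rho^2}$;
  a nonzero coupling with zero residual noise is impossible and raises
  an error. Coupling enters only the untrustworthy cells; baseline rates
  are independent of methylation.
* **Choices.** Logistic (softmax) link on the subjective-value
  difference, $P(\text{larger}) = \operatorname{logit}^{-1}(\beta
  (V_\ell - A_s))$. The hyperbolic equations specify values, not a
  response rule; the logistic link is the standard choice for binary
  value-based decisions and makes $\beta$ interpretable as sensitivity
  per currency unit (default 1; tests of parameter recovery push it high
  to make choices near-deterministic).
* **Response times.** A fixed 250 ms non-decision shift plus an
  inverse-Gaussian deviate whose mean depends on face presence and on the
  response given. Default total-time cells reproduce the reported
  pattern: about 3.1 s at baseline vs 2.8 s with a face, and
  smaller-sooner/certain responses about 0.3 s faster. The shift
  guarantees the fast-trial filter bound is exercised. The
  inverse-Gaussian sampler is the Michael–Schucany–Haas transformation,
  implemented in the package because no installed dependency provides
  one.

What the generator does **not** emulate: item-level response biases,
learning or fatigue across the session, key-side effects, task order
effects, participant dropout/technical exclusions, and any relationship
between methylation sites other than independence. Passing tests
therefore demonstrate that the machinery recovers the structure it
assumes, not that real data satisfy those assumptions.

```{r cohort-demo}
cfg <- sim_config(n_participants = 8, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
```

## Condition effects

Log discount rates are analyzed with random-intercept linear models
(REML, via lme4), respecting the repeated-measures structure. Two
parameterizations are used:

* **Treatment coding**, baseline as reference: each coefficient is a
  face-condition-vs-baseline contrast. Significance is flagged by the
  |t| > 2 rule of thumb (treating t as z); the flag is marked approximate
  in printed output.
* **Sum coding** on the six face conditions only, trustworthiness ×
  gender: feeds type-3 Wald chi-square omnibus tests computed directly
  from the fixed-effect covariance, $\chi^2 = \hat\beta_L' V_L^{-1}
  \hat\beta_L$ per term block. A single-df term's statistic equals its
  squared z exactly.

Estimated marginal means average the model's cell predictions over a
balanced factor grid and are back-transformed by exponentiation for
log-scale outcomes (delta-method SEs). Pairwise comparisons use the
normal approximation with Bonferroni multiplication, capped at 1.

Response times (seconds) are modeled without transformation using a
generalized mixed model with inverse-Gaussian family and identity link
(`glmer`, `nAGQ = 0` for a fast, stable fit), after filtering trials
faster than 250 ms or slower than the participant's per-task mean + 3 SD.
The slow bound is computed once on pre-filter data — the filter is
idempotent on its own output — and removal counts are reported per rule.

Delta scores are computed on the raw rate scale:
$\Delta = \tfrac{1}{2}(k_{FU} + k_{MU}) - k_{baseline}$, positive when
the untrustworthy proposers increased discounting.

## Moderation analysis

The moderation stage regresses the untrustworthy-condition rate $Y$ on
site-3 methylation $X$, the baseline rate $M$ and their product:
$Y = b_0 + b_1 X + b_2 M + b_3 XM$. The conditional (simple) effect of
$X$ at moderator value $m$ is $b_1 + b_3 m$ with delta-method SE
$\sqrt{V_{11} + m^2 V_{33} + 2m V_{13}}$ and a t test on $n - 4$ df.

Open design points were resolved as follows:

* **Probes**: "low / middle / high" defaults to the 16th/50th/84th
  percentiles of the observed moderator (the modern default of the
  standard macro for this analysis), with mean ± SD available via
  `policy = "meansd"`. Probes outside the observed range warn but do not
  error.
* **Bootstrap**: case resampling (rows with replacement), percentile
  intervals, default B = 1000 at 95%; fully seeded. Singular resamples
  are skipped and counted, with more than 10% an error.
* **Scales**: $X$ is the raw site-3 percent and $Y$, $M$ the raw rates,
  matching how the analysis is usually reported; the building blocks
  (`fit_moderation` etc.) are scale-agnostic so log-scale variants are a
  one-liner. The package's own size-calibration tests run on the log
  scale, where the generator's errors are exactly normal and the nominal
  5% type-I rate is a meaningful yardstick; raw-scale rates are lognormal
  and heavy-tailed at realistic $n$.
* The two-tailed Pearson p-value uses the exact t transform
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$; for $r = 0.361, n = 51$ this gives
  $p \approx 0.0093$.

## Numerical and testing choices

* All scoring arithmetic is deterministic; the scorer is
  property-tested for exact equality against a brute-force enumeration
  oracle over random response vectors, for order invariance, and for
  monotonicity under single choice flips.
* OLS internals use QR; the moderation fit is tested to 1e-8 against an
  independently coded normal-equations oracle, and the Wald identity
  $\chi^2_{1\mathrm{df}} = z^2$ to 1e-10.
* Stochastic checks use fixed seeds and Monte-Carlo-sized tolerances:
  generator coupling within ±0.05 of target at n = 5000; bootstrap
  coverage of a known interaction within [90%, 99%] over 200 replicates;
  parameter recovery Spearman ≥ 0.9 at high choice sensitivity with 60
  participants. Problem sizes (n = 60 cohorts, B = 400 bootstrap in the
  coverage loops, 200 replicates) were chosen as the smallest sizes at
  which these properties are comfortably powered.
* Degenerate inputs: zero-variance response times and singular designs
  raise informative errors; fully degenerate mixed fits (all variance
  components zero) fall back to the least-squares covariance, which is
  zero there.

## Known limitations

* The probability bank's probability rungs are a reconstruction (see
  above); rank-based analyses are unaffected, absolute $h$ norms may
  differ from the published instrument.
* `nAGQ = 0` trades a little fixed-effect accuracy in the
  inverse-Gaussian response-time models for robustness; the tested
  contract is the sign/significance pattern, not estimator identity with
  any particular fitting engine.
* The |t| > 2 criterion is anti-conservative at small samples; it is a
  reporting convention here, not an inferential recommendation.
* Bootstrap percentile intervals do not guarantee per-run containment of
  the point estimate; coverage is a repeated-sampling property.
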