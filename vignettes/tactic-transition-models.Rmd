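---
title: "Modelling male alternative reproductive tactics across oestrus events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling male alternative reproductive tactics across oestrus events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In some cooperatively breeding mammals, several adult males per group compete
over short, synchronous oestrus events. Three discrete male reproductive
tactics coexist: *mate guards* follow a single female closely and repel
rivals, *sneakers* attempt copulations when a guard is distracted, and
*subordinates* stay reproductively inactive. `arttrans` provides a complete,
testable pipeline for asking how males move between these tactics over their
lives, what each tactic costs in body condition, what it yields in siring
success, and how it shapes access to mates.

The package has five layers: a synthetic-population generator with known true
parameters, the data-derivation rules that turn daily focal observations into
per-oestrus tactics and covariates, a Bayesian multi-state tactic-transition
model, three hierarchical outcome models, and shared inference utilities.
Everything downstream of the generator is validated by parameter recovery:
fit the models to data whose generating parameters are known and check that
the posterior recovers them.

## From daily observations to modelling tables

Raw data arrive as five tables: daily focal observations (who guarded or
sneaked toward whom), weight records, demography, pairwise pedigree
relatedness, and litters with sire assignments. The derivation rules are:

* **Per-event tactic** (`summarize_tactic()`): a male who guarded on any day
  and never sneaked is a guard; sneaked and never guarded, a sneaker; both,
  the behaviour shown on more days; inactive throughout, a subordinate.
  Males younger than 180 days are excluded everywhere. When a male guards
  and sneaks on equally many days the default calls him a sneaker; because
  field protocols differ on this point the rule is exposed as
  `tie_rule = c("sneaker", "guard")` and tied cases are flagged.
* **Age rank** (`assign_age_ranks()`): within group and sex, oldest = rank 1;
  litter-mates share the minimum rank and the next-younger male skips by the
  tie-group size (1, 2, 2, 2, 5).
* **Oestrus weight** (`oestrus_weight()`): the mean of all weights from 60
  days before the event start to 60 days after the event end. The window is
  anchored at the event start (before) and end (after); anchoring at the
  midpoint changes little for events lasting a week or less, and the
  symmetric choice is conservative for multi-day events. Missing windows are
  imputed (`impute_missing_weights()`) from the individual's own age-weight
  regression, using records near the target window where possible (a
  lifetime-wide straight line is biased early in life because growth
  decelerates); imputed values are flagged and never enter weight-loss
  analyses. Weights are then centred on the group-event mean over observed
  males (`centre_weights()`), which makes the centred values sum to zero
  exactly.
* **Weight change** (`extract_weight_change()`): percentage change from the
  60-day pre-event average to the single nearest post-event weight, accepted
  up to day 9 after the event end (inclusive; dates are whole days and all
  intervals closed).
* **Relatedness** (`group_centred_relatedness()`): a male's relatedness to
  each adult female present, centred on his mean over those females; dyads
  with unknown relatedness are dropped and counted.
* **Litter linking** (`link_litters()`): a litter belongs to the oestrus
  event of its mother's group that ended 44-74 days before birth (gestation
  59 +/- 15 days). If two events qualify, the one whose end sits nearest to
  birth minus 59 days wins -- the gestation-implied choice; only the window
  itself is fixed by the biology.
* **Siring trials** (`build_siring_trials()`): one Bernoulli trial per male
  who pursued the mother during the linked event, keeping only litters whose
  mother was pursued by at least one guard and one sneaker. Each trial
  carries the suitor count and the share of the male's competitors using his
  tactic (excluding himself: with one guard and two sneakers the guard's
  share is 0 and each sneaker's is 1/2).
* **Mate-choice dyads** (`build_dyad_table()`): for every day a male
  interacted, one record per adult female present, marking which female(s)
  he pursued. The analysis conditions on days with at least one interaction;
  whether the likelihood unit should be the day or the whole event is
  genuinely ambiguous in field protocols, so `fit_matechoice()` exposes
  `unit = c("day", "event")` with per-day the default.

## The multi-state transition model

Let `z[i, t]` be male `i`'s state at his `t`-th oestrus event, with state
space {subordinate, sneaker, guard, dead} and dead absorbing. The transition
row for a live origin state `n` is

```
P(dead) = 1 - s[n]
P(m)    = s[n] * softmax_m( beta[n, m, ] %*% x + u_male + u_group + u_event )
```

where `x` holds an intercept, age rank, group-centred weight and group sex
ratio. Design choices worth stating explicitly:

* **Reference category.** `subordinate` is the reference destination
  (its coefficients are zero). The reference and the placement of random
  effects are parameterization choices the data cannot distinguish; both are
  stated here and fixed throughout.
* **Random effects** enter as one shared additive term per male, group and
  event on the non-reference destination predictors. A common term on *all*
  destinations would cancel in the softmax, and per-destination effects
  would not be identifiable at realistic sample sizes, so the shared
  non-reference placement is the minimal identifiable structure: it captures
  "this male (group, event) is generally more reproductively active".
* **Survival** depends on the origin state only, on the logit scale with a
  flat (logistic) prior, equivalent to uniform on the probability scale.
  No covariates enter survival; status-related mortality differences are the
  quantity of interest, and regressing survival on the same covariates would
  not be supported at these sample sizes.
* **Interactions** between sex ratio and age rank / weight are fitted first
  and dropped when no cell passes the credibility rule, then the model is
  refitted (`interactions = TRUE` automates the two-stage screen).
* **Standardization.** Numeric covariates whose range extends outside
  [0, 1] are z-scored; proportions are left alone. Fitted effects are
  mapped back to the raw scale (per-draw linear transformation), which is
  what the recovery studies compare against the generating values.

Default chain settings are 3 chains, 20,000 post-burn-in iterations thinned
by 100, burn-in 2,500 -- the conventional settings for this model family.
Convergence is summarized by split R-hat with the usual < 1.1 rule; an
effect is *credible* when at least 97.5% of its posterior mass sits on one
side of zero (boundary inclusive). Priors are weak: Normal(0, 10^2) on the
outcome-model coefficients, half-Normal(0, 5^2) on random-effect SDs, and
weakly-informative Normal(0, 2.5^2) on the transition model's standardized
coefficients. The last choice deserves a note: multinomial-logit estimates
are biased away from zero in small samples (the logistic analogue of the
bias that Firth-type penalties correct), and per-origin transition cells can
be small even in respectable datasets -- transitions out of sneaking are
intrinsically rare. A Normal(0, 2.5^2) prior on standardized predictors is
the standard weakly-informative default for logistic-family models and
restores the nominal coverage of the credible intervals in the package's
recovery studies, while shrinking strongly-identified effects by only a
percent or two; `coef_prior_sd` exposes the choice. The exact "uninformed"
priors behind any particular field analysis are rarely printed; conclusions
that depend on these defaults should be checked by re-running with
alternatives (all priors sit in one place in the model strings, and
`run_mcmc()` accepts any BUGS model).

Random effects are implemented in the non-centred parameterization
(`u = sigma * z`, `z ~ N(0, 1)`) -- the same model, but far better mixing
for slice samplers when the data only weakly pin the SDs.

Sampling is delegated to JAGS through `rjags` -- the standard engine for
multi-state mark-recapture-style models in this field -- wrapped so that
every fit is deterministic given an `mcmc_config()` seed.

## The outcome models

* **Weight loss** (`fit_weightloss()`): Gaussian model of percentage weight
  change with a mean per tactic and crossed random effects (male, group,
  event). The tactic factor has all three levels; pairwise contrasts are
  recomputed from the saved draws.
* **Siring success** (`fit_siring()`): Bernoulli GLMM on trials, with guard
  coded 1 and sneaker 0, suitor count (standardized) and same-tactic share,
  random effects for female, male and event (group is deliberately absent:
  the trial structure already nests within groups via females and events).
  The tactic-by-share interaction is screened by credibility.
* **Mate choice** (`fit_matechoice()`): Bernoulli GLMM on dyads with
  group-centred relatedness, male and female rank, their product
  (assortative mating), the tactic with its two- and three-way rank
  interactions (a positive three-way term means guards are more assortative
  than sneakers -- the sneaker rank-lag), the number of adult females, and
  random effects for male, female and event. The relatedness-by-tactic
  interaction is screened by credibility.

## What the synthetic generator emulates

`generate_population()` forward-simulates groups of a few to ~25 males and
1-7 adult females (target 2.2 adult males per female), oestrus events every
~91 days lasting 1-7 days (uniform on `days_per_event`, default mean 3),
per-event tactics driven by `transition_probs()` with an absorbing dead
state, daily focal records consistent with the per-event tactic (with an
occasional opposite-behaviour day on multi-day events, mimicking observation
inconsistency without ever overturning the majority), weights along
individual logistic-style growth curves (asymptote ~1800 g) with 30 g
measurement noise plus tactic-specific post-event percentage losses (defaults
0.32, -2.30, -2.31 for subordinate, sneaker, guard), 6.6% of oestrus-weight
windows deleted completely at random, male-female relatedness drawn from a
mixture over {0, 0.125, 0.25, 0.5} to mimic kin-structured groups, and
litters born 59 +/- 7 days after their event whose sires are sampled from
the siring logits among the mother's suitors. All males enter the study as
subordinates at age 180 days (an explicit convention; the data cannot say
what an entering male "was" before observation).

Features of real data the generator does *not* emulate -- and which passing
tests therefore say nothing about -- include female mortality and dispersal,
between-group movement of males, informative weight missingness (e.g. less
habituated animals weighed less often), observation effort varying with group
size, and pedigree errors. The generator's missingness is completely at
random because the field mechanism is not characterized; if missingness were
informative, the imputation step would need a model of the mechanism.

Siring truth values are anchored to published posterior scenarios where
derivable (a guard-vs-sneaker siring gap of 0.40 vs 0.12 implies a logit
difference near 1.6; a lone-tactic male at 0.48 vs shared-tactic males at
0.26 implies a same-tactic-share coefficient near -1.9).

## The validation studies and their problem sizes

Two replicate studies ship with the package (`transition_recovery_study()`,
`sign_recovery_study()`) and back both the test suite and
`scripts/acceptance.R`:

* **Coverage.** Twenty replicate populations (6 groups, 6 events each,
  roughly 40-70 males and 200-350 transitions per replicate) are generated
  from known coefficients and fitted with 3 chains x 2,000 post-burn-in
  draws. Across replicates, at least 90% of the 24 raw-scale coefficients'
  95% credible intervals must cover the generating values. These population
  sizes are the package's chosen simulation scale: they keep a full study in
  the minutes range on one CPU while leaving enough information that
  coverage is a meaningful calibration check (coverage, unlike power, does
  not require large samples). Six groups rather than fewer matters: the sex
  ratio is a group-level covariate, and very few groups leave it confounded
  with the group random effects.
* **Sign recovery.** Twenty replicates of two designs -- a siring design
  (10 groups, 12 events, every pursued female littering, giving ~200-500
  trials) and a mate-choice design (4 groups of 5-6 females, 6 short
  events, ~800-1,700 dyads, screened with 2 chains x 800 draws; the large
  female groups maximize the female-rank spread that carries the
  assortativity signal, which buys more power per dyad than raw sample
  size does)
  -- must recover, as credible with the generating sign, the guard siring
  advantage, the negative same-tactic-share effect, the positive
  tactic-by-rank-product term and the guards' overall assortativity, in at
  least 18 of 20 replicates each. The mate-choice design amplifies the
  tactic assortativity difference (`guard_rank_product = 0.18` per
  rank-product unit) relative to what field data suggest, because the
  direction structure -- not the magnitude -- is what this study checks, and
  an effect sized for a multi-thousand-dyad field dataset is undetectable at
  desk scale.

## Numerical conventions and degenerate inputs

* Credible intervals are equal-tailed 2.5/97.5 percentiles with linear
  interpolation (`quantile(type = 7)`), so summaries are bit-reproducible
  from saved draws.
* The credibility boundary is inclusive: exactly 97.5% of draws on one side
  counts as credible.
* Split R-hat returns `NA` for constant parameters; identical chains give
  values within `(n-1)/n` of 1, not exactly 1.
* `summarize_tactic()` on an empty day set is an error (a male not present
  must be excluded by the caller, not defaulted to subordinate).
* An all-missing weight group-event cannot be centred and raises an error
  pointing at imputation.
* Zero adult females make the sex ratio undefined; the event is excluded
  with a warning.
* Complete separation in the siring model warns but still returns
  summaries; the weak priors keep the posterior proper.
* Softmax computations subtract the row maximum before exponentiating, so
  extreme linear predictors cannot overflow.

## Known limitations

The sampler backend is JAGS; models with many thousands of dyads mix well
but take minutes, and users fitting full field-scale datasets should expect
run times in the tens of minutes at the default chain settings. The
imputation step is a deliberately simple individual-level regression --
adequate for covariate completion, and never used for outcome values. The
mate-choice model treats male-days as conditionally independent given the
random effects; short-term behavioural carry-over within an event is not
modelled (the `unit = "event"` option collapses it entirely instead).
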