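---
title: "Methods: home-cage social dynamics in the visible burrow system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: home-cage social dynamics in the visible burrow system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbstools)
```

## The measurement setting

`vbstools` analyzes two complementary recording streams from groups of four
mice housed continuously in a visible burrow system (VBS): an open foraging
area (feeder, water spout, exposed center, a "safer" strip along the burrow
partition) connected through tunnels to two sheltered burrow chambers.

* An **RFID reader grid** (24 readers, 4 × 6) under the floor logs a
  timestamped reader activation whenever an animal's transponder is
  detected. This stream is dense, continuous and automatic, and carries
  spatial information only.
* A **behavioral ethogram**: human observers score short videos (30 s every
  10 min, of which the first 4 h of each 12-h dark and light phase are
  annotated — 25 videos per phase, 250 per group over five days) against an
  18-behavior catalog spanning affiliative, defensive, offensive, approach,
  maintenance and activity domains. This stream is sparse and intermittent
  but semantically rich: who did what to whom, where, and for how long.

Experimental days run from dark onset (18:00) for 24 h, dark phase first;
the default housing window is five days (120 h). All phase arithmetic is
done in minutes since first dark onset, which avoids the calendar-day
ambiguity inherent in a day that spans two dates.

Two conventions deserve a note:

* **Scored-video counting** uses inclusive endpoints: a 4-h window sampled
  every 10 min contains `floor(240/10) + 1 = 25` start times. This is the
  only convention consistent with the protocol's own arithmetic of 25
  videos per phase and 250 per group.
* **Attack latencies** are measured on the *scored-observation clock*
  (`scored_minutes()`): behavior is only observable while scored footage
  exists, so unscored gaps do not accrue latency. Animals that never attack
  are censored at the total scored time (2,400 min under defaults) and
  carry an explicit `censored` flag rather than a silently fabricated
  number.

## Activity and place preference

Hourly distance is reconstructed by summing Euclidean distances between
consecutively activated reader centers per animal; repeated detections on
one reader contribute nothing, and a transition spanning an hour boundary
is credited to the hour of the later event (unambiguous and
order-preserving). Reader geometry is configurable; the default 0.08 m
pitch corresponds to a bench-scale VBS floor. Hours without any detection
are reported as zero distance but flagged `no_detection`, so sensor
dropout is distinguishable from genuine immobility and can be excluded
from averages.

Place preference is the relative activation frequency (%) of each reader,
optionally phase-filtered; maps always sum to 100%. Counting raw
activations is the default because the underlying quantity is "frequency
of activation"; a duration-weighted variant sits behind a flag for
installations whose readers report meaningful dwell times. Genotype
contrasts are elementwise map differences plus open-vs-burrow area sums.

## Behavior metrics and aggression criteria

Occurrence tallies are exhaustive over the catalog (absent behaviors appear
as zeros), per animal × phase, pooled or per day; pooled totals are, by
construction and by test, the sum of daily totals.

The pathological-aggression profile assembles four quantitative criteria
per animal: latency to first attack, total attacks, mean single-attack
duration, and the fight/threat ratio
(struggle + struggle-at-feeder) / (chasing + following + approach-to-back),
plus the modal zone where attacks occur. Two attack definitions coexist
deliberately: the latency filter includes chasing (an unambiguous overt
pursuit) while counts and durations are taken over the contact fights
(struggle, struggle at feeder); both sets are parameters. Degenerate
ratios are flagged (`infinite` for fights with zero threats, `undefined`
for 0/0) instead of raising errors, because both occur routinely in
wildtype animals.

Genotype comparisons use the exact two-sided Wilcoxon–Mann–Whitney test:
the exact null distribution when the pooled sample has no ties, otherwise
a full enumeration of group assignments (feasible at home-cage sample
sizes; the normal approximation is a guarded fallback for large inputs).
Correlation tables use Spearman's rank correlation with Benjamini–Hochberg
q-values across each family; the correction method is a parameter because
no single convention is canonical here.

## Social networks

For one behavior, day and phase, the dyadic network is the 4 × 4 matrix of
directed counts (initiator → target), zero diagonal. A node's **overall
interaction strength** is its row sum plus column sum — in- and
out-strength are nearly interchangeable in this kind of data, so the
undirected total is the primary statistic, with directed variants behind a
flag. Networks default to dark-phase events, when the large majority of
interactions occur. The handshake identity (total strength = 2 × total
edge weight) is enforced by test.

## Glicko dominance ratings

Each directed struggle-at-feeder bout is treated as a paired-comparison
outcome: the initiator wins (`s = 1`), the recipient loses (`s = 0`), no
draws. Ratings follow Glickman's update equations with
`q = ln(10)/400`: pre-period deviation inflation
`RD <- min(sqrt(RD^2 + c^2 t), cap)`, expected score
`E = 1/(1 + 10^(-g(RD_opp)(r − r_opp)/400))` with
`g(RD) = 1/sqrt(1 + 3 q^2 RD^2 / pi^2)`, and posterior
`r' = r + q/(1/RD^2 + 1/d^2) g (s − E)`,
`RD' = sqrt(1/(1/RD^2 + 1/d^2))`.

Parameter choices and their reasons:

* **Initial rating 0** so that hierarchies stratify visibly above and
  below the starting mark.
* **Initial deviation 350.** Starting "certainty" is best read as *no
  prior certainty*; a literal zero deviation is degenerate under the
  equations (it freezes ratings forever). 350 is the conventional maximum
  and also the default inflation cap. Both are config keys.
* **`c = 1`**, an accepted value for mouse agonistic data; at this scale
  inflation is mild, so intermittent observation does not wash out
  established ranks.
* **Rating periods.** Every interaction is its own rating period for its
  two participants. Non-participants are not re-rated; they accrue
  inactivity time that inflates their deviation at their next appearance.
  This is an interpretation — the alternative reading, actively adjusting
  bystander ratings after every bout, is not specified anywhere in enough
  detail to implement — and it reproduces the intended per-interaction
  dynamics.
* **Tie-breaking** in final rankings: higher rating, then lower deviation
  (more certain), then animal id; exact ties are additionally reported.

Derived statistics:

* **Emergence of dominance**: the earliest point after which the finally
  dominant animal holds the strictly top rating through the end, counted
  either in interactions the dominant engaged in (default) or in all
  scored interactions — the two bases bracket the ambiguity in how such
  counts are naturally reported, so both are first-class. The normalized
  variant divides by the group's total interaction count.
* **Emergence summaries** across groups report median, mean and the
  *population* standard deviation (divisor *n*); the convention was fixed
  by recomputing published group-score summaries, which only match with
  divisor *n*.
* **Despotism ratio** `(r1 − r2)/(r1 − r_last)` over final ratings, with
  the conventional 0.33 threshold; all-equal ratings give an `undefined`
  flag.

## Genotype classifier

The feature table has one row per animal: each behavior's total count in
dark and light phases separately plus total distance traveled (37 features
for the 18-behavior catalog). Classification uses the randomForest
implementation with library-default hyperparameters (echoed into the
report); accuracy is leave-one-out: every animal is predicted by a forest
trained on all others, repeated (default 100 runs) to stabilize both the
accuracy and the Gini importances. Importances are the implementation's
mean decrease in Gini impurity (averaged over trees), averaged over folds
and runs, on which the "key feature" rule *mean Gini ≥ 1* operates — the
scale note is recorded in the report so the threshold stays interpretable
if a different backend is ever substituted.

## The synthetic generator

Because no raw recordings ship with the package, `simulate_group()`
produces datasets with the statistical structure the analysis assumes,
and it is itself tested code:

* **Event counts** per scored 4-h window are Poisson by default
  (negative-binomial dispersion is a config key) at per-behavior rates;
  wildtype defaults are plausible home-cage magnitudes and the knockout
  multipliers (struggle-at-feeder ×4, chasing ×3, allogrooming ×0.4,
  sniffing ×0.6, eating ×1.5, grooming ×0.7) mirror the direction and
  rough scale of a serotonin-depletion phenotype.
* **Dominance** enters through a fixed latent Bradley–Terry hierarchy
  (default strengths 8, 4, 2, 1 — a steep, despotic-style group with 2:1
  win odds between adjacent ranks). Agonistic bouts draw the initiating
  pair proportionally to strength and the initiator wins with probability
  `s_i/(s_i + s_j)`, so the Glicko recovery analysis has a well-defined
  ground truth. Non-agonistic social initiation uses softened weights
  (`strengths^0.5`): affiliative contact tracks rank, but far more weakly
  than fight outcomes do. Without this softening, rank skew dominates the
  per-animal totals of social behaviors and masks planted genotype
  effects — an artifact of attributing every social event to a
  strength-drawn initiator, not a feature of real data.
* **Individual variation**: non-social rates carry stable per-animal
  log-normal multipliers (sd 0.25). Uniform attribution would make
  maintenance behaviors unrealistically clean relative to social ones.
* **First-attack latencies** are exponential per animal (means: wildtype
  150, knockout 16 scored minutes); earlier attack events are removed and
  one attack is planted at the drawn latency, so the latency analysis has
  an exact ground truth.
* **RFID** is a nearest-neighbor random walk on the reader grid: hourly
  step counts are Poisson at 60 steps/h in the light phase ×2.5 in the
  dark, and step direction is weighted by phase-dependent zone preferences
  (feeder-heavy at night, burrow-heavy by day, with the two-tunnel burrow
  preferred). With a 0.08 m pitch this yields dark-phase travel of roughly
  8–12 m/h — the right order for group-housed mice without pretending to
  be a trajectory model.

What the generator does *not* emulate: autocorrelated behavioral bouts,
social contagion between behaviors, drifting rates across days, tag
collisions, or continuous-space trajectories. Tests passing on synthetic
data therefore demonstrate the correctness and statistical behavior of the
*pipeline*, not biological claims about real animals.

## Problem sizes and numerical choices

The shipped tests run the distributional checks at sizes chosen to give
comfortable Monte-Carlo margins at interactive runtimes: 20 replicate
groups per genotype for generator contrasts, 100 simulated groups of 500
interactions for rating-recovery, 100 LOOCV runs on a 5 + 5-group cohort
(40 animals) for the classifier — the same group count per genotype as a
typical VBS study. Exact rank-sum enumeration is used up to a few hundred
thousand group assignments and approximated beyond. Floating-point
equality in oracle-replay tests is asserted at 1e-9 relative error;
place-preference normalization at 1e-9 absolute.

## Known limitations

* The Glicko bystander-update interpretation (inflation-only) is one of
  at least two defensible readings of sparse descriptions of the method.
* Reader-grid geometry is configurable but the default layout is a
  schematic, not a measured hardware map; distances scale linearly with
  the configured pitch.
* Behavior durations are simulated i.i.d. exponential and are not meant
  to support duration-process analyses beyond means.
* The exact-permutation rank-sum test enumerates; for samples much larger
  than home-cage group counts it falls back to the normal approximation
  with a method note in the output.
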