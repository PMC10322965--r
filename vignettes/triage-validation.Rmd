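---
title: "Validating in-hospital mass-casualty triage algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating in-hospital mass-casualty triage algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcitriage)
```

## The problem

In a mass-casualty incident (MANV), casualties exceed the immediately
available resources, and the shortage does not end at the scene: receiving
hospitals must re-triage every arriving patient at the emergency-department
entrance. In-hospital triage assigns each patient one of three categories —
SK I (red, immediate life threat), SK II (yellow, urgent), SK III (green,
minor). SK IV (expectant) is not assignable at hospital entry; it may only
be the outcome of re-evaluation in the red treatment area under actual
resource shortage.

Several decision-tree algorithms compete for this task: the in-hospital
Berlin algorithm (BER) and the Manchester Triage System's MCI module
(MTS-MANV), the everyday emergency-department Emergency Severity Index
(ESI), the prehospital sieves mSTaRT, PRIOR and PETRA, and the
Jordanian-German in-hospital project algorithm JorD. `mcitriage` encodes
these algorithms as declarative decision trees, runs them over coded
patient vignettes with step accounting, builds an expert-consensus
reference standard, and evaluates diagnostic accuracy, triage-error
profile, step cost and casemix-weighted time workload.

The reference study design behind this pipeline rates 210 standardized
patient vignettes by 36 triage-experienced emergency physicians; those
vignettes are not published, so this package ships a seeded synthetic
generator that emulates the data structure end to end.

## Data model

Vignettes are rows of a tri-state feature table. Each canonical query item
("able to walk?", "respiratory rate > 29/min?", ...) is coded `1` (yes),
`0` (no) or `n` — the answer is not derivable from the case record. The
ESI resource-need item is four-valued: `0` no resources, `1` one resource,
`2` many resources, `n` unknown.

Raw databases name columns per algorithm; semantically similar queries are
consolidated into one canonical item through a merge map (for example
*unstable pelvis* and *pelvic fracture* into `pelvic_fracture`, *FAST
positive*/*FAST negative* into `fast`). The cell-level combination rule is:
merged value is yes if any source is yes, else no if any source is no,
else unknown — a positive finding in either source column is a positive
finding for the merged item. Consolidation is idempotent and always
yields exactly one column per canonical item.

One consolidation is lossy by design: *respiratory rate > 20/min* folds
into *> 29/min*, so an algorithm querying the lower threshold sees the
stricter item. The shipped default vocabulary reproduces this merge;
`default_vocabulary(strict = TRUE)` keeps the lower threshold as its own
item for users who want to re-encode an algorithm against it.

## Decision-tree semantics and step accounting

An algorithm document (YAML) declares named nodes; each queries one item
and routes, on yes and on no, either to a successor node or to a terminal
raw output. The loader validates that successors resolve, the graph is a
rooted DAG, and every terminal is either mapped by `scale_map` onto the
comparison categories 1–3 or is a recognised extended output (`EX`,
`SK IV`). Extended outputs are representable — the prehospital sieves tag
apnoeic patients deceased — but flagged `out_of_scale` at run time and
excluded from accuracy tables, because the in-hospital reference scale is
SK I–III only.

ESI terminals are native five-level outputs; the scale map sends level 1
to SK I, level 2 to SK II and pools levels 3–5 into SK III, with
resource-need tests (`many`, `at_least_one`) differentiating the lower
levels.

**Step semantics.** One step per evaluated query node; the terminal
assignment is not a step; a multi-criterion box authored as a single node
counts once. Step counts are the study's surrogate for triage duration.

**Unknown handling.** The coding scheme marks underivable answers `n`,
but leaves their runtime resolution open. The default policy is `as_no` —
a finding not derivable from the record is treated as absent — which lets
every vignette reach a terminal. It is configurable per call (`as_yes`,
`abstain`) and per node; `abstain` stops with a partial trace and the
result is excluded from accuracy tables. This default is a substantive
modelling choice and is echoed in every run log.

Each encoding is a reviewable data document, not hard-coded logic;
`algorithm_dot()` renders a tree as Graphviz DOT for visual audit against
its source. The JorD and PETRA documents are marked *provisional*: their
original flow charts are project supplementary material, and the shipped
transcriptions follow the public project descriptions. The ESI document
includes the vital-sign danger-zone uprating as tagged nodes;
`read_algorithm(..., disable_tags = "danger_zone")` removes the block for
sensitivity analyses.

## Reference standard

The gold standard per vignette is the median of the panel's ordinal
ratings (1–3). With an even panel the median can be half-integral; the
default tie policy rounds toward the more urgent category — the triage
safety convention of preferring over- to under-triage in a reference —
and tied vignettes are flagged and counted. The alternative policy is one
argument away, and the package reports how often it would matter.

The preparatory two-stage Delphi filter is bookkeeping over a small
panel's first-round ratings: duplicates drop, vignettes meeting the
agreement rule keep, the rest go to discussion. The source process does
not state its exact agreement criterion; the default here is unanimity of
the six pre-raters, with a configurable majority threshold.

## Accuracy and step-cost evaluation

For each algorithm a 3×3 confusion table (reference × prediction) is
built; abstained and out-of-scale results are excluded with a count.
One-vs-rest metrics per category: sensitivity TP/(TP+FN), specificity
TN/(TN+FP), PPV, NPV, and the Youden index J = sensitivity +
specificity − 1. J is computed from unrounded inputs; rendering rounds
proportions to two decimals and percentages to one, which is why a
reported J can differ by 0.01 from the sum of its reported summands.
Undefined ratios (zero denominators) are explicit `NA` sentinels rendered
as dashes, never silent zeros — degenerate strata occur routinely in
small synthetic runs.

Triage-error proportions condition on the reference stratum: among
vignettes truly in category c, the shares triaged correctly, more
urgently (over-triage) and less urgently (under-triage) sum to one.
Structurally, SK I can only be under-triaged and SK III only over-triaged,
and under(SK I) = 1 − sensitivity(SK I); these identities are enforced by
property tests.

Step counts are summarised as median and IQR per category and correctness
stratum. Quartiles default to linear interpolation on fractional ranks
(`quantile` type 7); the weighted-average definition (type 6, the SPSS
default) is one argument away for cross-checks, since statistics packages
disagree on quartiles of small samples. Empty strata print as `none`.

**Step-count comparison.** The omnibus test is Welch's one-way ANOVA,
valid under unequal variances, computed explicitly so that zero-variance
groups are tolerated (their variance is floored at 1e−12: equal constant
groups give a null statistic, different ones an extreme one). Pairwise
comparisons use a Dunnett-T3-type procedure: Welch t statistics with
Satterthwaite degrees of freedom referred to a studentized-maximum-modulus
bound, implemented as the Šidák-style bound 1 − (2·pt(|t|) − 1)^m over
the m comparisons — exact under independence and conservative otherwise.
A Games-Howell alternative (|t|·√2 against the studentized range) sits
behind `method = "games_howell"`. Familywise error control at α = 0.05 is
verified by a seeded null simulation in the test suite.

Whether step counts should be pooled across categories or compared per
category is left to the caller: `compare_step_counts()` takes plain named
groups, and the batch pipeline pools, matching the across-categories
reading of the omnibus comparison.

## Workload model

Per-patient triage times per category (seconds) come from external timing
evaluations: PRIOR 27/28/42 s and mSTaRT 35/20/10 s for SK I/II/III.
Combined with a casemix p over SK I–III and EX, the time spent on
category c for n patients is n·p_c·t_c/60 minutes; shares are each
category's fraction of total triage time and are independent of n.
Deceased patients (EX) consume no algorithm time, so shares over SK I–III
are the same whether EX is carried at zero time or dropped. With the
15/20/60/5 % casemix and 100 patients, PRIOR spends 42 minutes on green
patients against mSTaRT's 10; with the 7/19/74 % field distribution, 81 %
of PRIOR's triage time goes to the lightly injured. Reports round minutes
to integers and shares to whole percents; unrounded values stay in the
JSON output.

## Synthetic data: what it emulates and what it does not

The generator plants identifiable truth by *path forcing*: draw a category
from the prevalence (default 20/30/50 % for SK I/II/III, a reported
scenario-dependent distribution), sample uniformly one root-to-terminal
path of the oracle algorithm reaching that category, and force the items
queried along that path. Off-path items take a benign baseline —
pathological findings absent, normally-present findings (spontaneous
breathing, palpable radial pulse) present — then flip away from baseline
with probability `feature_noise` and mask to unknown with
`unknown_rate`. Because the oracle's evaluation only ever visits forced
nodes, the oracle recovers the planted truth for 100 % of vignettes in
the noiseless limit; that exact-recovery property is the pipeline's
self-consistency anchor. The benign baseline matters for the *other*
algorithms: without it, sieve-type trees would tag nearly every
non-walking vignette as apnoeic/deceased.

Expert panels are simulated by drawing each rating independently from a
row-stochastic confusion matrix given the truth; `offby1_confusion(eps)`
gives symmetric off-by-one noise. At 20 % noise with 36 raters, the
median consensus recovers the planted category for over 99 % of 1000
vignettes — a seeded Monte-Carlo check in the suite.

Limitations, stated plainly: off-path items are independent Bernoulli
draws with no clinical correlation structure; prevalence, noise and panel
behaviour are homogeneous across vignettes; and planted truth is defined
*by an algorithm*, which favours that algorithm and its near-relatives in
any synthetic comparison. Passing the synthetic suite therefore
demonstrates pipeline correctness — not the clinical accuracy ranking of
the algorithms, which requires the real expert-consented vignette set.
For the same reason the published per-algorithm accuracy table ships as a
worked-example input (`reported_accuracy()`), and the package's tests
reproduce its internal identities (Youden from sensitivity/specificity,
error-rate complements) rather than its cells.

## Problem sizes and numerical choices

The test suite runs the study-scale structures where they are cheap
(36 × 210 = 7560 rating events; 1000-vignette consensus recovery) and
smaller sizes elsewhere: exhaustive interpreter-vs-enumeration checks on
random trees of up to 7 items (complete assignment grids), 200 random
confusion tables against a brute-force metric oracle, 300–400 null
replicates for familywise-error control, and end-to-end evaluations of
40–210 vignettes. Seeds are fixed throughout; identical configurations
produce byte-identical generator output and pipeline CSVs (each stamped
with an MD5 config hash).
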