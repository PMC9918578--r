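---
title: "Modelling early lexical growth with semantic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling early lexical growth with semantic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexnetgrow)
```

## The problem

Toddlers do not learn words in a random order. Words that are frequent,
short, and phonologically easy come earlier, but so do words that occupy
central positions in the *semantic environment* — the web of associations
among the words a child hears. `lexnetgrow` implements a complete pipeline
for studying this: it builds directed semantic networks from adult word
associations and from co-occurrence in child-directed speech, estimates
each word's age of acquisition (AoA) from parent-report production norms,
scores every unknown word each month under three network growth models, and
asks — with a softmax choice likelihood — whether those network scores
predict which words enter the typical vocabulary next, over and above
standard psycholinguistic covariates.

Because the data such studies collect (association norms, transcripts,
CDI-style checklists) cannot be redistributed here, the package ships a
synthetic-data module that generates every input with known ground truth.
All statistical machinery is exercised end-to-end against that ground
truth in the test suite.

## Networks

**Association networks.** Participants see a cue word and type the first
three words that come to mind. After normalization (lower-casing,
whitespace cleanup, collapsing letter runs longer than two, as in
`normalize_response()`), screening (`screen_participants()`), and capping
at 100 retained sessions per cue (`cap_and_crosstab()`), a directed edge
cue → response is drawn whenever a cue word was produced at least once as a
response to another cue (`build_association_network()`). Networks are
unweighted: any evidence of association merits an edge. Screening follows
the conventions of large multi-response norming studies — a session is
excluded when more than 30% of its responses are multi-word, more than 40%
are not recognizably English (operationalized as absence from a
user-supplied wordlist, which is an input rather than a baked-in
dictionary), more than 20% repeat one of the participant's own earlier
responses in the session, or the attention check is not answered with a
combination of red/white/blue. Each threshold is strict (`>`); the
repeated-response rule is evaluated session-wide, which is why real
protocols (and the synthetic generator) give each participant a limited
cue list rather than the full inventory.

**Co-occurrence networks.** For transcripts of child-directed speech,
`build_cooccurrence_network()` slides a five-token forward-looking window
over each utterance, accruing evidence from the window's first token to
each of the four that follow. Two conventions are ours and configurable:
windows never cross utterance boundaries (utterances are the natural unit
of speech to children), and the default edge threshold is one observed
co-occurrence, matching the most liberal connectivity criterion for the
association networks. Self-loops are dropped in both constructions. A thin
CHAT reader (`read_chat_utterances()`) extracts adult-caretaker utterances
by the role field of `@ID` headers; spelling regularization and phrase
merging are consumed as a user-supplied token map, not constructed here.

## Ages of acquisition and trajectories

For each word, `fit_word_aoa()` regresses produces/doesn't-produce on age
(logistic; the table is aggregated to per-age counts first, which is
algebraically the same fit). The AoA is the age at which the fitted curve
crosses 0.5, i.e. `-intercept/slope`. Words whose curve never reaches 0.5
by the last assessment month, or whose fitted slope is not positive, get
status `no_aoa` and are excluded; non-convergent fits are retried with a
Firth-penalized IRLS before giving up. `build_trajectory()` buckets each
word at the first month `m` with AoA ≤ `m` (so an AoA of exactly 17.0
belongs to month 17, and anything at or below the first month is initial
vocabulary). Known-sets are nested by construction.

## Growth values

Relative to the vocabulary known at month `m`, every still-unknown word
receives three scores (`growth_value()`, vectorized in
`monthly_growth_table()`):

* **Preferential attachment** — the mean indegree, *within the subgraph
  induced by known words*, of the known words the candidate shares an edge
  with in either direction (0 if it has no known neighbours). Two readings
  of the verbal definition were possible; we average indegree (not total
  degree) inside the known-word subgraph and treat candidate–vocabulary
  contact as undirected, the combination that reproduces the worked
  example's values (`toy_growth_example()`), and the neighbourhood
  direction is switchable in principle by editing one line of the core.
* **Lure of the associates** — the number of known words with a directed
  edge *into* the candidate.
* **Preferential acquisition** — the candidate's indegree in the full
  network, independent of the current vocabulary.

Within each month × model cell the scores are z-standardized; a constant
cell z-scores to 0 with a warning. `at_acquisition()` then picks, for each
word, its z in the month just before its acquisition bucket — the month at
which a predictive growth model should rank it highest. Words acquired in
the final assessment month can be included or excluded: in a 598-word
inventory with 18 initial words and 33 final-month learners this is the
difference between 580 and 547 values per model, and both counts are used
by downstream analyses (the likelihood analysis keeps final-month learners;
the mean-growth-value analyses drop them because every remaining unknown
word is acquired in the final month, making it uninformative).

## The acquisition likelihood

The probability that word *i*, acquired in month *m*+1, was the one
learned is a ratio of strengths over the words still unknown at month *m*:

$$p_i = \frac{e^{\beta x_i}}{\sum_{j \in U_m} e^{\beta x_j}}$$

with log-likelihood $\sum_i \log p_i$ over all scored acquisitions
(`log_likelihood()`, computed with log-sum-exp stabilization). All words
acquired in the same month share one denominator; there is no within-month
depletion. Psycholinguistic covariates are globally z-standardized by
`build_predictor_matrix()`; growth values enter as their within-month z.
`fit_acquisition()` maximizes by BFGS from a zero start with the analytic
softmax gradient, verifies the optimum from a deterministic perturbed
restart, and takes standard errors from the inverse observed information.
Exactly collinear columns are flagged rather than silently dropped.

Nested fits are compared by `compare_nested()`:
$\chi^2 = 2(\log L_1 - \log L_0)$ against $\chi^2_{\Delta k}$, and a BIC
difference on the "large positive favours the full model" convention,
$\mathrm{BIC} = \chi^2 - \Delta k \log n$. The `n` in the penalty defaults
to the number of scored acquisition events in the fit but is overridable:
published analyses of this design are not always internally consistent
about whether `n` counts the events with or without final-month learners,
so the package makes the choice explicit. Families of comparisons are
FDR-adjusted with Benjamini–Hochberg (`fdr_adjust()`, a thin validated
wrapper over `p.adjust`).

## Structure comparison

`cue_similarity()` binarizes the cue-by-response crosstab (so response
frequency cannot dominate) and correlates cue profiles with Pearson's r;
`rsa()` takes the Spearman rank correlation between the strictly-lower
triangles of two such matrices. `rsa_null()` builds the reference
distribution by pooling both conditions' sessions per cue and re-running
the full analysis on random half-splits; the splitting unit is the session
(a participant's response triple), preserving within-participant
structure.

One caveat discovered while calibrating this null: when sessions span many
cues, participants' tendency not to repeat themselves induces negative
dependencies between the responses of different cues *within a session*.
Random per-cue splits break these dependencies while the true condition
split preserves them, so the observed similarity sits below the null even
when the two conditions are generated identically. Split-half RSA nulls of
this design are therefore conservative evidence for condition differences
unless sessions contribute to few cues; the package's type-I calibration
uses single-cue sessions, where the split is exactly exchangeable.

`network_summary()` reports average shortest path length L and mean local
clustering C on the undirected projection of the largest component,
together with randomized references (degree-preserving edge swaps, 10
replicates of 10·|E| attempts) and a lattice reference, combined into the
small-world index `((L−L_l)/(L_r−L_l)) × ((C−C_r)/(C_l−C_r))` clamped to
[0, 1]. The lattice reference is built directly — same degree sequence,
edges placed greedily to the nearest ring neighbours under residual degree
capacity, with an exact edge-split repair for leftover stubs — because
swap-based latticization converges far too slowly to serve as a reference
at these sizes. The construction is deterministic and reproduces a ring
lattice exactly for regular graphs. Mean local clustering here is the
standard local clustering coefficient averaged over nodes (isolated and
degree-1 nodes count 0); values above 1 are impossible under this
definition.

`taxonomic_ratio()` partitions ordered node pairs by shared category and
reports the ratio of mean within-category to mean between-category
directed shortest-path distance (below 1 = taxonomic structure).
Unreachable pairs are excluded from the means and their fraction reported,
rather than imputed. Confidence intervals for functions of a network come
from `bca_interval()`, a bias-corrected and accelerated bootstrap (via the
boot package) whose resampling unit is chosen by the caller; for taxonomic
contrasts we resample cue words and recompute distances per resample.

## Response-property ANOVAs

`cell_means()` averages any word-level covariate within unit × condition ×
response-order cells (dropping units with empty cells, listwise);
`rm_anova_within()` runs the classical two-factor fully-within ANOVA on
those cell means, testing each effect against its own effect-by-unit
interaction, with Greenhouse–Geisser ε estimated from the covariance of
orthonormalized contrast scores (ε is exactly 1 for two-level factors) and
generalized η² computed with every unit-related sum of squares in the
denominator, the convention for fully-within designs. The same machinery
serves the 3 (growth model) × 2 (network) analysis of at-acquisition
values. `paired_simple_effects()` gives the per-level paired t tests with
95% intervals. Frequency-like covariates are conventionally analyzed on
the log10 scale; the package leaves the transformation to the caller's
norm table.

## The synthetic study

`gen_lexicon()` draws a CDI-like inventory (default 598 words in 22
categories) with correlated covariates and a true AoA per word; the AoA
range (14–31 months by default) deliberately extends past the 16–30-month
assessment window so that initial vocabulary and never-acquired words both
exist. `gen_production_norms()` emulates a cross-sectional norming study
(default logistic slope 0.5 per month, a production curve that rises from
10% to 90% over about nine months, typical of checklist norms).
`gen_association_study()` emulates the multi-response task with cue lists
(33 cues per session), a Zipf-concentrated cue→response kernel
(`default_similarity_kernel()`: a handful of strong associates per cue
drawn preferentially from its category carry 90% of the sampling mass),
an out-of-lexicon response pool, a child-oriented condition implemented as
exponential tilting of sampling weights toward earlier-acquired words, and
planted screening violators that deterministically cross their thresholds.
This kernel makes synthetic association networks sparse (about 4% edge
density at study scale) while windowed co-occurrence networks over the
same lexicon are dense (about 46% at a 300k-token corpus), reproducing the
qualitative contrast seen in real data. `gen_corpus()` samples utterances
(mean length 5 tokens) with dampened frequency weights and a
within-category boost for adjacent tokens, so co-occurrence networks can
recover planted category structure.

`simulate_acquisition()` is the generative inverse of the fitted model:
each month a configured number of unknown words is drawn *without
replacement* with probability ∝ exp(β·x). One subtlety matters for
parameter recovery: sampling without replacement is a Plackett–Luce
process, while the fitted likelihood shares one denominator per month.
The two agree when monthly acquisitions are small relative to the unknown
pool; when a month's draws approach the pool size (as in the final months
of an exhaustive trajectory, where the draws are nearly deterministic),
the shared-denominator likelihood treats those uninformative events as
informative and shrinks coefficient estimates toward zero. The package's
recovery experiment therefore uses a flat 20-words-per-month schedule at
598 words (280 events, monthly hazard ≤ 7%), where 2-SE coverage is
nominal; heavy-depletion schedules are a documented limitation of the
estimator, not of the generator.

## Numerical choices, sizes, and limitations

* Softmax optimization: BFGS, relative tolerance 1e-12, analytic gradient,
  one deterministic restart; log-sum-exp throughout. Degenerate Hessians
  give `NA` standard errors rather than failures.
* Month-boundary ties go to the earlier month; final-month inclusion is an
  explicit flag everywhere it matters.
* Constant z-cells warn and return 0; degenerate bootstrap distributions
  collapse to a point with a warning; a zero-SS ANOVA effect reports F = 0,
  p = 1 rather than 0/0.
* Test and calibration problem sizes were chosen to make each property
  measurable in seconds-to-minutes: oracle fixtures use 8–30 node graphs,
  calibrations use 1000 simulated studies (ANOVA, RSA), 500 (LRT null,
  BCa coverage), and recovery uses 100 seeded round trips at the full
  598-word scale.
* Known limitations: the synthetic association kernel has category-block
  structure rather than the graded thematic/taxonomic mix of real norms;
  synthetic word forms carry no real phonology, so length and
  neighborhood covariates are statistical stand-ins; the CHAT reader is a
  light adapter, not a full CHAT parser; and passing tests on synthetic
  data demonstrates correctness of the machinery, not the validity of any
  particular empirical claim about children.
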