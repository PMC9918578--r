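# lexnetgrow

Semantic network growth models of early word learning.

Children acquiring their first words do not sample the lexicon at random:
words that are central in the semantic environment tend to arrive earlier.
`lexnetgrow` is an R package for studying that process end to end. It
builds directed, unweighted semantic networks from two kinds of evidence —
multi-response word-association norms (cue → response edges) and windowed
word co-occurrence in child-directed speech — estimates each word's age of
acquisition (AoA) from CDI-style production norms as the age where a
logistic production curve crosses 0.5, and scores every unknown word at
every month under three growth models:

- **preferential attachment** — mean within-vocabulary indegree of the
  known words the candidate would attach to;
- **lure of the associates** — number of known words linking into the
  candidate;
- **preferential acquisition** — the candidate's indegree in the full
  semantic environment, regardless of what is known.

Whether those scores predict which words are learned next is tested with a
softmax ("ratio of strengths") likelihood

```
p_i = exp(beta · x_i) / sum_{j in unknown(m)} exp(beta · x_j)
```

fit by maximum likelihood, with nested likelihood-ratio tests,
`BIC = chi2 − k·log(n)` model comparison, and Benjamini–Hochberg FDR
control. The package also implements the surrounding comparative
machinery: representational similarity analysis between conditions with a
split-half permutation null, small-world indices with degree-preserving
random and lattice reference graphs, taxonomic within/between distance
ratios with BCa bootstrap intervals, and two-factor repeated-measures
ANOVAs with Greenhouse–Geisser correction and generalized eta-squared.

Because association norms, transcripts, and checklist data cannot be
bundled, a synthetic-data module (`gen_lexicon()`, `gen_production_norms()`,
`gen_association_study()`, `gen_corpus()`, `simulate_acquisition()`)
generates every input with known ground truth — planted screening
violators, a controllable child-oriented context effect, planted category
co-occurrence, and acquisition trajectories drawn from a known softmax
model — so the full pipeline is testable offline.

## Worked example

A complete synthetic study, from raw responses to a model comparison:

```r
library(lexnetgrow)
library(dplyr)

# ground truth: 120 words in 10 categories, norms from 2000 children
lex  <- gen_lexicon(n_words = 120, n_categories = 10, seed = 1)
prod <- gen_production_norms(lex, n_children = 2000, seed = 2)
aoa  <- fit_aoa(prod) |> filter(status == "ok", aoa <= 30)
traj <- build_trajectory(aoa)

# a child-oriented association study, screened and cross-tabulated
gt        <- ground_truth(condition_effect = 1.5, seed = 3)
responses <- gen_association_study(lex, n_participants_per_cue = 50,
                                   condition = "child", ground_truth = gt)
wordlist  <- c(lex$word, sprintf("xeno%03d", 1:50))
reports   <- screen_participants(responses, wordlist)
crosstab  <- cap_and_crosstab(responses, reports)
net       <- build_association_network(crosstab, node_set = aoa$word)
net
#> <semantic_network/association> 109 nodes, 2996 directed edges

# growth values for every unknown word at every month, z at acquisition
growth <- monthly_growth_table(net, traj)
at_acquisition_tests(at_acquisition(growth, traj))
#> # A tibble: 3 × 7
#>   model           n    mean     se      t    df        p
#>   <chr>       <int>   <dbl>  <dbl>  <dbl> <int>    <dbl>
#> 1 acquisition    94  1.01   0.0905 11.2      93 6.56e-19
#> 2 attachment     94 -0.0517 0.0910 -0.568    93 5.71e- 1
#> 3 lure           94  0.871  0.100   8.67     93 1.33e-13

# does network structure add to a psycholinguistic baseline?
norms <- lex |> transmute(word, phonemes, frequency = log10(frequency),
                          phonotactic_probability, neighborhood_density)
base <- build_predictor_matrix(norms)
full <- build_predictor_matrix(norms, growth = growth, models = "acquisition")
compare_nested(fit_acquisition(base, traj), fit_acquisition(full, traj))
#> # A tibble: 1 × 4
#>    chi2    df        p   bic
#>   <dbl> <int>    <dbl> <dbl>
#> 1  79.2     1 5.54e-19  74.6
```

Read it as follows. The mean standardized growth value at the month of
acquisition would be 0 if a growth model knew nothing about what is
learned next; here preferential acquisition (mean z ≈ 1.0) and lure of
the associates (≈ 0.87) are strongly predictive while preferential
attachment is not — the child-oriented response kernel concentrates
associations on early-acquired words, so environmental centrality tracks
acquisition order. The nested comparison says the preferential-acquisition
growth values improve prediction of the acquisition sequence beyond
phonemes, frequency, phonotactic probability, and neighborhood density
(chi-squared 79.2 on 1 df; BIC difference +74.6 on the
large-positive-favours-the-full-model convention).

The worked toy network behind the three growth models is available as
`toy_growth_example()`: its acquisition candidate scores 5 (degree in the
full environment), its lure candidate 3 (known words linking in), and its
attachment candidate 5 (its one known neighbour is a vocabulary hub of
within-vocabulary degree 5).

## Vignette

`vignettes/lexnetgrow-methods.Rmd` documents the models and their
assumptions, every convention the implementation had to pin down (edge
rules, month-boundary ties, the BIC sample size, attachment's
neighbourhood direction), the synthetic generator's design and what it
does and does not emulate, and known limitations.
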