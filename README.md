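# steprec

Moderated online social therapy platforms deliver interactive therapy
modules ("steps") and real-world behavioral tasks ("actions") alongside a
peer newsfeed and clinician moderators. Users only benefit from that content
if they find the right piece at the right moment — and most users will not
browse or search for it. `steprec` is a standalone, fully testable
implementation of the automated machinery that closes this gap: it reads
what a user just posted and suggests the step and the action that best fit
the post's mood and topic. It is aimed at researchers and engineers building
or studying content recommendation in digital mental health tools.

## What it computes

For a post *p* the engine:

1. **Analyzes** *p* with a deterministic lexicon analyzer: a sentiment score
   *s(p) ∈ [−1, 1]* (0 = neutral), a score in [0, 1] for each of the five
   emotions (anger, disgust, fear, joy, sadness) defined as the density of
   emotion-bearing content tokens, and the post's ranked keywords.
2. **Partitions** the candidate catalog by valence: if *s(p) > 0* only items
   suited to positive posts (or to either) remain; if *s(p) < 0* only those
   suited to negative posts (or either); a neutral post imposes no
   reduction.
3. **Scores** every admitted item *i* by

   *score(i) = α · sim(p, i) + (1 − α) · cong(p, i)*,  α ∈ (0.5, 1], default 0.7

   where *sim* is the Dice coefficient between keyword token sets,
   2|A∩B| / (|A|+|B|), and *cong* = 1 − mean|p<sub>e</sub> − r<sub>e</sub>|
   over the five emotions. Keyword similarity is the decisive factor;
   congruence splits similarity ties and downgrades emotionally
   inappropriate items.
4. **Selects** the argmax per kind — one step and one action — breaking
   exact ties (within 1e−9) uniformly at random under a configurable seed,
   with a full per-candidate audit trail.

Around this core the package provides the author-curated related-steps
list, strengths/history-driven newsfeed action suggestions, the
"Powered by your Strengths" page, basic search and alphabetical browse, the
four "Steps People are Taking" popularity lists (including the
anti-informational-cascade *Hidden Treasures* list of least-taken steps),
engagement analytics over usage-event logs and moderator-suggestion
ledgers, a minimal slot-filling chat assistant that front-ends the same
engine, and a seeded synthetic-data generator.

## Worked example

```r
library(steprec)

cat_ <- example_catalog()       # bundled synthetic catalog
res  <- suggest("Feeling stressed about my new job", cat_)
res
#> <suggestion_result: post is negative>
#>   step:   s_work
#>   action: a_kind
glance(res)
#> # A tibble: 1 × 7
#>   step   action sentiment sentiment_class tie_broken n_candidates n_admitted
#>   <chr>  <chr>      <dbl> <chr>           <lgl>             <int>      <int>
#> 1 s_work a_kind      -0.5 negative        FALSE                 8          5
```

The post's only matched lexicon token ("stressed", valence −0.5) makes it
negative, so the three positively-valenced items are excluded
(`n_admitted = 5` of 8). Among admitted steps, "Work and Study Survival"
(`s_work`) shares the keyword *job* with the post (similarity 0.286) while
every other step is keyword-disjoint, so it wins with combined score 0.458;
`tidy(res)` shows the full audit table and `autoplot(res)` plots it.

Analytics reproduce the deployment accounting exactly:

```r
fx <- build_reference_fixtures()
suggestion_outcomes(fx$ledger)
#> # A tibble: 1 × 6
#>   total completed client_dismissed moderator_dismissed pending completion_fraction
#> 1   701       211               21                 304     165               0.301
tracked_visit_share(fx$tracked_events, "moderator_suggestion")
#> [1] 39
```

A thin command-line front end lives at `exec/steprec`
(`steprec suggest --post "…" --catalog catalog.json --audit`, plus
`analyze`, `search`, `rank`, `stats`, `chat`, `fixtures build`,
`catalog validate`).

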