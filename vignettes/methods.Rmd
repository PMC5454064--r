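---
title: "How steprec scores and suggests therapy content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How steprec scores and suggests therapy content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steprec)
```

## The problem

Moderated online social therapy sites hold a catalog of *steps*
(interactive therapy modules) and *actions* (real-world behavioral tasks),
organized under a fixed taxonomy of three parent tags with three sub-tags
each, and connected to a set of 24 character strengths of which each user
selects five. Clinician moderators suggest content by hand, but that does
not scale; `steprec` implements the automated channel that reacts to a
user's newsfeed post by suggesting the one step and one action that best
fit it, plus the surrounding discovery and accounting apparatus.

## The analyzer

Production systems of this kind call a remote text-analysis API. This
package instead ships a deterministic lexicon analyzer so that every result
is reproducible offline and the decisive quantities are auditable. The
binding contract is only the output ranges: sentiment in $[-1, 1]$ with 0
neutral, five emotion scores in $[0, 1]$, and a keyword list. Numerical
agreement with any particular commercial analyzer is explicitly not a goal,
and any backend honoring the contract can be substituted (the engine takes
the lexicon/analyzer as an argument).

Choices, each made for auditability over sophistication:

* **Tokenization** lowercases and keeps apostrophes inside words;
  no stemming. Keeping it transparent matters more than recall here,
  because keywords are the decisive scoring component.
* **Sentiment** is the clipped mean valence of lexicon-matched tokens; a
  negator ("not", "never", …) flips the sign of the immediately following
  matched token (window of one). No matches gives exactly 0, the neutral
  class. The trichotomy positive / neutral / negative is what drives the
  valence partition, so the sign, not the magnitude, is what downstream
  code consumes.
* **Emotion scores** divide the count of tokens carrying an emotion by the
  count of *content* (non-stopword) tokens, not by matched tokens: the
  score then reads as emotional density, is bounded, and grows
  monotonically with the density of emotional vocabulary.
* **Keywords** are unigrams ranked by frequency with first-occurrence
  tie-breaks, capped at $k = 10$ by default. No noun-phrase chunking: a
  simple, decisive component is easier to reason about than a marginally
  better opaque one.

The bundled lexicon is small (~120 entries) and hand-curated; larger
lexicons in the same three-file plain-text format plug in unchanged.

## The suggestion score

For a post $p$ and item $i$, admitted candidates are scored

$$\mathrm{score}(i) = \alpha\,\mathrm{sim}(p,i) + (1-\alpha)\,\mathrm{cong}(p,i),
\qquad \alpha \in (0.5, 1],\ \text{default } 0.7.$$

* $\mathrm{sim}$ is the Dice coefficient on normalized keyword token sets.
  It is symmetric, set-size aware, and exactly 1 on identical sets — a
  natural "basic text match" generalization. The similarity function is
  pluggable; Dice is the package's declared stand-in for whatever a remote
  service would compute.
* $\mathrm{cong} = 1 - \tfrac{1}{5}\sum_e |p_e - r_e|$ over the five
  emotions — the L1-based congruence between the post's emotion vector and
  the item's emotion-relevance vector.
* $\alpha$ is constrained above 0.5 so similarity is always the decisive
  factor, while congruence splits similarity ties (for two items with equal
  similarity, the more congruent one scores strictly higher) and can
  downgrade a keyword-similar but emotionally inappropriate item. 0.7 was
  fixed a priori as a similarity-dominant but non-degenerate default.

Design points that were genuinely open and how they were settled:

* **Valence partition.** Items are marked positive / negative / either.
  "Reduce to those marked positive" is read as admitting `either` items
  alongside `positive` ones (symmetrically for negative): items explicitly
  suitable for either kind of post would otherwise be suggestible only for
  neutral posts, defeating their purpose.
* **Separate pools.** Steps and actions are partitioned and scored as
  separate candidate pools because the product suggests one of each; whether
  a joint pool was used in any deployment is unknowable from the outside,
  and per-pool argmax is the reading consistent with "one step and one
  action".
* **Ties.** Exact ties are declared at tolerance $10^{-9}$ on the combined
  score (floating-point equality is meaningless) and resolved uniformly at
  random. Randomness is confined to one documented primitive — a single
  uniform draw over the sorted tie set under a caller-supplied seed; the
  step pool uses the seed itself and the action pool seed + 1 so the two
  draws are independent but both reproducible. Identical inputs and seed
  give identical results, byte for byte.
* **Threshold.** A minimum combined score $\tau$ (default 0) lets stricter
  deployments suppress weak suggestions; the default always suggests,
  matching observed product behavior.
* **No keywords.** A post with no extractable keywords gets similarity 0
  everywhere and selection rides on congruence alone — documented behavior,
  not an error.

## Discovery, analytics, chat

The non-personalized access points are deliberately plain: substring search
ranked title > keyword > tag; alphabetical browse; and four popularity
lists. *Hidden Treasures* sorts by ascending visit count **including**
never-visited steps, because surfacing the least-taken content is the
list's entire anti-informational-cascade purpose. "Recently taken" uses
all-time latest-timestamp order; a time window would be a configuration,
not a different algorithm.

Analytics unify the three denominators that deployment reports mix
("visits to steps/actions", "step visits", "action/step visits") as all
tracked step+action visits, with per-kind filtering available — the
bundled fixtures are constructed under that unified reading, scaled to 100
events so integer percentages are exact rather than approximate. Ledger
outcome counts always partition the ledger, and shares are scale-invariant.

The chat assistant is a rule-based slot-filling FSM
(greet → mood → topic → confirm → done, at most two reprompts per slot,
hence bounded dialogs). It is a front end, not a second scoring path: the
elicited text is concatenated and passed through `suggest()` exactly as a
newsfeed post, and the pre-chat profile handed to a moderator contains that
analysis verbatim. Reply wording lives in a YAML template file so tone can
be revised without touching logic.

## The synthetic-data generator

`generate_posts()` samples content tokens from lexicon strata — 60% from
the targeted emotion or sentiment stratum, the rest from the neutral
stratum — padded with ~30% stopwords, 30–45 content tokens per post by
default, fully seeded. `generate_catalog()` draws valences uniformly,
emotion vectors with one dominant emotion (0.5–1) over a low base (0–0.3),
keywords from the lexicon vocabulary, and guarantees resolvable
related-step links. These choices emulate the *structure* real inputs have
(emotionally slanted posts, topically keyworded items), not real user
language: no clinical vocabulary, no code-switching, no misspellings, no
distributional realism. Passing tests therefore demonstrate correctness of
the machinery under its stated contracts, not performance on clinical text.

The fixtures that mirror published deployment counts (the 701-record
suggestion ledger split 211/21/304/165; 100-event logs split 48/14/11/27
and 39/5/9/47) are built deterministically, with no randomness, so they are
byte-stable. Only four of the 24 strength names are public; the other
twenty in `canonical_strengths()` are synthetic and labelled as such, as
are all item-to-tag and item-to-strength assignments in the example
catalog.

## Verification strategy and sizes

Unit tests pin each operation to hand-computed examples. Property-style
tests run the full engine against an independent brute-force oracle
(plain loops, its own normalization, the shared tie-break primitive) on
200 seeded random instances of up to 50 items, check valence safety on the
same instances, fuzz the analyzer with 10,000 random token streams for
range safety, verify emotion recovery on 200 targeted posts per emotion,
and check the tie-break splits 50% ± 5% over 1,000 seeds. These sizes give
tight binomial confidence at interactive runtimes; the acceptance script
uses the same machinery at comparable sizes.

## Known limitations

* English-only, unigram, lexicon-bound analysis; sarcasm, idiom and
  misspellings defeat it. The analyzer is a contract-compatible stand-in,
  not a clinical NLP system, and no risk/suicidality detection is included.
* Dice-on-unigrams cannot see synonymy ("job" vs "work" only match if both
  appear); a richer similarity can be plugged in without touching the
  pipeline.
* The emotion-relevance vectors of catalog items are author-assigned
  inputs, not learned quantities.
* Engagement analytics account for logs; they make no causal claims about
  why one access path outperforms another.
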