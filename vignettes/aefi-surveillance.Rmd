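---
title: "Methods: social-media AEFI surveillance and hybrid ensemble sentiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social-media AEFI surveillance and hybrid ensemble sentiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aefitrends)
```

## The problem

Passive pharmacovigilance systems such as the UK Yellow Card scheme rely on
people choosing to file a report. During a mass vaccination campaign, much of
the public conversation about adverse effects following immunization (AEFI)
happens instead on social media, in free text, at volumes no spontaneous
reporting system sees. `aefitrends` implements a surveillance pipeline over
post corpora from such platforms: thematic keyword filtering down to
vaccine-related discourse, grouped counting of AEFI mentions over fixed time
bins, and a hybrid ensemble sentiment classifier aggregated into weekly
trend series. Because platform data cannot be redistributed, the package
also ships a seeded synthetic-corpus generator that reproduces the
statistical structure the analysis assumes, making every stage testable.

## Pipeline model

The pipeline, in order, with the operation that implements each stage:

1. **Load and clean** (`read_corpus()`, `deduplicate_posts()`,
   `exclude_reposts()`, `geo_filter()`). A post record carries platform,
   post and user identifiers, a UTC timestamp, text, an optional ISO-3166
   country code and a repost flag. Deduplication keys on
   (platform, post_id) — identical text cross-posted by different users is
   legitimately distinct content. Repost exclusion removes flagged records
   plus twitter records prefixed `"RT @"`. The geographical filter keeps
   posts whose country equals the target (default `GB`); posts with *no*
   country are dropped, the conservative reading of applying a
   geographical filter across a whole data set when unlocated posts cannot
   be attributed to the target country.
2. **Thematic filter** (`apply_filter()`): an inclusive calendar window
   (default 2020-12-08 to 2021-04-30, the first five months of the UK
   rollout) followed by ordered keyword stages. The canonical configuration
   is two stages — pandemic terms, then vaccine and manufacturer terms. The
   stage-1 survivors are the corpus for AEFI counting; the stage-2
   survivors, necessarily a subset, feed sentiment analysis. Matching is
   case-insensitive with word boundaries: a term matches only when
   delimited by non-alphanumerics or string edges, and multi-word phrases
   match as contiguous token sequences. A `substring` mode exists per stage
   for hashtag-dense text (`#covidvaccine`), where word boundaries would
   miss embedded keywords. The shipped stage lexicons are sensible
   defaults, not an authoritative list; both are configurable from YAML or
   JSON (`read_filter_config()`).
3. **AEFI mention counting** (`count_mentions()`, `bin_mentions()`,
   `mention_percentages()`): a lexicon maps group names (appetite, allergy,
   injection_site, clots, bell_palsy, guillain_barre, headache, fever,
   diarrhea, generalized) to term lists. Counting is *mention-level*: each
   non-overlapping occurrence of each term counts, so one post can
   contribute several mentions to several groups — the unit is the mention,
   not the post, which is what makes group totals far exceed post counts on
   real corpora. Occurrences of the same term are scanned left-to-right
   without overlap; whether repeated occurrences within one post should
   count once or many times is genuinely open, and counting them all is the
   documented choice. A term may appear in two groups (counted in both,
   with a load-time warning); group disjointness is not assumed. Counts are
   binned by `floor((t - origin)/14 days)` with the origin fixed at the
   campaign start (2020-12-08), bins left-closed right-open, empty and
   final partial bins retained.
4. **User activity** (`user_activity()`): per-user post counts, mean
   (= posts/users exactly), sample (n-1) standard deviation, and a
   log-count histogram, since posts-per-user on these platforms is
   heavy-tailed and approximately log-normal.
5. **Hybrid ensemble sentiment** (`weighted_lexicon_score()`,
   `ensemble_classify()`, `classify_corpus()`): two continuous lexicon
   scorers are averaged with convex weights — 0.45 for the scorer in the
   valence-aware compound role and 0.55 for the scorer in the
   pattern-polarity role, the latter weighted higher for its marginally
   better positive-class accuracy. The averaged score is combined with a
   categorical model by an if-else rule: **if** the weighted score exceeds
   the positivity threshold, the final label is positive; **else** the
   categorical model's label is taken wholesale (lexicon scorers do better
   on positive text, categorical models on negative/neutral). The
   lexicon-stage negative/neutral distinction is deliberately unused on the
   else branch.
6. **Trends and reporting** (`weekly_trend()`, `overall_proportions()`,
   `annotate_events()`, `build_report()`): per-week label counts and
   proportions (origin 2020-12-08, width 7 days), overall percentages, an
   annotated Figure-style line plot, and a markdown + CSV run report in
   which every number is written from the same objects as the CSVs.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `weight_a`, `weight_b` | 0.45, 0.55 | convex weights | fixed ensemble weights; configurable, not re-fit (re-fitting needs labeled data — see `score_against_truth()`) |
| `positive_threshold` | 0.05 | polarity | conventional compound-score positivity cutoff; the score-to-label boundary is not otherwise pinned down, and a score exactly at the threshold goes to the else branch |
| `bin_width` (mentions) | 14 | days | biweekly surveillance bins anchored at the rollout start |
| `bin_width` (trend) | 7 | days | weekly sentiment series |
| date window | 2020-12-08 to 2021-04-30 | inclusive UTC dates | first five months of the UK campaign |
| `sentiment_mix` | 0.58/0.22/0.19 | probabilities | generator default, the aggregate positive/negative/neutral split of UK vaccine discourse in that window (renormalized from the printed integers) |
| `activity_mu`, `activity_sigma` | platform presets | log scale | see below |

"Average weekly sentiment" is operationalized as the per-week
label-proportion triple rather than a mean of numeric scores, consistent
with reporting percentages per class; the per-record `weighted_score` column
is retained so a numeric weekly mean can also be derived. The printed split
58+22+19 = 99 is treated as rounding, not a fourth class: the generator
renormalizes the triple, and reports show full-precision proportions
alongside rounded percentages.

## What the synthetic generator emulates

`generate_corpus()` draws, per user, a post count from the discretized
log-normal law `max(1, round(exp(N(activity_mu, activity_sigma))))` — the
simplest discretization that preserves the log-normal shape while
guaranteeing every counted user has at least one post. Platform presets are
moment-matched so the *continuous* law has mean/SD 3.26/6.40
(facebook) and 2.01/1.76 (twitter) posts per user; rounding and clamping
shift the realized mean upward somewhat (to roughly 2.8 for the facebook
preset), which is accepted — the presets are a calibration convenience, not
a fitted claim. Timestamps are uniform over the window, as no within-window
posting density is assumed.

Post text is assembled from neutral filler plus, at configured
probabilities, theme keywords (stage-1 *and* stage-2 together, probability
`theme_pass_prob`), one embedded term per mentioned AEFI group, and a
sentiment-bearing phrase matching the post's true label. Three properties
of the phrase banks are deliberate:

* the three sentiment banks use disjoint vocabularies, with no valenced
  word in the neutral bank, so the built-in lexicon scorers agree with the
  ground-truth label on ≥95% of generated posts and the keyword-oracle
  doubles agree exactly — this is what makes end-to-end recovery tests
  meaningful without training data;
* embedded AEFI terms each match exactly one lexicon term, so a mentioned
  group contributes exactly one counted mention and group probabilities are
  identifiable from mention shares;
* filler, theme and AEFI fragments contain no valenced words, and sentiment
  phrases contain no theme or symptom terms, so the three channels
  (filtering, counting, scoring) do not confound one another.

What the generator does **not** emulate: linguistic variety, sarcasm,
negated symptom talk ("no headache"), retweet cascades, bot behavior, or
any user network structure. Passing recovery tests therefore demonstrates
the pipeline's arithmetic and contracts, not classifier performance on real
social-media language — on real text the built-in scorers are small
dictionary models and should be treated as baselines, with the transformer
adapter slot (`categorical =`) taking a proper fine-tuned classifier.

## Numerical and degenerate-input choices

* Word-boundary matching uses Unicode case folding; emoji, URLs and user
  mentions are left in place and simply never match word-boundary terms.
* Scorers receive un-normalized text (no lowercasing before the user's
  scorer), since lexicon scorers may use capitalization as an intensity
  cue; the built-in scorers fold case internally.
* An empty corpus: filters return empty outputs with zero counts;
  `bin_mentions()` returns a full table of zeros when given the lexicon's
  group names; `weekly_trend()` flags every bin empty with `NA` proportions
  (never 0/0); `user_activity()` and `overall_proportions()` refuse empty
  input as a contract error.
* A weighted score exactly at `positive_threshold` takes the else branch
  (the rule is strictly "exceeds").
* The categorical model is invoked lazily; its absence on the else branch
  is an explicit `model_unavailable` error, never a silent fallback.
* Timestamps before the bin origin are a contract violation, not silently
  dropped.
* Probabilities, dates and weights are validated at construction with
  errors naming the offending field; `sentiment_mix` must sum to 1 within
  1e-9 after renormalization.

## Problem sizes in the test suite

Unit tests run on corpora of 10–800 users (hundreds to a few thousand
posts). Distributional recovery checks (sentiment mix within ±0.02, group
shares within ±2 percentage points) use 4000-user corpora of at least
10,000 posts, where binomial standard errors are comfortably inside the
tolerances; the law-of-large-numbers check on the activity law compares
1000 generated users against a 200,000-draw brute-force simulation of the
same discretized law. The whole suite completes in well under a minute.

## Known limitations

* Mention counting has no negation or experiencer detection: "worried about
  clots" and "had clots" count identically, so counts measure discussion,
  not incidence.
* The shipped keyword and AEFI lexicons are defaults; real deployments
  should supply curated lists via the YAML/JSON config readers.
* The geographic filter abstracts over how a country code was derived
  (geotag, profile, page metadata); treatment of unlocated posts (dropped)
  is a policy choice, configurable only by pre-filtering yourself.
* Per-vaccine-brand sentiment splitting, changepoint attribution of trend
  inflections, and model training/fine-tuning are out of scope.

## A worked run

```{r example, fig.width = 7, fig.height = 4}
corpus <- generate_corpus(corpus_spec(n_users = 500, seed = 42))
pipeline <- run_pipeline(corpus$posts)
pipeline$sizes
pipeline$sentiment
glance(pipeline$activity)
autoplot(pipeline$trend)
```
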