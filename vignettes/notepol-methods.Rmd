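---
title: "Methods: sentiment, polarity and topics in nursing notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sentiment, polarity and topics in nursing notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notepol)
```

This vignette documents the models and procedures implemented in
`notepol`, the assumptions behind them, the parameters a user may want to
change, and the design decisions taken where the methodology left choices
open. It states no empirical claim that the test suite does not itself
compute.

## The data model

A corpus is a table of notes: `note_id`, `patient_id`, `group`
(`covid` / `non_covid`), `shift` (`morning` / `afternoon` / `night`),
ISO `date`, and raw `text`. Nursing notes are written up to three times a
day, once per shift, and are frequently copied verbatim into the next
shift's record; deduplication is therefore the first analysis step, not an
afterthought. A note is considered a copy-paste duplicate when its
whitespace-normalized, case-folded text matches an earlier note *of the
same patient*; the earliest record (date, then shift order, then id)
survives. The per-patient scope is a deliberate choice — copy-paste
happens within one chart — and a corpus-wide scope is available via
`deduplicate(..., scope = "corpus")` for sensitivity analysis.

Two token streams flow out of preprocessing, and they are intentionally
different:

* **content lemmas** (lemmatized, stopwords removed) feed sentiment
  scoring, topic modeling and classification;
* **raw lowercased sentences** (stopwords retained, commas kept as
  tokens) feed the polarity score, because negators ("no"), amplifiers
  ("muy") and deamplifiers ("poco") are exactly the function words a
  stopword list deletes. Whether the original workflow lemmatized before
  polarity is not documented; `polarity_corpus(use_lemmas = TRUE)` flips
  the choice.

Lemmatization is table-driven (surface → lemma TSV) with identity
fallback; no morphological analysis is attempted. This keeps the operation
idempotent and language-agnostic.

## Lexicon sentiment

Three dictionary schemas are supported: 10 emotion categories (anger,
anticipation, disgust, fear, joy, sadness, surprise, trust, negative,
positive), integer valences in −5..+5 (zero excluded), and binary
positive/negative. Scoring counts lemma occurrences with multiplicity; a
word listed under several emotion categories counts once per category, the
convention of emotion lexicons of this family.

Group differences are tested on the **raw count** contingency table
(never on percentages) with Pearson's χ², without Yates continuity
correction by default — note corpora give large tables, and the
uncorrected statistic matches the usual reporting; `yates = TRUE` is
available. Post hoc, each cell gets an adjusted standardized residual
\(z = (O - E)/\sqrt{E(1 - r/n)(1 - c/n)}\) with a two-sided normal test at
the Bonferroni level \(\alpha/m\) over the \(m\) testable cells. The
methodology we follow names only "Bonferroni-corrected post hoc" tests;
residual z-tests are the standard realization for χ² tables, and that
choice is confined to `posthoc_bonferroni()`.

## Sentence polarity

For every token found in the binary lexicon with polarity
\(p_i \in \{-1, +1\}\), a *context cluster* is formed: up to 4 tokens to
the left and 2 to the right (`polarity_config(before, after)`). If a comma
lies to the left of the anchor inside the window, only tokens after the
last such comma remain — a comma marks a clause boundary that shifters do
not cross. Comma tokens are never cluster members and do not count as
words. Cluster tokens are classified by the shifter lexicon as negators,
amplifiers or deamplifiers; everything else is neutral and affects only
the word count. The anchor's weight is

\[ w_i = p_i \cdot (-1)^{n_{neg}} \cdot \bigl(1 + \max(f,\; c\,(n_{amp} - n_{deamp}))\bigr) \]

with amplifier weight \(c = 0.8\) and deamplifier floor \(f = -1\) (so the
multiplicative factor never drops below zero — deamplifiers can silence a
word but not flip it). The sentence score is
\(\delta = \sum_i w_i / \sqrt{n}\), with \(n\) the sentence word count
excluding commas; \(\delta\) is unbounded by design. Note-level polarity
is the unweighted mean of its sentence scores, matching the comment-level
aggregation used when groups are compared.

**The combination rule is the package's declared reconstruction.** The
source methodology lists the ingredients (negators, amplifiers,
deamplifiers, the weight \(c\), the floor, \(\sqrt{n}\)) but its printed
formula is not legible; parity negation plus additive
\(c\,(n_{amp}-n_{deamp})\) follows the published behavior of the standard
augmented-dictionary polarity method. Because this is the one genuinely
underdetermined step, it is isolated in a single function
(`cluster_weight()`), and the test oracle — a separately written,
straight-line implementation (`build_polarity_fixtures()`) — encodes the
same rule: the exhaustive grid equivalence test verifies implementation
integrity, not the rule choice. Negated amplifiers are *not* reinterpreted
as deamplifiers; overlapping clusters of adjacent polarized words are
scored independently.

Trend confirmation uses a low-pass discrete Fourier filter
(`fourier_trend`): keep DC plus the `k_low` lowest nonzero frequencies
(conjugate-symmetric) and invert. A retained pure cosine passes through to
1e-9; `k_low >= floor(n/2)` leaves the series unchanged with a warning.

Group comparison: Lilliefors-corrected Kolmogorov-Smirnov normality
screening per group, then Mann-Whitney U. The Lilliefors p-value is
Monte-Carlo: the KS statistic of a standardized sample against its fitted
normal is parameter-free given \(n\), so the null table can be simulated
once (`lilliefors_null`, ≥ 2000 reps) and reused; the standard KS tables
would be anti-conservative here. The Mann-Whitney implementation uses
mid-ranks, tie-corrected variance and a continuity correction, and reports
the normal-approximation Z alongside U and the two-sided p — the form in
which clinical studies quote the test.

## Temporal comparison

Monthly series per group: a sentiment category's value is its share of
that group's matched tokens in the month; polarity's value is the monthly
mean of note polarity. Months without notes are omitted, so two groups'
series may have different lengths — the reason dynamic time warping is
used rather than pointwise distances. `dtw_distance` is the classic
dynamic program with squared-difference local cost and symmetric unit-
weight steps; the reported distance is \(\sqrt{C^*}/(|a|+|b|)\), a
path-length-normalized Euclidean-type distance comparable across lengths.
The normalization scheme is not fully specified by the phrase "normalized
Euclidean distance"; endpoint normalization with symmetric steps is the
common convention and is pinned by tests against exhaustive path
enumeration. No warping window is imposed: the series here have at most
six points.

## Topic modeling

`fit_lda` implements collapsed Gibbs sampling for symmetric-prior LDA
(defaults \(\alpha = 50/K\), \(\eta = 0.01\), 1000 sweeps, 500 burn-in,
thinning 10; the estimation settings of the original analysis are not
documented, so these are declared package defaults, not inferred values).
\(\hat\beta\) and \(\hat\theta\) are posterior means over post-burn-in
thinned sweeps; the collapsed joint log-likelihood is recorded per sweep
for monitoring, and token-count conservation is asserted inside the
sampler. The sampler consumes R's RNG, so a fixed seed fixes the fit. The
test suite runs reduced schedules (300/150/5) to stay inside its time
budget; the recovery tests pass at those settings.

Model selection fits a K grid and computes two per-topic criteria, both
"higher is better":

* **semantic coherence** over the top-\(M\) (=10) words by \(\hat\beta\):
  \(\sum_{i<j} \log\frac{D(w_i, w_j) + 1}{D(w_j)}\) with \(D\) document
  (co-)frequencies — the +1-smoothed co-occurrence form; pairs whose
  conditioning word never occurs contribute zero;
* **FREX exclusivity**: for each top word, the harmonic mean (exclusivity
  weight 0.7) of its share \(\hat\beta_{t,w}/\sum_{t'}\hat\beta_{t',w}\)
  and its within-topic frequency quantile.

The automatic rule maximizes the rank-sum of the two criteria (ties toward
smaller K), and the full frontier is returned so a human can override the
choice, as the original analysts did when they fixed their model at ten
topics. The rank-sum rule is the package's own; the methodology states
only the two criteria.

**Covariate prevalence is a declared approximation.** The original
analysis used structural topic modeling, which places covariates inside
the topic prior. `notepol` fits plain LDA and regresses each
\(\hat\theta\) column on group, month index and their interaction
post hoc. The month index is centered so the group coefficient is the
group contrast at the average month rather than an extrapolation to
month zero — without centering the permutation test loses most of its
power in an interaction model. Significance for the group and interaction
terms comes from permuting group labels within month strata (seeded,
default 999 permutations, p = (1 + exceedances)/(B + 1)); the month trend
keeps its analytic t-test. The estimation is isolated behind
`prevalence_effects()` so an STM backend could replace it without touching
callers. Topic correlations are Pearson correlations of the \(\hat\theta\)
columns (note these are compositional, hence slightly negatively biased);
network edges keep \(|r| \ge 0.3\).

## Classification

Features are content-lemma counts (`build_dtm`; tf-idf behind a flag —
counts are the simplest reading of "documents" here). The split is random,
stratified by class, 75/25 by default, deterministic per seed. The native
learner is multinomial naive Bayes with add-1 smoothing, scoring posterior
log-odds; SVMs, random forests and neural networks are deliberately *not*
reimplemented — they enter through the backend contract
(`fit(x, y)`; `predict(model, x)` → scores + labels), as the packaged
ridge-logistic `backend_glmnet()` demonstrates. All backends share the
identical split and metric suite, and a failing backend is isolated to its
own row.

Metrics: AUC by the rank (Mann-Whitney) formulation with mid-rank ties
(tested against exhaustive pairwise comparison); sensitivity, specificity
and Cohen's \(\kappa\) from the confusion matrix; exact Clopper-Pearson
95% CI for accuracy; and "accuracy (P value)" realized as the one-sided
exact binomial test of accuracy against the no-information rate (the
majority-class share) — the conventional meaning of accuracy significance
in this workflow, stated explicitly because the source leaves it implicit.

## The synthetic world

`generate_corpus()` emulates the *structure* of a shift-based nursing
corpus, not its language: an abstract topic vocabulary (`w0001`, ...)
drawn from a per-note LDA process; one sentiment-slot emission per
sentence from a per-group positive/negative/neutral mix; valence shifters
prepended to sentiment words at a configurable rate; interspersed
stopwords and commas; 1–6 sentences of 3–15 topic tokens per note (the
real notes' length distribution is undocumented; these defaults are
declared in `synth_config` and exposed); up to three notes per patient-day
in distinct shifts; and verbatim duplicates — full text and metadata
copied, fresh id, timestamp advanced one shift — at exactly
`round(duplicate_rate × N)` of the final corpus. Every generated sentence
carries its analytic polarity computed by the independent oracle, and the
truth object records topic-word/doc-topic distributions, per-token topic
assignments, emission counters and the duplicate ledger.

A green test on this corpus establishes that the *machinery* is correct —
scores match oracles, planted effects are recovered, null calibrations
hold. It does not establish anything about real clinical language:
Spanish morphology, negation scope beyond function-word windows, topic
semantics, or the empirical values reported for any hospital corpus
(which would require the undeposited data). Calibration tests reduce the
generator to its exact corpus-level law where that is equivalent (e.g.
per-group category counts are multinomial in the emission mix —
`simulate_sentiment_tables`), trading no fidelity for large speedups.

## Numerical and degenerate-input choices

* Simplexes are validated to 1e-8; stochastic-matrix rows to 1e-9.
* A sentence with no binary-lexicon match scores δ = 0 (not `NA`): absence
  of polarized vocabulary is a neutral observation.
* Constant samples make the Lilliefors statistic undefined — flagged, not
  silently skipped; all-tied Mann-Whitney returns Z = 0, p = 1.
* χ² requires a 2×2-or-larger table with positive margins;
  all-zero categories are dropped before testing.
* `fit_lda` accepts K = 1 as the closed-form degenerate case (smoothed
  corpus frequencies), which the tests use as an anchor.
* Duplicate counts solve `d = round(rate · (base + d))` exactly by local
  search, so the planted count matches the advertised invariant even at
  awkward rates.
* Every stochastic stage derives a named substream seed
  (`derive_seed(seed, name)`, kept below 2^31); the pipeline manifest
  records all of them, and reruns are bit-identical.

## Configuration note

The pipeline configuration is JSON (`read_pipeline_config`), not YAML: the
package keeps its dependency set to what a minimal scientific R stack
guarantees, and `jsonlite` is already required for the manifests and
reports.

## Known limitations

* Polarity's combination rule is a reconstruction (see above); an
  alternative rule drops into `cluster_weight()`.
* Post hoc prevalence regression is not STM: prior-level covariate effects
  and content covariates are out of scope.
* Lemmatization is lookup-only; unseen inflections pass through unchanged.
* The Fourier filter assumes an evenly spaced series; monthly aggregation
  guarantees that only when every month is populated.
* Topic "specificity" (the observation that topics concentrate in few
  documents) is reported descriptively (`topic_concentration`: the θ̂ mass
  carried by a topic's top documents) without a formal test, as no formal
  statistic is defined for it.
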