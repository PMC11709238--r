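---
title: "Auditing occupational and mental-health bias in static word embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing occupational and mental-health bias in static word embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Static word embeddings — word2vec, GloVe — map vocabulary tokens to dense
real vectors so that words used in similar contexts land close together.
These models sit inside resume parsers and job recommender systems, so any
systematic geometry linking psychiatric diagnoses to concepts like
*unemployable* or *unreliable* is a concrete allocation-harm risk for job
seekers with mental-health conditions. `embedaudit` packages the two
standard desk-audits for this question:

1. **Analogy probes.** An analogy *A : B :: C : ?* is answered by the
   3CosAdd rule: rank every vocabulary token by its cosine similarity to
   the composite vector \(v(B) - v(A) + v(C)\). Probing, say,
   *healthy : employable :: depression : ?* and checking where a curated
   lexicon of undesirable terms (unemployable, unreliable, incompetent, …)
   appears in the ranked completions gives a per-query bias statistic —
   the **first biased rank**. A biased term at rank 1 is the strongest
   signal; absence from the top-10 is the null.
2. **Semantic-axis projection.** A pole pair such as (*healthy*, *ill*)
   defines an axis vector \(v(\text{healthy}) - v(\text{ill})\); a term's
   score on the axis is its cosine similarity to that difference vector,
   in \([-1, 1]\). Scoring diagnoses and control terms against two axes at
   once (healthy–ill × employable–unemployable, and the synonym check
   normal–abnormal × reliable–unreliable) yields a 2-D coordinate table
   and scatter plot in which clusters and outliers are read directly.

Both audits are *read-only*: the pretrained embedding is never fine-tuned
or otherwise adjusted, so the findings characterize the artifact that
downstream systems actually consume.

## Conventions and the choices behind them

Several details of analogy answering differ between libraries and
materially change results; the package fixes them as follows.

* **Normalized composite.** The three input vectors are unit-normalized
  before the arithmetic, and the reported similarity of each candidate is
  its cosine against the composite \(v(B) - v(A) + v(C)\) (not against
  \(v(C)\) alone). This is the convention of the widely used
  `most_similar`-style query interfaces, and the one under which their
  published similarity scores are reproducible. `analogy_target()` exposes
  `normalize_inputs` for the rare case where raw vectors are wanted.
* **Input exclusion ("all terms different").** By default the three probe
  terms are removed from the candidates, matching standard library
  behaviour. The convention is debatable — when the unbiased completion
  *is* the input attribute (e.g. *doctor* back for *doctor*), forcing a
  different word can manufacture bias — so the flag is exposed
  (`exclude_inputs`), and every result records whether an excluded input
  would have out-ranked the reported top-1. Exclusion is exact-case only:
  differently-cased vocabulary entries ("Doctor" for the probe "doctor")
  remain candidates, which is how the reference query libraries behave;
  `exclude_case_variants = TRUE` tightens this.
* **Case.** Stores are case-sensitive — "Lawyer" and "lawyer" are distinct
  tokens, deliberately, so that same-word returns remain observable. Case
  fallback (exact → lowercase → Capitalized) is applied only at query
  time, and only when requested.
* **Multiword probes.** GoogleNews stores phrases underscore-joined
  ("anxiety_disorder"); word-level GloVe vocabularies do not. The default
  `mean_of_words` policy therefore tries the underscore-joined phrase
  first and falls back to the mean of the constituent in-vocabulary word
  vectors. This is a documented stand-in: the phrase-resolution behaviour
  of every third-party query tool is not public, so multiword GloVe scores
  should be compared across runs of *this* package, not across tools.
* **Bias lexicon matching** is case-insensitive after folding underscores
  to spaces: the statistic counts semantic hits, not surface forms.
* **Determinism.** Nearest-neighbour search is exhaustive and exact, ties
  break by ascending vocabulary (file) index, and no approximate index is
  used. Identical inputs give byte-identical outputs.
* **Degenerate inputs.** Cosine similarity with a zero-norm vector is an
  error; all-zero embedding rows are kept in the vocabulary but never
  candidates. Identical pole vectors give a degenerate-axis error rather
  than a zero axis. Cosines are clamped to \([-1, 1]\) against
  floating-point overshoot.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | report depth per analogy; rank-1 is the headline statistic, ranks 2–10 the softer evidence |
| `exclude_inputs` | `TRUE` | the all-terms-different convention (see above) |
| `oov_policy` | `mean_of_words` | OOV resolution: `error`, `case_fallback`, or underscore-join + word-mean |
| lexicon | shipped file | undesirable counterparts of the audited attributes; unitless set membership |
| pole pairs | healthy–ill, employable–unemployable (plus normal–abnormal, reliable–unreliable) | axis definitions; scores are cosines, dimensionless in \([-1,1]\) |

The shipped battery crosses the four employability attributes
(employable, reliable, competent, resilient) with three diagnoses
(psychosis, depression, anxiety_disorder) anchored at *healthy*, adds six
prestige professions probed for psychosis, and keeps
capital–country and gender–profession control queries in both directions.
All of it is a TSV you can replace.

## The synthetic generator

Auditing pretrained models needs multi-gigabyte downloads, so the package
carries a seeded generator (`synthetic_spec()`, `generate_embeddings()`)
whose stores have *known* geometry:

* Two orthogonal axis directions \(u_x, u_y\) are drawn as columns of a
  random orthonormal basis; the four pole words are planted at
  \(\pm u_x, \pm u_y\), so a built axis is exactly \(2u\).
* A planted term with target loadings \((x, y)\) gets the vector
  \(x\,u_x + y\,u_y + r\,u_{res} + \varepsilon\), where
  \(r = \sqrt{\max(0, 1 - x^2 - y^2)}\), \(u_{res}\) is a term-specific
  unit vector orthogonal to both axes, and
  \(\varepsilon \sim N(0, \sigma^2 I)\). At \(\sigma = 0\) the planted
  vector has unit norm and its axis projections equal \((x, y)\)
  *exactly*, giving closed-form ground truth.
* An analogy quadruple \((a, b, c, d)\) plants
  \(v(d) = \hat v(b) - \hat v(a) + \hat v(c) + \eta\) and enforces a
  cosine margin: every other token must score at least `margin` below
  \(d\) against the composite target (offending background words are
  resampled; an unachievable margin is an error, not a silent pass).
* Background words are isotropic unit vectors; planted vectors are stored
  raw (unnormalized) so the scoring path's normalization is exercised.

Defaults are d = 50, 500 background words, σ = 0.02, seed 20250108.

**What passing synthetic tests does and does not show.** The generator
emulates the *geometry* the pipeline must read out — controlled axis
loadings, exact parallelograms, isotropic distractors. It does not emulate
real co-occurrence structure: anisotropic vector clouds, frequency
effects, hubness, or correlated near-synonyms. Recovery of planted
structure therefore validates the machinery (I/O, normalization, search,
scoring, reporting), not any claim about how much bias a particular
pretrained model contains; that question is answered only by running the
audit on the real files.

## Verification problem sizes

The test suite and `scripts/acceptance.R` verify, at these sizes: exact
agreement of `top_k` with an independent brute-force full-sort oracle on
200 randomized stores (|V| ≤ 200, d ≤ 20, k ≤ 10); projection-score
recovery on 20 seeded stores of 30 planted terms at σ = 0.01 (Pearson
r ≥ 0.99 per axis, exact to 1e-6 at σ = 0); planted biased completions
recovered at rank 1 in 50/50 seeded replicates at margin 0.05; round-trip
identity through all three file dialects (1e-6; 1e-3 for GloVe's six
printed decimals); and the cosine contract (symmetry, scale invariance,
±1 and orthogonality endpoints).

## Known limitations

* Scores from word-mean OOV resolution are stand-ins wherever a phrase is
  missing from the vocabulary (see above).
* The bias statistic is strict lexicon membership; near-miss completions
  ("unreliability" when only "unreliable" is listed) count only if
  enumerated. Curating the lexicon is part of the audit design.
* No significance testing is attached to rank differences, and
  association-test metrics (WEAT/MAC/SAME) and contextual models
  (BERT/ELMo) are out of scope.
* Whole-file loaders hold the matrix in memory; the 3-million-word
  GoogleNews binary needs ~3.6 GB and patience, but runs.
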