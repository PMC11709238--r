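# embedaudit

Bias audits for static word embeddings, aimed at occupational stigma
against psychiatric diagnoses. Word2vec- and GloVe-style embeddings power
resume parsers and job recommender systems; if their geometry ties
*depression* or *psychosis* to *unemployable* or *unreliable*, that bias
flows straight into hiring pipelines. `embedaudit` gives
mental-health-informatics and fairness researchers the two standard
desk-audits as reproducible, scriptable primitives:

* **3CosAdd analogy probes.** An analogy *A : B :: C : ?* is answered by
  ranking every vocabulary token by cosine similarity to
  v(B) − v(A) + v(C) (inputs unit-normalized), with exact, exhaustive
  top-k search. Each query is scored by the **first biased rank**: the
  smallest position at which a token from a curated lexicon of
  undesirable completions (unemployable, unreliable, incompetent, …)
  appears.
* **Semantic-axis projection.** A pole pair (*healthy*, *ill*) defines
  the axis vector v(healthy) − v(ill); a term's score is its cosine
  similarity to that difference, in [−1, 1]. Diagnoses and control terms
  are placed on two axes at once (e.g. healthy–ill ×
  employable–unemployable) and emitted as a coordinates table plus a
  colour-coded scatter plot.

The package reads the word2vec binary, word2vec text and GloVe text
dialects, ships the default probe battery, bias lexicon and term lists as
editable config files, and includes a seeded synthetic-embedding
generator with planted axis loadings and analogy parallelograms so the
whole pipeline is testable without downloading pretrained models.

## Worked example

On a synthetic store with a planted parallelogram
v(unemployable) = v(employable) − v(healthy) + v(psychosis) and three
terms planted at known axis loadings:

```r
library(embedaudit)

spec <- synthetic_spec(
  dim = 50, n_background = 300,
  planted_terms = data.frame(term = c("depression", "obesity", "tall"),
                             x = c(-0.10, 0.13, 0.05),
                             y = c(-0.08, 0.02, 0.10)),
  pole_pairs = list(x = c("healthy", "ill"), y = c("good", "bad")),
  analogy_quads = data.frame(a = "healthy", b = "employable",
                             c = "psychosis", d = "unemployable",
                             margin = 0.05),
  noise_sd = 0.02, seed = 20250108)
store <- generate_embeddings(spec)$store

run_analogy(store, analogy_query("healthy", "employable", "psychosis"),
            default_bias_lexicon())
#> 'healthy' is to 'employable' as 'psychosis' is to:
#>           token similarity biased
#> 1  unemployable     0.9961   TRUE
#> 2           ill     0.5159  FALSE
#> 3    noise_0245     0.3559  FALSE
#> ...
#> first biased completion at rank 1
```

The planted biased completion is recovered at rank 1 with cosine 0.9961
against the composite query vector — on a real store this is the paper-
style headline finding, a biased term as the single best completion. The
projection audit recovers the planted loadings (σ = 0.02 noise accounts
for the wobble around the planted (−0.10, −0.08), (0.13, 0.02),
(0.05, 0.10)):

```r
xa <- build_axis(store, "healthy", "ill")
ya <- build_axis(store, "good", "bad")
project_battery(store,
  term_set(c("depression", "obesity", "tall"),
           c("psychiatric", "physical", "favourable_attribute")), xa, ya)
#>         term             category       x       y
#> 1 depression          psychiatric -0.1146 -0.0937
#> 2    obesity             physical  0.1447  0.0313
#> 3       tall favourable_attribute  0.0768  0.1105
```

A negative `x` means the term sits closer to the *ill* pole than the
*healthy* pole; here *depression* is the most "ill" and least "good" of
the three, exactly as planted.

To audit a real pretrained model, point the config at the file and run
everything at once (the shipped battery and term lists are used when none
are given):

```sh
Rscript inst/cli/embedaudit.R audit-all --config my_audit.yaml
```

with `my_audit.yaml` based on
`inst/extdata/audit_config_template.yaml` — it names the embedding file
(e.g. the uncompressed GoogleNews `.bin` or a GloVe `.txt`), and the run
writes per-query TSV tables, a JSON summary, scatter plots and a
plain-text report with the file's checksum for provenance.

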