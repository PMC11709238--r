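Package: embedaudit
Title: Bias Audits for Static Word Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing occupational and mental-health bias in
    pretrained static word embeddings. Reads word2vec (binary and text)
    and GloVe vector files, answers A:B::C:? word analogies by the
    3CosAdd rule with exact top-k nearest-neighbour search, computes a
    biased-completion rank statistic against a curated lexicon, and
    places probe terms on pole-word semantic axes (e.g. healthy-ill by
    employable-unemployable) via cosine similarity to pole difference
    vectors. A seeded synthetic-embedding generator with planted axis
    loadings and analogy parallelograms makes every stage testable
    without downloading pretrained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
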