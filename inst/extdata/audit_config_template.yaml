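# Template config for `run_full_audit()` / the embedaudit CLI.
# Relative paths resolve against this file's directory.
embeddings:
  path: GoogleNews-vectors-negative300.bin   # uncompressed
  format: word2vec_binary                    # word2vec_binary | word2vec_text | glove_text
  oov_policy: mean_of_words                  # error | case_fallback | mean_of_words

# Omit `battery` / `lexicon` / `terms` to use the package defaults.
analogy:
  # battery: my_battery.tsv      # columns: a  b  c  k  group
  # lexicon: my_lexicon.txt      # one biased term per line

axes:
  # terms: my_terms.tsv          # columns: term  category
  pairs:
    - x: [healthy, ill]
      y: [employable, unemployable]
    - x: [normal, abnormal]
      y: [reliable, unreliable]
  plot: true

out: audit_output
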