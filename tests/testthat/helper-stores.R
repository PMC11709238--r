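# Shared fixtures: randomized stores and an independent brute-force
# nearest-neighbour oracle (scalar cosine per token + full sort), kept
# deliberately separate from the package's matrix-product code path.

random_store <- function(V, d, seed, tokens = sprintf("w%03d", seq_len(V))) {
  set.seed(seed)
  word_vector_store(tokens, matrix(stats::rnorm(V * d), V, d))
}

oracle_cosine <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))

oracle_top_k <- function(store, query, k, exclude = character(0)) {
  sims <- vapply(seq_along(store$tokens), function(i) {
    oracle_cosine(store$matrix[i, ], query)
  }, numeric(1))
  norms <- vapply(seq_along(store$tokens), function(i) {
    sqrt(sum(store$matrix[i, ]^2))
  }, numeric(1))
  keep <- which(norms > 0 & !(store$tokens %in% exclude))
  ord <- keep[order(-sims[keep], keep)]
  ord <- utils::head(ord, k)
  data.frame(token = store$tokens[ord],
             similarity = pmin(1, pmax(-1, sims[ord])),
             stringsAsFactors = FALSE)
}

# random loadings inside the unit disk, away from the rim so the
# residual direction keeps some mass
random_loadings <- function(n, seed) {
  set.seed(seed)
  r <- sqrt(stats::runif(n)) * 0.95
  th <- stats::runif(n, 0, 2 * pi)
  data.frame(term = sprintf("term_%03d", seq_len(n)),
             x = r * cos(th), y = r * sin(th), stringsAsFactors = FALSE)
}
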