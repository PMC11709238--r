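planted_bias_store <- function(seed = 1, margin = 0.05, noise_sd = 0,
                               n_background = 200) {
  spec <- synthetic_spec(
    dim = 50, n_background = n_background,
    pole_pairs = list(x = c("healthy", "ill"), y = c("good", "bad")),
    analogy_quads = data.frame(a = "healthy", b = "employable",
                               c = "psychosis", d = "unemployable",
                               margin = margin),
    noise_sd = noise_sd, seed = seed)
  generate_embeddings(spec)$store
}

test_that("lexicon matching is case-insensitive and folds underscores", {
  lex <- bias_lexicon(c("unemployable", "not_hireable"))
  s <- word_vector_store(c("seed", "Unemployable", "not hireable", "employable"),
                         rbind(c(1, 0), c(0.9, 0.1), c(0.8, 0.2), c(0.7, 0.3)))
  r <- run_analogy(s, analogy_query("seed", "seed", "seed", k = 3), lex,
                   oov_policy = "error")
  expect_identical(r$ranked$token[r$ranked$biased],
                   c("Unemployable", "not hireable"))
})

test_that("a planted biased completion is found at rank 1", {
  s <- planted_bias_store(seed = 7)
  r <- run_analogy(s, analogy_query("healthy", "employable", "psychosis"),
                   default_bias_lexicon())
  expect_identical(r$ranked$token[1], "unemployable")
  expect_identical(r$first_biased_rank, 1L)
  expect_identical(r$biased_positions, 1L)
  # matches the independent oracle on the same composite target
  t <- analogy_target(s, "healthy", "employable", "psychosis")
  want <- oracle_top_k(s, t, k = 10,
                       exclude = c("healthy", "employable", "psychosis"))
  expect_identical(r$ranked$token, want$token)
})

test_that("a lexicon token orthogonal to the target outside the top-k is not reported", {
  # target direction e1; the lexicon token sits on e3 (cosine 0) while
  # 20 decoys hug e1, so no biased item can enter the top 10
  d <- 5
  e <- diag(d)
  set.seed(9)
  decoys <- t(vapply(1:20, function(i) {
    v <- e[1, ] + 0.05 * stats::rnorm(d)
    v / sqrt(sum(v^2))
  }, numeric(d)))
  s <- word_vector_store(
    c("a", "b", "c", "unemployable", sprintf("d%02d", 1:20)),
    rbind(e[2, ], e[2, ] + e[1, ], e[4, ], e[3, ], decoys))
  r <- run_analogy(s, analogy_query("a", "b", "c", k = 10),
                   bias_lexicon("unemployable"), oov_policy = "error")
  expect_true(is.na(r$first_biased_rank))
  expect_length(r$biased_positions, 0)
})

test_that("input exclusion removes the probe terms from the completions", {
  for (seed in 1:5) {
    s <- planted_bias_store(seed = seed)
    q <- analogy_query("healthy", "employable", "psychosis")
    r <- run_analogy(s, q, default_bias_lexicon())
    expect_false(any(c(q$a, q$b, q$c) %in% r$ranked$token))
    # with exclusion off the inputs are eligible again
    q2 <- analogy_query("healthy", "employable", "psychosis",
                        exclude_inputs = FALSE)
    r2 <- run_analogy(s, q2, default_bias_lexicon())
    expect_gte(nrow(r2$ranked), nrow(r$ranked))
  }
})

test_that("the audit annotates when an excluded input would out-rank the top-1", {
  s <- random_store(40, 10, seed = 61)
  # a = b makes the target exactly v(c): the excluded input c is top-1
  r <- run_analogy(s, analogy_query("w003", "w003", "w010"), NULL,
                   oov_policy = "error")
  expect_identical(r$input_outranked, "w010")
  expect_false("w010" %in% r$ranked$token)
})

test_that("growing the lexicon can only keep or lower the first biased rank", {
  s <- planted_bias_store(seed = 13, n_background = 100)
  q <- analogy_query("healthy", "employable", "psychosis")
  full <- c("unemployable", s$tokens[startsWith(s$tokens, "noise")][1:20])
  prev <- Inf
  for (n in c(1, 5, 10, 21)) {
    r <- run_analogy(s, q, bias_lexicon(full[seq_len(n)]))
    rank_n <- if (is.na(r$first_biased_rank)) Inf else r$first_biased_rank
    expect_lte(rank_n, prev)
    prev <- rank_n
  }
})

test_that("query reversal swaps the anchor and probe and is an involution", {
  q <- analogy_query("man", "doctor", "woman")
  rq <- reverse_query(q)
  expect_identical(c(rq$a, rq$b, rq$c), c("woman", "doctor", "man"))
  expect_identical(reverse_query(rq), q)
  tq <- reverse_query(analogy_query("Tokyo", "Japan", "London"))
  expect_identical(c(tq$a, tq$b, tq$c), c("London", "Japan", "Tokyo"))
})

test_that("batteries preserve order, record per-query errors, and are deterministic", {
  s <- planted_bias_store(seed = 17, n_background = 50)
  lex <- default_bias_lexicon()
  queries <- list(
    analogy_query("healthy", "employable", "psychosis"),
    analogy_query("healthy", "employable", "nosuchterm"),
    analogy_query("healthy", "employable", "psychosis"))
  res <- run_battery(s, queries, lex)
  expect_length(res, 3)
  expect_s3_class(res[[1]], "analogy_result")
  expect_s3_class(res[[2]], "analogy_error")
  expect_match(res[[2]]$error, "nosuchterm")
  # duplicated query gives an identical result; whole run reproduces
  expect_identical(res[[1]], res[[3]])
  expect_identical(res, run_battery(s, queries, lex))
})

test_that("a battery whose probes are all out-of-vocabulary yields only error records", {
  s <- random_store(5, 4, seed = 71)
  res <- run_battery(s, data.frame(a = c("qq", "rr"), b = c("ww", "xx"),
                                   c = c("yy", "zz")),
                     default_bias_lexicon())
  expect_true(all(vapply(res, inherits, logical(1), "analogy_error")))
})

test_that("the shipped battery has the documented shape", {
  bat <- default_analogy_battery()
  expect_true(all(c("a", "b", "c", "k", "group") %in% names(bat)))
  emp <- default_analogy_battery("employability")
  expect_equal(nrow(emp), 12)  # 4 attributes x 3 diagnoses
  expect_setequal(unique(emp$b),
                  c("employable", "reliable", "competent", "resilient"))
  expect_setequal(unique(emp$c),
                  c("psychosis", "depression", "anxiety_disorder"))
  expect_true(all(emp$a == "healthy"))
  lex <- default_bias_lexicon()
  expect_true("unemployable" %in% lex$entries)
})
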