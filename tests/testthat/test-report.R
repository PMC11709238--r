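fake_result <- function(rank, b = "employable") {
  structure(list(
    query = analogy_query("healthy", b, "psychosis"),
    ranked = data.frame(token = sprintf("t%d", 1:10),
                        similarity = seq(0.9, 0.45, length.out = 10),
                        biased = seq_len(10) %in% rank),
    biased_positions = if (is.na(rank)) integer(0) else as.integer(rank),
    first_biased_rank = as.integer(rank),
    input_outranked = NA_character_
  ), class = "analogy_result")
}

test_that("bias summaries count ranks into the documented buckets", {
  # known ranks {1, 4, none} -> top1 1, top5 2, top10 2, none 1
  res <- structure(list(fake_result(1), fake_result(4), fake_result(NA)),
                   class = "analogy_battery")
  s <- summarize_bias(res)
  expect_equal(s$top1, 1)
  expect_equal(s$top5, 2)
  expect_equal(s$top10, 2)
  expect_equal(s$none, 1)
  expect_equal(s$n_errors, 0)

  # eleven queries with exactly one rank-1 biased completion
  res11 <- structure(c(list(fake_result(1)),
                       lapply(c(2, 4, NA, NA, 3, NA, 10, NA, 2, NA),
                              fake_result)),
                     class = "analogy_battery")
  expect_equal(summarize_bias(res11)$top1, 1)
  expect_equal(summarize_bias(res11)$n_queries, 11)

  all_none <- structure(lapply(c(NA, NA, NA), fake_result),
                        class = "analogy_battery")
  s0 <- summarize_bias(all_none)
  expect_equal(s0$top1 + s0$top5 + s0$top10, 0)
})

write_fixture_config <- function(dir, battery = TRUE, axes = TRUE) {
  spec <- synthetic_spec(
    dim = 30, n_background = 100,
    planted_terms = random_loadings(5, seed = 99),
    pole_pairs = list(x = c("healthy", "ill"), y = c("good", "bad")),
    analogy_quads = data.frame(a = "healthy", b = "employable",
                               c = "psychosis", d = "unemployable",
                               margin = 0.1),
    noise_sd = 0, seed = 77)
  emit_fixture(spec, dir)
  if (battery) {
    utils::write.table(
      data.frame(a = "healthy", b = "employable", c = "psychosis", k = 10,
                 group = "employability"),
      file.path(dir, "battery.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeLines("unemployable", file.path(dir, "lexicon.txt"))
  }
  if (axes) {
    utils::write.table(
      data.frame(term = sprintf("term_%03d", 1:5), category = "psychiatric"),
      file.path(dir, "terms.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- list(embeddings = list(path = "vectors_glove.txt",
                                format = "glove_text",
                                oov_policy = "mean_of_words"))
  if (battery) cfg$analogy <- list(battery = "battery.tsv",
                                   lexicon = "lexicon.txt")
  if (axes) cfg$axes <- list(terms = "terms.tsv",
                             pairs = list(list(x = c("healthy", "ill"),
                                               y = c("good", "bad"))))
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}

test_that("a full audit over a synthetic fixture reports the planted bias rank", {
  dir <- withr::local_tempdir()
  cfg <- write_fixture_config(dir)
  out <- file.path(dir, "out")
  report <- run_full_audit(cfg, out_dir = out)

  expect_s3_class(report, "audit_report")
  expect_equal(report$analogy$summary$top1, 1)
  r <- report$analogy$results[[1]]
  expect_identical(r$ranked$token[1], "unemployable")
  expect_identical(r$first_biased_rank, 1L)

  # projection table recovered the planted loadings through the file round trip
  tab <- report$axes$tables[[1]]
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)$loadings
  m <- match(truth$term, tab$term)
  expect_lt(max(abs(tab$x[m] - truth$x)), 1e-3)

  expect_true(file.exists(file.path(out, "analogy_results.tsv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "report.txt")))
})

test_that("report counts are recomputable from the emitted TSV", {
  dir <- withr::local_tempdir()
  cfg <- write_fixture_config(dir)
  out <- file.path(dir, "out")
  report <- run_full_audit(cfg, out_dir = out)

  tsv <- utils::read.delim(file.path(out, "analogy_results.tsv"))
  first_ranks <- tapply(ifelse(tsv$biased, tsv$rank, NA), tsv$query_id,
                        function(r) if (all(is.na(r))) NA else min(r, na.rm = TRUE))
  expect_equal(sum(first_ranks == 1, na.rm = TRUE), report$analogy$summary$top1)

  js <- jsonlite::read_json(file.path(out, "summary.json"), simplifyVector = TRUE)
  expect_equal(js$analogy$counts$top1, report$analogy$summary$top1)
  expect_equal(js$analogy$per_query$first_biased_rank, 1L)
})

test_that("an axes-only config yields a report with an empty analogy section", {
  dir <- withr::local_tempdir()
  cfg <- write_fixture_config(dir, battery = FALSE)
  report <- run_full_audit(cfg, out_dir = file.path(dir, "out"))
  expect_null(report$analogy)
  expect_length(report$axes$tables, 1)
  expect_false(file.exists(file.path(dir, "out", "analogy_results.tsv")))
  expect_true(file.exists(file.path(dir, "out", "summary.json")))
})

test_that("a missing embedding file is fatal; OOV terms are only warnings", {
  dir <- withr::local_tempdir()
  cfg <- write_fixture_config(dir)
  expect_error(run_full_audit(list(embeddings = list(path = "nope.txt",
                                                     format = "glove_text"),
                                   axes = list())),
               "not found")
  expect_error(run_full_audit(list(embeddings = list(
    path = file.path(dir, "vectors_glove.txt"), format = "glove_text"))),
    "at least one audit block")

  # an extra OOV term in the term list must not abort the audit
  terms <- utils::read.delim(file.path(dir, "terms.tsv"))
  terms <- rbind(terms, data.frame(term = "unobtainium", category = "physical"))
  utils::write.table(terms, file.path(dir, "terms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- run_full_audit(list(
    embeddings = list(path = file.path(dir, "vectors_glove.txt"),
                      format = "glove_text"),
    axes = list(terms = file.path(dir, "terms.tsv"),
                pairs = list(list(x = c("healthy", "ill"),
                                  y = c("good", "bad"))))))
  expect_match(paste(report$warnings, collapse = " "), "unobtainium")
})
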