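#' An A:B::C:? analogy query
#'
#' Reads "a is to b as c is to ?". The unknown completion is found by
#' the 3CosAdd rule (see [analogy_target()]) and the `k` most similar
#' vocabulary tokens are reported. By convention the three input terms
#' are excluded from the candidates ("all terms different"); that
#' convention is debated — a completion identical to `b` can be the
#' unbiased answer — so it is exposed as a flag, and audit results
#' annotate when an excluded input would have out-ranked the top-1.
#'
#' @param a,b,c non-empty probe terms.
#' @param k report depth (default 10).
#' @param exclude_inputs drop a, b, c from the ranked completions
#'   (default TRUE).
#' @return an object of class `analogy_query`.
#' @export
analogy_query <- function(a, b, c, k = 10, exclude_inputs = TRUE) {
  for (t in list(a, b, c)) {
    if (!is.character(t) || length(t) != 1 || !nzchar(t)) {
      stop("analogy terms must be single non-empty strings", call. = FALSE)
    }
  }
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  structure(list(a = a, b = b, c = c, k = as.integer(k),
                 exclude_inputs = isTRUE(exclude_inputs)),
            class = "analogy_query")
}

#' @export
print.analogy_query <- function(x, ...) {
  cat(sprintf("<analogy_query> '%s' is to '%s' as '%s' is to ? (k = %d%s)\n",
              x$a, x$b, x$c, x$k,
              if (x$exclude_inputs) ", inputs excluded" else ""))
  invisible(x)
}

#' Swap the roles of a query's first and third terms
#'
#' "a is to b as c is to ?" becomes "c is to b as a is to ?" — the
#' reversal used to probe whether a finding survives when the anchor
#' and probe trade places (woman:doctor::man:? versus
#' man:doctor::woman:?). Applying it twice returns the original query.
#'
#' @param query an [analogy_query()].
#' @return an [analogy_query()] with `a` and `c` swapped.
#' @export
reverse_query <- function(query) {
  stopifnot(inherits(query, "analogy_query"))
  analogy_query(query$c, query$b, query$a, k = query$k,
                exclude_inputs = query$exclude_inputs)
}

#' Lexicon of biased completion tokens
#'
#' The audit counts a ranked completion as biased when it matches an
#' entry of this curated set of undesirable terms (e.g. unemployable,
#' unreliable, incompetent). Matching is case-insensitive after folding
#' underscores to spaces, so "Unemployable" and "un_employable" both
#' match "unemployable": the statistic counts semantic hits, not
#' surface forms.
#'
#' @param entries character vector of lexicon terms.
#' @return an object of class `bias_lexicon`.
#' @export
bias_lexicon <- function(entries) {
  entries <- unique(as.character(entries))
  entries <- entries[nzchar(entries)]
  structure(list(entries = entries, folded = fold_term(entries)),
            class = "bias_lexicon")
}

fold_term <- function(x) tolower(gsub("_", " ", x, fixed = TRUE))

#' @export
print.bias_lexicon <- function(x, ...) {
  cat("<bias_lexicon> ", length(x$entries), " entries: ",
      paste(utils::head(x$entries, 8), collapse = ", "),
      if (length(x$entries) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' The bias lexicon shipped with the package
#'
#' Undesirable counterparts of the audited employability attributes
#' (employability, reliability, competence, resilience), read from the
#' package's `extdata/bias_lexicon.txt`.
#'
#' @return a [bias_lexicon()].
#' @export
default_bias_lexicon <- function() {
  path <- system.file("extdata", "bias_lexicon.txt", package = "embedaudit",
                      mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  bias_lexicon(lines[nzchar(lines) & !startsWith(lines, "#")])
}

input_exclusion_set <- function(query, case_variants = FALSE) {
  terms <- c(query$a, query$b, query$c)
  keys <- c(terms, gsub("[[:space:]]+", "_", terms))
  if (case_variants) {
    keys <- c(keys, tolower(keys), capitalize(tolower(keys)))
  }
  unique(keys)
}

#' Run one analogy query against a store
#'
#' Computes the 3CosAdd target for the query, ranks the vocabulary by
#' cosine similarity to it, and locates biased completions: every
#' 1-based rank whose token matches the lexicon, and the smallest such
#' rank (`first_biased_rank`, `NA` when no match in the top k).
#'
#' Input exclusion removes exact-case matches of the three probe terms
#' (and their underscore-joined forms). Differently-cased vocabulary
#' entries such as "Doctor" for the probe "doctor" remain candidates,
#' mirroring how the common query libraries behave; set
#' `exclude_case_variants = TRUE` to remove those too.
#'
#' @param store a [word_vector_store()].
#' @param query an [analogy_query()].
#' @param lexicon a [bias_lexicon()], or NULL to skip bias marking.
#' @param oov_policy passed to [lookup()] for the probe terms.
#' @param exclude_case_variants also exclude case variants of the
#'   inputs (default FALSE).
#' @return an object of class `analogy_result`: list with `query`,
#'   `ranked` (token/similarity/biased data frame), `biased_positions`,
#'   `first_biased_rank`, and `input_outranked` (the excluded input
#'   token that would have placed above the reported top-1, or `NA`).
#' @export
run_analogy <- function(store, query, lexicon = NULL,
                        oov_policy = "mean_of_words",
                        exclude_case_variants = FALSE) {
  stopifnot(inherits(store, "word_vector_store"))
  stopifnot(inherits(query, "analogy_query"))
  target <- analogy_target(store, query$a, query$b, query$c,
                           oov_policy = oov_policy)

  exclude <- character(0)
  input_outranked <- NA_character_
  if (query$exclude_inputs) {
    exclude <- input_exclusion_set(query, exclude_case_variants)
    unexcluded <- top_k(store, target, k = 1)
    if (nrow(unexcluded) && unexcluded$token[1] %in% exclude) {
      input_outranked <- unexcluded$token[1]
    }
  }
  ranked <- top_k(store, target, k = query$k, exclude = exclude)

  biased <- logical(nrow(ranked))
  if (!is.null(lexicon)) {
    stopifnot(inherits(lexicon, "bias_lexicon"))
    biased <- fold_term(ranked$token) %in% lexicon$folded
  }
  ranked$biased <- biased
  positions <- which(biased)
  structure(list(
    query = query,
    ranked = ranked,
    biased_positions = positions,
    first_biased_rank = if (length(positions)) min(positions) else NA_integer_,
    input_outranked = input_outranked
  ), class = "analogy_result")
}

#' @export
print.analogy_result <- function(x, ...) {
  cat(sprintf("'%s' is to '%s' as '%s' is to:\n", x$query$a, x$query$b, x$query$c))
  df <- x$ranked
  df$similarity <- sprintf("%.4f", df$similarity)
  print(df, row.names = TRUE)
  if (!is.na(x$first_biased_rank)) {
    cat("first biased completion at rank ", x$first_biased_rank, "\n", sep = "")
  } else {
    cat("no biased completion in the top ", x$query$k, "\n", sep = "")
  }
  if (!is.na(x$input_outranked)) {
    cat("note: excluded input '", x$input_outranked,
        "' would have ranked above the top-1\n", sep = "")
  }
  invisible(x)
}

#' Run a battery of analogy queries
#'
#' One result per query, in input order. A failing query (e.g. an
#' out-of-vocabulary probe term) is recorded as a per-query error entry
#' rather than aborting the batch.
#'
#' @param store a [word_vector_store()].
#' @param queries list of [analogy_query()] objects, or a data frame
#'   with columns `a`, `b`, `c` (optional `k`).
#' @param lexicon a [bias_lexicon()] or NULL.
#' @inheritParams run_analogy
#' @return list of class `analogy_battery`: each element an
#'   `analogy_result` or an `analogy_error` (list with `query`,
#'   `error`).
#' @export
run_battery <- function(store, queries, lexicon = NULL,
                        oov_policy = "mean_of_words",
                        exclude_case_variants = FALSE) {
  queries <- as_query_list(queries)
  if (!length(queries)) stop("query list is empty", call. = FALSE)
  out <- lapply(queries, function(q) {
    tryCatch(
      run_analogy(store, q, lexicon, oov_policy = oov_policy,
                  exclude_case_variants = exclude_case_variants),
      error = function(e) {
        structure(list(query = q, error = conditionMessage(e)),
                  class = "analogy_error")
      })
  })
  structure(out, class = "analogy_battery")
}

as_query_list <- function(queries) {
  if (is.data.frame(queries)) {
    stopifnot(all(c("a", "b", "c") %in% names(queries)))
    k <- if ("k" %in% names(queries)) queries$k else rep(10L, nrow(queries))
    queries <- lapply(seq_len(nrow(queries)), function(i) {
      analogy_query(queries$a[i], queries$b[i], queries$c[i], k = k[i])
    })
  }
  stopifnot(all(vapply(queries, inherits, logical(1), "analogy_query")))
  queries
}

#' The analogy battery shipped with the package
#'
#' The audited probes: the four employability attributes (employable,
#' reliable, competent, resilient) crossed with three psychiatric
#' diagnoses (psychosis, depression, anxiety_disorder) anchored at
#' "healthy", plus six prestige professions (lawyer, doctor, surgeon,
#' engineer, banker, CEO) probed for psychosis, plus sanity-control
#' queries (gender/profession and capital/country in both directions).
#' Read from the package's `extdata/analogy_battery.tsv`; pass your own
#' TSV with columns `a`, `b`, `c`, `k`, `group` to audit other probes.
#'
#' @param groups optional character vector to subset the `group` column
#'   (e.g. `"employability"`, `"professions"`, `"controls"`).
#' @return data frame with columns `a`, `b`, `c`, `k`, `group`.
#' @export
default_analogy_battery <- function(groups = NULL) {
  path <- system.file("extdata", "analogy_battery.tsv", package = "embedaudit",
                      mustWork = TRUE)
  bat <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(groups)) bat <- bat[bat$group %in% groups, , drop = FALSE]
  bat
}
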