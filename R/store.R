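#' In-memory store of static word vectors
#'
#' A `word_vector_store` holds a vocabulary of unique, case-sensitive tokens
#' together with a |V| x d real matrix whose i-th row is the vector of the
#' i-th token. The store is the uniform container behind all audit
#' operations regardless of which on-disk dialect (word2vec binary,
#' word2vec text, GloVe text) the vectors came from.
#'
#' All-zero rows are legal (some distributions contain padding entries);
#' they are retained in the vocabulary but excluded from nearest-neighbour
#' candidacy because cosine similarity is undefined for them.
#'
#' @param tokens character vector of unique tokens (case-sensitive).
#' @param matrix numeric matrix with `length(tokens)` rows; every entry
#'   must be finite.
#' @param source optional path the vectors were read from.
#' @param format optional name of the on-disk dialect.
#'
#' @return An object of class `word_vector_store` with fields `tokens`,
#'   `matrix`, `dim` and `meta`.
#' @export
#' @examples
#' s <- word_vector_store(c("a", "b"), rbind(c(1, 0, 0), c(0, 1, 0)))
#' lookup(s, "a")
word_vector_store <- function(tokens, matrix, source = NA_character_,
                              format = NA_character_) {
  tokens <- as.character(tokens)
  if (!is.matrix(matrix)) matrix <- base::matrix(matrix, nrow = length(tokens))
  storage.mode(matrix) <- "double"
  if (nrow(matrix) != length(tokens)) {
    stop("number of tokens (", length(tokens), ") does not match number of ",
         "matrix rows (", nrow(matrix), ")", call. = FALSE)
  }
  if (length(tokens) > 0 && ncol(matrix) < 1) {
    stop("vectors must have at least one dimension", call. = FALSE)
  }
  if (anyDuplicated(tokens)) {
    dup <- unique(tokens[duplicated(tokens)])
    stop("duplicate tokens in store: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (length(matrix) && !all(is.finite(matrix))) {
    stop("vector matrix contains non-finite entries", call. = FALSE)
  }
  dimnames(matrix) <- NULL
  structure(
    list(
      tokens = tokens,
      matrix = matrix,
      dim = ncol(matrix),
      meta = list(source = source, format = format, case_sensitive = TRUE),
      .cache = new.env(parent = emptyenv())
    ),
    class = "word_vector_store"
  )
}

#' @export
print.word_vector_store <- function(x, ...) {
  cat(sprintf("<word_vector_store> %d tokens x %d dims", length(x$tokens), x$dim))
  if (!is.na(x$meta$format)) cat(sprintf(" [%s]", x$meta$format))
  cat("\n")
  if (length(x$tokens)) {
    cat("  tokens: ", paste(utils::head(x$tokens, 6), collapse = ", "),
        if (length(x$tokens) > 6) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.word_vector_store <- function(x) length(x$tokens)

#' Row-normalized copy of a store's matrix
#'
#' Rows are scaled to Euclidean norm 1. All-zero rows stay zero and are
#' flagged in the `"zero_rows"` attribute (a logical vector). The result
#' is cached inside the store, so repeated nearest-neighbour queries pay
#' the normalization cost once.
#'
#' @param store a [word_vector_store()].
#' @return numeric matrix of the same shape, with attribute `zero_rows`.
#' @export
unit_rows <- function(store) {
  stopifnot(inherits(store, "word_vector_store"))
  cache <- store$.cache
  if (!is.null(cache$unit)) return(cache$unit)
  norms <- sqrt(rowSums(store$matrix^2))
  zero <- norms == 0
  scale <- ifelse(zero, 1, norms)
  u <- store$matrix / scale
  attr(u, "zero_rows") <- zero
  cache$unit <- u
  u
}

token_index <- function(store, term) match(term, store$tokens)

capitalize <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

oov_error <- function(term, attempted) {
  stop(structure(
    class = c("embedaudit_oov_error", "error", "condition"),
    list(message = sprintf(
           "no vector found for term '%s' (tried: %s)",
           term, paste(unique(attempted), collapse = ", ")),
         call = NULL, term = term, attempted = unique(attempted))
  ))
}

resolve_with_case <- function(store, term) {
  # exact, then lowercase, then capitalized
  cands <- unique(c(term, tolower(term), capitalize(tolower(term))))
  idx <- match(cands, store$tokens)
  hit <- which(!is.na(idx))
  if (length(hit)) {
    list(index = idx[hit[1]], key = cands[hit[1]], attempted = cands)
  } else {
    list(index = NA_integer_, key = NA_character_, attempted = cands)
  }
}

#' Look up the vector of a term
#'
#' Resolution is exact and case-sensitive by default. Multiword probe
#' terms ("anxiety disorder", "olympic gold medallist") are supported
#' under `oov_policy = "mean_of_words"`: the underscore-joined phrase
#' ("anxiety_disorder") is tried first — the GoogleNews vocabulary stores
#' phrases that way — and if absent the term falls back to the arithmetic
#' mean of its constituent in-vocabulary word vectors, each word resolved
#' with case fallback. `"case_fallback"` tries exact, then lowercase,
#' then Capitalized, in that order.
#'
#' @param store a [word_vector_store()].
#' @param term a non-empty string.
#' @param oov_policy one of `"error"` (exact match only),
#'   `"case_fallback"`, `"mean_of_words"`.
#' @return numeric vector of length `store$dim`.
#' @export
lookup <- function(store, term,
                   oov_policy = c("case_fallback", "error", "mean_of_words")) {
  stopifnot(inherits(store, "word_vector_store"))
  oov_policy <- match.arg(oov_policy)
  if (!is.character(term) || length(term) != 1 || !nzchar(term)) {
    stop("term must be a single non-empty string", call. = FALSE)
  }

  i <- token_index(store, term)
  if (!is.na(i)) return(store$matrix[i, ])
  if (oov_policy == "error") oov_error(term, term)

  res <- resolve_with_case(store, term)
  if (!is.na(res$index)) return(store$matrix[res$index, ])
  attempted <- res$attempted

  if (oov_policy == "mean_of_words") {
    joined <- gsub("[[:space:]]+", "_", term)
    if (!identical(joined, term)) {
      rj <- resolve_with_case(store, joined)
      attempted <- c(attempted, rj$attempted)
      if (!is.na(rj$index)) return(store$matrix[rj$index, ])
    }
    words <- strsplit(trimws(term), "[[:space:]_]+")[[1]]
    if (length(words) > 1) {
      rows <- integer(0)
      for (w in words) {
        rw <- resolve_with_case(store, w)
        attempted <- c(attempted, rw$attempted)
        if (!is.na(rw$index)) rows <- c(rows, rw$index)
      }
      if (length(rows)) {
        return(colMeans(store$matrix[rows, , drop = FALSE]))
      }
    }
  }
  oov_error(term, attempted)
}

#' Set of probe terms with audit categories
#'
#' Audit term lists carry one of four fixed categories, used downstream
#' for colour-coded projection plots and per-category extreme summaries.
#'
#' @param term character vector of non-empty probe terms.
#' @param category character vector (recycled) drawn from `psychiatric`,
#'   `physical`, `favourable_attribute`, `very_healthy_control`.
#' @return A data frame of class `term_set` with columns `term`, `category`.
#' @export
term_set <- function(term, category) {
  term <- as.character(term)
  category <- rep_len(as.character(category), length(term))
  if (any(!nzchar(term))) stop("terms must be non-empty", call. = FALSE)
  bad <- setdiff(unique(category), TERM_CATEGORIES)
  if (length(bad)) {
    stop("unknown categories: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(TERM_CATEGORIES, collapse = ", "), ")",
         call. = FALSE)
  }
  structure(data.frame(term = term, category = category,
                       stringsAsFactors = FALSE),
            class = c("term_set", "data.frame"))
}

TERM_CATEGORIES <- c("psychiatric", "physical", "favourable_attribute",
                     "very_healthy_control")
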