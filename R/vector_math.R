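#' Cosine similarity between two vectors
#'
#' The dot product of the vectors divided by the product of their
#' Euclidean norms: 1 means identical direction, 0 orthogonal, -1
#' opposite. The result is clamped to \[-1, 1\] against floating-point
#' overshoot.
#'
#' @param a,b numeric vectors of equal length, both nonzero.
#' @return a number in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))  # 0
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors have different lengths (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity is undefined for a zero-norm vector", call. = FALSE)
  }
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' Exact top-k nearest neighbours by cosine similarity
#'
#' Exhaustive search over the full vocabulary: every token's cosine with
#' the query is computed and the k largest are returned in descending
#' order, ties broken by ascending vocabulary index (file order). There
#' is no approximation, so results are bit-reproducible. All-zero rows
#' and tokens in `exclude` are never candidates.
#'
#' @param store a [word_vector_store()].
#' @param query nonzero numeric vector of length `store$dim`.
#' @param k number of neighbours requested (>= 1). If fewer tokens are
#'   eligible, all of them are returned and a notice is emitted.
#' @param exclude character vector of tokens to remove from candidacy
#'   (exact match).
#' @return A data frame of class `ranked_neighbors` with columns `token`
#'   and `similarity` (non-increasing).
#' @export
top_k <- function(store, query, k = 10, exclude = character(0)) {
  stopifnot(inherits(store, "word_vector_store"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (length(query) != store$dim) {
    stop("query has length ", length(query), ", store dimension is ",
         store$dim, call. = FALSE)
  }
  qn <- sqrt(sum(query^2))
  if (qn == 0) stop("query vector has zero norm", call. = FALSE)

  u <- unit_rows(store)
  sims <- as.vector(u %*% (query / qn))
  eligible <- !attr(u, "zero_rows")
  if (length(exclude)) eligible <- eligible & !(store$tokens %in% exclude)

  idx <- which(eligible)
  if (length(idx) < k) {
    message("top_k: only ", length(idx), " eligible tokens for k = ", k)
    k <- length(idx)
  }
  ord <- idx[order(-sims[idx], idx)][seq_len(k)]
  ranked_neighbors(store$tokens[ord], pmin(1, pmax(-1, sims[ord])))
}

ranked_neighbors <- function(tokens, similarities, query_meta = NULL) {
  structure(data.frame(token = tokens, similarity = similarities,
                       stringsAsFactors = FALSE),
            query_meta = query_meta,
            class = c("ranked_neighbors", "data.frame"))
}

#' 3CosAdd analogy target vector
#'
#' Completes "a is to b as c is to ?" by vector arithmetic: the target
#' is v(b) - v(a) + v(c). By default the three input vectors are
#' unit-normalized before the arithmetic, the standard 3CosAdd
#' convention implemented by the common embedding query libraries;
#' candidates are then ranked by cosine similarity to this composite
#' vector.
#'
#' @param store a [word_vector_store()].
#' @param a,b,c probe terms, resolvable under `oov_policy`.
#' @param normalize_inputs unit-normalize v(a), v(b), v(c) first
#'   (default TRUE).
#' @param oov_policy passed to [lookup()].
#' @return numeric vector of length `store$dim`.
#' @export
analogy_target <- function(store, a, b, c, normalize_inputs = TRUE,
                           oov_policy = "mean_of_words") {
  vecs <- lapply(stats::setNames(c(a, b, c), c("a", "b", "c")), function(t) {
    lookup(store, t, oov_policy)
  })
  if (normalize_inputs) {
    vecs <- lapply(vecs, function(v) {
      n <- sqrt(sum(v^2))
      if (n == 0) stop("probe term resolves to a zero vector", call. = FALSE)
      v / n
    })
  }
  vecs$b - vecs$a + vecs$c
}
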