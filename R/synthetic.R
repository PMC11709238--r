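#' Specification of a synthetic embedding store
#'
#' Describes a vocabulary whose geometry is known in closed form, so
#' every pipeline stage can be tested against ground truth without
#' downloading pretrained vectors. The construction plants:
#'
#' * two orthogonal semantic-axis directions, with the four pole words
#'   stored as plus/minus unit vectors along them, so a built axis
#'   recovers exactly twice the axis direction;
#' * probe terms with prescribed cosine loadings (x, y) on the two
#'   axes — the remaining mass, sqrt(1 - x^2 - y^2), goes to a
#'   term-specific direction orthogonal to both axes, so at zero noise
#'   the projected scores equal the planted loadings exactly;
#' * analogy parallelograms v(d) = v(b) - v(a) + v(c) whose completion
#'   `d` beats every other token's cosine against the composite target
#'   by at least `margin`;
#' * isotropic unit-norm background noise words.
#'
#' All randomness derives from `seed`.
#'
#' @param dim embedding dimension (>= 4).
#' @param n_background number of isotropic noise words.
#' @param planted_terms data frame with columns `term`, `x`, `y`; each
#'   loading pair must satisfy x^2 + y^2 <= 1.
#' @param pole_pairs list with elements `x` and `y`, each
#'   `c(positive, negative)` pole words.
#' @param analogy_quads data frame with columns `a`, `b`, `c`, `d` and
#'   optional `margin` (default 0.05): required cosine gap between `d`
#'   and the best non-input decoy.
#' @param noise_sd standard deviation of the isotropic Gaussian noise
#'   added per coordinate to planted vectors.
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(dim = 50, n_background = 500,
                           planted_terms = NULL,
                           pole_pairs = list(x = c("healthy", "ill"),
                                             y = c("employable", "unemployable")),
                           analogy_quads = NULL,
                           noise_sd = 0.02, seed = 20250108) {
  if (dim < 4) stop("dim must be >= 4", call. = FALSE)
  if (n_background < 0) stop("n_background must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(is.list(pole_pairs), all(c("x", "y") %in% names(pole_pairs)),
            length(pole_pairs$x) == 2, length(pole_pairs$y) == 2)

  if (!is.null(planted_terms)) {
    stopifnot(all(c("term", "x", "y") %in% names(planted_terms)))
    if (any(planted_terms$x^2 + planted_terms$y^2 > 1 + 1e-12)) {
      stop("planted loadings must satisfy x^2 + y^2 <= 1", call. = FALSE)
    }
  }
  if (!is.null(analogy_quads)) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(analogy_quads)))
    if (is.null(analogy_quads$margin)) analogy_quads$margin <- 0.05
    if (any(analogy_quads$margin < 0)) {
      stop("analogy margins must be >= 0", call. = FALSE)
    }
  }

  named <- c(unlist(pole_pairs, use.names = FALSE),
             planted_terms$term, analogy_quads$d)
  if (anyDuplicated(named)) {
    stop("planted terms, pole words and quad completions must be distinct",
         call. = FALSE)
  }
  structure(list(dim = as.integer(dim), n_background = as.integer(n_background),
                 planted_terms = planted_terms, pole_pairs = pole_pairs,
                 analogy_quads = analogy_quads, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_unit <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

orthonormal_complement_unit <- function(basis) {
  # random unit vector orthogonal to the columns of `basis`
  d <- nrow(basis)
  v <- stats::rnorm(d)
  v <- v - basis %*% crossprod(basis, v)
  as.vector(v / sqrt(sum(v^2)))
}

#' Generate a synthetic store with its ground truth
#'
#' @param spec a [synthetic_spec()].
#' @param max_retries how many times offending background words may be
#'   resampled before an analogy margin is declared infeasible.
#' @return list with elements `store` (a [word_vector_store()]) and
#'   `truth` (list: `loadings` — the planted per-term (x, y) scores the
#'   projection pipeline should recover at zero noise; `quads` — the
#'   expected top-1 completion per analogy; `pole_pairs`).
#' @export
generate_embeddings <- function(spec, max_retries = 100) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    d <- spec$dim
    Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
    u_x <- Q[, 1]; u_y <- Q[, 2]
    axes <- cbind(u_x, u_y)

    tokens <- c(spec$pole_pairs$x[1], spec$pole_pairs$x[2],
                spec$pole_pairs$y[1], spec$pole_pairs$y[2])
    vecs <- list(u_x, -u_x, u_y, -u_y)

    pt <- spec$planted_terms
    if (!is.null(pt)) {
      for (i in seq_len(nrow(pt))) {
        r <- sqrt(max(0, 1 - pt$x[i]^2 - pt$y[i]^2))
        u_res <- orthonormal_complement_unit(axes)
        v <- pt$x[i] * u_x + pt$y[i] * u_y + r * u_res +
          stats::rnorm(d, sd = spec$noise_sd)
        tokens <- c(tokens, pt$term[i])
        vecs <- c(vecs, list(v))
      }
    }

    quads <- spec$analogy_quads
    if (!is.null(quads)) {
      for (t in unique(unlist(quads[c("a", "b", "c")], use.names = FALSE))) {
        if (!(t %in% tokens)) {
          tokens <- c(tokens, t)
          vecs <- c(vecs, list(random_unit(d)))
        }
      }
      unit_of <- function(t) {
        v <- vecs[[match(t, tokens)]]
        v / sqrt(sum(v^2))
      }
      for (i in seq_len(nrow(quads))) {
        target <- unit_of(quads$b[i]) - unit_of(quads$a[i]) + unit_of(quads$c[i])
        tokens <- c(tokens, quads$d[i])
        vecs <- c(vecs, list(target + stats::rnorm(d, sd = spec$noise_sd)))
      }
    }

    n_fixed <- length(tokens)
    bg_tokens <- if (spec$n_background > 0) {
      sprintf("noise_%04d", seq_len(spec$n_background))
    } else character(0)
    bg <- matrix(stats::rnorm(spec$n_background * d), ncol = d)
    if (spec$n_background > 0) bg <- bg / sqrt(rowSums(bg^2))

    mat <- rbind(do.call(rbind, vecs), bg)
    all_tokens <- c(tokens, bg_tokens)

    # enforce the analogy margins: resample background decoys that come
    # within `margin` of the planted completion's cosine to the target
    if (!is.null(quads)) {
      unit_tok <- function(ti) {
        v <- mat[ti, ]
        v / sqrt(sum(v^2))
      }
      for (attempt in seq_len(max_retries + 1)) {
        worst <- NULL
        for (i in seq_len(nrow(quads))) {
          ia <- match(quads$a[i], all_tokens); ib <- match(quads$b[i], all_tokens)
          ic <- match(quads$c[i], all_tokens); id <- match(quads$d[i], all_tokens)
          target <- unit_tok(ib) - unit_tok(ia) + unit_tok(ic)
          sims <- as.vector((mat / sqrt(rowSums(mat^2))) %*%
                              (target / sqrt(sum(target^2))))
          cos_d <- sims[id]
          cand <- setdiff(seq_along(all_tokens), c(ia, ib, ic, id))
          viol <- cand[sims[cand] > cos_d - quads$margin[i]]
          if (length(viol)) { worst <- viol; break }
        }
        if (is.null(worst)) break
        fixable <- worst[worst > n_fixed]
        if (length(fixable) < length(worst) || attempt > max_retries) {
          stop("infeasible analogy margin: a planted token intrudes within ",
               "the required cosine gap", call. = FALSE)
        }
        for (ti in fixable) mat[ti, ] <- random_unit(d)
      }
    }

    store <- word_vector_store(all_tokens, mat, format = "synthetic")
    truth <- list(
      loadings = if (is.null(pt)) NULL else
        data.frame(term = pt$term, x = pt$x, y = pt$y, stringsAsFactors = FALSE),
      quads = if (is.null(quads)) NULL else
        quads[c("a", "b", "c", "d", "margin")],
      pole_pairs = spec$pole_pairs
    )
    list(store = store, truth = truth)
  })
}

#' Write a synthetic fixture directory
#'
#' Emits the generated store in all three on-disk dialects plus the
#' ground truth as JSON — exactly four files — for loader round-trip
#' and end-to-end tests.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return named character vector of the four file paths, invisibly.
#' @export
emit_fixture <- function(spec, dir) {
  gen <- generate_embeddings(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    word2vec_binary = file.path(dir, "vectors_word2vec.bin"),
    word2vec_text = file.path(dir, "vectors_word2vec.txt"),
    glove_text = file.path(dir, "vectors_glove.txt"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_store(gen$store, paths[["word2vec_binary"]], "word2vec_binary")
  write_store(gen$store, paths[["word2vec_text"]], "word2vec_text")
  write_store(gen$store, paths[["glove_text"]], "glove_text")
  jsonlite::write_json(gen$truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
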