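#' Semantic axis between two pole words
#'
#' The axis is the raw difference of the two pole vectors,
#' v(positive) - v(negative); a term's position on the axis is its
#' cosine similarity to this difference vector. With poles
#' (healthy, ill), a positive score means the term sits closer to the
#' "healthy" end of the spectrum than to the "ill" end.
#'
#' @param store a [word_vector_store()].
#' @param positive_pole,negative_pole distinct pole terms.
#' @param oov_policy passed to [lookup()]; pole words in GloVe
#'   vocabularies are lowercase, which case fallback handles.
#' @return an object of class `semantic_axis` with fields
#'   `positive_pole`, `negative_pole`, `axis_vector`.
#' @export
build_axis <- function(store, positive_pole, negative_pole,
                       oov_policy = "case_fallback") {
  stopifnot(inherits(store, "word_vector_store"))
  if (identical(positive_pole, negative_pole)) {
    stop("axis poles must be distinct terms", call. = FALSE)
  }
  vp <- lookup(store, positive_pole, oov_policy)
  vn <- lookup(store, negative_pole, oov_policy)
  axis <- vp - vn
  if (all(axis == 0)) {
    stop(sprintf("degenerate axis: '%s' and '%s' have identical vectors",
                 positive_pole, negative_pole), call. = FALSE)
  }
  structure(list(positive_pole = positive_pole, negative_pole = negative_pole,
                 axis_vector = axis),
            class = "semantic_axis")
}

#' @export
print.semantic_axis <- function(x, ...) {
  cat(sprintf("<semantic_axis> %s - %s (d = %d)\n",
              x$positive_pole, x$negative_pole, length(x$axis_vector)))
  invisible(x)
}

#' Project a term onto a semantic axis
#'
#' @param store a [word_vector_store()].
#' @param term the term to place.
#' @param axis a [build_axis()] result.
#' @param oov_policy passed to [lookup()].
#' @return cosine similarity in \[-1, 1\] between the term's vector and
#'   the axis vector.
#' @export
project <- function(store, term, axis, oov_policy = "mean_of_words") {
  stopifnot(inherits(axis, "semantic_axis"))
  cosine_similarity(lookup(store, term, oov_policy), axis$axis_vector)
}

#' Place a term set on two semantic axes
#'
#' Computes each term's cosine score against the x and y axes, carrying
#' the term's category through for plotting and summaries. Terms that
#' do not resolve are listed in the `unresolved` attribute instead of
#' aborting the batch; per-category score extremes are attached as the
#' `extremes` attribute.
#'
#' @param store a [word_vector_store()].
#' @param terms a [term_set()] (or data frame with `term`, `category`).
#' @param x_axis,y_axis [build_axis()] results built on the same store.
#' @param oov_policy passed to [lookup()].
#' @return A data frame of class `projection_table` with columns
#'   `term`, `category`, `x`, `y`, and attributes `axes_meta`,
#'   `unresolved`, `extremes`.
#' @export
project_battery <- function(store, terms, x_axis, y_axis,
                            oov_policy = "mean_of_words") {
  stopifnot(inherits(store, "word_vector_store"))
  if (!inherits(terms, "term_set")) terms <- term_set(terms$term, terms$category)

  rows <- vector("list", nrow(terms))
  unresolved <- character(0)
  for (i in seq_len(nrow(terms))) {
    scores <- tryCatch({
      v <- lookup(store, terms$term[i], oov_policy)
      c(cosine_similarity(v, x_axis$axis_vector),
        cosine_similarity(v, y_axis$axis_vector))
    }, embedaudit_oov_error = function(e) NULL)
    if (is.null(scores)) {
      unresolved <- c(unresolved, terms$term[i])
    } else {
      rows[[i]] <- data.frame(term = terms$term[i], category = terms$category[i],
                              x = scores[1], y = scores[2],
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(term = character(0), category = character(0),
                      x = numeric(0), y = numeric(0), stringsAsFactors = FALSE)
  }
  structure(tab,
            axes_meta = list(
              x = c(positive = x_axis$positive_pole, negative = x_axis$negative_pole),
              y = c(positive = y_axis$positive_pole, negative = y_axis$negative_pole)),
            unresolved = unresolved,
            extremes = category_extremes(tab),
            class = c("projection_table", "data.frame"))
}

category_extremes <- function(tab) {
  if (!nrow(tab)) return(NULL)
  do.call(rbind, lapply(split(tab, tab$category), function(g) {
    data.frame(category = g$category[1],
               x_min_term = g$term[which.min(g$x)], x_min = min(g$x),
               x_max_term = g$term[which.max(g$x)], x_max = max(g$x),
               y_min_term = g$term[which.min(g$y)], y_min = min(g$y),
               y_max_term = g$term[which.max(g$y)], y_max = max(g$y),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

AUDIT_COLORS <- c(psychiatric = "green", physical = "blue",
                  favourable_attribute = "red", very_healthy_control = "yellow")

#' Scatter plot of a projection table
#'
#' One labelled point per row, coloured by category with the fixed
#' audit palette (psychiatric = green, physical = blue, favourable
#' attribute = red, very-healthy control = yellow); axis labels name
#' the pole words. Coincident points are all drawn. The plot is a
#' visual aid — the coordinates table is the analysed surface.
#'
#' @param table a [project_battery()] result.
#' @param out_path output image path; the extension selects the device
#'   (`.png` or `.svg`).
#' @param width,height device size in inches.
#' @return the file path, invisibly.
#' @export
render_scatter <- function(table, out_path, width = 8, height = 6) {
  stopifnot(inherits(table, "projection_table"))
  if (!nrow(table)) stop("projection table is empty", call. = FALSE)
  meta <- attr(table, "axes_meta")
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$x, y = .data$y,
                                           fill = .data$category)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point(shape = 21, size = 3, colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$term), hjust = -0.12,
                       vjust = 0.4, size = 3, check_overlap = FALSE) +
    ggplot2::scale_fill_manual(values = AUDIT_COLORS, drop = FALSE) +
    ggplot2::labs(
      x = sprintf("%s  ↔  %s", meta$x[["negative"]], meta$x[["positive"]]),
      y = sprintf("%s  ↔  %s", meta$y[["negative"]], meta$y[["positive"]]),
      fill = "category") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = 150)
  invisible(out_path)
}

#' The projection term set shipped with the package
#'
#' Psychiatric diagnoses, physical diagnoses, favourable physical
#' attributes, and very-healthy control occupations, read from the
#' package's `extdata/term_categories.tsv`.
#'
#' @return a [term_set()].
#' @export
default_term_set <- function() {
  path <- system.file("extdata", "term_categories.tsv", package = "embedaudit",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  term_set(df$term, df$category)
}
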