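#' Summarize biased-completion ranks over a battery
#'
#' Counts how many queries surfaced a lexicon term at rank 1, within
#' the top 5, within the top 10, or not at all, with a per-attribute
#' (per-`b`-term) breakdown. Error entries are counted separately and
#' never contribute to the rank counts.
#'
#' @param results an `analogy_battery` (list of `analogy_result` /
#'   `analogy_error`) as returned by [run_battery()].
#' @return list with `n_queries`, `n_errors`, `top1`, `top5`, `top10`,
#'   `none`, and `by_attribute` (data frame).
#' @export
summarize_bias <- function(results) {
  if (!length(results)) stop("no results to summarize", call. = FALSE)
  ok <- Filter(function(r) inherits(r, "analogy_result"), results)
  ranks <- vapply(ok, function(r) r$first_biased_rank, integer(1))
  battr <- vapply(ok, function(r) r$query$b, character(1))

  by_attr <- NULL
  if (length(ok)) {
    by_attr <- do.call(rbind, lapply(split(seq_along(ok), battr), function(i) {
      data.frame(attribute = battr[i[1]],
                 n = length(i),
                 top1 = sum(!is.na(ranks[i]) & ranks[i] == 1),
                 top10 = sum(!is.na(ranks[i]) & ranks[i] <= 10),
                 none = sum(is.na(ranks[i])),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
  list(
    n_queries = length(results),
    n_errors = length(results) - length(ok),
    top1 = sum(!is.na(ranks) & ranks == 1),
    top5 = sum(!is.na(ranks) & ranks <= 5),
    top10 = sum(!is.na(ranks) & ranks <= 10),
    none = sum(is.na(ranks)),
    by_attribute = by_attr
  )
}

battery_to_table <- function(results) {
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (inherits(r, "analogy_error")) {
      data.frame(query_id = i, a = r$query$a, b = r$query$b, c = r$query$c,
                 rank = NA_integer_, token = NA_character_,
                 similarity = NA_real_, biased = NA,
                 error = r$error, stringsAsFactors = FALSE)
    } else {
      n <- nrow(r$ranked)
      data.frame(query_id = i, a = r$query$a, b = r$query$b, c = r$query$c,
                 rank = seq_len(n), token = r$ranked$token,
                 similarity = r$ranked$similarity, biased = r$ranked$biased,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

resolve_path <- function(p, base) {
  if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

# YAML 1.1 reads a bare `y:` key as the boolean TRUE; restore the key so
# axis configs can say `y: [employable, unemployable]` unquoted
fix_yaml_bool_keys <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) {
      nm[nm == "TRUE"] <- "y"
      nm[nm == "FALSE"] <- "n"
      names(x) <- nm
    }
    x <- lapply(x, fix_yaml_bool_keys)
  }
  x
}

read_audit_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    base <- dirname(normalizePath(config))
    cfg <- fix_yaml_bool_keys(yaml::read_yaml(config))
  } else {
    base <- "."
    cfg <- config
  }
  cfg$.base <- base
  cfg
}

#' Run the full audit described by a config file
#'
#' A single YAML config drives both audits so a whole study is one
#' command. It names an embedding file (`embeddings:` with `path`,
#' `format`, optional `oov_policy`) and one or both audit blocks:
#' `analogy:` (optional `battery` TSV with columns a/b/c/k, optional
#' `lexicon` file, one entry per line — package defaults are used when
#' omitted) and `axes:` (optional `terms` TSV with columns
#' term/category, and `pairs`, a list of `{x: [pos, neg], y: [pos,
#' neg]}` axis pairs). Relative paths are resolved against the config
#' file's directory.
#'
#' A missing embedding file is fatal; individual out-of-vocabulary
#' terms are recorded as warnings in the report and never abort a run.
#' When `out_dir` is given, per-query TSV tables, a JSON summary, a
#' plain-text report and (if `axes$plot` is true) scatter images are
#' written there; every number in the report traces to a cell of those
#' tables.
#'
#' @param config path to a YAML file, or an equivalent nested list.
#' @param out_dir optional output directory (overrides `out:` in the
#'   config).
#' @return an object of class `audit_report`.
#' @export
run_full_audit <- function(config, out_dir = NULL) {
  cfg <- read_audit_config(config)
  if (is.null(cfg$embeddings$path)) {
    stop("config must name an embedding file under embeddings: path",
         call. = FALSE)
  }
  emb_path <- resolve_path(cfg$embeddings$path, cfg$.base)
  if (!file.exists(emb_path)) {
    stop("embedding file not found: ", emb_path, call. = FALSE)
  }
  if (is.null(cfg$analogy) && is.null(cfg$axes)) {
    stop("config must contain at least one audit block (analogy: or axes:)",
         call. = FALSE)
  }
  store <- read_embeddings(emb_path, cfg$embeddings$format)
  oov_policy <- cfg$embeddings$oov_policy %||% "mean_of_words"
  out_dir <- out_dir %||% resolve_path(cfg$out, cfg$.base)
  warnings <- character(0)

  analogy_section <- NULL
  if (!is.null(cfg$analogy)) {
    bat <- if (!is.null(cfg$analogy$battery)) {
      utils::read.delim(resolve_path(cfg$analogy$battery, cfg$.base),
                        stringsAsFactors = FALSE)
    } else default_analogy_battery()
    lex <- if (!is.null(cfg$analogy$lexicon)) {
      lines <- readLines(resolve_path(cfg$analogy$lexicon, cfg$.base),
                         encoding = "UTF-8")
      bias_lexicon(trimws(lines[nzchar(trimws(lines))]))
    } else default_bias_lexicon()
    results <- run_battery(store, bat, lex, oov_policy = oov_policy)
    for (r in results) {
      if (inherits(r, "analogy_error")) {
        warnings <- c(warnings, sprintf("analogy (%s, %s, %s): %s",
                                        r$query$a, r$query$b, r$query$c, r$error))
      } else if (!is.na(r$input_outranked)) {
        warnings <- c(warnings, sprintf(
          "analogy (%s, %s, %s): excluded input '%s' would out-rank the top-1",
          r$query$a, r$query$b, r$query$c, r$input_outranked))
      }
    }
    analogy_section <- list(results = results,
                            table = battery_to_table(results),
                            summary = summarize_bias(results))
  }

  axes_section <- NULL
  if (!is.null(cfg$axes)) {
    terms <- if (!is.null(cfg$axes$terms)) {
      df <- utils::read.delim(resolve_path(cfg$axes$terms, cfg$.base),
                              stringsAsFactors = FALSE)
      term_set(df$term, df$category)
    } else default_term_set()
    pairs <- cfg$axes$pairs %||%
      list(list(x = c("healthy", "ill"), y = c("employable", "unemployable")))
    tables <- lapply(pairs, function(p) {
      xa <- build_axis(store, p$x[[1]], p$x[[2]], oov_policy = oov_policy)
      ya <- build_axis(store, p$y[[1]], p$y[[2]], oov_policy = oov_policy)
      project_battery(store, terms, xa, ya, oov_policy = oov_policy)
    })
    for (tab in tables) {
      miss <- attr(tab, "unresolved")
      if (length(miss)) {
        warnings <- c(warnings, sprintf("axes: out-of-vocabulary terms: %s",
                                        paste(miss, collapse = ", ")))
      }
    }
    axes_section <- list(tables = tables)
  }

  report <- structure(list(
    meta = list(
      embedding_path = emb_path,
      embedding_md5 = unname(tools::md5sum(emb_path)),
      format = cfg$embeddings$format,
      oov_policy = oov_policy,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    analogy = analogy_section,
    axes = axes_section,
    warnings = warnings
  ), class = "audit_report")

  if (!is.null(out_dir)) write_report(report, out_dir, plot = isTRUE(cfg$axes$plot))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, out_dir, plot = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary_json <- list(meta = report$meta, warnings = report$warnings)

  if (!is.null(report$analogy)) {
    utils::write.table(report$analogy$table,
                       file.path(out_dir, "analogy_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    per_query <- data.frame(
      query_id = seq_along(report$analogy$results),
      a = vapply(report$analogy$results, function(r) r$query$a, character(1)),
      b = vapply(report$analogy$results, function(r) r$query$b, character(1)),
      c = vapply(report$analogy$results, function(r) r$query$c, character(1)),
      first_biased_rank = vapply(report$analogy$results, function(r) {
        if (inherits(r, "analogy_error")) NA_integer_ else r$first_biased_rank
      }, integer(1)),
      stringsAsFactors = FALSE)
    summary_json$analogy <- list(per_query = per_query,
                                 counts = report$analogy$summary[
                                   c("n_queries", "n_errors", "top1", "top5",
                                     "top10", "none")])
  }
  if (!is.null(report$axes)) {
    for (i in seq_along(report$axes$tables)) {
      tab <- report$axes$tables[[i]]
      utils::write.table(as.data.frame(tab),
                         file.path(out_dir, sprintf("projections_%d.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (plot && nrow(tab)) {
        render_scatter(tab, file.path(out_dir, sprintf("scatter_%d.png", i)))
      }
    }
    summary_json$axes <- lapply(report$axes$tables, function(tab) {
      list(axes = attr(tab, "axes_meta"), n_terms = nrow(tab),
           unresolved = attr(tab, "unresolved"),
           extremes = attr(tab, "extremes"))
    })
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.audit_report <- function(x, ...) {
  cat("== embedding bias audit ==\n")
  cat("embeddings: ", x$meta$embedding_path, " (", x$meta$format,
      ", md5 ", x$meta$embedding_md5, ")\n", sep = "")
  cat("generated:  ", x$meta$timestamp, "\n", sep = "")
  if (!is.null(x$analogy)) {
    s <- x$analogy$summary
    cat("\n-- analogy battery --\n")
    cat(sprintf("%d queries (%d errors): biased completion at rank 1 in %d, within top-5 in %d, within top-10 in %d, absent in %d\n",
                s$n_queries, s$n_errors, s$top1, s$top5, s$top10, s$none))
    for (r in x$analogy$results) {
      if (inherits(r, "analogy_error")) {
        cat(sprintf("  %-14s %-12s %-18s ERROR: %s\n",
                    r$query$a, r$query$b, r$query$c, r$error))
      } else {
        fb <- if (is.na(r$first_biased_rank)) "-" else r$first_biased_rank
        cat(sprintf("  %-14s %-12s %-18s top-1: %-22s first biased rank: %s\n",
                    r$query$a, r$query$b, r$query$c,
                    if (nrow(r$ranked)) r$ranked$token[1] else "-", fb))
      }
    }
  } else {
    cat("\n-- analogy battery: not run --\n")
  }
  if (!is.null(x$axes)) {
    cat("\n-- axis projections --\n")
    for (tab in x$axes$tables) {
      meta <- attr(tab, "axes_meta")
      cat(sprintf("axes x: %s-%s, y: %s-%s (%d terms placed)\n",
                  meta$x[["positive"]], meta$x[["negative"]],
                  meta$y[["positive"]], meta$y[["negative"]], nrow(tab)))
      ext <- attr(tab, "extremes")
      if (!is.null(ext)) {
        for (i in seq_len(nrow(ext))) {
          cat(sprintf("  %-22s x in [%+.6f (%s), %+.6f (%s)]  y in [%+.6f (%s), %+.6f (%s)]\n",
                      ext$category[i], ext$x_min[i], ext$x_min_term[i],
                      ext$x_max[i], ext$x_max_term[i],
                      ext$y_min[i], ext$y_min_term[i],
                      ext$y_max[i], ext$y_max_term[i]))
        }
      }
    }
  } else {
    cat("\n-- axis projections: not run --\n")
  }
  if (length(x$warnings)) {
    cat("\nwarnings:\n")
    for (w in x$warnings) cat("  - ", w, "\n", sep = "")
  }
  invisible(x)
}
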