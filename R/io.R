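#' @title Reading and writing static embedding files
#' @description Loaders for the three dialects in common circulation:
#'   the word2vec binary format (header line `"<|V|> <d>"`, then
#'   space-terminated token bytes followed by d little-endian float32
#'   values), the word2vec text format (same header, ASCII floats), and
#'   the GloVe text format (headerless, one `token v1 ... vd` line per
#'   word). All loaders return a [word_vector_store()].
#' @name embedding_io
NULL

format_error <- function(msg, ...) {
  stop(structure(
    class = c("embedaudit_format_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

raw_to_token <- function(bytes) {
  # tokens are UTF-8 in modern distributions but GoogleNews contains
  # stray non-UTF-8 bytes; fall back to latin1 so no byte is lost
  s <- rawToChar(bytes)
  if (validUTF8(s)) {
    Encoding(s) <- "UTF-8"
  } else {
    s <- iconv(s, from = "latin1", to = "UTF-8")
  }
  s
}

drop_duplicate_tokens <- function(tokens, mat, path) {
  dup <- duplicated(tokens)
  if (any(dup)) {
    warning(sprintf("%s: %d duplicate token(s) (e.g. '%s'); keeping first occurrence",
                    path, sum(dup), tokens[which(dup)[1]]), call. = FALSE)
    tokens <- tokens[!dup]
    mat <- mat[!dup, , drop = FALSE]
  }
  list(tokens = tokens, matrix = mat)
}

#' Load word2vec binary embeddings
#'
#' @param path path to a `.bin` file (uncompressed).
#' @return a [word_vector_store()].
#' @export
#' @seealso [load_glove_text()], [load_word2vec_text()], [write_store()]
load_word2vec_binary <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  bytes <- readBin(path, "raw", n = file.size(path))
  nl <- which(bytes == as.raw(0x0A))[1]
  if (is.na(nl)) format_error("%s: missing header line", path)
  header <- strsplit(trimws(rawToChar(bytes[seq_len(nl - 1)])), "[[:space:]]+")[[1]]
  vocab <- suppressWarnings(as.integer(header[1]))
  d <- suppressWarnings(as.integer(header[2]))
  if (length(header) != 2 || is.na(vocab) || is.na(d) || vocab < 0 || d < 1) {
    format_error("%s: malformed header '%s' (expected '<vocab_size> <dim>')",
                 path, rawToChar(bytes[seq_len(nl - 1)]))
  }

  tokens <- character(vocab)
  mat <- matrix(0, nrow = vocab, ncol = d)
  pos <- nl + 1L
  total <- length(bytes)
  space <- as.raw(0x20); newline <- as.raw(0x0A)
  for (i in seq_len(vocab)) {
    while (pos <= total && bytes[pos] == newline) pos <- pos + 1L
    start <- pos
    while (pos <= total && bytes[pos] != space) pos <- pos + 1L
    if (pos > total) {
      format_error("%s: truncated token block at byte offset %d (entry %d of %d)",
                   path, start - 1L, i, vocab)
    }
    tokens[i] <- raw_to_token(bytes[start:(pos - 1L)])
    pos <- pos + 1L  # skip the space
    end <- pos + 4L * d - 1L
    if (end > total) {
      format_error("%s: truncated vector block at byte offset %d (entry %d of %d)",
                   path, pos - 1L, i, vocab)
    }
    mat[i, ] <- readBin(bytes[pos:end], "numeric", n = d, size = 4,
                        endian = "little")
    pos <- end + 1L
  }
  parts <- drop_duplicate_tokens(tokens, mat, path)
  word_vector_store(parts$tokens, parts$matrix, source = path,
                    format = "word2vec_binary")
}

parse_numeric_fields <- function(fields, path, line_no) {
  vals <- suppressWarnings(as.numeric(fields))
  if (anyNA(vals)) {
    format_error("%s: non-numeric vector component on line %d ('%s')",
                 path, line_no, fields[which(is.na(vals))[1]])
  }
  vals
}

#' Load word2vec text embeddings
#'
#' @param path path to a text file whose first line is `"<|V|> <d>"`.
#' @return a [word_vector_store()].
#' @export
load_word2vec_text <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) format_error("%s: empty file", path)
  header <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  vocab <- suppressWarnings(as.integer(header[1]))
  d <- suppressWarnings(as.integer(header[2]))
  if (length(header) != 2 || is.na(vocab) || is.na(d) || vocab < 0 || d < 1) {
    format_error("%s: malformed header '%s'", path, lines[1])
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != vocab) {
    format_error("%s: header declares %d tokens but file has %d vector lines",
                 path, vocab, length(body))
  }
  parsed <- parse_vector_lines(body, path, d = d, line_offset = 1L)
  parts <- drop_duplicate_tokens(parsed$tokens, parsed$matrix, path)
  word_vector_store(parts$tokens, parts$matrix, source = path,
                    format = "word2vec_text")
}

parse_vector_lines <- function(body, path, d = NULL, line_offset = 0L) {
  fields <- strsplit(body, " ", fixed = TRUE)
  n <- length(fields)
  if (is.null(d)) d <- length(fields[[1]]) - 1L
  if (d < 1) format_error("%s: first vector line has no components", path)
  tokens <- character(n)
  mat <- matrix(0, nrow = n, ncol = d)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) != d + 1L) {
      format_error("%s: line %d has %d components, expected %d",
                   path, i + line_offset, length(f) - 1L, d)
    }
    tokens[i] <- f[1]
    mat[i, ] <- parse_numeric_fields(f[-1], path, i + line_offset)
  }
  list(tokens = tokens, matrix = mat)
}

#' Load GloVe text embeddings
#'
#' GloVe files have no header; the dimensionality is inferred from the
#' first line and must be consistent across the file.
#'
#' @param path path to a GloVe `.txt` file (uncompressed).
#' @return a [word_vector_store()].
#' @export
load_glove_text <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(word_vector_store(character(0), matrix(0, 0, 1),
                             source = path, format = "glove_text"))
  }
  parsed <- parse_vector_lines(lines, path)
  parts <- drop_duplicate_tokens(parsed$tokens, parsed$matrix, path)
  word_vector_store(parts$tokens, parts$matrix, source = path,
                    format = "glove_text")
}

#' Load embeddings in any supported dialect
#'
#' @param path file path.
#' @param format one of `"word2vec_binary"`, `"word2vec_text"`,
#'   `"glove_text"`.
#' @return a [word_vector_store()].
#' @export
read_embeddings <- function(path, format = c("word2vec_binary",
                                             "word2vec_text",
                                             "glove_text")) {
  format <- match.arg(format)
  switch(format,
         word2vec_binary = load_word2vec_binary(path),
         word2vec_text = load_word2vec_text(path),
         glove_text = load_glove_text(path))
}

#' Write a store to disk
#'
#' Round trips hold to float32 precision for the binary dialect, to 9
#' significant digits for word2vec text, and to 6 decimal places for
#' GloVe text (the precision those files conventionally ship with).
#' Text dialects cannot represent tokens containing whitespace; write
#' multiword phrases underscore-joined instead.
#'
#' @param store a [word_vector_store()].
#' @param path output file path.
#' @param format one of `"word2vec_binary"`, `"word2vec_text"`,
#'   `"glove_text"`.
#' @export
write_store <- function(store, path, format = c("word2vec_binary",
                                                "word2vec_text",
                                                "glove_text")) {
  stopifnot(inherits(store, "word_vector_store"))
  format <- match.arg(format)
  if (any(grepl("[[:space:]]", store$tokens))) {
    bad <- store$tokens[grepl("[[:space:]]", store$tokens)][1]
    stop(sprintf("token '%s' contains whitespace and is unrepresentable; underscore-join it first", bad),
         call. = FALSE)
  }
  if (format == "word2vec_binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("%d %d\n", length(store$tokens), store$dim)), con)
    for (i in seq_along(store$tokens)) {
      writeBin(c(charToRaw(enc2utf8(store$tokens[i])), as.raw(0x20)), con)
      writeBin(store$matrix[i, ], con, size = 4, endian = "little")
    }
  } else {
    fmt <- if (format == "glove_text") "%.6f" else "%.9g"
    body <- vapply(seq_along(store$tokens), function(i) {
      paste(store$tokens[i], paste(sprintf(fmt, store$matrix[i, ]), collapse = " "))
    }, character(1))
    if (format == "word2vec_text") {
      body <- c(sprintf("%d %d", length(store$tokens), store$dim), body)
    }
    con <- file(path, "wb")  # binary mode: byte-identical output across platforms
    on.exit(close(con))
    writeLines(enc2utf8(body), con, useBytes = TRUE)
  }
  invisible(NULL)
}
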