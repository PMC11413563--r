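#' Read / write a numeric matrix as TSV
#'
#' Plain-text exchange format for time series, FC matrices and gradient
#' tables: a header row of column labels, optionally a first column of row
#' labels.
#'
#' @param x Numeric matrix.
#' @param path File path.
#' @param row_labels Write row names as a leading `label` column?
#' @return `read_matrix_tsv` returns a numeric matrix; `write_matrix_tsv`
#'   returns `path` invisibly.
#' @export
write_matrix_tsv <- function(x, path, row_labels = !is.null(rownames(x))) {
  if (row_labels) {
    df <- data.frame(label = rownames(x) %||% default_labels(nrow(x)), x,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1] == "label") {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$label
  } else {
    m <- as.matrix(df)
  }
  m
}

#' Read / write embeddings in word2vec text format
#'
#' The word2vec text convention: a header line `<n_units> <dim>` followed
#' by one line per unit, `label v1 ... vdim`, space-separated.
#'
#' @param x Unit-by-dim numeric matrix with row names.
#' @param path File path.
#' @return `read_word2vec` returns the matrix; `write_word2vec` returns
#'   `path` invisibly.
#' @export
write_word2vec <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(x), ncol(x)), con)
  labs <- rownames(x) %||% default_labels(nrow(x), "unit")
  for (i in seq_len(nrow(x))) {
    writeLines(paste(labs[i], paste(format(x[i, ], scientific = FALSE,
                                           trim = TRUE, digits = 8),
                                    collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  assert_that(length(hdr) == 2, "malformed word2vec header")
  body <- strsplit(lines[-1], "\\s+")
  assert_that(length(body) == hdr[1], "unit count does not match header")
  m <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(hdr[2])))
  rownames(m) <- vapply(body, `[[`, character(1), 1)
  m
}

#' Read / write a parcel-to-network lookup table
#'
#' Two-column TSV `roi_label<TAB>network` mapping each parcel to its
#' network.
#'
#' @param partition Named character vector (names = ROI labels, values =
#'   network names).
#' @param path File path.
#' @return `read_network_lookup` returns the named character vector.
#' @export
write_network_lookup <- function(partition, path) {
  write.table(data.frame(roi_label = names(partition),
                         network = unname(partition)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_lookup
#' @export
read_network_lookup <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  setNames(as.character(df$network), df$roi_label)
}

#' Read / write tree files
#'
#' One bracketed tree string per line.
#'
#' @param trees Character vector of bracketed strings.
#' @param path File path.
#' @return `read_trees` returns a character vector (blank lines dropped).
#' @export
write_trees <- function(trees, path) {
  writeLines(trees, path)
  invisible(path)
}

#' @rdname write_trees
#' @export
read_trees <- function(path) {
  lines <- readLines(path)
  lines[nzchar(trimws(lines))]
}
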