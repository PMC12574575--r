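#' Read a feature-by-sample matrix from a delimited text file
#'
#' Reads a TSV or CSV file (delimiter sniffed from the header line) whose
#' first column holds feature identifiers and whose header row holds sample
#' identifiers. Cells must be numeric or the missing-value marker.
#'
#' @param path Path to the file.
#' @param features_in_rows If `FALSE`, the file is sample-by-feature and the
#'   returned matrix is transposed so that features are rows.
#' @param missing String encoding missing values (default `"NA"`).
#' @return A numeric matrix with features as rows and samples as columns.
#' @export
read_matrix <- function(path, features_in_rows = TRUE, missing = "NA") {
  if (!file.exists(path)) ml_stop("file not found: %s", path)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- suppressWarnings(readr::read_delim(
    path, delim = delim, na = character(),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))  # malformed rows are reported below via readr::problems()
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    ml_stop("malformed row in %s (data line %d): %s",
            path, probs$row[1], probs$expected[1])
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    ml_stop("duplicated identifier '%s' in %s", ids[duplicated(ids)][1], path)
  }
  cols <- names(df)[-1]
  if (anyDuplicated(cols)) {
    ml_stop("duplicated column identifier '%s' in %s",
            cols[duplicated(cols)][1], path)
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- is.na(num) & raw != missing
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    ml_stop("non-numeric cell '%s' at feature '%s', column '%s'",
            raw[bad][1], ids[idx[1]], cols[idx[2]])
  }
  dimnames(num) <- list(ids, cols)
  if (!features_in_rows) num <- t(num)
  check_matrix(num, basename(path))
  num
}

#' Write a feature-by-sample matrix to a delimited text file
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param delim Field delimiter, tab by default.
#' @param id_column Name used for the identifier column header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, delim = "\t", id_column = "feature") {
  check_matrix(x, "x")
  df <- tibble::as_tibble(x, rownames = id_column)
  readr::write_delim(df, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Each line holds a set name, a description, and one or more gene symbols,
#' tab-separated. Duplicate genes within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one element per set), with the
#'   set descriptions stored in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) ml_stop("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    ml_warn("empty GMT file: %s", path)
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0) {
    ml_stop("GMT line %d in %s has fewer than 3 fields", short[1], path)
  }
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    ml_stop("duplicated gene-set name '%s' in %s", nms[duplicated(nms)][1], path)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  attr(sets, "descriptions") <- setNames(vapply(fields, `[[`, "", 2L), nms)
  sets
}
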