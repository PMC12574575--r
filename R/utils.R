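# internal helpers shared across modules

ml_msg <- function(...) {
  if (isTRUE(getOption("methylload.verbose", TRUE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

ml_stop <- function(...) stop(sprintf(...), call. = FALSE)

ml_warn <- function(...) warning(sprintf(...), call. = FALSE)

# x must be a numeric matrix with unique, non-empty dimnames
check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    ml_stop("%s must be a numeric matrix", what)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    ml_stop("%s must have row and column names", what)
  }
  if (anyDuplicated(rownames(x))) {
    ml_stop("%s has duplicated row identifiers (e.g. '%s')",
            what, rownames(x)[duplicated(rownames(x))][1])
  }
  if (anyDuplicated(colnames(x))) {
    ml_stop("%s has duplicated column identifiers (e.g. '%s')",
            what, colnames(x)[duplicated(colnames(x))][1])
  }
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# numerically stable log(sum(exp(x))) along rows of a matrix
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  for (c in seq_len(ncol(m))[-1L]) mx <- pmax.int(mx, m[, c])
  mx + log(rowSums(exp(m - mx)))
}
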