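#' Remove sex-chromosome and blacklisted probes from a beta matrix
#'
#' Probes on chromosomes X or Y, and probes flagged in the annotation's
#' blacklist column (cross-reactive or polymorphic probes), are removed
#' before deconvolution so that methylation differences are not driven by
#' sex chromosomes or unreliable probes. A probe removable for both reasons
#' is removed once but counted in both tallies.
#'
#' @param beta CpG-by-sample matrix of beta values.
#' @param annotation Data frame with columns `cpg`, `chrom`, and logical
#'   `blacklist`; must cover every probe in `beta`.
#' @return The filtered beta matrix, with an attribute `"removed"` holding
#'   the per-reason counts.
#' @export
filter_probes <- function(beta, annotation) {
  check_matrix(beta, "beta")
  ann <- annotation[match(rownames(beta), annotation$cpg), , drop = FALSE]
  if (anyNA(ann$cpg)) {
    ml_stop("probe '%s' has no annotation",
            rownames(beta)[is.na(ann$cpg)][1])
  }
  on_sex <- ann$chrom %in% c("chrX", "chrY", "X", "Y")
  on_bl <- isTRUE_vec(ann$blacklist)
  drop <- on_sex | on_bl
  counts <- list(
    sex_chrom = sum(on_sex),
    blacklist = sum(on_bl),
    removed = sum(drop),
    retained = sum(!drop)
  )
  ml_msg("filter_probes: removed %d probes (%d sex-chromosome, %d blacklisted), %d retained",
         counts$removed, counts$sex_chrom, counts$blacklist, counts$retained)
  out <- beta[!drop, , drop = FALSE]
  attr(out, "removed") <- counts
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Infer sample sex from chromosome-X methylation
#'
#' X-inactivation in females drives intermediate methylation at chrX probes,
#' so the per-sample median chrX beta separates the sexes: a median inside
#' the female window (default \[0.35, 0.65\]) is called female, anything
#' outside it male. Run this before probe filtering, which removes chrX.
#'
#' @param beta CpG-by-sample beta matrix including chrX probes.
#' @param annotation Probe annotation with columns `cpg`, `chrom`.
#' @param female_window Length-2 numeric window of median chrX beta values
#'   called female.
#' @return A tibble with columns `sample`, `median_chrx`, `predicted_sex`.
#' @export
infer_sex <- function(beta, annotation, female_window = c(0.35, 0.65)) {
  check_matrix(beta, "beta")
  chrx <- annotation$cpg[annotation$chrom %in% c("chrX", "X")]
  chrx <- intersect(chrx, rownames(beta))
  if (length(chrx) == 0) ml_stop("no chrX probes available for sex inference")
  if (length(chrx) < 20) {
    ml_warn("only %d chrX probes available; sex calls may be unstable",
            length(chrx))
  }
  med <- apply(beta[chrx, , drop = FALSE], 2L, median, na.rm = TRUE)
  tibble::tibble(
    sample = colnames(beta),
    median_chrx = unname(med),
    predicted_sex = unname(ifelse(med >= female_window[1] &
                                    med <= female_window[2],
                                  "female", "male"))
  )
}

#' Drop samples whose methylation-predicted sex contradicts the reported sex
#'
#' @param predicted Data frame with columns `sample`, `predicted_sex` (as
#'   returned by [infer_sex()]), or a named character vector.
#' @param reported Named character vector (names = samples) or data frame
#'   with columns `sample`, `sex`.
#' @return Character vector of retained sample identifiers, with the dropped
#'   samples in the `"dropped"` attribute.
#' @export
drop_sex_mismatches <- function(predicted, reported) {
  if (is.data.frame(predicted)) {
    predicted <- setNames(predicted$predicted_sex, predicted$sample)
  }
  if (is.data.frame(reported)) {
    reported <- setNames(reported$sex, reported$sample)
  }
  only <- c(setdiff(names(predicted), names(reported)),
            setdiff(names(reported), names(predicted)))
  if (length(only) > 0) {
    ml_stop("sample '%s' present in only one sex labeling", only[1])
  }
  reported <- reported[names(predicted)]
  keep <- predicted == reported
  if (!any(keep)) {
    ml_warn("all %d samples are sex-mismatched; nothing retained", length(keep))
  }
  ml_msg("drop_sex_mismatches: %d mismatched sample(s) removed, %d retained",
         sum(!keep), sum(keep))
  structure(names(predicted)[keep], dropped = names(predicted)[!keep])
}

#' Quantile normalization within probe-type strata
#'
#' Infinium probe chemistries produce systematically different beta
#' distributions, so normalization is run separately per probe-type stratum
#' (e.g. type I red, type I green, type II). Within a stratum each sample's
#' values are mapped onto the stratum's reference distribution: the
#' element-wise mean of the designated reference samples' sorted values
#' (all samples serve as reference when none are designated). Rank order
#' within a sample and stratum is preserved; ties are interpolated.
#'
#' @param beta CpG-by-sample beta matrix.
#' @param annotation Probe annotation with columns `cpg`, `stratum`.
#' @param reference_samples Optional character vector of reference sample
#'   identifiers (e.g. technical duplicates); defaults to all samples.
#' @return The normalized beta matrix, same dimensions and names.
#' @export
quantile_normalize_stratified <- function(beta, annotation,
                                          reference_samples = NULL) {
  check_matrix(beta, "beta")
  ann <- annotation[match(rownames(beta), annotation$cpg), , drop = FALSE]
  if (anyNA(ann$cpg)) {
    ml_stop("probe '%s' has no annotation", rownames(beta)[is.na(ann$cpg)][1])
  }
  if (is.null(reference_samples)) reference_samples <- colnames(beta)
  missing_ref <- setdiff(reference_samples, colnames(beta))
  if (length(missing_ref) > 0) {
    ml_stop("reference sample '%s' not in beta matrix", missing_ref[1])
  }
  out <- beta
  for (s in unique(ann$stratum)) {
    idx <- which(ann$stratum == s)
    if (length(idx) < 2) {
      ml_warn("stratum '%s' has fewer than 2 probes; passed through unchanged", s)
      next
    }
    ref_block <- beta[idx, reference_samples, drop = FALSE]
    ref <- rowMeans(apply(ref_block, 2L, sort))
    n <- length(idx)
    for (j in seq_len(ncol(beta))) {
      v <- beta[idx, j]
      r <- rank(v, ties.method = "average")
      out[idx, j] <- stats::approx(seq_len(n), ref, xout = r, rule = 2)$y
    }
  }
  out
}

#' Map expression row identifiers to gene symbols and filter
#'
#' Rows whose identifier has no gene symbol in the map are dropped; rows
#' mapping to the same symbol are collapsed (summed by default, preserving
#' total signal); rows with no observed value in any sample are dropped.
#'
#' @param expr Gene-by-sample expression matrix with source identifiers
#'   (e.g. Ensembl IDs) as row names.
#' @param map Data frame with columns `source_id`, `symbol` (`NA` or empty
#'   symbol means unmapped); must cover every row of `expr`.
#' @param collapse How to collapse duplicate symbols: `"sum"`, `"first"`, or
#'   `"maxmean"` (keep the row with the largest mean).
#' @return Expression matrix keyed by gene symbol.
#' @export
map_and_filter_genes <- function(expr, map,
                                 collapse = c("sum", "first", "maxmean")) {
  collapse <- match.arg(collapse)
  check_matrix(expr, "expr")
  idx <- match(rownames(expr), map$source_id)
  if (anyNA(idx)) {
    ml_stop("expression identifier '%s' absent from gene-ID map",
            rownames(expr)[is.na(idx)][1])
  }
  symbol <- map$symbol[idx]
  mapped <- !is.na(symbol) & nzchar(symbol)
  ml_msg("map_and_filter_genes: %d of %d identifiers mapped, %d dropped",
         sum(mapped), length(mapped), sum(!mapped))
  expr <- expr[mapped, , drop = FALSE]
  symbol <- symbol[mapped]
  if (anyDuplicated(symbol)) {
    n_dup <- length(symbol) - length(unique(symbol))
    ml_msg("map_and_filter_genes: collapsing %d duplicate symbol row(s) by '%s'",
           n_dup, collapse)
    if (collapse == "sum") {
      n_obs <- rowsum((!is.na(expr)) * 1, group = symbol)
      expr <- rowsum(expr, group = symbol, na.rm = TRUE)
      expr[n_obs == 0] <- NA  # rowsum() turns all-NA groups into 0
    } else {
      ord <- if (collapse == "maxmean") {
        order(-rowMeans(expr, na.rm = TRUE))
      } else {
        seq_len(nrow(expr))
      }
      keep <- ord[!duplicated(symbol[ord])]
      expr <- expr[sort(keep), , drop = FALSE]
      rownames(expr) <- symbol[sort(keep)]
    }
  } else {
    rownames(expr) <- symbol
  }
  observed <- rowSums(!is.na(expr)) > 0
  if (any(!observed)) {
    ml_msg("map_and_filter_genes: dropping %d gene(s) with no observed value",
           sum(!observed))
  }
  expr[observed, , drop = FALSE]
}
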