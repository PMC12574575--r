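#' Dichotomize a biomarker value against a clinical cutoff
#'
#' A value scores 1 (at risk) when it lies strictly on the risk side of the
#' cutoff: strictly above for `risk_side = "above"` (most biomarkers), or
#' strictly below for `risk_side = "below"` (HDL cholesterol is the classic
#' case, where low values indicate risk). A value exactly at the cutoff
#' scores 0. Missing values propagate as `NA`.
#'
#' @param value Numeric vector of biomarker values.
#' @param cutoff Numeric cutoff(s), recycled against `value`.
#' @param risk_side `"above"` or `"below"`, recycled against `value`.
#' @return Integer vector of 0/1 (with `NA` where `value` is missing).
#' @export
al_dichotomize <- function(value, cutoff, risk_side = "above") {
  if (!is.numeric(cutoff) || anyNA(cutoff)) {
    ml_stop("cutoff must be numeric and non-missing")
  }
  if (!all(risk_side %in% c("above", "below"))) {
    ml_stop("risk_side must be 'above' or 'below'")
  }
  out <- ifelse(risk_side == "above", value > cutoff, value < cutoff)
  as.integer(out)
}

# pick, for each sample, the applicable cutoff row of one biomarker:
# a sex-specific row when present, otherwise the sex = "any" row
.applicable_thresholds <- function(thresholds, biomarker, sex) {
  rows <- thresholds[thresholds$biomarker == biomarker, , drop = FALSE]
  if (nrow(rows) == 0) {
    ml_stop("no threshold entry for biomarker '%s'", biomarker)
  }
  idx <- match(sex, rows$sex)
  any_row <- match("any", rows$sex)
  idx[is.na(idx)] <- any_row
  if (anyNA(idx)) {
    ml_stop("biomarker '%s' has no applicable cutoff for sex '%s'",
            biomarker, sex[is.na(idx)][1])
  }
  rows[idx, , drop = FALSE]
}

#' Allostatic-load index score (sum of dichotomized biomarkers)
#'
#' Each configured biomarker is dichotomized against its clinical cutoff
#' (sex-stratified where the threshold table provides sex-specific rows) and
#' the 0/1 values are summed per sample. Samples missing any biomarker get a
#' missing score and are flagged incomplete; no imputation is performed.
#'
#' @param panel Data frame with a `sample` column, a `sex` column
#'   (`"male"`/`"female"`), and one numeric column per biomarker.
#' @param thresholds Data frame with columns `biomarker`, `sex` (`"any"`,
#'   `"male"` or `"female"`), `cutoff`, `risk_side`.
#' @param biomarkers Character vector of biomarker column names; defaults to
#'   every biomarker named in `thresholds`.
#' @return A tibble with columns `sample`, `score` (integer), `n_missing`,
#'   `complete`.
#' @export
al_index_score <- function(panel, thresholds, biomarkers = NULL) {
  panel <- tibble::as_tibble(panel)
  if (is.null(biomarkers)) biomarkers <- unique(thresholds$biomarker)
  absent <- setdiff(biomarkers, colnames(panel))
  if (length(absent) > 0) {
    ml_stop("biomarker '%s' missing from panel", absent[1])
  }
  no_thr <- setdiff(biomarkers, thresholds$biomarker)
  if (length(no_thr) > 0) {
    ml_stop("no threshold entry for biomarker '%s'", no_thr[1])
  }
  flags <- vapply(biomarkers, function(b) {
    thr <- .applicable_thresholds(thresholds, b, panel$sex)
    al_dichotomize(panel[[b]], thr$cutoff, thr$risk_side)
  }, integer(nrow(panel)))
  flags <- matrix(flags, nrow = nrow(panel))
  n_missing <- rowSums(is.na(flags))
  score <- rowSums(flags)
  tibble::tibble(
    sample = panel$sample,
    score = as.integer(score),
    n_missing = as.integer(n_missing),
    complete = n_missing == 0L
  )
}

#' Allostatic-load score from summed absolute z-scores
#'
#' Each biomarker is standardized against reference statistics (by default
#' the mean and standard deviation of the supplied cohort itself) and the
#' absolute z-scores are summed per sample.
#'
#' @param panel Data frame with a `sample` column and numeric biomarker
#'   columns.
#' @param biomarkers Character vector of biomarker column names.
#' @param reference Optional data frame with columns `biomarker`, `mean`,
#'   `sd`; computed from `panel` when omitted.
#' @return A tibble with columns `sample`, `score`.
#' @export
al_zscore <- function(panel, biomarkers, reference = NULL) {
  panel <- tibble::as_tibble(panel)
  absent <- setdiff(biomarkers, colnames(panel))
  if (length(absent) > 0) {
    ml_stop("biomarker '%s' missing from panel", absent[1])
  }
  if (is.null(reference)) {
    reference <- tibble::tibble(
      biomarker = biomarkers,
      mean = vapply(biomarkers, function(b) mean(panel[[b]], na.rm = TRUE), 0),
      sd = vapply(biomarkers, function(b) sd(panel[[b]], na.rm = TRUE), 0)
    )
  }
  ref <- reference[match(biomarkers, reference$biomarker), , drop = FALSE]
  if (anyNA(ref$mean) || anyNA(ref$sd)) {
    ml_stop("reference statistics missing for biomarker '%s'",
            biomarkers[is.na(ref$mean) | is.na(ref$sd)][1])
  }
  zero <- ref$sd <= 0
  if (any(zero)) {
    ml_stop("zero standard deviation for biomarker '%s'", ref$biomarker[zero][1])
  }
  z <- vapply(seq_along(biomarkers), function(i) {
    abs((panel[[biomarkers[i]]] - ref$mean[i]) / ref$sd[i])
  }, numeric(nrow(panel)))
  z <- matrix(z, nrow = nrow(panel))
  tibble::tibble(sample = panel$sample, score = rowSums(z))
}

#' Assign high/low allostatic-load groups
#'
#' For the index variant a sample is `low` when its score is less than or
#' equal to the cutoff (default 2) and `high` when strictly greater. For the
#' z-score variant the cutoff is the third quartile of the cohort's scores
#' (linear-interpolation quantile), with `high` meaning strictly greater
#' than the cutoff; the cutoff used is echoed in the output.
#'
#' @param scores Data frame with columns `sample` and `score` (rows with a
#'   missing score are kept but get a missing group).
#' @param method `"index"` or `"zscore"`.
#' @param index_cutoff Cutoff for the index method (default 2).
#' @return A tibble with columns `sample`, `score`, `group`, `method`,
#'   `cutoff_used`.
#' @export
al_assign_groups <- function(scores, method = c("index", "zscore"),
                             index_cutoff = 2) {
  method <- match.arg(method)
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) ml_stop("empty score table")
  ok <- !is.na(scores$score)
  if (!any(ok)) ml_stop("no complete scores to group")
  cutoff <- if (method == "index") {
    index_cutoff
  } else {
    unname(quantile(scores$score[ok], probs = 0.75, type = 7))
  }
  group <- ifelse(scores$score > cutoff, "high", "low")
  tibble::tibble(
    sample = scores$sample,
    score = scores$score,
    group = group,
    method = method,
    cutoff_used = cutoff
  )
}
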