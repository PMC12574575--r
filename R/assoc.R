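#' Call per-sample methylation states in the high-AL group
#'
#' Fits (or reuses) a beta mixture on the high-AL samples' beta values at
#' one CpG and labels each mixture component relative to the low-AL
#' reference mean: a component is *hyper* when its mean exceeds the low-AL
#' mean by more than `dm_threshold` beta units and a rank-sum test of its
#' member samples' betas against all low-AL betas is significant at
#' `p_threshold`; *hypo* symmetrically. Samples in unlabeled components are
#' *normal*. Prevalences are the fractions of high-AL samples in hypo and
#' hyper states.
#'
#' @param high_values Beta values of the high-AL samples (named by sample).
#' @param low_values Beta values of the low-AL samples.
#' @param fit Optional precomputed `"beta_mixture"` fit of `high_values`.
#' @param dm_threshold Minimum absolute beta difference between a component
#'   mean and the low-AL mean (default 0.10).
#' @param p_threshold Significance level for the component-vs-low rank-sum
#'   test (default 0.05).
#' @return An object of class `"state_call"`: list with `states` (character
#'   vector per high-AL sample), `prev_hypo`, `prev_hyper`, `low_mean`, and
#'   a per-component `components` tibble (mean, weight, n, dm, p, label).
#' @export
call_states <- function(high_values, low_values, fit = NULL,
                        dm_threshold = 0.10, p_threshold = 0.05) {
  if (is.null(fit)) fit <- fit_beta_mixture(high_values)
  low_mean <- mean(low_values, na.rm = TRUE)
  assign <- mixture_assign(fit, high_values)
  labels <- rep("normal", fit$k)
  comp <- tibble::tibble(
    component = seq_len(fit$k),
    mean = fit$means,
    weight = fit$weights,
    n = tabulate(assign, nbins = fit$k),
    dm = fit$means - low_mean,
    p = NA_real_,
    label = "normal"
  )
  for (c in seq_len(fit$k)) {
    if (comp$n[c] == 0) next
    members <- high_values[assign == c]
    if (comp$dm[c] > dm_threshold) {
      p <- wilcox.test(members, low_values, alternative = "greater",
                       exact = FALSE)$p.value
      comp$p[c] <- p
      if (p < p_threshold) labels[c] <- "hyper"
    } else if (comp$dm[c] < -dm_threshold) {
      p <- wilcox.test(members, low_values, alternative = "less",
                       exact = FALSE)$p.value
      comp$p[c] <- p
      if (p < p_threshold) labels[c] <- "hypo"
    }
  }
  comp$label <- labels
  states <- labels[assign]
  names(states) <- names(high_values)
  structure(
    list(states = states,
         prev_hypo = mean(states == "hypo"),
         prev_hyper = mean(states == "hyper"),
         low_mean = low_mean,
         components = comp,
         fit = fit),
    class = "state_call"
  )
}

#' @export
print.state_call <- function(x, ...) {
  cat(sprintf("<state_call> prev_hypo %.2f, prev_hyper %.2f (low-AL mean %.3f)\n",
              x$prev_hypo, x$prev_hyper, x$low_mean))
  invisible(x)
}

# one-sided alternative for the expression test of an abnormal subset:
# negative mode expects hyper -> lower expression, hypo -> higher;
# positive mode is the reverse
.expr_alternative <- function(state, mode) {
  if (mode == "negative") {
    if (state == "hyper") "less" else "greater"
  } else {
    if (state == "hyper") "greater" else "less"
  }
}

# raw one-sided rank-sum p-values for each abnormal state subset of one CpG.
# baseline = normal-state high-AL samples pooled with all low-AL samples.
.state_expr_tests <- function(call, expr_high, expr_low, mode, min_subset) {
  out <- list()
  normal_ids <- names(call$states)[call$states == "normal"]
  baseline <- c(expr_high[normal_ids], expr_low)
  baseline <- baseline[is.finite(baseline)]
  for (state in c("hypo", "hyper")) {
    ids <- names(call$states)[call$states == state]
    vals <- expr_high[ids]
    vals <- vals[is.finite(vals)]
    if (length(ids) == 0) next
    if (length(vals) < min_subset || length(baseline) < 2) next
    p <- wilcox.test(vals, baseline,
                     alternative = .expr_alternative(state, mode),
                     exact = FALSE)$p.value
    out[[state]] <- tibble::tibble(state = state, n_subset = length(vals),
                                   p_raw = p)
  }
  dplyr::bind_rows(out)
}

#' Test one CpG's abnormal methylation states against gene expression
#'
#' For each abnormal state subset called at a CpG (hypo members, hyper
#' members), runs a one-sided rank-sum test of that subset's expression of
#' the linked gene against the baseline (normal-state high-AL samples
#' pooled with all low-AL samples), sided according to the correlation
#' mode. When run standalone the raw p-values are compared with `alpha`;
#' within [run_mode()] the adjustment is applied jointly instead.
#'
#' @param call A `"state_call"` for the CpG.
#' @param expr_high Named expression values of the high-AL samples.
#' @param expr_low Expression values of the low-AL samples.
#' @param mode `"negative"` or `"positive"`.
#' @param alpha Significance level applied to the raw p-values.
#' @param min_subset Smallest abnormal subset tested (default
#'   `max(5, 0.05 * n_high)`).
#' @return A one-row tibble describing the emitted pair (state `hypo`,
#'   `hyper`, or `dual` when both subsets pass), or a zero-row tibble when
#'   no state passes.
#' @export
pair_test <- function(call, expr_high, expr_low, mode = c("negative", "positive"),
                      alpha = 0.05, min_subset = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(call, "state_call"))
  if (is.null(min_subset)) min_subset <- max(5, ceiling(0.05 * length(call$states)))
  tests <- .state_expr_tests(call, expr_high, expr_low, mode, min_subset)
  .emit_pair(tests, call, mode, alpha, p_col = "p_raw")
}

.emit_pair <- function(tests, call, mode, alpha, p_col = "p_adj") {
  empty <- tibble::tibble(
    mode = character(), state = character(), prev_hypo = numeric(),
    prev_hyper = numeric(), p_raw = numeric(), p_adj = numeric()
  )
  if (nrow(tests) == 0) return(empty)
  pass <- tests[tests[[p_col]] < alpha, , drop = FALSE]
  if (nrow(pass) == 0) return(empty)
  state <- if (all(c("hypo", "hyper") %in% pass$state)) "dual" else pass$state[1]
  best <- which.min(pass[[p_col]])
  tibble::tibble(
    mode = mode,
    state = state,
    prev_hypo = call$prev_hypo,
    prev_hyper = call$prev_hyper,
    p_raw = pass$p_raw[best],
    p_adj = if ("p_adj" %in% names(pass)) pass$p_adj[best] else NA_real_
  )
}

# fit mixtures and call states for a set of CpGs (shared across modes)
.states_for_cpgs <- function(meth, cpgs, high, low, dm_threshold, p_threshold) {
  calls <- vector("list", length(cpgs))
  names(calls) <- cpgs
  for (cpg in cpgs) {
    hv <- meth[cpg, high]
    lv <- meth[cpg, low]
    hv <- hv[is.finite(hv)]
    lv <- lv[is.finite(lv)]
    if (length(hv) < 10 || length(lv) < 2) next
    calls[[cpg]] <- call_states(hv, lv, dm_threshold = dm_threshold,
                                p_threshold = p_threshold)
  }
  calls
}

# expand the annotation's linked-gene column into one row per CpG-gene link
.cpg_gene_links <- function(annotation, cpgs, genes) {
  ann <- annotation[annotation$cpg %in% cpgs, c("cpg", "gene")]
  ann <- ann[!is.na(ann$gene) & nzchar(ann$gene), , drop = FALSE]
  links <- tidyr::separate_rows(tibble::as_tibble(ann), "gene", sep = ";")
  links$gene <- trimws(links$gene)
  dplyr::distinct(links[links$gene %in% genes, , drop = FALSE])
}

#' Detect functional CpG-gene pairs for one cell type and correlation mode
#'
#' For every CpG linked to a gene present in the expression matrix, calls
#' methylation states on the high-AL samples and tests each abnormal state
#' subset's expression one-sidedly according to the mode. All raw p-values
#' of the cell type and mode are adjusted jointly by Benjamini-Hochberg;
#' pairs with an adjusted p-value below `alpha` are returned sorted by
#' adjusted p, with state `dual` when both the hypo and hyper subsets pass.
#'
#' @param cell_meth CpG-by-sample methylation matrix of one cell type.
#' @param cell_expr Gene-by-sample expression matrix of the same cell type.
#' @param groups Named character vector (`"high"`/`"low"`) per sample.
#' @param annotation Probe annotation with columns `cpg`, `gene`
#'   (semicolon-separated for multi-gene probes).
#' @param mode `"negative"` or `"positive"`.
#' @param alpha Benjamini-Hochberg-adjusted significance level (default 0.05).
#' @param dm_threshold,p_threshold State-calling thresholds, see
#'   [call_states()].
#' @param min_subset Smallest abnormal subset tested.
#' @param cell_type Optional cell-type label carried into the result.
#' @param state_calls Optional precomputed list of state calls keyed by CpG
#'   (used by [associate_cell_type()] to share fits between modes).
#' @return A tibble of class `"al_pairs"` with columns `cpg`, `gene`,
#'   `cell_type`, `mode`, `state`, `prev_hypo`, `prev_hyper`, `p_raw`,
#'   `p_adj`.
#' @export
run_mode <- function(cell_meth, cell_expr, groups, annotation,
                     mode = c("negative", "positive"), alpha = 0.05,
                     dm_threshold = 0.10, p_threshold = 0.05,
                     min_subset = NULL, cell_type = NA_character_,
                     state_calls = NULL) {
  mode <- match.arg(mode)
  check_matrix(cell_meth, "cell_meth")
  check_matrix(cell_expr, "cell_expr")
  groups <- groups[!is.na(groups)]
  high <- intersect(names(groups)[groups == "high"], colnames(cell_meth))
  low <- intersect(names(groups)[groups == "low"], colnames(cell_meth))
  if (is.null(min_subset)) min_subset <- max(5, ceiling(0.05 * length(high)))
  links <- .cpg_gene_links(annotation, rownames(cell_meth), rownames(cell_expr))
  empty <- tibble::tibble(
    cpg = character(), gene = character(), cell_type = character(),
    mode = character(), state = character(), prev_hypo = numeric(),
    prev_hyper = numeric(), p_raw = numeric(), p_adj = numeric()
  )
  if (nrow(links) == 0) {
    ml_warn("no CpG-gene links to test")
    return(structure(empty, class = c("al_pairs", class(empty))))
  }
  if (is.null(state_calls)) {
    state_calls <- .states_for_cpgs(cell_meth, unique(links$cpg), high, low,
                                    dm_threshold, p_threshold)
  }
  tests <- vector("list", nrow(links))
  for (i in seq_len(nrow(links))) {
    cpg <- links$cpg[i]
    gene <- links$gene[i]
    call <- state_calls[[cpg]]
    if (is.null(call)) next
    if (call$prev_hypo == 0 && call$prev_hyper == 0) next
    tt <- .state_expr_tests(call, cell_expr[gene, high], cell_expr[gene, low],
                            mode, min_subset)
    if (nrow(tt) == 0) next
    tt$cpg <- cpg
    tt$gene <- gene
    tests[[i]] <- tt
  }
  tests <- dplyr::bind_rows(tests)
  if (nrow(tests) == 0) {
    return(structure(empty, class = c("al_pairs", class(empty))))
  }
  tests$p_adj <- p.adjust(tests$p_raw, method = "BH")
  pairs <- tests |>
    dplyr::group_by(.data$cpg, .data$gene) |>
    dplyr::group_modify(function(df, key) {
      .emit_pair(df, state_calls[[key$cpg]], mode, alpha)
    }) |>
    dplyr::ungroup()
  pairs <- pairs[!is.na(pairs$state), , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(structure(empty, class = c("al_pairs", class(empty))))
  }
  pairs$cell_type <- cell_type
  pairs <- pairs[, c("cpg", "gene", "cell_type", "mode", "state",
                     "prev_hypo", "prev_hyper", "p_raw", "p_adj")]
  pairs <- dplyr::arrange(pairs, .data$p_adj, .data$p_raw)
  structure(pairs, class = c("al_pairs", class(pairs)))
}

#' Run both correlation modes for one cell type, sharing mixture fits
#'
#' @inheritParams run_mode
#' @param modes Correlation modes to run.
#' @return Named list of `"al_pairs"` tibbles, one per mode.
#' @export
associate_cell_type <- function(cell_meth, cell_expr, groups, annotation,
                                modes = c("negative", "positive"),
                                alpha = 0.05, dm_threshold = 0.10,
                                p_threshold = 0.05, min_subset = NULL,
                                cell_type = NA_character_) {
  groups <- groups[!is.na(groups)]
  high <- intersect(names(groups)[groups == "high"], colnames(cell_meth))
  low <- intersect(names(groups)[groups == "low"], colnames(cell_meth))
  links <- .cpg_gene_links(annotation, rownames(cell_meth), rownames(cell_expr))
  calls <- .states_for_cpgs(cell_meth, unique(links$cpg), high, low,
                            dm_threshold, p_threshold)
  out <- lapply(modes, function(m) {
    run_mode(cell_meth, cell_expr, groups, annotation, mode = m,
             alpha = alpha, dm_threshold = dm_threshold,
             p_threshold = p_threshold, min_subset = min_subset,
             cell_type = cell_type, state_calls = calls)
  })
  names(out) <- modes
  out
}

#' Concatenate negative- and positive-mode functional pairs
#'
#' @param neg_pairs,pos_pairs `"al_pairs"` tibbles from the two modes (any
#'   number of cell types).
#' @return A combined `"al_pairs"` tibble with the source mode retained,
#'   plus summary counts in the `"summary"` attribute (total pairs, unique
#'   CpGs, unique genes).
#' @export
combine_modes <- function(neg_pairs, pos_pairs) {
  combined <- dplyr::bind_rows(tibble::as_tibble(neg_pairs),
                               tibble::as_tibble(pos_pairs))
  smry <- tibble::tibble(
    n_pairs = nrow(combined),
    n_cpgs = dplyr::n_distinct(combined$cpg),
    n_genes = dplyr::n_distinct(combined$gene)
  )
  ml_msg("combine_modes: %d pairs (%d unique CpGs, %d unique genes)",
         smry$n_pairs, smry$n_cpgs, smry$n_genes)
  structure(combined, summary = smry, class = c("al_pairs", class(combined)))
}

#' @describeIn combine_modes Pair-table summary counts.
#' @param x An `"al_pairs"` tibble.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.al_pairs <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_cpgs = dplyr::n_distinct(x$cpg),
    n_genes = dplyr::n_distinct(x$gene),
    n_negative = sum(x$mode == "negative"),
    n_positive = sum(x$mode == "positive")
  )
}
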