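#' Direction of regulation implied by a CpG's state and correlation mode
#'
#' Rule table: hypomethylated in negative mode or hypermethylated in
#' positive mode means the gene is upregulated; hypermethylated in negative
#' mode or hypomethylated in positive mode means downregulated. Dual states
#' must be resolved with [resolve_dual()] first.
#'
#' @param state `"hypo"` or `"hyper"` (vectorized).
#' @param mode `"negative"` or `"positive"` (vectorized).
#' @return Character vector of `"up"`/`"down"`.
#' @export
cpg_direction <- function(state, mode) {
  if (any(!state %in% c("hypo", "hyper"))) {
    bad <- state[!state %in% c("hypo", "hyper")][1]
    ml_stop("unresolved state '%s'; dual states must pass through resolve_dual()",
            bad)
  }
  if (any(!mode %in% c("negative", "positive"))) {
    ml_stop("mode must be 'negative' or 'positive'")
  }
  ifelse(
    (state == "hypo") == (mode == "negative"),
    "up", "down"
  )
}

#' Resolve a dual-methylated CpG to its dominant state
#'
#' Picks the state (hypo or hyper) with the strictly greater prevalence
#' among high-AL samples. Equal prevalences cannot be resolved: the CpG is
#' flagged with `NA` and excluded from direction calling.
#'
#' @param prev_hypo,prev_hyper Prevalences of the hypo- and hypermethylated
#'   subsets (both must be positive for a dual CpG; vectorized).
#' @return Character vector of `"hypo"`/`"hyper"`, with `NA` at ties.
#' @export
resolve_dual <- function(prev_hypo, prev_hyper) {
  if (any(prev_hypo <= 0 & prev_hyper <= 0)) {
    ml_stop("both prevalences are zero: not a dual CpG")
  }
  out <- ifelse(prev_hypo > prev_hyper, "hypo",
                ifelse(prev_hyper > prev_hypo, "hyper", NA_character_))
  if (anyNA(out)) {
    ml_warn("%d dual CpG(s) with tied prevalences excluded from direction calling",
            sum(is.na(out)))
  }
  out
}

#' Gene-level direction from its per-CpG calls
#'
#' A gene is upregulated when all of its CpG calls are up, downregulated
#' when all are down, and inconsistent otherwise (inconsistent genes are
#' excluded from downstream proportions and enrichment).
#'
#' @param cpg_calls Character vector of `"up"`/`"down"` calls for one gene
#'   in one cell type.
#' @return `"up"`, `"down"`, or `"inconsistent"`.
#' @export
gene_direction <- function(cpg_calls) {
  if (length(cpg_calls) == 0) ml_stop("no CpG calls supplied")
  if (all(cpg_calls == "up")) return("up")
  if (all(cpg_calls == "down")) return("down")
  "inconsistent"
}

#' Per-gene, per-cell-type direction calls from a functional-pair table
#'
#' Resolves dual pairs to their dominant state (dropping unresolvable
#' ties), maps each CpG to an up/down call via [cpg_direction()], pools the
#' calls of both correlation modes per gene and cell type, and applies the
#' unanimity rule of [gene_direction()].
#'
#' @param pairs An `"al_pairs"` tibble (typically from [combine_modes()]).
#' @return A tibble of class `"al_directions"` with columns `gene`,
#'   `cell_type`, `direction`, `n_cpgs`, `cpgs` (comma-separated).
#' @export
direction_calls <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  empty <- structure(
    tibble::tibble(gene = character(), cell_type = character(),
                   direction = character(), n_cpgs = integer(),
                   cpgs = character()),
    class = c("al_directions", "tbl_df", "tbl", "data.frame")
  )
  if (nrow(pairs) == 0) return(empty)
  state <- pairs$state
  dual <- state == "dual"
  if (any(dual)) {
    state[dual] <- resolve_dual(pairs$prev_hypo[dual], pairs$prev_hyper[dual])
  }
  keep <- !is.na(state)
  pairs <- pairs[keep, , drop = FALSE]
  state <- state[keep]
  if (nrow(pairs) == 0) return(empty)
  pairs$call <- cpg_direction(state, pairs$mode)
  out <- pairs |>
    dplyr::group_by(.data$gene, .data$cell_type) |>
    dplyr::summarise(
      direction = gene_direction(.data$call),
      n_cpgs = dplyr::n_distinct(.data$cpg),
      cpgs = paste(sort(unique(.data$cpg)), collapse = ","),
      .groups = "drop"
    )
  structure(out, class = c("al_directions", class(out)))
}

#' Cross-cell-type summary of pairs and direction calls
#'
#' Tabulates, per cell type and globally, the functional-pair counts, the
#' proportions of hypo/hyper/dual methylation states, the differentially
#' methylated gene (DMG) counts, the proportions of up- and downregulated
#' genes among genes with a definite direction, and the genes shared
#' between cell types. Percentages are rounded to one decimal in the
#' printed report; the returned tables keep full precision.
#'
#' @param pairs Combined `"al_pairs"` tibble.
#' @param calls `"al_directions"` tibble from [direction_calls()].
#' @return A list of class `"al_summary"` with tibbles `per_cell_type`,
#'   `global`, and `shared_genes`.
#' @export
summarize_results <- function(pairs, calls) {
  pairs <- tibble::as_tibble(pairs)
  calls <- tibble::as_tibble(calls)
  per_ct_pairs <- pairs |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_cpgs = dplyr::n_distinct(.data$cpg),
      prop_hypo = mean(.data$state == "hypo"),
      prop_hyper = mean(.data$state == "hyper"),
      prop_dual = mean(.data$state == "dual"),
      .groups = "drop"
    )
  per_ct_dir <- calls |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_definite = sum(.data$direction != "inconsistent"),
      prop_up = mean(.data$direction[.data$direction != "inconsistent"] == "up"),
      prop_down = mean(.data$direction[.data$direction != "inconsistent"] == "down"),
      .groups = "drop"
    )
  per_cell_type <- dplyr::full_join(per_ct_pairs, per_ct_dir, by = "cell_type")
  gene_ct <- dplyr::distinct(calls[, c("gene", "cell_type")])
  shared <- gene_ct |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_cell_types = dplyr::n(),
      cell_types = paste(sort(.data$cell_type), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_cell_types >= 2)
  definite <- calls[calls$direction != "inconsistent", , drop = FALSE]
  n_unique_genes <- dplyr::n_distinct(calls$gene)
  global <- tibble::tibble(
    n_pairs = nrow(pairs),
    n_unique_cpgs = dplyr::n_distinct(pairs$cpg),
    n_unique_genes = n_unique_genes,
    n_gene_occurrences = nrow(gene_ct),
    n_shared_genes = nrow(shared),
    pct_shared = 100 * nrow(shared) / max(n_unique_genes, 1),
    n_definite_calls = nrow(definite),
    n_inconsistent = sum(calls$direction == "inconsistent"),
    prop_up = mean(definite$direction == "up"),
    prop_down = mean(definite$direction == "down")
  )
  structure(
    list(per_cell_type = per_cell_type, global = global, shared_genes = shared),
    class = "al_summary"
  )
}

#' @export
print.al_summary <- function(x, ...) {
  g <- x$global
  cat("Functional CpG-gene pair summary\n")
  cat(sprintf("  %d pairs, %d unique CpGs, %d unique genes (%d occurrences across cell types)\n",
              g$n_pairs, g$n_unique_cpgs, g$n_unique_genes, g$n_gene_occurrences))
  cat(sprintf("  shared between >=2 cell types: %d (%.1f%%)\n",
              g$n_shared_genes, g$pct_shared))
  cat(sprintf("  definite-direction genes: %d (%.1f%% down, %.1f%% up); %d inconsistent excluded\n",
              g$n_definite_calls, 100 * g$prop_down, 100 * g$prop_up,
              g$n_inconsistent))
  cat("Per cell type:\n")
  for (i in seq_len(nrow(x$per_cell_type))) {
    r <- x$per_cell_type[i, ]
    cat(sprintf("  %-10s %3d pairs, %3s DMGs | states %.1f%% hypo / %.1f%% hyper / %.1f%% dual\n",
                r$cell_type, r$n_pairs,
                ifelse(is.na(r$n_genes), "0", as.character(r$n_genes)),
                100 * r$prop_hypo, 100 * r$prop_hyper, 100 * r$prop_dual))
  }
  invisible(x)
}
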