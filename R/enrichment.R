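#' Hypergeometric over-representation analysis
#'
#' For each gene set, computes the upper-tail hypergeometric probability of
#' observing at least the realized overlap between the query and the set
#' when drawing `n` genes from a universe of `N` containing `K` set
#' members, then adjusts across all sets by Benjamini-Hochberg. Set sizes
#' are taken after intersection with the universe. The reported
#' `gene_ratio` is the overlap divided by the query size (k/n); `k`, `n`,
#' `K` and `N` are all stored so other ratios are derivable.
#'
#' @param query Character vector of query gene symbols (deduplicated; genes
#'   outside the universe are dropped with a warning).
#' @param universe Character vector of background gene symbols.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param alpha Adjusted-p significance level used for the `significant`
#'   flag (default 0.05).
#' @param min_size,max_size Optional set-size filter applied after universe
#'   intersection (`NULL` = no filter).
#' @return A tibble of class `"al_enrichment"` with columns `set`, `k`,
#'   `n`, `K`, `N`, `gene_ratio`, `p`, `p_adj`, `significant`, `genes`,
#'   sorted by adjusted p.
#' @export
ora <- function(query, universe, sets, alpha = 0.05,
                min_size = NULL, max_size = NULL) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    ml_warn("%d query gene(s) outside the universe dropped", length(outside))
    query <- intersect(query, universe)
  }
  empty <- tibble::tibble(
    set = character(), k = integer(), n = integer(), K = integer(),
    N = integer(), gene_ratio = numeric(), p = numeric(), p_adj = numeric(),
    significant = logical(), genes = character()
  )
  if (length(query) == 0) {
    ml_warn("empty query; no enrichment computed")
    return(structure(empty, class = c("al_enrichment", class(empty))))
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::map(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (!is.null(min_size) && K < min_size) return(NULL)
    if (!is.null(max_size) && K > max_size) return(NULL)
    overlap <- intersect(query, members)
    k <- length(overlap)
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(
      set = nm, k = k, n = n, K = K, N = N,
      gene_ratio = k / n, p = p,
      genes = paste(sort(overlap), collapse = ",")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(structure(empty, class = c("al_enrichment", class(empty))))
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- out[, c("set", "k", "n", "K", "N", "gene_ratio", "p", "p_adj",
                 "significant", "genes")]
  out <- dplyr::arrange(out, .data$p_adj, .data$p)
  structure(out, class = c("al_enrichment", class(out)))
}

#' Over-representation per cell type and regulation direction
#'
#' Splits the definite-direction genes into (cell type x direction) strata
#' and runs [ora()] on each non-empty stratum. Inconsistent genes are
#' excluded. When `sets` is a named list of collections (namespaces, e.g.
#' GO BP/MF/CC and pathways), the Benjamini-Hochberg adjustment is applied
#' independently within each namespace of each stratum.
#'
#' @param calls `"al_directions"` tibble from [direction_calls()].
#' @param sets Named list of gene vectors, or a named list of such lists
#'   (namespaces).
#' @param universe Background gene vector (typically all genes present in
#'   the expression matrices after preprocessing).
#' @param alpha Significance level (default 0.05).
#' @param min_size,max_size Optional set-size filters passed to [ora()].
#' @return A tibble of class `"al_enrichment"` with additional columns
#'   `cell_type`, `direction`, and `namespace`.
#' @export
stratified_enrichment <- function(calls, sets, universe, alpha = 0.05,
                                  min_size = NULL, max_size = NULL) {
  calls <- tibble::as_tibble(calls)
  calls <- calls[calls$direction %in% c("up", "down"), , drop = FALSE]
  namespaces <- if (length(sets) > 0 && is.list(sets[[1]])) {
    sets
  } else {
    list(sets = sets)
  }
  strata <- dplyr::distinct(calls[, c("cell_type", "direction")])
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    ct <- strata$cell_type[i]
    dir <- strata$direction[i]
    genes <- unique(calls$gene[calls$cell_type == ct & calls$direction == dir])
    if (length(genes) == 0) {
      ml_msg("stratum %s/%s has no genes; skipped", ct, dir)
      next
    }
    for (ns in names(namespaces)) {
      res <- ora(genes, universe, namespaces[[ns]], alpha = alpha,
                 min_size = min_size, max_size = max_size)
      if (nrow(res) == 0) next
      res$cell_type <- ct
      res$direction <- dir
      res$namespace <- ns
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      set = character(), k = integer(), n = integer(), K = integer(),
      N = integer(), gene_ratio = numeric(), p = numeric(),
      p_adj = numeric(), significant = logical(), genes = character(),
      cell_type = character(), direction = character(), namespace = character()
    )
  }
  structure(out, class = c("al_enrichment", setdiff(class(out), "al_enrichment")))
}
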