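#' Assemble and validate a pipeline configuration
#'
#' Collects input-file paths and analysis parameters for [run_pipeline()].
#' All numeric tolerances must be positive, significance levels must lie in
#' (0, 1), and the seed must be a non-negative integer.
#'
#' @param beta,expression,panel,thresholds,annotation,gene_map,signature
#'   Paths to the input TSV/CSV tables (matrices stored features-as-rows).
#' @param gmt Optional named character vector of GMT file paths (one per
#'   namespace) for the enrichment stage.
#' @param al_method `"index"` or `"zscore"`.
#' @param al_index_cutoff Group cutoff for the index method (default 2).
#' @param dm_threshold Methylation-state beta-difference threshold.
#' @param state_p_threshold State-calling rank-sum significance level.
#' @param assoc_alpha BH-adjusted significance level for functional pairs.
#' @param enrich_alpha Adjusted significance level for enrichment.
#' @param mixture_tol,tca_tol EM / model-fit convergence tolerances.
#' @param refactor_k,refactor_t Reference-free component parameters.
#' @param c1_covariates Panel columns used as cell-level covariates.
#' @param c2_covariates Panel columns used as global covariates.
#' @param reference_samples Optional reference sample ids for quantile
#'   normalization.
#' @param write_tensors Whether to write the per-cell-type tensors (they
#'   are the largest outputs).
#' @param seed Random seed for the run.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(beta, expression, panel, thresholds, annotation,
                            gene_map, signature, gmt = NULL,
                            al_method = "index", al_index_cutoff = 2,
                            dm_threshold = 0.10, state_p_threshold = 0.05,
                            assoc_alpha = 0.05, enrich_alpha = 0.05,
                            mixture_tol = 1e-6, tca_tol = 1e-6,
                            refactor_k = 6, refactor_t = 500,
                            c1_covariates = c("sex", "age", "smoking"),
                            c2_covariates = "center",
                            reference_samples = NULL,
                            write_tensors = TRUE, seed = 1) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A candidate configuration list.
#' @export
validate_pipeline_config <- function(config) {
  if (!config$al_method %in% c("index", "zscore")) {
    ml_stop("al_method must be 'index' or 'zscore'")
  }
  for (f in c("assoc_alpha", "enrich_alpha", "state_p_threshold")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1) {
      ml_stop("%s must lie in (0, 1)", f)
    }
  }
  for (f in c("dm_threshold", "mixture_tol", "tca_tol")) {
    if (!is.numeric(config[[f]]) || config[[f]] <= 0) {
      ml_stop("%s must be positive", f)
    }
  }
  if (config$seed < 0 || config$seed != round(config$seed)) {
    ml_stop("seed must be a non-negative integer")
  }
  invisible(config)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; arguments passed via
#' `...` override keys in the file.
#'
#' @param path Path to a YAML configuration file.
#' @param ... Overrides.
#' @return A validated `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) ml_stop("config file not found: %s", path)
  keys <- yaml::read_yaml(path)
  overrides <- list(...)
  keys[names(overrides)] <- overrides
  do.call(pipeline_config, keys)
}

# one-hot / numeric covariate matrix from panel columns (no intercept; the
# proportion columns already span a constant, so factors drop one level)
build_covariates <- function(panel, vars) {
  if (length(vars) == 0) return(NULL)
  absent <- setdiff(vars, colnames(panel))
  if (length(absent) > 0) ml_stop("covariate '%s' not in panel", absent[1])
  cols <- list()
  for (v in vars) {
    x <- panel[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- as.numeric(scale(x))
    } else {
      lev <- sort(unique(as.character(x)))
      for (l in lev[-1]) {
        cols[[paste(v, l, sep = "_")]] <- as.numeric(x == l)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- panel$sample
  m
}

#' Run the full analysis on in-memory inputs
#'
#' The engine behind [run_pipeline()]: allostatic-load scoring and
#' grouping, methylation/expression QC, proportion estimation, tensor
#' deconvolution of both modalities, per-cell-type functional-pair
#' detection in both correlation modes, direction calling, summary, and
#' (when gene sets are supplied) over-representation analysis.
#'
#' @param inputs A list (or `"al_cohort"`) with elements `beta`, `expr`,
#'   `panel`, `thresholds`, `annotation`, `gene_map`, `signature`, and
#'   optionally `gene_sets` (named list of collections).
#' @param al_method,al_index_cutoff,dm_threshold,state_p_threshold,assoc_alpha,enrich_alpha,refactor_k,refactor_t,c1_covariates,c2_covariates,reference_samples
#'   See [pipeline_config()].
#' @param compute_refactor Whether to compute reference-free composition
#'   components (diagnostic output; not used as model covariates by
#'   default).
#' @return A list with all stage outputs (`al`, `sex_calls`, `retained`,
#'   `beta_qc`, `expr_qc`, `proportions`, `refactor`, `tca`,
#'   `meth_tensor`, `expr_tensor`, `pairs_by_cell_type`, `pairs`,
#'   `directions`, `summary`, `enrichment`).
#' @export
run_cohort_analysis <- function(inputs, al_method = "index",
                                al_index_cutoff = 2, dm_threshold = 0.10,
                                state_p_threshold = 0.05, assoc_alpha = 0.05,
                                enrich_alpha = 0.05, refactor_k = 6,
                                refactor_t = 500,
                                c1_covariates = c("sex", "age", "smoking"),
                                c2_covariates = "center",
                                reference_samples = NULL,
                                compute_refactor = TRUE) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      ml_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    ml_msg("stage %-12s done in %.1fs", name,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  beta <- inputs$beta
  expr <- inputs$expr
  panel <- tibble::as_tibble(inputs$panel)

  al <- stage("score", {
    scores <- if (al_method == "index") {
      al_index_score(panel, inputs$thresholds)
    } else {
      biom <- intersect(unique(inputs$thresholds$biomarker), colnames(panel))
      al_zscore(panel, biom)
    }
    al_assign_groups(scores, method = al_method,
                     index_cutoff = al_index_cutoff)
  })
  ml_msg("score: %d/%d samples high-AL",
         sum(al$group == "high", na.rm = TRUE), nrow(al))

  sex_calls <- stage("sex", infer_sex(beta, inputs$annotation))
  retained <- stage("sex_filter", {
    drop_sex_mismatches(sex_calls, setNames(panel$sex, panel$sample))
  })
  beta <- beta[, retained, drop = FALSE]
  expr <- expr[, retained, drop = FALSE]
  panel <- panel[panel$sample %in% retained, , drop = FALSE]
  al <- al[al$sample %in% retained, , drop = FALSE]
  groups <- setNames(al$group, al$sample)
  groups <- groups[!is.na(groups)]

  beta_qc <- stage("meth_qc", {
    b <- filter_probes(beta, inputs$annotation)
    quantile_normalize_stratified(b, inputs$annotation,
                                  reference_samples = reference_samples)
  })
  expr_qc <- stage("expr_qc", map_and_filter_genes(expr, inputs$gene_map))

  W <- stage("proportions", estimate_proportions(expr_qc, inputs$signature))
  refactor <- if (compute_refactor) {
    stage("refactor", {
      adj <- build_covariates(panel, intersect(c2_covariates, colnames(panel)))
      refactor_components(beta_qc, k = min(refactor_k, ncol(beta_qc) - 1),
                          t = refactor_t, adjust = adj)
    })
  }

  c1 <- build_covariates(panel, intersect(c1_covariates, colnames(panel)))
  c2 <- build_covariates(panel, intersect(c2_covariates, colnames(panel)))
  tca <- stage("tca", fit_tca(beta_qc, W, c1 = c1, c2 = c2))
  meth_tensor <- stage("meth_tensor",
                       tca_tensor(beta_qc, tca, W, c1 = c1, c2 = c2))
  expr_tensor <- stage("expr_tensor", purify_expression(expr_qc, W))

  pairs_by_ct <- stage("associate", {
    lapply(setNames(colnames(W), colnames(W)), function(ct) {
      associate_cell_type(
        tensor_slice(meth_tensor, ct), tensor_slice(expr_tensor, ct),
        groups, inputs$annotation, alpha = assoc_alpha,
        dm_threshold = dm_threshold, p_threshold = state_p_threshold,
        cell_type = ct
      )
    })
  })
  pairs <- stage("combine", {
    neg <- dplyr::bind_rows(lapply(pairs_by_ct, `[[`, "negative"))
    pos <- dplyr::bind_rows(lapply(pairs_by_ct, `[[`, "positive"))
    combine_modes(neg, pos)
  })
  directions <- stage("direction", direction_calls(pairs))
  smry <- stage("summary", summarize_results(pairs, directions))

  enrichment <- if (!is.null(inputs$gene_sets) && nrow(directions) > 0) {
    stage("enrich", {
      stratified_enrichment(directions, inputs$gene_sets,
                            universe = rownames(expr_qc),
                            alpha = enrich_alpha)
    })
  }

  list(al = al, sex_calls = sex_calls, retained = retained,
       beta_qc = beta_qc, expr_qc = expr_qc, proportions = W,
       refactor = refactor, tca = tca, meth_tensor = meth_tensor,
       expr_tensor = expr_tensor, pairs_by_cell_type = pairs_by_ct,
       pairs = pairs, directions = directions, summary = smry,
       enrichment = enrichment)
}

#' Run the pipeline from configured input files to a results directory
#'
#' Reads the configured input tables, runs [run_cohort_analysis()], and
#' writes every stage output to `out_dir` in order: AL scores and groups,
#' sex calls and retained samples, QC'd matrices, proportions,
#' reference-free components, per-cell-type tensors (optional),
#' per-cell-type per-mode functional pairs, the combined pair table,
#' direction calls, summary tables, a human-readable report, and (when
#' gene sets are configured) enrichment tables. Every stage logs its
#' input/output dimensions; any stage error aborts with the stage name.
#'
#' @param config A `"pipeline_config"` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [run_cohort_analysis()] result list.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logit <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    writeLines(line, log_con)
    ml_msg("%s", line)
  }

  logit("reading inputs")
  inputs <- list(
    beta = read_matrix(config$beta),
    expr = read_matrix(config$expression),
    panel = readr::read_tsv(config$panel, show_col_types = FALSE),
    thresholds = readr::read_tsv(config$thresholds, show_col_types = FALSE),
    annotation = readr::read_tsv(config$annotation, show_col_types = FALSE),
    gene_map = readr::read_tsv(config$gene_map, show_col_types = FALSE),
    signature = read_matrix(config$signature)
  )
  if (!is.null(config$gmt)) {
    inputs$gene_sets <- lapply(config$gmt, read_gmt)
    if (is.null(names(inputs$gene_sets))) {
      names(inputs$gene_sets) <- paste0("sets", seq_along(inputs$gene_sets))
    }
  }
  logit("beta %d x %d; expression %d x %d; panel %d samples",
        nrow(inputs$beta), ncol(inputs$beta),
        nrow(inputs$expr), ncol(inputs$expr), nrow(inputs$panel))

  res <- run_cohort_analysis(
    inputs,
    al_method = config$al_method, al_index_cutoff = config$al_index_cutoff,
    dm_threshold = config$dm_threshold,
    state_p_threshold = config$state_p_threshold,
    assoc_alpha = config$assoc_alpha, enrich_alpha = config$enrich_alpha,
    refactor_k = config$refactor_k, refactor_t = config$refactor_t,
    c1_covariates = config$c1_covariates,
    c2_covariates = config$c2_covariates,
    reference_samples = config$reference_samples
  )

  logit("writing outputs")
  readr::write_tsv(res$al, file.path(out_dir, "al_scores.tsv"))
  readr::write_tsv(res$sex_calls, file.path(out_dir, "sex_calls.tsv"))
  readr::write_tsv(tibble::tibble(sample = res$retained),
                   file.path(out_dir, "retained_samples.tsv"))
  write_matrix(res$beta_qc, file.path(out_dir, "beta_qc.tsv"),
               id_column = "cpg")
  write_matrix(res$expr_qc, file.path(out_dir, "expression_qc.tsv"),
               id_column = "gene")
  write_matrix(res$proportions, file.path(out_dir, "proportions.tsv"),
               id_column = "sample")
  if (!is.null(res$refactor)) {
    write_matrix(res$refactor$components,
                 file.path(out_dir, "refactor_components.tsv"),
                 id_column = "sample")
  }
  if (isTRUE(config$write_tensors)) {
    for (ct in colnames(res$proportions)) {
      write_matrix(tensor_slice(res$meth_tensor, ct),
                   file.path(out_dir, sprintf("tensor_methylation_%s.tsv", ct)),
                   id_column = "cpg")
      write_matrix(tensor_slice(res$expr_tensor, ct),
                   file.path(out_dir, sprintf("tensor_expression_%s.tsv", ct)),
                   id_column = "gene")
    }
  }
  for (ct in names(res$pairs_by_cell_type)) {
    for (m in names(res$pairs_by_cell_type[[ct]])) {
      readr::write_tsv(
        tibble::as_tibble(res$pairs_by_cell_type[[ct]][[m]]),
        file.path(out_dir, sprintf("pairs_%s_%s.tsv", ct, m))
      )
    }
  }
  readr::write_tsv(tibble::as_tibble(res$pairs),
                   file.path(out_dir, "pairs_combined.tsv"))
  readr::write_tsv(tibble::as_tibble(res$directions),
                   file.path(out_dir, "directions.tsv"))
  readr::write_tsv(res$summary$per_cell_type,
                   file.path(out_dir, "summary_per_cell_type.tsv"))
  readr::write_tsv(res$summary$global, file.path(out_dir, "summary_global.tsv"))
  readr::write_tsv(res$summary$shared_genes,
                   file.path(out_dir, "summary_shared_genes.tsv"))
  report <- utils::capture.output(print(res$summary))
  writeLines(report, file.path(out_dir, "report.txt"))
  if (!is.null(res$enrichment)) {
    readr::write_tsv(tibble::as_tibble(res$enrichment),
                     file.path(out_dir, "enrichment.tsv"))
  }
  logit("pipeline complete: %d pairs, %d direction calls",
        nrow(res$pairs), nrow(res$directions))
  invisible(res)
}
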