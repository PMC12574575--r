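# fixed latent biomarker panel used by the generator: plausible population
# means/SDs for the 14 markers of the clinical-cutoff AL index
.biomarker_params <- function() {
  tibble::tibble(
    biomarker = c("sbp", "dbp", "heart_rate", "glucose", "insulin", "bmi",
                  "whr", "cortisol", "hdl", "total_chol", "triglycerides",
                  "uric_acid", "ggt", "crp"),
    mean = c(118, 74, 66, 5.1, 7.5, 25.5, 0.9, 125, 1.5, 5.0, 1.0,
             320, 28, 2.2),
    sd = c(15, 9, 10, 0.7, 4.5, 4.5, 0.07, 70, 0.4, 1.0, 0.5, 80, 18, 2.5),
    risk_side = c(rep("above", 8), "below", rep("above", 5))
  )
}

#' Default planted functional-pair table
#'
#' Twenty CpG-gene pairs allocated across cell types in proportion to where
#' cell-type-resolved studies of allostatic load find differentially
#' methylated genes: dominated by CD8 T cells and neutrophils, with smaller
#' shares in B cells, CD4 T cells and monocytes, and essentially none in NK
#' cells. Modes lean about two-to-one toward negative (promoter-like)
#' correlation, abnormal states alternate hyper/hypo, and each pair affects
#' a 30% subset of the high-AL group with a 0.3 beta-unit methylation shift
#' coupled to a 2-SD expression shift.
#'
#' @param n_pairs Number of pairs (default 20).
#' @param cell_types Cell types to allocate over. With the default blood
#'   panel, allocation follows the weights above; otherwise the types are
#'   cycled round-robin.
#' @param effect Methylation effect size in beta units.
#' @param expr_shift Expression shift in within-cell-type SD units.
#' @param subset_fraction Fraction of high-AL samples affected.
#' @param modes,states Values cycled over the pairs.
#' @return A tibble with one row per planted pair.
#' @export
planted_pairs <- function(n_pairs = 20,
                          cell_types = c("CD8T", "CD4T", "B", "NK",
                                         "Neutro", "Mono"),
                          effect = 0.3, expr_shift = 2,
                          subset_fraction = 0.3,
                          modes = c("negative", "negative", "positive"),
                          states = c("hyper", "hypo")) {
  default_panel <- c("CD8T", "CD4T", "B", "NK", "Neutro", "Mono")
  ct <- if (identical(cell_types, default_panel)) {
    # DMG shares observed across blood cell types: CD8T and neutrophils
    # carry about two thirds, NK close to none
    weights <- c(CD8T = 0.37, CD4T = 0.10, B = 0.13, NK = 0.01,
                 Neutro = 0.30, Mono = 0.09)
    counts <- floor(weights * n_pairs)
    left <- n_pairs - sum(counts)
    if (left > 0) {
      top_up <- names(sort(weights * n_pairs - counts, decreasing = TRUE))
      counts[top_up[seq_len(left)]] <- counts[top_up[seq_len(left)]] + 1
    }
    rep(names(counts), counts)
  } else {
    rep_len(cell_types, n_pairs)
  }
  tibble::tibble(
    cell_type = ct,
    mode = rep_len(modes, n_pairs),
    state = rep_len(states, n_pairs),
    effect = effect,
    expr_shift = expr_shift,
    subset_fraction = subset_fraction
  )
}

#' Configuration for the synthetic-cohort generator
#'
#' Defaults describe the reference study design: 429 whole-blood samples of
#' which 126 are high-AL, six immune cell types mixed with Dirichlet
#' proportions dominated by neutrophils, 2,000 CpGs, 1,500 genes, a
#' 300-gene expression signature, and 20 planted CpG-gene pairs.
#'
#' @param n_samples,n_cpgs,n_genes,n_celltypes Cohort dimensions.
#' @param cell_types Cell-type names.
#' @param dirichlet_alpha Dirichlet concentration vector for the mixing
#'   proportions (length `n_celltypes`).
#' @param high_fraction Fraction of samples in the high-AL group.
#' @param n_signature_genes Genes given distinct per-cell-type expression.
#' @param discriminative_fraction Fraction of CpGs made cell-type
#'   discriminative.
#' @param gene_link_fraction Fraction of autosomal CpGs linked to a gene.
#' @param chrx_fraction,chry_fraction,blacklist_fraction Probe annotation
#'   composition.
#' @param unmapped_fraction Fraction of expression identifiers with no gene
#'   symbol (dropped during preprocessing).
#' @param meth_cell_sd Per-sample SD of cell-level methylation around the
#'   cell-type profile (beta units).
#' @param meth_noise_sd SD of additive Gaussian measurement noise on bulk
#'   methylation (truncated to \[0, 1\]).
#' @param expr_cell_sd Log-SD of per-sample cell-level expression noise.
#' @param expr_noise_sd Log-SD of multiplicative bulk expression noise.
#' @param pairs Planted-pair table (see [planted_pairs()]); zero rows for a
#'   null cohort.
#' @param sex_mismatch Number of samples whose reported sex is flipped.
#' @param seed Non-negative integer seed controlling all randomness.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 429, n_cpgs = 2000, n_genes = 1500,
                       n_celltypes = 6,
                       cell_types = c("CD8T", "CD4T", "B", "NK",
                                      "Neutro", "Mono"),
                       dirichlet_alpha = c(10, 8, 3, 2, 14, 5),
                       high_fraction = 126 / 429,
                       n_signature_genes = 300,
                       discriminative_fraction = 0.2,
                       gene_link_fraction = 0.5,
                       chrx_fraction = 0.04, chry_fraction = 0.01,
                       blacklist_fraction = 0.02,
                       unmapped_fraction = 0.05,
                       meth_cell_sd = 0.02, meth_noise_sd = 0.03,
                       expr_cell_sd = 0.15, expr_noise_sd = 0.1,
                       pairs = planted_pairs(cell_types = cell_types),
                       sex_mismatch = 0, seed = 7) {
  cfg <- list(
    n_samples = n_samples, n_cpgs = n_cpgs, n_genes = n_genes,
    n_celltypes = n_celltypes, cell_types = cell_types,
    dirichlet_alpha = dirichlet_alpha, high_fraction = high_fraction,
    n_signature_genes = n_signature_genes,
    discriminative_fraction = discriminative_fraction,
    gene_link_fraction = gene_link_fraction,
    chrx_fraction = chrx_fraction, chry_fraction = chry_fraction,
    blacklist_fraction = blacklist_fraction,
    unmapped_fraction = unmapped_fraction,
    meth_cell_sd = meth_cell_sd, meth_noise_sd = meth_noise_sd,
    expr_cell_sd = expr_cell_sd, expr_noise_sd = expr_noise_sd,
    pairs = tibble::as_tibble(pairs), sex_mismatch = sex_mismatch,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param config A `"sim_config"` candidate list.
#' @export
validate_sim_config <- function(config) {
  stopifnot(is.list(config))
  with(config, {
    if (length(cell_types) != n_celltypes ||
        length(dirichlet_alpha) != n_celltypes) {
      ml_stop("cell_types and dirichlet_alpha must have length n_celltypes")
    }
    if (any(dirichlet_alpha <= 0)) ml_stop("dirichlet_alpha must be positive")
    for (f in c("high_fraction", "discriminative_fraction",
                "gene_link_fraction")) {
      v <- config[[f]]
      if (!is.numeric(v) || v <= 0 || v >= 1) {
        ml_stop("%s must lie in (0, 1)", f)
      }
    }
    for (f in c("meth_cell_sd", "meth_noise_sd", "expr_cell_sd",
                "expr_noise_sd")) {
      if (config[[f]] < 0) ml_stop("%s must be non-negative", f)
    }
    if (seed < 0 || seed != round(seed)) {
      ml_stop("seed must be a non-negative integer")
    }
    if (nrow(pairs) > 0) {
      if (any(!pairs$cell_type %in% cell_types)) {
        ml_stop("planted pair references unknown cell type '%s'",
                setdiff(pairs$cell_type, cell_types)[1])
      }
      if (any(pairs$effect <= 0) || any(pairs$expr_shift <= 0)) {
        ml_stop("planted effect sizes must be positive")
      }
      if (any(pairs$subset_fraction <= 0 | pairs$subset_fraction >= 1)) {
        ml_stop("subset_fraction must lie in (0, 1)")
      }
      if (!all(pairs$mode %in% c("negative", "positive")) ||
          !all(pairs$state %in% c("hyper", "hypo"))) {
        ml_stop("planted pair mode/state outside vocabulary")
      }
    }
  })
  invisible(config)
}

#' Generate cell-type reference profiles
#'
#' Draws, per cell type, CpG methylation means from low (Beta(2,10)), mid
#' (Beta(5,5)) and high (Beta(10,2)) regimes with a configurable fraction
#' of cell-type-discriminative CpGs (between-cell-type spread > 0.3 by
#' construction), chrX probes with sex-dependent regimes (intermediate
#' methylation in females, predominantly low in males), log-normal
#' expression means with distinct per-cell-type signature-gene profiles,
#' the probe annotation, and the gene-identifier map.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_reference"`.
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  J <- config$n_cpgs
  H <- config$n_celltypes
  cts <- config$cell_types
  cpgs <- sprintf("cg%06d", seq_len(J))

  chrom_draw <- runif(J)
  chrom <- ifelse(
    chrom_draw < config$chrx_fraction, "chrX",
    ifelse(chrom_draw < config$chrx_fraction + config$chry_fraction, "chrY",
           paste0("chr", sample(1:22, J, replace = TRUE)))
  )
  stratum <- sample(c("typeII", "typeI_red", "typeI_green"), J,
                    replace = TRUE, prob = c(0.8, 0.1, 0.1))
  autosomal <- !chrom %in% c("chrX", "chrY")
  blacklist <- autosomal & runif(J) < config$blacklist_fraction

  regime <- sample(c("low", "mid", "high"), J, replace = TRUE,
                   prob = c(0.4, 0.2, 0.4))
  base_mean <- numeric(J)
  base_mean[regime == "low"] <- rbeta(sum(regime == "low"), 2, 10)
  base_mean[regime == "mid"] <- rbeta(sum(regime == "mid"), 5, 5)
  base_mean[regime == "high"] <- rbeta(sum(regime == "high"), 10, 2)

  meth <- matrix(0, J, H, dimnames = list(cpgs, cts))
  for (h in seq_len(H)) {
    meth[, h] <- clip01(base_mean + rnorm(J, 0, 0.01))
  }
  disc_pool <- which(autosomal & !blacklist)
  n_disc <- round(config$discriminative_fraction * J)
  disc <- sample(disc_pool, min(n_disc, length(disc_pool)))
  for (j in disc) {
    grp <- sample(c(TRUE, FALSE), H, replace = TRUE)
    if (all(grp) || all(!grp)) grp[sample(H, 1)] <- !grp[1]
    meth[j, grp] <- 0.70 + 0.25 * rbeta(sum(grp), 2, 2)
    meth[j, !grp] <- 0.05 + 0.25 * rbeta(sum(!grp), 2, 2)
  }
  # chrX: males predominantly unmethylated, some fully methylated probes;
  # females intermediate through X-inactivation
  x_idx <- which(chrom == "chrX")
  male_low <- runif(length(x_idx)) < 0.7
  male_x <- ifelse(male_low, rbeta(length(x_idx), 2, 12),
                   rbeta(length(x_idx), 12, 2))
  meth[x_idx, ] <- matrix(rep(male_x, H), ncol = H)
  female_chrx <- setNames(rbeta(length(x_idx), 20, 20), cpgs[x_idx])

  # expression reference: shared log-normal base, signature genes distinct
  G <- config$n_genes
  source_ids <- sprintf("ENSG%08d", seq_len(G))
  n_mapped <- G - round(config$unmapped_fraction * G)
  symbols <- c(sprintf("GENE%04d", seq_len(n_mapped)),
               rep(NA_character_, G - n_mapped))
  gene_map <- tibble::tibble(source_id = source_ids, symbol = symbols)
  analysis_names <- ifelse(is.na(symbols), source_ids, symbols)

  base_expr <- rlnorm(G, meanlog = log(100), sdlog = 1)
  expr <- matrix(0, G, H, dimnames = list(analysis_names, cts))
  for (h in seq_len(H)) {
    expr[, h] <- base_expr * exp(rnorm(G, 0, 0.1))
  }
  sig_idx <- sample(seq_len(n_mapped), min(config$n_signature_genes, n_mapped))
  for (h in seq_len(H)) {
    expr[sig_idx, h] <- base_expr[sig_idx] * exp(rnorm(length(sig_idx), 0, 1.2))
  }
  signature <- expr[sig_idx, , drop = FALSE]

  # CpG-gene links: autosomal, non-blacklisted, non-discriminative CpGs
  # linked to mapped, non-signature genes
  linkable_genes <- setdiff(analysis_names[seq_len(n_mapped)],
                            rownames(signature))
  link_pool <- setdiff(which(autosomal & !blacklist), disc)
  linked <- link_pool[runif(length(link_pool)) < config$gene_link_fraction]
  gene_col <- rep(NA_character_, J)
  gene_col[linked] <- sample(linkable_genes, length(linked), replace = TRUE)
  annotation <- tibble::tibble(
    cpg = cpgs, chrom = chrom, stratum = stratum,
    gene = gene_col, blacklist = blacklist
  )
  structure(
    list(meth_profiles = meth, female_chrx = female_chrx,
         expr_profiles = expr, annotation = annotation,
         gene_map = gene_map, signature = signature,
         discriminative = cpgs[disc], linked_cpgs = cpgs[linked]),
    class = "sim_reference"
  )
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# draw one sample's biomarker values so that exactly `k` markers fall
# strictly on the risk side of the sample's applicable cutoffs
.draw_biomarkers <- function(k, cutoffs, params) {
  at_risk <- rep(FALSE, nrow(params))
  if (k > 0) at_risk[sample(nrow(params), k)] <- TRUE
  off <- abs(rnorm(nrow(params), 0.6, 0.25)) + 0.02
  side <- ifelse(params$risk_side == "above", 1, -1)
  ifelse(at_risk,
         cutoffs + side * off * params$sd,
         cutoffs - side * off * params$sd)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces the full input bundle for the pipeline: bulk methylation (a
#' Dirichlet-proportion-weighted mixture of per-sample cell-type
#' methylomes plus truncated Gaussian noise), bulk expression (analogous,
#' with multiplicative log-normal noise), a 14-marker biomarker panel whose
#' dichotomized index crosses the group cutoff for the intended high-AL
#' fraction, the probe annotation, threshold table, gene-ID map and
#' signature matrix, and a truth table recording everything planted. Each
#' planted pair shifts the chosen CpG's cell-level methylation in a subset
#' of high-AL samples (sign per state) and couples an expression shift to
#' it (sign per mode and state) so the pair is detectable in the intended
#' correlation mode.
#'
#' @param config A [sim_config()].
#' @param reference Optional precomputed [generate_reference()] output.
#' @return A list of class `"al_cohort"` with elements `beta`, `expr`
#'   (bulk matrices), `panel`, `thresholds`, `annotation`, `gene_map`,
#'   `signature`, `truth`, and `config`.
#' @export
generate_cohort <- function(config, reference = NULL) {
  validate_sim_config(config)
  if (is.null(reference)) reference <- generate_reference(config)
  set.seed(config$seed + 1)
  n <- config$n_samples
  H <- config$n_celltypes
  cts <- config$cell_types
  samples <- sprintf("S%04d", seq_len(n))
  ann <- reference$annotation
  cpgs <- ann$cpg
  J <- length(cpgs)

  sex_true <- sample(c("male", "female"), n, replace = TRUE)
  mismatched <- character(0)
  sex_reported <- sex_true
  if (config$sex_mismatch > 0) {
    mismatched <- sample(samples, config$sex_mismatch)
    i <- match(mismatched, samples)
    sex_reported[i] <- ifelse(sex_true[i] == "male", "female", "male")
  }

  W <- .rdirichlet(n, config$dirichlet_alpha)
  dimnames(W) <- list(samples, cts)

  n_high <- round(config$high_fraction * n)
  high <- sample(samples, n_high)
  groups <- setNames(ifelse(samples %in% high, "high", "low"), samples)

  # cell-level methylation: profile + per-sample wobble; female chrX override
  z <- array(NA_real_, c(J, n, H), dimnames = list(cpgs, samples, cts))
  x_idx <- match(names(reference$female_chrx), cpgs)
  female <- sex_true == "female"
  for (h in seq_len(H)) {
    m <- matrix(reference$meth_profiles[, h], J, n)
    if (length(x_idx) > 0 && any(female)) {
      m[x_idx, female] <- matrix(reference$female_chrx, length(x_idx),
                                 sum(female))
    }
    z[, , h] <- clip01(m + rnorm(J * n, 0, config$meth_cell_sd))
  }

  # cell-level expression
  enames <- rownames(reference$expr_profiles)
  G <- length(enames)
  E <- array(NA_real_, c(G, n, H), dimnames = list(enames, samples, cts))
  for (h in seq_len(H)) {
    E[, , h] <- reference$expr_profiles[, h] *
      exp(matrix(rnorm(G * n, 0, config$expr_cell_sd), G, n))
  }

  # plant pairs
  pairs <- tibble::as_tibble(config$pairs)
  if (nrow(pairs) > 0) {
    if (!"cpg" %in% names(pairs)) {
      # a planted shift must fit inside [0, 1] at the target cell type's
      # baseline, otherwise truncation would erase the planted signal
      pairs$cpg <- NA_character_
      used <- character(0)
      for (p in seq_len(nrow(pairs))) {
        h <- match(pairs$cell_type[p], cts)
        base <- reference$meth_profiles[reference$linked_cpgs, h]
        ok <- if (pairs$state[p] == "hyper") {
          base + pairs$effect[p] <= 0.95
        } else {
          base - pairs$effect[p] >= 0.05
        }
        cand <- setdiff(reference$linked_cpgs[ok], used)
        # keep planted genes distinct so each pair has unambiguous truth
        cand_gene <- ann$gene[match(cand, ann$cpg)]
        cand <- cand[!cand_gene %in% ann$gene[match(used, ann$cpg)]]
        if (length(cand) == 0) {
          ml_stop("no linked CpG with headroom for planted pair %d", p)
        }
        pairs$cpg[p] <- sample(cand, 1)
        used <- c(used, pairs$cpg[p])
      }
      pairs$gene <- ann$gene[match(pairs$cpg, ann$cpg)]
    }
    if (any(pairs$gene %in% rownames(reference$signature))) {
      ml_stop("planted pair gene '%s' collides with a signature gene",
              intersect(pairs$gene, rownames(reference$signature))[1])
    }
    if (any(!pairs$cpg %in% cpgs) || any(!pairs$gene %in% enames)) {
      ml_stop("planted pair references unknown CpG or gene")
    }
    pairs$direction <- cpg_direction(pairs$state, pairs$mode)
    affected_list <- vector("list", nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      h <- match(pairs$cell_type[p], cts)
      aff <- sample(high, max(2, round(pairs$subset_fraction[p] * n_high)))
      affected_list[[p]] <- aff
      sgn <- if (pairs$state[p] == "hyper") 1 else -1
      z[pairs$cpg[p], aff, h] <- clip01(z[pairs$cpg[p], aff, h] +
                                          sgn * pairs$effect[p])
      esgn <- (if (pairs$mode[p] == "negative") -1 else 1) * sgn
      gvals <- E[pairs$gene[p], , h]
      E[pairs$gene[p], aff, h] <- pmax(0, gvals[aff] +
                                         esgn * pairs$expr_shift[p] * sd(gvals))
    }
    pairs$affected <- affected_list
  }

  # mix to bulk
  beta <- matrix(0, J, n, dimnames = list(cpgs, samples))
  for (h in seq_len(H)) {
    beta <- beta + t(t(z[, , h]) * W[, h])
  }
  beta <- clip01(beta + matrix(rnorm(J * n, 0, config$meth_noise_sd), J, n))

  bulk_expr <- matrix(0, G, n, dimnames = list(enames, samples))
  for (h in seq_len(H)) {
    bulk_expr <- bulk_expr + t(t(E[, , h]) * W[, h])
  }
  bulk_expr <- bulk_expr * exp(matrix(rnorm(G * n, 0, config$expr_noise_sd),
                                      G, n))
  # bulk expression table is keyed by source identifiers, as delivered by a
  # quantification pipeline; the gene-ID map restores symbols during QC
  rownames(bulk_expr) <- reference$gene_map$source_id

  # biomarker panel: high-AL samples get 3-6 risk markers, low-AL 0-2
  params <- .biomarker_params()
  thr_any <- params$mean + ifelse(params$risk_side == "above", 1, -1) * params$sd
  thresholds <- tibble::tibble(
    biomarker = params$biomarker, sex = "any",
    cutoff = thr_any, risk_side = params$risk_side
  )
  # sex-stratified cutoffs for HDL (clinical practice uses different
  # cutoffs per sex); generation uses the applicable cutoff per sample
  thresholds <- thresholds[thresholds$biomarker != "hdl", ]
  hdl <- params[params$biomarker == "hdl", ]
  thresholds <- dplyr::bind_rows(
    thresholds,
    tibble::tibble(biomarker = "hdl", sex = c("male", "female"),
                   cutoff = c(hdl$mean - hdl$sd, hdl$mean - 0.8 * hdl$sd),
                   risk_side = "below")
  )
  k_risk <- ifelse(groups == "high",
                   sample(3:6, n, replace = TRUE),
                   sample(0:2, n, replace = TRUE, prob = c(0.45, 0.35, 0.2)))
  biom <- matrix(NA_real_, n, nrow(params),
                 dimnames = list(samples, params$biomarker))
  cut_by_sex <- vapply(c("male", "female"), function(s) {
    vapply(params$biomarker, function(b) {
      .applicable_thresholds(thresholds, b, s)$cutoff
    }, 0)
  }, numeric(nrow(params)))
  for (i in seq_len(n)) {
    biom[i, ] <- .draw_biomarkers(k_risk[i], cut_by_sex[, sex_reported[i]],
                                  params)
  }
  panel <- tibble::tibble(
    sample = samples, sex = sex_reported,
    age = round(rnorm(n, 55, 15)),
    smoking = sample(c(0, 1), n, replace = TRUE, prob = c(0.78, 0.22)),
    center = sample(c("Lausanne", "Geneva", "Bern"), n, replace = TRUE,
                    prob = c(0.39, 0.47, 0.14)),
    family = paste0("F", ceiling(sample(seq_len(n)) / 2))
  )
  panel <- dplyr::bind_cols(panel, tibble::as_tibble(biom))

  truth <- list(
    proportions = W,
    meth_profiles = reference$meth_profiles,
    expr_profiles = reference$expr_profiles,
    cell_meth = new_cell_tensor(z, "methylation"),
    cell_expr = new_cell_tensor(E, "expression"),
    pairs = pairs,
    groups = groups,
    sex_true = setNames(sex_true, samples),
    mismatched = mismatched,
    k_risk = setNames(k_risk, samples)
  )
  structure(
    list(beta = beta, expr = bulk_expr, panel = panel,
         thresholds = thresholds, annotation = ann,
         gene_map = reference$gene_map, signature = reference$signature,
         truth = truth, config = config),
    class = "al_cohort"
  )
}

#' Generate a cohort with no planted pairs
#'
#' Identical to [generate_cohort()] but with an empty planted-pair table;
#' used for type-I-error evaluation.
#'
#' @param config A [sim_config()].
#' @return An `"al_cohort"` whose truth pair table has zero rows.
#' @export
null_cohort <- function(config) {
  config$pairs <- config$pairs[0, , drop = FALSE]
  generate_cohort(config)
}

#' @export
print.al_cohort <- function(x, ...) {
  cat(sprintf("<al_cohort> %d samples, %d CpGs, %d genes, %d cell types, %d planted pair(s)\n",
              ncol(x$beta), nrow(x$beta), nrow(x$expr),
              x$config$n_celltypes, nrow(x$truth$pairs)))
  invisible(x)
}

#' Write a synthetic cohort's input bundle to a directory
#'
#' Writes the bulk matrices, panel, thresholds, annotation, gene map and
#' signature as TSV files consumable by [run_pipeline()], plus the truth
#' tables (prefixed `truth_`) for recovery checks.
#'
#' @param cohort An `"al_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f))
  write_matrix(cohort$beta, file.path(dir, "beta.tsv"), id_column = "cpg")
  write_matrix(cohort$expr, file.path(dir, "expression.tsv"),
               id_column = "source_id")
  write_matrix(cohort$signature, file.path(dir, "signature.tsv"),
               id_column = "gene")
  w(cohort$panel, "panel.tsv")
  w(cohort$thresholds, "thresholds.tsv")
  w(cohort$annotation, "annotation.tsv")
  w(cohort$gene_map, "gene_map.tsv")
  write_matrix(cohort$truth$proportions, file.path(dir, "truth_proportions.tsv"),
               id_column = "sample")
  truth_pairs <- cohort$truth$pairs
  if (nrow(truth_pairs) > 0 && !is.null(truth_pairs$affected)) {
    truth_pairs$affected <- vapply(truth_pairs$affected, paste,
                                   "", collapse = ",")
  }
  w(truth_pairs, "truth_pairs.tsv")
  w(tibble::tibble(sample = names(cohort$truth$groups),
                   group = unname(cohort$truth$groups)), "truth_groups.tsv")
  invisible(dir)
}
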