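test_that("configuration invariants are enforced", {
  expect_error(sim_config(high_fraction = 1.2), "high_fraction")
  expect_error(sim_config(seed = -1), "seed")
  expect_error(sim_config(dirichlet_alpha = c(1, 1)), "length")
  bad_pairs <- planted_pairs(2)
  bad_pairs$effect <- -0.3
  expect_error(sim_config(pairs = bad_pairs), "positive")
  bad_ct <- planted_pairs(2)
  bad_ct$cell_type <- "Platelet"
  expect_error(sim_config(pairs = bad_ct), "Platelet")
})

test_that("reference profiles are valid and discriminative where promised", {
  cfg <- sim_config(n_samples = 20, n_cpgs = 300, n_genes = 100,
                    n_signature_genes = 30, pairs = planted_pairs(0),
                    seed = 71)
  ref <- generate_reference(cfg)
  expect_true(all(ref$meth_profiles >= 0 & ref$meth_profiles <= 1))
  spreads <- apply(ref$meth_profiles[ref$discriminative, , drop = FALSE], 1L,
                   function(x) max(x) - min(x))
  expect_true(all(spreads > 0.3))
  expect_true(all(ref$expr_profiles >= 0))
  # same seed regenerates identical profiles
  ref2 <- generate_reference(cfg)
  expect_identical(ref$meth_profiles, ref2$meth_profiles)
  expect_identical(ref$expr_profiles, ref2$expr_profiles)
})

test_that("bulk methylation is the exact mixture at zero noise", {
  cfg <- sim_config(n_samples = 25, n_cpgs = 120, n_genes = 80,
                    n_signature_genes = 20, meth_cell_sd = 0.02,
                    meth_noise_sd = 0, expr_noise_sd = 0,
                    pairs = planted_pairs(0), seed = 72)
  coh <- generate_cohort(cfg)
  z <- coh$truth$cell_meth
  W <- coh$truth$proportions
  recon <- matrix(0, nrow(coh$beta), ncol(coh$beta))
  for (h in seq_len(dim(z)[3])) {
    recon <- recon + t(t(z[, , h]) * W[, h])
  }
  expect_lt(max(abs(recon - coh$beta)), 1e-12)
})

test_that("a single cell type at zero noise passes the bulk through", {
  cfg <- sim_config(n_samples = 15, n_cpgs = 60, n_genes = 50,
                    n_signature_genes = 15, n_celltypes = 1,
                    cell_types = "only", dirichlet_alpha = 5,
                    meth_noise_sd = 0, pairs = planted_pairs(0), seed = 73)
  coh <- generate_cohort(cfg)
  expect_lt(max(abs(coh$beta - coh$truth$cell_meth[, , 1])), 1e-12)
  expect_true(all(coh$truth$proportions == 1))
})

test_that("Dirichlet proportions have the intended mean composition", {
  cfg <- sim_config(n_cpgs = 60, n_genes = 50, n_signature_genes = 15,
                    pairs = planted_pairs(0), seed = 74)
  coh <- generate_cohort(cfg)   # default 429 samples
  W <- coh$truth$proportions
  expect_identical(nrow(W), 429L)
  expect_true(all(W >= 0))
  expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
  expected <- cfg$dirichlet_alpha / sum(cfg$dirichlet_alpha)
  expect_lt(max(abs(colMeans(W) - expected)), 0.03)
})

test_that("planted pairs are recorded with valid coordinates and real shifts", {
  cfg <- sim_config(n_samples = 150, n_cpgs = 500, n_genes = 300,
                    n_signature_genes = 50, seed = 75)
  coh <- generate_cohort(cfg)
  pairs <- coh$truth$pairs
  expect_identical(nrow(pairs), 20L)
  expect_true(all(pairs$cpg %in% coh$annotation$cpg))
  expect_true(all(pairs$gene %in% rownames(coh$truth$expr_profiles)))
  expect_false(any(pairs$gene %in% rownames(coh$signature)))
  expect_true(all(pairs$cell_type %in% cfg$cell_types))
  groups <- coh$truth$groups
  for (p in seq_len(nrow(pairs))) {
    aff <- pairs$affected[[p]]
    expect_true(all(groups[aff] == "high"))
    h <- pairs$cell_type[p]
    meth <- tensor_slice(coh$truth$cell_meth, h)[pairs$cpg[p], ]
    others <- setdiff(names(groups), aff)
    dm <- mean(meth[aff]) - mean(meth[others])
    if (pairs$state[p] == "hyper") expect_gt(dm, 0.2) else expect_lt(dm, -0.2)
    expr <- tensor_slice(coh$truth$cell_expr, h)[pairs$gene[p], ]
    de <- mean(expr[aff]) - mean(expr[others])
    expected_sign <- (if (pairs$mode[p] == "negative") -1 else 1) *
      (if (pairs$state[p] == "hyper") 1 else -1)
    expect_identical(sign(de), expected_sign)
  }
})

test_that("null cohorts carry no planted structure", {
  cfg <- sim_config(n_samples = 40, n_cpgs = 100, n_genes = 80,
                    n_signature_genes = 20, seed = 76)
  coh <- null_cohort(cfg)
  expect_identical(nrow(coh$truth$pairs), 0L)
})

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_samples = 30, n_cpgs = 100, n_genes = 80,
                    n_signature_genes = 20, pairs = planted_pairs(2), seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$expr, b$expr)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$pairs$cpg, b$truth$pairs$cpg)
})

test_that("the dichotomized index reproduces the intended AL groups", {
  cfg <- sim_config(n_samples = 200, n_cpgs = 60, n_genes = 50,
                    n_signature_genes = 15, pairs = planted_pairs(0),
                    seed = 78)
  coh <- generate_cohort(cfg)
  scores <- al_index_score(coh$panel, coh$thresholds)
  groups <- al_assign_groups(scores, "index")
  expect_identical(unname(setNames(groups$group, groups$sample)[
    names(coh$truth$groups)]), unname(coh$truth$groups))
  # scores equal the planted risk-marker counts
  expect_identical(groups$score[match(names(coh$truth$k_risk),
                                      groups$sample)],
                   as.integer(coh$truth$k_risk))
})
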