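test_that("a constant vector yields a single component at its mean", {
  fit <- fit_beta_mixture(rep(0.5, 20))
  expect_identical(fit$k, 1L)
  expect_equal(fit$means, 0.5, tolerance = 1e-6)
  expect_error(fit_beta_mixture(runif(5)), "at least 10")
  expect_error(fit_beta_mixture(c(runif(10), 1.5)), "0, 1")
})

test_that("a single beta population is mostly called unimodal", {
  ones <- 0
  for (seed in 1:50) {
    set.seed(seed)
    fit <- fit_beta_mixture(rbeta(200, 20, 5))
    if (fit$k == 1L) ones <- ones + 1
  }
  expect_gte(ones, 45)  # >= 90% of 50 seeds
})

test_that("a balanced two-component mixture is resolved with accurate means", {
  set.seed(77)
  x <- c(rbeta(100, 25, 4), rbeta(100, 4, 25))
  fit <- fit_beta_mixture(x)
  expect_identical(fit$k, 2L)
  # analytic component means: 4/29 and 25/29
  expect_lt(abs(fit$means[1] - 4 / 29), 0.05)
  expect_lt(abs(fit$means[2] - 25 / 29), 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
  expect_true(!is.unsorted(fit$means))
})

test_that("the EM log-likelihood is non-decreasing for random inputs", {
  set.seed(88)
  for (rep in 1:20) {
    x <- rbeta(120, runif(1, 0.8, 20), runif(1, 0.8, 20))
    fit <- fit_beta_mixture(x)
    if (length(fit$trace) > 1) {
      expect_true(all(diff(fit$trace) >= -1e-8))
    }
  }
})

test_that("state calling is null when groups share a distribution", {
  set.seed(101)
  high <- setNames(rbeta(120, 10, 10), paste0("h", 1:120))
  low <- rbeta(300, 10, 10)
  call <- call_states(high, low)
  expect_identical(call$prev_hypo, 0)
  expect_identical(call$prev_hyper, 0)
  expect_true(all(call$states == "normal"))
})

test_that("a planted hypermethylated subset is called with its prevalence", {
  set.seed(102)
  n_high <- 120
  shifted <- seq_len(round(0.3 * n_high))
  base <- rbeta(n_high, 30, 30)            # mean 0.5
  base[shifted] <- methylload:::clip01(base[shifted] + 0.3)
  high <- setNames(base, paste0("h", seq_len(n_high)))
  low <- rbeta(300, 30, 30)
  call <- call_states(high, low)
  expect_lt(abs(call$prev_hyper - 0.3), 0.1)
  expect_identical(call$prev_hypo, 0)
})

test_that("planted hypo and hyper subsets make a dual candidate", {
  set.seed(103)
  n_high <- 120
  base <- rbeta(n_high, 30, 30)
  up <- 1:30
  dn <- 31:60
  base[up] <- methylload:::clip01(base[up] + 0.3)
  base[dn] <- methylload:::clip01(base[dn] - 0.3)
  high <- setNames(base, paste0("h", seq_len(n_high)))
  low <- rbeta(300, 30, 30)
  call <- call_states(high, low)
  expect_gt(call$prev_hyper, 0)
  expect_gt(call$prev_hypo, 0)
})

test_that("pair_test emits a hyper pair when expression is depressed", {
  set.seed(111)
  states <- setNames(rep("normal", 100), paste0("h", 1:100))
  states[1:30] <- "hyper"
  call <- make_state_call(states)
  expr_high <- setNames(rnorm(100, 10, 1), names(states))
  expr_high[1:30] <- rnorm(30, 8, 1)      # 2 SD below baseline
  expr_low <- rnorm(200, 10, 1)
  res <- pair_test(call, expr_high, expr_low, mode = "negative")
  expect_identical(nrow(res), 1L)
  expect_identical(res$state, "hyper")
  # the same configuration carries no positive-mode signal
  res_pos <- pair_test(call, expr_high, expr_low, mode = "positive")
  expect_identical(nrow(res_pos), 0L)
})

test_that("pair_test maintains its nominal type-I error on null expression", {
  set.seed(112)
  states <- setNames(rep("normal", 100), paste0("h", 1:100))
  states[1:30] <- "hyper"
  call <- make_state_call(states)
  hits <- 0
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    expr_high <- setNames(rnorm(100), names(states))
    expr_low <- rnorm(200)
    res <- pair_test(call, expr_high, expr_low, mode = "negative",
                     alpha = 0.05)
    if (nrow(res) > 0) hits <- hits + 1
  }
  expect_lt(abs(hits / n_rep - 0.05), 0.025)  # within 50% of nominal
})

test_that("dual pairs require both subsets to pass in the tested direction", {
  set.seed(113)
  states <- setNames(rep("normal", 120), paste0("h", 1:120))
  states[1:30] <- "hypo"
  states[31:60] <- "hyper"
  call <- make_state_call(states)
  expr_high <- setNames(rnorm(120, 10, 1), names(states))
  expr_high[1:30] <- rnorm(30, 8, 1)       # hypo subset low
  expr_high[31:60] <- rnorm(30, 12, 1)     # hyper subset high
  expr_low <- rnorm(200, 10, 1)
  res <- pair_test(call, expr_high, expr_low, mode = "positive")
  expect_identical(res$state, "dual")
})

test_that("run_mode finds planted pairs in the right mode only", {
  cfg <- sim_config(n_samples = 150, n_cpgs = 500, n_genes = 300,
                    n_signature_genes = 50,
                    pairs = planted_pairs(n_pairs = 4,
                                          cell_types = "Neutro",
                                          modes = "positive"),
                    seed = 42)
  coh <- generate_cohort(cfg)
  meth <- tensor_slice(coh$truth$cell_meth, "Neutro")
  expr <- tensor_slice(coh$truth$cell_expr, "Neutro")
  pos <- run_mode(meth, expr, coh$truth$groups, coh$annotation,
                  mode = "positive", cell_type = "Neutro")
  neg <- run_mode(meth, expr, coh$truth$groups, coh$annotation,
                  mode = "negative", cell_type = "Neutro")
  expect_gte(sum(coh$truth$pairs$cpg %in% pos$cpg), 3)
  expect_false(any(coh$truth$pairs$cpg %in% neg$cpg))
})

test_that("mode concatenation keeps counts and the source mode", {
  mk <- function(n, mode, cpg_offset = 0) {
    tibble::tibble(
      cpg = sprintf("cg%05d", cpg_offset + seq_len(n)),
      gene = sprintf("G%04d", seq_len(n)),
      cell_type = "CD8T", mode = mode,
      state = "hyper", prev_hypo = 0, prev_hyper = 0.3,
      p_raw = runif(n, 0, 0.01), p_adj = runif(n, 0, 0.05)
    )
  }
  neg <- mk(173, "negative")
  pos <- mk(90, "positive", cpg_offset = 1000)
  # some pairs share a CpG: 163 and 87 unique CpGs in disjoint mode sets
  neg$cpg[164:173] <- neg$cpg[1:10]
  pos$cpg[88:90] <- pos$cpg[1:3]
  combined <- combine_modes(neg, pos)
  expect_identical(nrow(combined), 263L)
  expect_identical(attr(combined, "summary")$n_cpgs, 250L)
  expect_identical(sum(combined$mode == "negative"), 173L)

  only_neg <- combine_modes(neg, neg[0, ])
  expect_identical(nrow(only_neg), 173L)
})

test_that("the step-up adjustment matches the reference construction", {
  set.seed(120)
  for (rep in 1:10) {
    p <- runif(sample(5:50, 1))
    adj <- p.adjust(p, method = "BH")
    expect_equal(adj, bh_reference(p), tolerance = 1e-12)
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})
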