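.mk_signature <- function(G = 30, H = 3, seed = 1) {
  set.seed(seed)
  matrix(rlnorm(G * H, log(50), 1), G, H,
         dimnames = list(sprintf("g%03d", seq_len(G)),
                         paste0("ct", seq_len(H))))
}

test_that("pure and exact two-way mixtures are recovered exactly", {
  S <- .mk_signature()
  bulk <- cbind(pure = S[, 1], half = 0.5 * S[, 1] + 0.5 * S[, 2])
  W <- estimate_proportions(bulk, S)
  expect_equal(unname(W["pure", ]), c(1, 0, 0), tolerance = 1e-8)
  expect_equal(unname(W["half", ]), c(0.5, 0.5, 0), tolerance = 1e-8)
  expect_true(all(abs(rowSums(W) - 1) < 1e-8))
})

test_that("NNLS proportions match an exhaustive simplex grid search", {
  S <- .mk_signature(G = 15, seed = 3)
  set.seed(4)
  for (rep in 1:3) {
    w_true <- as.vector(methylload:::.rdirichlet(1, c(4, 2, 3)))
    x <- as.vector(S %*% w_true)
    bulk <- matrix(x, ncol = 1, dimnames = list(rownames(S), "s1"))
    w_hat <- estimate_proportions(bulk, S)[1, ]
    w_grid <- grid_search_proportions(S, x)
    expect_lt(max(abs(w_hat - w_grid)), 0.0100001)
  }
})

test_that("proportions are recovered under multiplicative noise", {
  set.seed(8)
  S <- .mk_signature(G = 60, H = 6, seed = 8)
  alpha <- c(10, 8, 3, 2, 14, 5)
  W_true <- methylload:::.rdirichlet(60, alpha)
  bulk <- S %*% t(W_true) * exp(matrix(rnorm(60 * 60, 0, 0.1), 60, 60))
  colnames(bulk) <- sprintf("S%03d", 1:60)
  W <- estimate_proportions(bulk, S)
  mae <- colMeans(abs(W - W_true))
  expect_true(all(mae < 0.05))
  expect_error(estimate_proportions(bulk[1:5, ], S[1:5, ]), ">= 10")
})

test_that("expression purification recovers shared profiles on noiseless data", {
  set.seed(12)
  G <- 10; n <- 20; H <- 3
  profiles <- matrix(rlnorm(G * H, log(20), 0.5), G, H)
  W <- methylload:::.rdirichlet(n, c(5, 3, 2))
  dimnames(W) <- list(sprintf("S%03d", 1:n), paste0("ct", 1:H))
  bulk <- profiles %*% t(W)
  dimnames(bulk) <- list(sprintf("g%03d", 1:G), rownames(W))
  tensor <- purify_expression(bulk, W)
  for (h in 1:H) {
    slice <- tensor_slice(tensor, h)
    expect_lt(max(abs(slice - profiles[, h])), 1e-6)
  }
  # mixture of slices reconstitutes the bulk signal
  recon <- sapply(seq_len(n), function(i) {
    rowSums(sapply(1:H, function(h) W[i, h] * tensor[, i, h]))
  })
  expect_lt(max(abs(recon - bulk)), 1e-6)
})

test_that("a zero-proportion sample gets the shared profile, no residual", {
  set.seed(13)
  G <- 8; n <- 15; H <- 3
  profiles <- matrix(rlnorm(G * H, log(20), 0.5), G, H)
  W <- methylload:::.rdirichlet(n, c(5, 3, 2))
  W[1, ] <- c(0, 0.6, 0.4)
  dimnames(W) <- list(sprintf("S%03d", 1:n), paste0("ct", 1:H))
  bulk <- profiles %*% t(W) * exp(matrix(rnorm(G * n, 0, 0.05), G, n))
  dimnames(bulk) <- list(sprintf("g%03d", 1:G), rownames(W))
  tensor <- purify_expression(bulk, W)
  g_est <- sapply(seq_len(G), function(g) {
    pracma::lsqnonneg(W, bulk[g, ])$x[1]
  })
  expect_equal(unname(tensor[, 1, 1]), unname(g_est), tolerance = 1e-8)
})

test_that("a planted sample-specific up-shift is recovered in direction", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(100 + seed)
    G <- 30; n <- 50; H <- 3
    profiles <- matrix(rlnorm(G * H, log(30), 0.4), G, H)
    repeat {
      W <- methylload:::.rdirichlet(n, c(10, 4, 4))
      if (W[1, 1] >= 0.4) break
    }
    dimnames(W) <- list(sprintf("S%03d", 1:n), paste0("ct", 1:H))
    E <- array(rep(profiles, n), c(G, H, n))
    E <- aperm(E, c(1, 3, 2))
    E[5, 1, 1] <- 2 * E[5, 1, 1]  # two-fold up-shift, sample 1, cell type 1
    bulk <- sapply(seq_len(n), function(i) {
      as.vector(E[, i, ] %*% W[i, ]) * exp(rnorm(G, 0, 0.05))
    })
    dimnames(bulk) <- list(sprintf("g%03d", 1:G), rownames(W))
    tensor <- purify_expression(bulk, W)
    slice <- tensor_slice(tensor, 1)
    if (slice[5, 1] > median(slice[5, -1])) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("reference-free components find exact low-rank sites and covary with truth", {
  set.seed(21)
  J <- 120; n <- 40; H <- 3
  mu <- matrix(runif(J * H), J, H)
  W <- methylload:::.rdirichlet(n, c(4, 3, 3))
  beta <- mu %*% t(W)
  dimnames(beta) <- list(sprintf("cg%04d", 1:J), sprintf("S%03d", 1:n))
  rc <- refactor_components(beta, k = H, t = 50)
  expect_lt(max(rc$site_scores[rc$sites]), 1e-8)
  expect_equal(dim(rc$components), c(n, H))
  # components are orthogonal
  cross <- crossprod(rc$components)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-6)
  expect_error(refactor_components(beta, k = n), "smaller")
})

test_that("components track cell composition in realistic mixtures", {
  cfg <- sim_config(n_samples = 80, n_cpgs = 500, n_genes = 80,
                    n_signature_genes = 30, discriminative_fraction = 0.4,
                    pairs = planted_pairs(0), seed = 23)
  coh <- generate_cohort(cfg)
  beta <- filter_probes(coh$beta, coh$annotation)
  rc <- refactor_components(beta, k = 6, t = 200)
  cc <- stats::cancor(rc$components[, 1:2],
                      coh$truth$proportions[rownames(rc$components), ])
  expect_gt(cc$cor[1], 0.9)
  expect_gt(cc$cor[2], 0.9)
})

test_that("permuting samples permutes component rows identically", {
  set.seed(25)
  beta <- rand_beta(80, 20)
  rc <- refactor_components(beta, k = 3, t = 40)
  perm <- sample(ncol(beta))
  rc_p <- refactor_components(beta[, perm], k = 3, t = 40)
  expect_identical(rc$sites, rc_p$sites)
  expect_equal(abs(rc_p$components[colnames(beta), ]), abs(rc$components),
               tolerance = 1e-8)
})

test_that("the model collapses to the sample mean for a single cell type", {
  set.seed(31)
  beta <- rand_beta(5, 40)
  W <- matrix(1, 40, 1, dimnames = list(colnames(beta), "only"))
  fit <- fit_tca(beta, W)
  expect_equal(unname(fit$mu[, 1]), unname(rowMeans(beta)), tolerance = 1e-8)
})

test_that("planted two-cell-type means are recovered on noiseless data", {
  set.seed(32)
  n <- 100
  w1 <- seq(0.1, 0.9, length.out = n)
  W <- cbind(a = w1, b = 1 - w1)
  rownames(W) <- sprintf("S%03d", 1:n)
  beta <- matrix(rep(0.2 * w1 + 0.8 * (1 - w1), 3), 3, n, byrow = TRUE)
  dimnames(beta) <- list(paste0("cg", 1:3), rownames(W))
  fit <- fit_tca(beta, W)
  expect_lt(max(abs(fit$mu[, "a"] - 0.2)), 0.02)
  expect_lt(max(abs(fit$mu[, "b"] - 0.8)), 0.02)
})

test_that("null covariate effects are estimated near zero", {
  set.seed(33)
  n <- 120; J <- 200
  W <- methylload:::.rdirichlet(n, c(5, 5))
  dimnames(W) <- list(sprintf("S%03d", 1:n), c("a", "b"))
  mu <- cbind(runif(J, 0.2, 0.8), runif(J, 0.2, 0.8))
  beta <- mu %*% t(W) + matrix(rnorm(J * n, 0, 0.02), J, n)
  beta <- methylload:::clip01(beta)
  dimnames(beta) <- list(sprintf("cg%04d", 1:J), rownames(W))
  c1 <- matrix(rnorm(n), n, 1, dimnames = list(rownames(W), "cov"))
  fit <- fit_tca(beta, W, c1 = c1)
  prop_small <- mean(abs(fit$gamma) < 0.05)
  expect_gte(prop_small, 0.95)
})

test_that("the fit log-likelihood never decreases across iterations", {
  set.seed(34)
  n <- 60; J <- 10
  W <- methylload:::.rdirichlet(n, c(4, 3, 3))
  dimnames(W) <- list(sprintf("S%03d", 1:n), c("a", "b", "c"))
  mu <- matrix(runif(J * 3, 0.1, 0.9), J, 3)
  beta <- methylload:::clip01(mu %*% t(W) + matrix(rnorm(J * n, 0, 0.05), J, n))
  dimnames(beta) <- list(sprintf("cg%04d", 1:J), rownames(W))
  fit <- fit_tca(beta, W, keep_trace = TRUE)
  for (tr in fit$trace) {
    if (length(tr) > 1) expect_true(all(diff(tr) >= -1e-7))
  }
})

test_that("tensor limits: tau to zero reproduces x; sigma zero gives means", {
  n <- 20
  x <- seq(0.05, 0.95, length.out = n)
  beta <- matrix(x, 1, n, dimnames = list("cg1", sprintf("S%03d", 1:n)))
  W <- matrix(1, n, 1, dimnames = list(colnames(beta), "only"))
  model <- structure(list(
    mu = matrix(0.5, 1, 1, dimnames = list("cg1", "only")),
    sigma = matrix(0.1, 1, 1, dimnames = list("cg1", "only")),
    tau = c(cg1 = 1e-9), gamma = NULL, delta = NULL,
    cell_types = "only"), class = "tca_model")
  tensor <- tca_tensor(beta, model, W)
  expect_equal(unname(tensor[1, , 1]), x, tolerance = 1e-6)

  model$sigma[] <- 0
  model$tau <- c(cg1 = 0.05)
  tensor0 <- tca_tensor(beta, model, W)
  expect_true(all(tensor0[1, , 1] == 0.5))
})

test_that("the weighted tensor reconstitutes the bulk signal", {
  set.seed(36)
  n <- 80; J <- 30
  W <- methylload:::.rdirichlet(n, c(5, 3, 2))
  dimnames(W) <- list(sprintf("S%03d", 1:n), c("a", "b", "c"))
  mu <- matrix(runif(J * 3, 0.1, 0.9), J, 3)
  beta <- methylload:::clip01(mu %*% t(W) + matrix(rnorm(J * n, 0, 0.03), J, n))
  dimnames(beta) <- list(sprintf("cg%04d", 1:J), rownames(W))
  fit <- fit_tca(beta, W)
  tensor <- tca_tensor(beta, fit, W)
  recon <- sapply(seq_len(n), function(i) {
    rowSums(sapply(1:3, function(h) W[i, h] * tensor[, i, h]))
  })
  tol <- 3 * (fit$tau + 0.01)
  frac_ok <- mean(abs(recon - beta) <= matrix(tol, J, n))
  expect_gte(frac_ok, 0.99)
})
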