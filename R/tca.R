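#' Fit a tensor-composition model of bulk methylation
#'
#' Models each CpG's bulk beta value as a cell-proportion-weighted mixture
#' of cell-type-level means plus covariate effects:
#' \deqn{x_{ij} \sim N\!\Big(\sum_h w_{ih}(\mu_{hj} + c^{(1)}_i\gamma_{hj})
#'   + c^{(2)}_i\delta_j,\; \sum_h w_{ih}^2\sigma_{hj}^2 + \tau_j^2\Big)}
#' where `c1` covariates act at the cell level (one effect per cell type)
#' and `c2` covariates act globally on the bulk signal. Each CpG is fitted
#' independently by alternating exact generalized least squares on the mean
#' parameters with numerical likelihood maximization over the variance
#' parameters, until the relative log-likelihood change falls below `tol`.
#' The per-iteration log-likelihood is non-decreasing by construction.
#'
#' @param beta CpG-by-sample matrix of bulk beta values.
#' @param proportions Sample-by-cell-type proportion matrix.
#' @param c1 Optional sample-by-covariate numeric matrix of cell-level
#'   covariates (categoricals must be one-hot encoded).
#' @param c2 Optional sample-by-covariate numeric matrix of global
#'   covariates.
#' @param max_iter Maximum alternations per CpG (default 100).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param keep_trace If `TRUE`, store the per-iteration log-likelihood trace
#'   of every CpG (for diagnostics).
#' @return An object of class `"tca_model"`: a list with matrices `mu`
#'   (CpG x cell type, clipped to \[0, 1\]), `sigma`, vector `tau`, arrays
#'   `gamma` (CpG x cell type x c1 covariate) and `delta` (CpG x c2
#'   covariate) when covariates are supplied, per-CpG `loglik`, `n_iter`,
#'   and `converged`.
#' @export
fit_tca <- function(beta, proportions, c1 = NULL, c2 = NULL,
                    max_iter = 100, tol = 1e-6, keep_trace = FALSE) {
  check_matrix(beta, "beta")
  check_proportions(proportions, colnames(beta))
  W <- proportions[colnames(beta), , drop = FALSE]
  H <- ncol(W)
  n <- nrow(W)
  if (!is.null(c1)) c1 <- as.matrix(c1)[colnames(beta), , drop = FALSE]
  if (!is.null(c2)) c2 <- as.matrix(c2)[colnames(beta), , drop = FALSE]
  p1 <- if (is.null(c1)) 0L else ncol(c1)
  p2 <- if (is.null(c2)) 0L else ncol(c2)

  # design for the mean: [W | w_h * c1 blocks | c2]
  X <- W
  if (p1 > 0) {
    for (h in seq_len(H)) X <- cbind(X, W[, h] * c1)
  }
  if (p2 > 0) X <- cbind(X, c2)
  W2 <- W^2
  J <- nrow(beta)

  mu <- matrix(NA_real_, J, H, dimnames = list(rownames(beta), colnames(W)))
  sigma <- mu
  tau <- setNames(numeric(J), rownames(beta))
  gamma <- if (p1 > 0) {
    array(NA_real_, c(J, H, p1),
          dimnames = list(rownames(beta), colnames(W), colnames(c1)))
  }
  delta <- if (p2 > 0) {
    matrix(NA_real_, J, p2, dimnames = list(rownames(beta), colnames(c2)))
  }
  loglik <- setNames(numeric(J), rownames(beta))
  n_iter <- setNames(integer(J), rownames(beta))
  converged <- setNames(logical(J), rownames(beta))
  traces <- if (keep_trace) vector("list", J)

  ll_const <- -0.5 * n * log(2 * pi)
  nll_var <- function(s, r2) {
    v <- as.vector(W2 %*% s[seq_len(H)]^2) + s[H + 1L]^2
    0.5 * sum(log(v) + r2 / v)
  }

  for (j in seq_len(J)) {
    y <- beta[j, ]
    b <- qr.solve(X, y)
    r <- y - as.vector(X %*% b)
    s2 <- max(mean(r^2), 1e-8)
    svec <- c(rep(sqrt(s2 / 2), H), sqrt(s2 / 2))
    ll_prev <- -Inf
    trace_j <- numeric(0)
    it <- 0L
    conv <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      v <- as.vector(W2 %*% svec[seq_len(H)]^2) + svec[H + 1L]^2
      sw <- 1 / sqrt(v)
      b <- qr.solve(X * sw, y * sw)
      r <- y - as.vector(X %*% b)
      r2 <- r^2
      f0 <- nll_var(svec, r2)
      opt <- optim(svec, nll_var, r2 = r2, method = "L-BFGS-B",
                   lower = c(rep(0, H), 1e-6),
                   control = list(maxit = 50))
      if (is.finite(opt$value) && opt$value <= f0) svec <- opt$par
      ll <- ll_const - nll_var(svec, r2)
      if (!is.finite(ll)) {
        ml_stop("non-finite likelihood while fitting CpG '%s'", rownames(beta)[j])
      }
      if (keep_trace) trace_j <- c(trace_j, ll)
      if (ll < ll_prev) {          # numerical guard; should not trigger
        ll <- ll_prev
        break
      }
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * (abs(ll_prev) + tol)) {
        conv <- TRUE
        ll_prev <- ll
        break
      }
      ll_prev <- ll
    }
    mu[j, ] <- clip01(b[seq_len(H)])
    if (p1 > 0) {
      gamma[j, , ] <- matrix(b[H + seq_len(H * p1)], H, p1, byrow = TRUE)
    }
    if (p2 > 0) delta[j, ] <- b[H + H * p1 + seq_len(p2)]
    sigma[j, ] <- abs(svec[seq_len(H)])
    tau[j] <- abs(svec[H + 1L])
    loglik[j] <- ll_prev
    n_iter[j] <- it
    converged[j] <- conv || it < max_iter
    if (keep_trace) traces[[j]] <- trace_j
  }
  structure(
    list(mu = mu, sigma = sigma, tau = tau, gamma = gamma, delta = delta,
         cell_types = colnames(W), loglik = loglik, n_iter = n_iter,
         converged = converged, trace = if (keep_trace) traces),
    class = "tca_model"
  )
}

#' Per-sample, per-cell-type methylation estimates from a fitted model
#'
#' Computes the conditional expectation of each cell-type-level methylation
#' value given the observed bulk value under the fitted mixture model:
#' \deqn{\hat z_{hij} = \mu'_{hij} +
#'   \frac{w_{ih}\sigma_{hj}^2}{\sum_l w_{il}^2\sigma_{lj}^2 + \tau_j^2}
#'   \big(x_{ij} - c^{(2)}_i\delta_j - \sum_l w_{il}\mu'_{lij}\big)}
#' where \eqn{\mu'} includes the cell-level covariate terms. Entries are
#' clipped to \[0, 1\].
#'
#' @param beta CpG-by-sample bulk beta matrix (same probes/samples the model
#'   was fitted on).
#' @param model A `"tca_model"` from [fit_tca()].
#' @param proportions Sample-by-cell-type proportion matrix.
#' @param c1,c2 The covariate matrices used at fit time (or `NULL`).
#' @return A CpG-by-sample-by-cell-type `"cell_tensor"` array (modality
#'   `"methylation"`).
#' @export
tca_tensor <- function(beta, model, proportions, c1 = NULL, c2 = NULL) {
  stopifnot(inherits(model, "tca_model"))
  check_matrix(beta, "beta")
  check_proportions(proportions, colnames(beta))
  if (!all(rownames(beta) %in% rownames(model$mu))) {
    ml_stop("model was not fitted on all probes of this beta matrix")
  }
  W <- proportions[colnames(beta), , drop = FALSE]
  H <- ncol(W)
  if (!is.null(c1)) c1 <- as.matrix(c1)[colnames(beta), , drop = FALSE]
  if (!is.null(c2)) c2 <- as.matrix(c2)[colnames(beta), , drop = FALSE]
  W2 <- W^2
  tensor <- array(
    NA_real_, dim = c(nrow(beta), ncol(beta), H),
    dimnames = list(rownames(beta), colnames(beta), colnames(W))
  )
  for (j in seq_len(nrow(beta))) {
    cpg <- rownames(beta)[j]
    mu_mat <- matrix(model$mu[cpg, ], nrow(W), H, byrow = TRUE)
    if (!is.null(c1) && !is.null(model$gamma)) {
      g <- model$gamma[cpg, , ]                    # H x p1
      g <- matrix(g, H, ncol(c1))
      mu_mat <- mu_mat + c1 %*% t(g)
    }
    x <- beta[j, ]
    if (!is.null(c2) && !is.null(model$delta)) {
      x <- x - as.vector(c2 %*% model$delta[cpg, ])
    }
    s2 <- model$sigma[cpg, ]^2
    v <- as.vector(W2 %*% s2) + model$tau[cpg]^2
    resid <- x - rowSums(W * mu_mat)
    shrink <- sweep(W, 2L, s2, `*`) / v
    tensor[j, , ] <- clip01(mu_mat + shrink * resid)
  }
  new_cell_tensor(tensor, "methylation")
}

#' @export
print.tca_model <- function(x, ...) {
  cat(sprintf("<tca_model> %d CpGs x %d cell types (%s)\n",
              nrow(x$mu), length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  cat(sprintf("  converged: %d/%d; mean residual sd (tau): %.4f\n",
              sum(x$converged), length(x$converged), mean(x$tau)))
  invisible(x)
}

#' @describeIn fit_tca Tidy per-CpG, per-cell-type parameter estimates.
#' @param x A `"tca_model"`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tca_model <- function(x, ...) {
  tibble::tibble(
    cpg = rep(rownames(x$mu), times = ncol(x$mu)),
    cell_type = rep(colnames(x$mu), each = nrow(x$mu)),
    mu = as.vector(x$mu),
    sigma = as.vector(x$sigma)
  ) |> dplyr::arrange(.data$cpg, .data$cell_type)
}

#' @describeIn fit_tca One-row model summary.
#' @exportS3Method generics::glance
glance.tca_model <- function(x, ...) {
  tibble::tibble(
    n_cpgs = nrow(x$mu),
    n_cell_types = length(x$cell_types),
    mean_tau = mean(x$tau),
    total_loglik = sum(x$loglik),
    prop_converged = mean(x$converged)
  )
}
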