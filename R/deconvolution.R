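#' Estimate cell-type proportions from bulk expression
#'
#' Regresses each sample's bulk expression over the signature genes on the
#' signature matrix by non-negative least squares and renormalizes the
#' coefficients to sum to one, giving a reference-based estimate of the
#' mixing fractions of the signature's cell types (an LM6-style blood
#' signature distinguishes CD8 T, CD4 T, B, NK cells, neutrophils and
#' monocytes).
#'
#' @param bulk_expr Gene-by-sample bulk expression matrix.
#' @param signature Gene-by-cell-type signature matrix (non-negative; at
#'   least two cell types, no all-zero gene row).
#' @return Sample-by-cell-type proportion matrix (rows sum to 1), with
#'   per-sample residual norms in the `"residuals"` attribute and the number
#'   of signature genes used in `"n_signature_genes"`.
#' @export
estimate_proportions <- function(bulk_expr, signature) {
  check_matrix(bulk_expr, "bulk_expr")
  check_matrix(signature, "signature")
  if (ncol(signature) < 2) ml_stop("signature must have at least 2 cell types")
  if (any(signature < 0)) ml_stop("signature values must be non-negative")
  if (any(rowSums(signature) == 0)) ml_stop("signature has an all-zero gene row")
  common <- intersect(rownames(signature), rownames(bulk_expr))
  if (length(common) < 10) {
    ml_stop("only %d signature genes overlap the bulk matrix (>= 10 required)",
            length(common))
  }
  ml_msg("estimate_proportions: using %d of %d signature genes",
         length(common), nrow(signature))
  S <- signature[common, , drop = FALSE]
  X <- bulk_expr[common, , drop = FALSE]
  fits <- apply(X, 2L, function(x) {
    fit <- pracma::lsqnonneg(S, x)
    p <- fit$x
    if (sum(p) <= 0) {
      ml_warn("all-zero coefficients for a sample; falling back to uniform")
      p <- rep(1 / ncol(S), ncol(S))
    }
    c(p / sum(p), sqrt(fit$resid.norm))
  })
  W <- t(fits[seq_len(ncol(S)), , drop = FALSE])
  rownames(W) <- colnames(X)
  colnames(W) <- colnames(S)
  attr(W, "residuals") <- setNames(fits[ncol(S) + 1L, ], colnames(X))
  attr(W, "n_signature_genes") <- length(common)
  W
}

#' Purify per-sample, per-cell-type expression from bulk signals
#'
#' A two-step constrained-regression scheme. Step 1 estimates, per gene,
#' shared cell-type expression profiles by non-negative least squares of the
#' gene's bulk values across samples on the proportion matrix. Step 2 makes
#' the profiles sample-specific: each sample's residual (bulk minus mixed
#' profiles) is redistributed to cell types proportionally to their
#' contribution `w_ih * g_h` (proportionally to `w_ih` when all profiles are
#' zero), and results are clamped at zero. The mixture of the purified
#' signals reconstitutes the bulk signal exactly before clamping.
#'
#' @param bulk_expr Gene-by-sample bulk expression matrix.
#' @param proportions Sample-by-cell-type proportion matrix (rows sum to 1).
#' @return A gene-by-sample-by-cell-type array of class `"cell_tensor"`
#'   (modality `"expression"`).
#' @export
purify_expression <- function(bulk_expr, proportions) {
  check_matrix(bulk_expr, "bulk_expr")
  check_proportions(proportions, colnames(bulk_expr))
  W <- proportions[colnames(bulk_expr), , drop = FALSE]
  H <- ncol(W)
  empty <- colSums(W) == 0
  if (any(empty)) {
    ml_warn("cell type '%s' has zero proportion in every sample; its slice equals the shared profile",
            colnames(W)[empty][1])
  }
  genes <- rownames(bulk_expr)
  tensor <- array(
    NA_real_, dim = c(nrow(bulk_expr), ncol(bulk_expr), H),
    dimnames = list(genes, colnames(bulk_expr), colnames(W))
  )
  for (g in seq_along(genes)) {
    y <- bulk_expr[g, ]
    obs <- !is.na(y)
    if (!any(obs)) next
    gh <- pracma::lsqnonneg(W[obs, , drop = FALSE], y[obs])$x
    fitted <- as.vector(W %*% gh)
    r <- y - fitted
    contrib <- sweep(W, 2L, gh, `*`)            # n x H, w_ih * g_h
    denom <- rowSums(contrib)
    share <- contrib / ifelse(denom > 0, denom, 1)
    share[denom <= 0, ] <- W[denom <= 0, , drop = FALSE]
    # cell-level increment: residual allocated in bulk space, mapped back
    inc <- share * r / ifelse(W > 0, W, Inf)    # w=0 -> no residual allocated
    z <- sweep(inc, 2L, gh, `+`)
    z[!obs, ] <- NA
    tensor[g, , ] <- pmax(z, 0)
  }
  new_cell_tensor(tensor, "expression")
}

#' Reference-free cell-composition components
#'
#' Selects the `t` sites whose standardized profiles are best approximated
#' by a rank-`k` principal subspace (after optionally regressing out
#' technical covariates) and returns the first `k` principal components of
#' the selected submatrix as sample-level composition surrogates.
#'
#' @param beta CpG-by-sample beta matrix.
#' @param k Assumed number of cell types (component rank), default 6.
#' @param t Number of informative sites to select, default 500.
#' @param adjust Optional sample-by-covariate numeric matrix of technical
#'   covariates regressed out of each site before scoring.
#' @return A list of class `"refactor_components"` with elements
#'   `components` (sample-by-k matrix), `sites` (selected CpG ids), and
#'   `site_scores` (reconstruction errors for all sites).
#' @export
refactor_components <- function(beta, k = 6, t = 500, adjust = NULL) {
  check_matrix(beta, "beta")
  n <- ncol(beta)
  if (k >= n) ml_stop("k (%d) must be smaller than the number of samples (%d)", k, n)
  if (k >= nrow(beta)) ml_stop("k must be smaller than the number of probes")
  t <- min(t, nrow(beta))
  if (t < k) ml_stop("t (%d) must be at least k (%d)", t, k)
  sds <- apply(beta, 1L, sd)
  keep <- sds > 0
  X <- (beta[keep, , drop = FALSE] - rowMeans(beta[keep, , drop = FALSE])) /
    sds[keep]
  if (!is.null(adjust)) {
    A <- cbind(1, as.matrix(adjust))
    Q <- qr.Q(qr(A))
    X <- X - (X %*% Q) %*% t(Q)
  }
  sv <- svd(X, nu = 0, nv = k)
  Vk <- sv$v
  err <- rowSums(X^2) - rowSums((X %*% Vk)^2)
  ord <- order(err)
  sites <- rownames(X)[ord[seq_len(min(t, nrow(X)))]]
  sel <- X[sites, , drop = FALSE]
  pc <- stats::prcomp(t(sel), center = TRUE, scale. = FALSE)
  comps <- pc$x[, seq_len(k), drop = FALSE]
  rownames(comps) <- colnames(beta)
  colnames(comps) <- paste0("RC", seq_len(k))
  structure(
    list(components = comps, sites = sites,
         site_scores = setNames(err, rownames(X))),
    class = "refactor_components"
  )
}

# --- shared containers -----------------------------------------------------

check_proportions <- function(W, samples = NULL, tol = 1e-8) {
  check_matrix(W, "proportions")
  if (any(W < -tol)) ml_stop("proportions must be non-negative")
  if (any(abs(rowSums(W) - 1) > 1e-6)) {
    ml_stop("proportion rows must sum to 1")
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(W))
    if (length(missing) > 0) {
      ml_stop("sample '%s' missing from proportion matrix", missing[1])
    }
  }
  invisible(W)
}

new_cell_tensor <- function(arr, modality = c("expression", "methylation")) {
  modality <- match.arg(modality)
  stopifnot(length(dim(arr)) == 3)
  structure(arr, modality = modality, class = c("cell_tensor", class(arr)))
}

#' Extract one cell type's feature-by-sample slice from a cell tensor
#'
#' @param tensor A `"cell_tensor"` array (feature x sample x cell type).
#' @param cell_type Cell-type name or index.
#' @return A feature-by-sample matrix.
#' @export
tensor_slice <- function(tensor, cell_type) {
  stopifnot(inherits(tensor, "cell_tensor"))
  tensor[, , cell_type, drop = TRUE]
}

#' @export
print.cell_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cell_tensor: %s> %d features x %d samples x %d cell types\n",
              attr(x, "modality"), d[1], d[2], d[3]))
  invisible(x)
}
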