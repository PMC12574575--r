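# Weighted maximum-likelihood update of one beta component.
# Given weighted means of log(x) and log(1-x), solve
#   digamma(a) - digamma(a+b) = T1,  digamma(b) - digamma(a+b) = T2
# by Newton iteration in (log a, log b), started from moment matching.
.beta_ml <- function(t1, t2, m, v, max_iter = 30, tol = 1e-10, init = NULL) {
  if (is.null(init)) {
    v <- max(min(v, m * (1 - m) * 0.999), 1e-6)
    phi <- m * (1 - m) / v - 1
    a <- max(m * phi, 1e-2)
    b <- max((1 - m) * phi, 1e-2)
  } else {
    a <- init[1]
    b <- init[2]
  }
  for (i in seq_len(max_iter)) {
    dab <- digamma(a + b)
    f1 <- digamma(a) - dab - t1
    f2 <- digamma(b) - dab - t2
    if (abs(f1) + abs(f2) < tol) break
    tab <- trigamma(a + b)
    j11 <- trigamma(a) - tab
    j22 <- trigamma(b) - tab
    det <- j11 * j22 - tab^2
    if (!is.finite(det) || abs(det) < 1e-14) break
    da <- (j22 * f1 + tab * f2) / det
    db <- (tab * f1 + j11 * f2) / det
    # damped step in log space keeps parameters positive
    step <- 1
    repeat {
      a_new <- a * exp(-min(max(step * da / a, -2), 2))
      b_new <- b * exp(-min(max(step * db / b, -2), 2))
      if (is.finite(a_new) && is.finite(b_new)) break
      step <- step / 2
      if (step < 1e-4) { a_new <- a; b_new <- b; break }
    }
    a <- min(max(a_new, 1e-2), 1e4)
    b <- min(max(b_new, 1e-2), 1e4)
  }
  c(a, b)
}

.mix_loglik <- function(x, w, a, b) {
  ld <- vapply(seq_along(w), function(k) {
    log(w[k]) + stats::dbeta(x, a[k], b[k], log = TRUE)
  }, numeric(length(x)))
  sum(row_logsumexp(matrix(ld, nrow = length(x))))
}

.em_beta <- function(x, k, init_means, max_iter = 100, tol = 1e-6) {
  n <- length(x)
  w <- rep(1 / k, k)
  a <- numeric(k); b <- numeric(k)
  s0 <- 0.08
  for (c in seq_len(k)) {
    ab <- .beta_ml(log(init_means[c]), log(1 - init_means[c]),
                   init_means[c], s0^2, max_iter = 0)
    a[c] <- ab[1]; b[c] <- ab[2]
  }
  lx <- log(x); l1x <- log(1 - x)
  ll_prev <- -Inf
  trace <- numeric(0)
  ld <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    for (c in seq_len(k)) {
      # beta log-density from precomputed log(x), log(1-x)
      ld[, c] <- log(w[c]) + (a[c] - 1) * lx + (b[c] - 1) * l1x -
        lbeta(a[c], b[c])
    }
    lse <- row_logsumexp(ld)
    ll <- sum(lse)
    if (!is.finite(ll)) break
    if (ll < ll_prev - 1e-9) {     # guard: exact M-step should not decrease
      ll <- ll_prev
      break
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + tol)) {
      ll_prev <- ll
      break
    }
    ll_prev <- ll
    r <- exp(ld - lse)
    rs <- colSums(r)
    dead <- rs < 1e-8
    for (c in which(!dead)) {
      t1 <- sum(r[, c] * lx) / rs[c]
      t2 <- sum(r[, c] * l1x) / rs[c]
      m <- sum(r[, c] * x) / rs[c]
      v <- sum(r[, c] * (x - m)^2) / rs[c]
      ab <- .beta_ml(t1, t2, m, v, init = c(a[c], b[c]))
      a[c] <- ab[1]; b[c] <- ab[2]
    }
    w <- rs / n
    w[w < 1e-10] <- 1e-10
    w <- w / sum(w)
  }
  list(weights = w, alpha = a, beta = b, loglik = ll_prev, trace = trace)
}

#' Fit a zero/one-inflated mixture of beta distributions
#'
#' Fits 1-, 2- and 3-component beta mixtures by expectation-maximization
#' (exact weighted maximum-likelihood M-step via Newton iteration on the
#' digamma equations; three quantile-anchored starts per component count)
#' and returns the fit with the lowest Bayesian information criterion.
#' Values saturated at the boundaries (common after deconvolution estimates
#' are clipped to \[0, 1\]) would otherwise be absorbed as spurious
#' high-concentration components; when a boundary carries at least
#' `boundary_min` of the mass it is instead modeled as a degenerate
#' inflation component at that boundary and the beta mixture is fitted to
#' the interior values. Component means are reported in ascending order. A
#' constant input returns a single-component fit directly.
#'
#' @param values Numeric vector of beta values in \[0, 1\] (at least 10
#'   finite values).
#' @param max_components Largest number of beta components tried (default 3).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param eps Interior values are clipped to `[eps, 1 - eps]` before
#'   fitting.
#' @param boundary Values within `boundary` of 0 or 1 count as saturated.
#' @param boundary_min Minimum fraction of saturated values for a boundary
#'   inflation component (default 0.02, at least 3 values).
#' @return An object of class `"beta_mixture"`: list with `k`, `weights`,
#'   `alpha`, `beta` (`NA` for inflation components), `means`, `loglik`,
#'   `bic`, `trace` (log-likelihood per EM iteration of the selected beta
#'   fit), `bic_all`, and logical `inflated_lo`/`inflated_hi`.
#' @export
fit_beta_mixture <- function(values, max_components = 3, max_iter = 100,
                             tol = 1e-6, eps = 1e-4, boundary = 1e-3,
                             boundary_min = 0.02) {
  x <- values[is.finite(values)]
  if (length(x) < 10) ml_stop("need at least 10 finite values, got %d", length(x))
  if (any(x < 0 | x > 1)) ml_stop("beta values must lie in [0, 1]")
  n_all <- length(x)
  min_sat <- max(3, ceiling(boundary_min * n_all))
  at_lo <- x <= boundary
  at_hi <- x >= 1 - boundary
  use_lo <- sum(at_lo) >= min_sat
  use_hi <- sum(at_hi) >= min_sat
  interior <- x[!(use_lo & at_lo) & !(use_hi & at_hi)]
  if ((use_lo || use_hi) && length(interior) >= 10 &&
      var(interior) >= 1e-10) {
    core <- .fit_beta_core(pmin(pmax(interior, eps), 1 - eps),
                           max_components, max_iter, tol, eps)
    w_int <- 1 - use_lo * mean(at_lo) - use_hi * mean(at_hi)
    weights <- core$weights * w_int
    alpha <- core$alpha
    beta <- core$beta
    means <- core$means
    if (use_lo) {
      weights <- c(mean(at_lo), weights)
      alpha <- c(NA_real_, alpha)
      beta <- c(NA_real_, beta)
      means <- c(mean(x[at_lo]), means)
    }
    if (use_hi) {
      weights <- c(weights, mean(at_hi))
      alpha <- c(alpha, NA_real_)
      beta <- c(beta, NA_real_)
      means <- c(means, mean(x[at_hi]))
    }
    return(structure(
      list(k = length(weights), weights = weights, alpha = alpha,
           beta = beta, means = means, loglik = core$loglik,
           bic = core$bic, trace = core$trace, bic_all = core$bic_all,
           inflated_lo = use_lo, inflated_hi = use_hi,
           boundary = boundary, values = x),
      class = "beta_mixture"
    ))
  }
  x <- pmin(pmax(x, eps), 1 - eps)
  if (var(x) < 1e-10) {
    m <- mean(x)
    return(structure(
      list(k = 1L, weights = 1, alpha = NA_real_, beta = NA_real_,
           means = m, loglik = NA_real_, bic = NA_real_,
           trace = numeric(0), bic_all = NA_real_,
           inflated_lo = FALSE, inflated_hi = FALSE, boundary = boundary,
           values = x),
      class = "beta_mixture"
    ))
  }
  core <- .fit_beta_core(x, max_components, max_iter, tol, eps)
  structure(
    c(core, list(inflated_lo = FALSE, inflated_hi = FALSE,
                 boundary = boundary, values = x)),
    class = "beta_mixture"
  )
}

# BIC-selected plain beta mixture on interior values
.fit_beta_core <- function(x, max_components, max_iter, tol, eps) {
  n <- length(x)
  best <- NULL
  bics <- setNames(rep(NA_real_, max_components),
                   paste0("k", seq_len(max_components)))
  for (k in seq_len(max_components)) {
    fit_k <- NULL
    for (s in if (k == 1) 2 else 1:3) {
      probs <- (seq_len(k) - 0.5) / k + (s - 2) * 0.12
      anchors <- unname(quantile(x, probs = pmin(pmax(probs, 0.02), 0.98)))
      anchors <- pmin(pmax(anchors, eps), 1 - eps)
      f <- .em_beta(x, k, anchors, max_iter = max_iter, tol = tol)
      if (is.null(fit_k) || f$loglik > fit_k$loglik) fit_k <- f
    }
    npar <- 3 * k - 1
    bic_k <- -2 * fit_k$loglik + npar * log(n)
    bics[k] <- bic_k
    if (is.null(best) || bic_k < best$bic) {
      best <- c(fit_k, list(k = k, bic = bic_k))
    }
  }
  ord <- order(best$alpha / (best$alpha + best$beta))
  list(k = as.integer(best$k),
       weights = best$weights[ord],
       alpha = best$alpha[ord],
       beta = best$beta[ord],
       means = (best$alpha / (best$alpha + best$beta))[ord],
       loglik = best$loglik,
       bic = best$bic,
       trace = best$trace,
       bic_all = bics)
}

#' Posterior component assignment for a fitted beta mixture
#'
#' @param fit A `"beta_mixture"` object.
#' @param values Values to assign (defaults to the values used at fit time).
#' @return Integer vector of maximum-a-posteriori component indices
#'   (components sorted by ascending mean).
#' @export
mixture_assign <- function(fit, values = fit$values) {
  stopifnot(inherits(fit, "beta_mixture"))
  out <- rep(1L, length(values))
  beta_comp <- which(!is.na(fit$alpha))
  lo <- isTRUE(fit$inflated_lo) & values <= fit$boundary
  hi <- isTRUE(fit$inflated_hi) & values >= 1 - fit$boundary
  mid <- !lo & !hi
  if (length(beta_comp) >= 2 && any(mid)) {
    x <- pmin(pmax(values[mid], 1e-4), 1 - 1e-4)
    ld <- vapply(beta_comp, function(c) {
      log(fit$weights[c]) + stats::dbeta(x, fit$alpha[c], fit$beta[c],
                                         log = TRUE)
    }, numeric(length(x)))
    out[mid] <- beta_comp[max.col(matrix(ld, nrow = length(x)),
                                  ties.method = "first")]
  } else if (length(beta_comp) >= 1) {
    out[mid] <- beta_comp[1]
  }
  out[lo] <- 1L
  out[hi] <- fit$k
  out
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat(sprintf("<beta_mixture> %d component(s), BIC %.1f\n", x$k, x$bic))
  cat(sprintf("  means: %s; weights: %s\n",
              paste(sprintf("%.3f", x$means), collapse = ", "),
              paste(sprintf("%.2f", x$weights), collapse = ", ")))
  invisible(x)
}

#' @describeIn fit_beta_mixture Per-component parameter tibble.
#' @param x A `"beta_mixture"`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.beta_mixture <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    weight = x$weights,
    alpha = x$alpha,
    beta = x$beta,
    mean = x$means
  )
}

#' @describeIn fit_beta_mixture One-row fit summary.
#' @exportS3Method generics::glance
glance.beta_mixture <- function(x, ...) {
  tibble::tibble(
    k = x$k, loglik = x$loglik, bic = x$bic, n = length(x$values)
  )
}
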