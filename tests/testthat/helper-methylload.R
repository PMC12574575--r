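options(methylload.verbose = FALSE)

# named random beta matrix
rand_beta <- function(J, n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(J * n), J, n,
              dimnames = list(sprintf("cg%04d", seq_len(J)),
                              sprintf("S%03d", seq_len(n))))
  m
}

# minimal state_call object with planted states (for expression tests that
# should not depend on the mixture fitting path)
make_state_call <- function(states, low_mean = 0.5) {
  structure(
    list(states = states,
         prev_hypo = mean(states == "hypo"),
         prev_hyper = mean(states == "hyper"),
         low_mean = low_mean,
         components = NULL,
         fit = NULL),
    class = "state_call"
  )
}

# exhaustive simplex grid (step 0.01) least-squares oracle for 3 cell types
grid_search_proportions <- function(S, x, step = 0.01) {
  best <- NULL
  best_err <- Inf
  for (p1 in seq(0, 1, step)) {
    for (p2 in seq(0, 1 - p1, step)) {
      p <- c(p1, p2, 1 - p1 - p2)
      err <- sum((as.vector(S %*% p) - x)^2)
      if (err < best_err) {
        best_err <- err
        best <- p
      }
    }
  }
  best
}

# exhaustive hypergeometric tail: probability of >= k overlaps when drawing
# n from a universe of size N containing K marked elements
enum_hyper_tail <- function(k, K, N, n) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# reference step-up false-discovery-rate adjustment
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(scaled))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
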