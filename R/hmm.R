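#' Fit the three-state bias HMM to a Directionality Index profile
#'
#' DI values are discretized into `K` quantile levels and segmented with a
#' three-state hidden Markov model (upstream_bias / no_bias /
#' downstream_bias) with categorical emissions over the levels. Parameters
#' are estimated by Baum-Welch expectation-maximization from seeded
#' initializations ordered negative / zero / positive; the best of
#' `n_restarts` runs by log-likelihood wins (ties broken by lowest restart
#' index) and the state path is recovered by Viterbi decoding. Each fitted
#' state is labeled by the sign of the mean DI over the bins decoded into
#' it (near-zero or unused states are no_bias; same-sign states share a
#' label and their runs merge downstream).
#'
#' @param di a `di_profile` from [compute_directionality_index()].
#' @param K number of quantile levels for discretization (default 7;
#'   degenerate profiles fall back to sign levels).
#' @param seed integer seed for the EM initializations.
#' @param n_restarts independent seeded EM restarts (default 5).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   drops below `tol` or after `max_iter` iterations (then the best-so-far
#'   fit is returned with `converged = FALSE` and a warning).
#' @return object of class `bias_hmm`: `transition`, `emission`,
#'   `discretization_edges`, `loglik`, `converged`, `states` and `path`
#'   (factor over upstream_bias/no_bias/downstream_bias per bin).
#' @export
fit_bias_hmm <- function(di, K = 7L, seed = 1L, n_restarts = 5L,
                         max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(di, "di_profile"))
  x <- di$di
  window <- attr(di, "window")
  bin_size <- attr(di, "bin_size")
  if (length(x) < 2L * window / bin_size)
    stop("profile too short for HMM segmentation (need >= 2*window/bin_size bins)")

  states <- c("upstream_bias", "no_bias", "downstream_bias")
  disc <- discretize_di(x, K)
  obs <- disc$obs
  Ke <- disc$K
  if (Ke < 2L || all(x == 0)) {
    # flat profile: nothing to segment
    path <- factor(rep("no_bias", length(x)), levels = states)
    return(structure(list(transition = NULL, emission = NULL,
                          discretization_edges = disc$edges,
                          loglik = 0, converged = TRUE,
                          states = states, path = path),
                     class = "bias_hmm"))
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, 300L + r))
    fit <- baum_welch(obs, Ke, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$loglik > best$loglik + 1e-9) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best-so-far fit")

  # label each EM state by the sign of the mean DI over the bins Viterbi
  # assigns to it; two states capturing the same sign simply share a label
  # (their runs merge downstream). Unused or near-zero states are no_bias.
  vit <- viterbi_path(obs, best$transition, best$emission, best$init)
  eps <- 0.1 * max(abs(x))
  labels <- vapply(1:3, function(s) {
    if (!any(vit == s)) return("no_bias")
    m <- mean(x[vit == s])
    if (m > eps) "downstream_bias"
    else if (m < -eps) "upstream_bias"
    else "no_bias"
  }, character(1))
  path <- factor(labels[vit], levels = states)

  structure(list(transition = best$transition,
                 emission = best$emission,
                 state_labels = labels,
                 discretization_edges = disc$edges,
                 loglik = best$loglik,
                 converged = best$converged,
                 states = states,
                 path = path),
            class = "bias_hmm")
}

# Quantile discretization of DI values; falls back to sign levels when the
# value set is too degenerate for K distinct quantile edges.
discretize_di <- function(x, K) {
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = K + 1),
                                  names = FALSE))
  if (length(edges) - 1L >= 3L) {
    obs <- .bincode(x, edges, right = TRUE, include.lowest = TRUE)
    list(obs = obs, K = length(edges) - 1L, edges = edges)
  } else {
    obs <- as.integer(sign(x)) + 2L   # -,0,+ -> 1,2,3
    list(obs = obs, K = 3L, edges = c(-Inf, 0, Inf))
  }
}

# Baum-Welch EM for a 3-state categorical-emission HMM, with scaling.
# Initialization under the caller's RNG state: sticky transitions and
# emissions biased low / central / high so state identities start ordered.
baum_welch <- function(obs, K, n_states = 3L, max_iter = 200L, tol = 1e-6) {
  n <- length(obs)
  A <- matrix(0.1 / (n_states - 1), n_states, n_states)
  diag(A) <- 0.9
  A <- jitter_rows(A)
  lv <- seq_len(K)
  mid <- (K + 1) / 2
  B <- rbind(exp(-(lv - 1) / 2),          # upstream: weight on low levels
             exp(-abs(lv - mid) / 2),     # no bias: central levels
             exp(-(K - lv) / 2))          # downstream: high levels
  B <- jitter_rows(B / rowSums(B))
  init <- rep(1 / n_states, n_states)

  loglik <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    fb <- forward_backward(obs, A, B, init)
    if (fb$loglik - loglik < tol && iter > 1L) {
      loglik <- fb$loglik
      converged <- TRUE
      break
    }
    loglik <- fb$loglik
    # M step
    init <- fb$gamma[1L, ]
    xi_sum <- fb$xi_sum
    A <- xi_sum / pmax(rowSums(xi_sum), .Machine$double.eps)
    for (k in seq_len(K))
      B[, k] <- colSums(fb$gamma[obs == k, , drop = FALSE])
    B <- B / pmax(rowSums(B), .Machine$double.eps)
    B <- pmax(B, 1e-10)
    B <- B / rowSums(B)
  }
  list(transition = A, emission = B, init = init,
       loglik = loglik, converged = converged)
}

jitter_rows <- function(M) {
  J <- matrix(stats::rgamma(length(M), shape = 50), nrow(M))
  M <- M * J / 50
  M / rowSums(M)
}

forward_backward <- function(obs, A, B, init) {
  n <- length(obs)
  S <- nrow(A)
  alpha <- matrix(0, n, S)
  beta <- matrix(0, n, S)
  scale <- numeric(n)
  emis <- t(B)[obs, , drop = FALSE]    # n x S
  alpha[1L, ] <- init * emis[1L, ]
  scale[1L] <- sum(alpha[1L, ])
  alpha[1L, ] <- alpha[1L, ] / scale[1L]
  for (t in 2:n) {
    a <- (alpha[t - 1L, ] %*% A) * emis[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1L):1L) {
    beta[t, ] <- (A %*% (emis[t + 1L, ] * beta[t + 1L, ])) / scale[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, S, S)
  for (t in seq_len(n - 1L)) {
    xi <- (alpha[t, ] %o% (emis[t + 1L, ] * beta[t + 1L, ])) * A
    xi_sum <- xi_sum + xi / sum(xi)
  }
  list(gamma = gamma, xi_sum = xi_sum, loglik = sum(log(scale)))
}

#' Most-likely state path of a categorical-emission HMM
#'
#' Standard Viterbi decoding in log space. Exposed so that decoding can be
#' checked against hand-set parameters independently of EM fitting.
#'
#' @param obs integer observation symbols (1..K).
#' @param transition row-stochastic state transition matrix.
#' @param emission per-state categorical emission matrix (states x K).
#' @param init initial state distribution.
#' @return integer state indices along the sequence.
#' @export
viterbi_path <- function(obs, transition, emission,
                         init = rep(1 / nrow(transition), nrow(transition))) {
  n <- length(obs)
  S <- nrow(transition)
  logA <- log(pmax(transition, 1e-300))
  logB <- log(pmax(emission, 1e-300))
  delta <- matrix(-Inf, n, S)
  psi <- matrix(0L, n, S)
  delta[1L, ] <- log(pmax(init, 1e-300)) + logB[, obs[1L]]
  for (t in 2:n) {
    for (s in seq_len(S)) {
      cand <- delta[t - 1L, ] + logA[, s]
      psi[t, s] <- which.max(cand)
      delta[t, s] <- cand[psi[t, s]] + logB[s, obs[t]]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}
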