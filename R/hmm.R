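# 1D Gaussian-emission hidden Markov model fit by Baum-Welch (EM) with
# scaled forward/backward recursions, plus Viterbi decoding. Used for
# classifying directionality-index states; kept deliberately small.

hmm_emission <- function(x, mu, sigma) {
  out <- vapply(seq_along(mu), function(s)
    stats::dnorm(x, mu[s], sigma[s]), numeric(length(x)))
  matrix(pmax(out, 1e-300), length(x), length(mu))
}

hmm_forward_backward <- function(B, init, trans) {
  n <- nrow(B); S <- ncol(B)
  alpha <- matrix(0, n, S); beta <- matrix(0, n, S); cs <- numeric(n)
  a <- init * B[1, ]
  cs[1] <- sum(a); alpha[1, ] <- a / cs[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% trans) * B[t, ]
    cs[t] <- sum(a); alpha[t, ] <- a / cs[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1)
    beta[t, ] <- (trans %*% (B[t + 1, ] * beta[t + 1, ])) / cs[t + 1]
  list(alpha = alpha, beta = beta, loglik = sum(log(cs)))
}

#' Fit a Gaussian-emission hidden Markov model
#'
#' Baum-Welch EM over one or more observation sequences with the best of
#' several random restarts retained. Emissions are univariate Gaussians,
#' one per state.
#'
#' @param seqs list of numeric vectors (observation sequences).
#' @param n_states number of hidden states (default 3).
#' @param n_restarts random restarts (default 5).
#' @param max_iter EM iterations per restart.
#' @param tol log-likelihood convergence tolerance.
#' @param seed integer seed.
#' @return list with `init`, `trans`, `mu`, `sigma`, `loglik`,
#'   `converged`.
#' @export
fit_gaussian_hmm <- function(seqs, n_states = 3, n_restarts = 5,
                             max_iter = 60, tol = 1e-4, seed = 1) {
  if (!is.list(seqs)) seqs <- list(seqs)
  seqs <- lapply(seqs, function(s) s[!is.na(s)])
  seqs <- seqs[lengths(seqs) >= 2]
  if (!length(seqs)) stop("no usable observation sequences")
  x_all <- unlist(seqs)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    qs <- sort(runif(n_states))
    mu <- as.numeric(quantile(x_all, probs = qs))
    sigma <- rep(stats::sd(x_all) / n_states + 1e-6, n_states)
    init <- rep(1 / n_states, n_states)
    trans <- matrix(0.1 / (n_states - 1), n_states, n_states)
    diag(trans) <- 0.9
    ll_prev <- -Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      g_sum <- matrix(0, 1, n_states)
      gx <- numeric(n_states); gx2 <- numeric(n_states)
      xi_sum <- matrix(0, n_states, n_states)
      init_new <- numeric(n_states)
      ll <- 0
      for (s in seqs) {
        B <- hmm_emission(s, mu, sigma)
        fb <- hmm_forward_backward(B, init, trans)
        gamma <- fb$alpha * fb$beta
        gamma <- gamma / rowSums(gamma)
        ll <- ll + fb$loglik
        init_new <- init_new + gamma[1, ]
        g_sum <- g_sum + colSums(gamma)
        gx <- gx + colSums(gamma * s)
        gx2 <- gx2 + colSums(gamma * s^2)
        n <- length(s)
        for (t in seq_len(n - 1)) {
          xi <- (fb$alpha[t, ] %o% (B[t + 1, ] * fb$beta[t + 1, ])) * trans
          xi_sum <- xi_sum + xi / sum(xi)
        }
      }
      init <- init_new / sum(init_new)
      trans <- xi_sum / rowSums(xi_sum)
      mu <- gx / as.numeric(g_sum)
      sigma <- sqrt(pmax(gx2 / as.numeric(g_sum) - mu^2, 1e-8))
      if (abs(ll - ll_prev) < tol * (1 + abs(ll))) { converged <- TRUE; break }
      ll_prev <- ll
    }
    fit <- list(init = init, trans = trans, mu = mu, sigma = sigma,
                loglik = ll, converged = converged)
    if (is.null(best) || ll > best$loglik) best <- fit
  }
  if (!best$converged)
    warning("HMM EM did not converge; best restart used")
  best
}

#' Viterbi decoding under a fitted Gaussian HMM
#'
#' @param x numeric observation sequence.
#' @param fit result of [fit_gaussian_hmm()].
#' @return integer vector of most likely state indices.
#' @export
hmm_viterbi <- function(x, fit) {
  n <- length(x); S <- length(fit$mu)
  if (!n) return(integer(0))
  logB <- log(hmm_emission(x, fit$mu, fit$sigma))
  logT <- log(pmax(fit$trans, 1e-300))
  delta <- matrix(-Inf, n, S); psi <- matrix(0L, n, S)
  delta[1, ] <- log(pmax(fit$init, 1e-300)) + logB[1, ]
  if (n > 1) for (t in 2:n) for (s in seq_len(S)) {
    cand <- delta[t - 1, ] + logT[, s]
    psi[t, s] <- which.max(cand)
    delta[t, s] <- max(cand) + logB[t, s]
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}
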