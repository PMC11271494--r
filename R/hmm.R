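# Gaussian-emission hidden Markov model for hopping traces: EM
# (Baum-Welch) on means/sds/transition matrix followed by Viterbi decoding.
# Deterministic: states are initialised from quantiles of the data.

#' Fit a Gaussian-emission HMM to a level-hopping signal
#'
#' Small self-contained Baum--Welch/Viterbi implementation used by
#' [detect_steps()] for two-state hopping traces. Emission means are
#' initialised at data quantiles, so the fit is deterministic. States whose
#' stationary occupancy collapses are pruned.
#'
#' @param x numeric signal
#' @param K number of hidden states (levels)
#' @param max_iter maximal EM iterations
#' @param tol relative log-likelihood convergence tolerance
#' @param sd_floor lower bound on emission standard deviations
#' @return list with `means`, `sds`, `transmat`, `path` (Viterbi state per
#'   sample), `loglik`, `occupancy`
#' @export
gaussian_hmm <- function(x, K = 2, max_iter = 100, tol = 1e-6,
                         sd_floor = 1e-6) {
  n <- length(x)
  if (K < 1) stop("'K' must be >= 1")
  if (K == 1) {
    return(list(means = mean(x), sds = max(stats::sd(x), sd_floor),
                transmat = matrix(1, 1, 1), path = rep(1L, n),
                loglik = sum(stats::dnorm(x, mean(x),
                                          max(stats::sd(x), sd_floor),
                                          log = TRUE)),
                occupancy = 1))
  }
  mu <- as.numeric(stats::quantile(x, probs = (seq_len(K) - 0.5) / K))
  sdv <- rep(max(stats::sd(x) / K, sd_floor), K)
  A <- matrix(0.05 / (K - 1), K, K); diag(A) <- 0.95
  pi0 <- rep(1 / K, K)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      stats::dnorm(x, mu[k], sdv[k]), numeric(n))
    dens <- pmax(dens, 1e-300)
    # scaled forward-backward
    alpha <- matrix(0, n, K); beta <- matrix(0, n, K); cvec <- numeric(n)
    a <- pi0 * dens[1, ]; cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% A) * dens[t, ]
      cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
    }
    beta[n, ] <- 1
    for (t in (n - 1):1)
      beta[t, ] <- (A %*% (dens[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    xi_num <- matrix(0, K, K)
    for (t in 1:(n - 1)) {
      m <- (alpha[t, ] %o% (dens[t + 1, ] * beta[t + 1, ])) * A
      xi_num <- xi_num + m / sum(m)
    }
    pi0 <- gamma[1, ]
    A <- xi_num / pmax(rowSums(xi_num), 1e-300)
    occ <- colSums(gamma)
    mu <- colSums(gamma * x) / occ
    sdv <- pmax(sqrt(colSums(gamma * (x - rep(mu, each = n))^2) / occ),
                sd_floor)
    ll <- sum(log(cvec))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  # Viterbi decoding in log space
  logA <- log(pmax(A, 1e-300))
  logd <- vapply(seq_len(K), function(k)
    stats::dnorm(x, mu[k], sdv[k], log = TRUE), numeric(n))
  v <- log(pmax(pi0, 1e-300)) + logd[1, ]
  back <- matrix(0L, n, K)
  for (t in 2:n) {
    m <- v + logA                       # K x K: from row, to col
    back[t, ] <- max.col(t(m))
    v <- m[cbind(back[t, ], seq_len(K))] + logd[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(v)
  for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  list(means = mu, sds = sdv, transmat = A, path = path, loglik = ll_old,
       occupancy = tabulate(path, K) / n)
}
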