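#' Gaussian hidden Markov model (EM + Viterbi)
#'
#' A minimal univariate Gaussian HMM used to segment the directionality
#' index into upstream-biased / unbiased / downstream-biased states.
#' `fit_gaussian_hmm()` fits by EM (Baum-Welch) over a list of independent
#' sequences with quantile-based initial means, stopping when the total
#' log-likelihood improves by less than `tol` or after `max_iter`
#' iterations; states are relabelled in increasing mean order so state 1 is
#' the most upstream-biased. On a degenerate fit (vanishing variance or
#' non-finite likelihood) the initialisation is perturbed once (seeded)
#' before erroring. `viterbi_decode()` returns the most likely state path of
#' one sequence.
#'
#' @param seqs list of numeric vectors (one per chromosome segment).
#' @param n_states number of states (default 3).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol log-likelihood convergence tolerance (default 1e-4).
#' @param seed seed for the perturbed-restart path.
#' @return `fit_gaussian_hmm()`: list of class `gaussian_hmm` with `mu`,
#'   `sigma`, `trans`, `init`, `loglik`, `n_iter`. `viterbi_decode()`: an
#'   integer state vector.
#' @export
fit_gaussian_hmm <- function(seqs, n_states = 3L, max_iter = 200L,
                             tol = 1e-4, seed = 13L) {
  x_all <- unlist(seqs, use.names = FALSE)
  stopifnot(length(x_all) >= 10 * n_states)
  qs <- seq(0.1, 0.9, length.out = n_states)
  mu0 <- as.numeric(quantile(x_all, qs))
  sd0 <- max(stats::sd(x_all), 1e-8)
  for (attempt in 1:2) {
    if (attempt == 2L) {
      set.seed(seed)
      mu0 <- mu0 + rnorm(n_states, 0, sd0 / 4)
    }
    fit <- try(hmm_em(seqs, mu0, rep(sd0 / 2, n_states), max_iter, tol),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      o <- order(fit$mu)
      fit$mu <- fit$mu[o]; fit$sigma <- fit$sigma[o]
      fit$trans <- fit$trans[o, o, drop = FALSE]
      fit$init <- fit$init[o]
      class(fit) <- "gaussian_hmm"
      return(fit)
    }
  }
  stop_named("hmm", paste("EM failed:", attr(fit, "condition")$message))
}

hmm_em <- function(seqs, mu, sigma, max_iter, tol) {
  K <- length(mu)
  trans <- matrix(0.05 / (K - 1), K, K); diag(trans) <- 0.95
  init <- rep(1 / K, K)
  sd_floor <- max(stats::sd(unlist(seqs)), 1e-8) * 1e-4
  ll_old <- -Inf
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    ll <- 0
    g_sum <- numeric(K); gx <- numeric(K); gx2 <- numeric(K)
    xi_sum <- matrix(0, K, K); init_sum <- numeric(K)
    for (x in seqs) {
      n <- length(x)
      B <- vapply(seq_len(K), function(k) dnorm(x, mu[k], sigma[k]), numeric(n))
      B <- pmax(matrix(B, n, K), 1e-300)
      a <- matrix(0, n, K); cvec <- numeric(n)
      a[1, ] <- init * B[1, ]
      cvec[1] <- sum(a[1, ]); a[1, ] <- a[1, ] / cvec[1]
      if (n > 1) for (t in 2:n) {
        a[t, ] <- (a[t - 1, ] %*% trans) * B[t, ]
        cvec[t] <- sum(a[t, ]); a[t, ] <- a[t, ] / cvec[t]
      }
      b <- matrix(0, n, K); b[n, ] <- 1
      if (n > 1) for (t in (n - 1):1)
        b[t, ] <- (trans %*% (B[t + 1, ] * b[t + 1, ])) / cvec[t + 1]
      gam <- a * b
      gam <- gam / rowSums(gam)
      ll <- ll + sum(log(cvec))
      g_sum <- g_sum + colSums(gam)
      gx <- gx + colSums(gam * x)
      init_sum <- init_sum + gam[1, ]
      for (t in seq_len(n - 1)) {
        xi <- (a[t, ] %o% (B[t + 1, ] * b[t + 1, ])) * trans / cvec[t + 1]
        xi_sum <- xi_sum + xi
      }
      gx2 <- gx2 + colSums(gam * outer(x, mu, "-")^2)
    }
    if (!is.finite(ll)) stop("non-finite log-likelihood")
    mu_new <- gx / g_sum
    sigma_new <- sqrt(pmax(gx2 / g_sum, sd_floor^2))
    if (any(!is.finite(mu_new)) || any(!is.finite(sigma_new)))
      stop("degenerate state")
    mu <- mu_new; sigma <- sigma_new
    trans <- xi_sum / rowSums(xi_sum)
    trans[!is.finite(trans)] <- 1 / K
    init <- init_sum / sum(init_sum)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, trans = trans, init = init,
       loglik = ll, n_iter = n_iter)
}

#' @rdname fit_gaussian_hmm
#' @param model a fitted `gaussian_hmm`.
#' @param x numeric sequence to decode; `NA` values are treated as missing
#'   emissions (every state equally likely), so the path stays continuous
#'   across masked bins.
#' @export
viterbi_decode <- function(model, x) {
  K <- length(model$mu)
  n <- length(x)
  if (n == 0L) return(integer(0))
  logB <- vapply(seq_len(K),
                 function(k) dnorm(x, model$mu[k], model$sigma[k], log = TRUE),
                 numeric(n))
  logB <- matrix(logB, n, K)
  logB[is.na(logB)] <- 0
  logT <- log(pmax(model$trans, 1e-300))
  v <- matrix(-Inf, n, K); ptr <- matrix(0L, n, K)
  v[1, ] <- log(pmax(model$init, 1e-300)) + logB[1, ]
  if (n > 1) for (t in 2:n) {
    for (k in seq_len(K)) {
      cand <- v[t - 1, ] + logT[, k]
      ptr[t, k] <- which.max(cand)
      v[t, k] <- cand[ptr[t, k]] + logB[t, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
  path
}
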