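# One-dimensional Gaussian mixture with known per-observation variances.
#
# Model: x_i | component k ~ Normal(mu_k, s_i^2), with s_i^2 fixed from each
# projected QTL's CI width (not re-estimated). EM:
#   E: r_ik  propto  pi_k * phi(x_i; mu_k, s_i^2)
#   M: mu_k = sum_i r_ik x_i / s_i^2  /  sum_i r_ik / s_i^2
#      pi_k = mean_i r_ik
# Free parameters p = 2K - 1 (K means + K-1 proportions).

#' Fit a 1-D Gaussian mixture with known observation variances
#'
#' EM with deterministic-seeded multiple restarts (quantile seeding plus
#' jitter); convergence when the log-likelihood improves by less than `tol`
#' or after `max_iter` iterations. Components are returned sorted by mean.
#'
#' @param x observed positions (cM).
#' @param s2 known observation variances (cM^2), same length as `x`.
#' @param K number of components (1 <= K <= length(x)).
#' @param n_restarts number of EM initializations (the first is plain
#'   quantile seeding, the rest add jitter).
#' @param seed integer seed controlling restart jitter.
#' @param tol,max_iter EM stopping rule.
#' @return an object of class `qtl_mixture`: fields `K`, `mu`, `pi`,
#'   `loglik`, `loglik_trace`, `resp` (n x K responsibilities), `criteria`
#'   (AIC, AICc, AIC3, BIC, AWE), `df` (free parameters), `n`, `converged`.
#' @export
fit_qtl_mixture <- function(x, s2, K, n_restarts = 5, seed = 1,
                            tol = 1e-8, max_iter = 500) {
  n <- length(x)
  if (length(s2) != n) {
    stop_metaqtl("metaqtl_input_error", "x and s2 lengths differ")
  }
  if (!all(is.finite(x)) || !all(is.finite(s2))) {
    stop_metaqtl("metaqtl_input_error", "non-finite input")
  }
  if (any(s2 <= 0)) {
    stop_metaqtl("metaqtl_input_error", "all variances must be positive")
  }
  if (K < 1 || K > n) {
    stop_metaqtl("metaqtl_input_error", "K must satisfy 1 <= K <= n")
  }
  best <- NULL
  base_mu <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K,
                             names = FALSE, type = 7)
  jitter_sd <- if (n > 1) max(stats::sd(x), 1e-3) / K else 1e-3
  for (r in seq_len(n_restarts)) {
    mu0 <- if (r == 1) base_mu else {
      set.seed(derive_seed(seed, r))
      base_mu + stats::rnorm(K, 0, jitter_sd)
    }
    fit <- em_known_var(x, s2, sort(mu0), tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik + 1e-12) best <- fit
  }
  ord <- order(best$mu)
  mu <- best$mu[ord]
  pi_k <- best$pi[ord]
  resp <- best$resp[, ord, drop = FALSE]
  p <- 2 * K - 1
  ll <- best$loglik
  hard <- max.col(resp, ties.method = "first")
  # classification log-likelihood under hard max-posterior assignment
  ll_c <- sum(log(pi_k[hard]) +
                stats::dnorm(x, mu[hard], sqrt(s2), log = TRUE))
  criteria <- c(
    AIC = -2 * ll + 2 * p,
    AICc = if (n > p + 1) -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1)
           else Inf,
    AIC3 = -2 * ll + 3 * p,
    BIC = -2 * ll + p * log(n),
    AWE = -2 * ll_c + 2 * p * (3 / 2 + log(n))
  )
  structure(list(K = K, mu = mu, pi = pi_k, loglik = ll,
                 loglik_trace = best$trace, resp = resp,
                 criteria = criteria, df = p, n = n,
                 converged = best$converged, x = x, s2 = s2),
            class = "qtl_mixture")
}

em_known_var <- function(x, s2, mu, tol, max_iter) {
  n <- length(x); K <- length(mu)
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step in log space for numerical stability
    logd <- vapply(seq_len(K), function(k)
      log(pi_k[k]) + stats::dnorm(x, mu[k], sqrt(s2), log = TRUE),
      numeric(n))
    logd <- matrix(logd, nrow = n)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logd - lse)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    # M-step: precision-weighted means
    w <- resp / s2
    denom <- colSums(w)
    mu <- ifelse(denom > 0, colSums(w * x) / denom, mu)
    pi_k <- pmax(colMeans(resp), 1e-12)
    pi_k <- pi_k / sum(pi_k)
  }
  list(mu = mu, pi = pi_k, resp = resp, loglik = ll, trace = trace,
       converged = converged)
}

#' @export
print.qtl_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture (known variances): K = %d, n = %d\n",
              x$K, x$n))
  cat(sprintf("  logLik %.4f (%s)\n", x$loglik,
              if (x$converged) "converged" else "not converged"))
  tab <- data.frame(component = seq_len(x$K), mu = round(x$mu, 4),
                    pi = round(x$pi, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.qtl_mixture <- function(object, ...) {
  list(mu = object$mu, pi = object$pi)
}

#' @export
logLik.qtl_mixture <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
predict.qtl_mixture <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(max.col(object$resp, ties.method = "first"))
  x <- newdata$x; s2 <- newdata$s2
  logd <- vapply(seq_len(object$K), function(k)
    log(object$pi[k]) + stats::dnorm(x, object$mu[k], sqrt(s2), log = TRUE),
    numeric(length(x)))
  max.col(matrix(logd, nrow = length(x)), ties.method = "first")
}

#' Choose the number of mixture components by five-criterion vote
#'
#' Each of AIC, AICc, AIC3, BIC and AWE votes for the K minimizing it. The
#' model chosen is the K winning at least three of the five criteria; if no
#' K reaches three votes, the K with the most votes wins, ties resolved
#' toward the smaller K.
#'
#' @param fits list of `qtl_mixture` fits of the same data for K = 1, 2, ...
#' @return list with `K` (chosen component count), `votes` (named integer
#'   vector) and `criteria` (matrix, criteria x K).
#' @export
select_model <- function(fits) {
  if (!length(fits)) stop_metaqtl("metaqtl_input_error", "empty fit list")
  Ks <- vapply(fits, function(f) f$K, integer(1))
  fits <- fits[order(Ks)]
  Ks <- sort(Ks)
  crit <- vapply(fits, function(f) f$criteria, numeric(5))
  crit <- matrix(crit, nrow = 5,
                 dimnames = list(c("AIC", "AICc", "AIC3", "BIC", "AWE"), Ks))
  winners <- Ks[apply(crit, 1, which.min)]
  votes <- vapply(Ks, function(k) sum(winners == k), integer(1))
  names(votes) <- Ks
  chosen <- if (any(votes >= 3)) {
    Ks[votes >= 3][1]
  } else {
    Ks[votes == max(votes)][1]     # most votes, ties -> smaller K
  }
  list(K = chosen, votes = votes, criteria = crit, winners = winners)
}
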