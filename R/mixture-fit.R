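# Two-component mixture model on the normalized parapodial elevation
# angle. The observed angle distribution is bimodal (low-angle vs
# wide-angle responses); a finite mixture of Gaussians truncated to
# [0, 1] is fitted by EM and the class cutoff is the equal-posterior
# point between the component means (the published cutoff is 0.4).

#' Truncated-Gaussian density on [0, 1]
#' @noRd
dtnorm01 <- function(x, mean, sd) {
  z <- pnorm(1, mean, sd) - pnorm(0, mean, sd)
  out <- dnorm(x, mean, sd) / z
  out[x < 0 | x > 1] <- 0
  out
}

#' @noRd
mixture_loglik <- function(x, w, mu, sigma) {
  sum(log(w[1] * dtnorm01(x, mu[1], sigma[1]) +
            w[2] * dtnorm01(x, mu[2], sigma[2])))
}

#' Single EM fit (no bootstrap); returns parameters ordered by mean
#' @noRd
em_fit <- function(x, max_iter = 500, tol = 1e-8) {
  # initialization from the two extreme quartiles
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- c(mean(x[x <= q[1]]), mean(x[x >= q[2]]))
  if (!is.finite(mu[1])) mu[1] <- q[1]
  if (!is.finite(mu[2])) mu[2] <- q[2]
  if (diff(mu) < 1e-3) mu <- mu + c(-5e-4, 5e-4)
  sigma <- rep(max(sd(x) / 2, 0.02), 2)
  w <- c(0.5, 0.5)

  ll_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dtnorm01(x, mu[1], sigma[1])
    d2 <- w[2] * dtnorm01(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot <= 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    w <- c(mean(r1), mean(r2))
    # weighted truncated-normal MLE has no closed form: conditional
    # maximization by box-constrained quasi-Newton (a generalized EM step)
    for (k in 1:2) {
      r <- if (k == 1) r1 else r2
      nll <- function(par) {
        dk <- dtnorm01(x, par[1], par[2])
        dk[dk <= 0] <- .Machine$double.xmin
        -sum(r * log(dk))
      }
      fit <- optim(c(mu[k], sigma[k]), nll, method = "L-BFGS-B",
                   lower = c(0, 1e-3), upper = c(1, 2))
      mu[k] <- fit$par[1]; sigma[k] <- fit$par[2]
    }
    ll <- mixture_loglik(x, w, mu, sigma)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {  # order components by mean
    mu <- rev(mu); sigma <- rev(sigma); w <- rev(w)
  }
  list(weights = w, means = mu, sds = sigma, loglik = ll_old,
       n_iter = it, converged = converged)
}

#' Equal-posterior cutoff between the two component means
#' @noRd
mixture_cutoff <- function(fit) {
  h <- function(c) fit$weights[1] * dtnorm01(c, fit$means[1], fit$sds[1]) -
    fit$weights[2] * dtnorm01(c, fit$means[2], fit$sds[2])
  lo <- fit$means[1] + 1e-9; hi <- fit$means[2] - 1e-9
  if (hi <= lo) return(mean(fit$means))
  if (sign(h(lo)) == sign(h(hi))) return(mean(fit$means))
  uniroot(h, c(lo, hi), tol = 1e-10)$root
}

#' Fit a two-component truncated-Gaussian mixture to normalized angles
#'
#' Classifies the bimodal normalized elevation-angle distribution into a
#' low-angle and a wide-angle component. The fit is by
#' expectation-maximization (conditional maximization of the truncated
#' component likelihoods); the reported cutoff is the angle between the
#' two component means at which the posterior component probabilities are
#' equal, and its 95% interval comes from a nonparametric bootstrap. When
#' `larva_id` is supplied the bootstrap resamples larvae (cluster
#' bootstrap), since trials within a larva are dependent.
#'
#' @param x Normalized angles in \[0, 1\] (n >= 20).
#' @param n_boot Bootstrap refits for the cutoff interval (default 1000;
#'   0 skips the interval).
#' @param rng_seed Integer seed for the bootstrap.
#' @param larva_id Optional vector of larva identifiers, same length as
#'   `x`, enabling the cluster bootstrap.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return An object of class `mixture_fit`: `weights`, `means`, `sds`
#'   (component order is by mean), `cutoff`, `cutoff_ci`, `loglik`,
#'   `n_iter`, `converged`, `n`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(100, 0.2, 0.05), rnorm(100, 0.8, 0.05))
#' x <- pmin(pmax(x, 0), 1)
#' fit <- fit_mixture(x, n_boot = 50, rng_seed = 1)
#' fit$means; fit$cutoff
#' @export
fit_mixture <- function(x, n_boot = 1000, rng_seed = 1L, larva_id = NULL,
                        max_iter = 500, tol = 1e-8) {
  x <- x[!is.na(x)]
  if (length(x) < 20) stopf("at least 20 angle values are required")
  if (any(x < 0 | x > 1)) stopf("normalized angles must lie in [0, 1]")
  fit <- em_fit(x, max_iter = max_iter, tol = tol)
  if (!fit$converged)
    warnf("EM did not converge within %d iterations; best fit returned", max_iter)
  cutoff <- mixture_cutoff(fit)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(rng_seed)
    boots <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      xb <- if (is.null(larva_id)) {
        sample(x, replace = TRUE)
      } else {
        ids <- unique(larva_id)
        take <- sample(ids, replace = TRUE)
        unlist(lapply(take, function(i) x[larva_id == i]))
      }
      if (length(xb) < 20) { boots[b] <- NA_real_; next }
      fb <- suppressWarnings(em_fit(xb, max_iter = max_iter, tol = tol))
      boots[b] <- mixture_cutoff(fb)
    }
    ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }

  structure(list(weights = fit$weights, means = fit$means, sds = fit$sds,
                 cutoff = cutoff, cutoff_ci = ci, loglik = fit$loglik,
                 n_iter = fit$n_iter, converged = fit$converged,
                 n = length(x), n_boot = n_boot),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<mixture_fit> n = %d\n",
    "  components: %.2f * TN(%.3f, %.3f) + %.2f * TN(%.3f, %.3f)\n",
    "  cutoff: %.3f"), x$n,
    x$weights[1], x$means[1], x$sds[1],
    x$weights[2], x$means[2], x$sds[2], x$cutoff))
  if (!is.na(x$cutoff_ci[1]))
    cat(sprintf("  (95%% CI %.3f-%.3f, %d bootstrap refits)",
                x$cutoff_ci[1], x$cutoff_ci[2], x$n_boot))
  cat(sprintf("\n  loglik %.2f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
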