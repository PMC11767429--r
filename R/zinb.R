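#' Zero-inflated negative binomial distribution
#'
#' Density and random generation for the ZINB mixture: with probability
#' `pi` a structural zero, otherwise a negative binomial with mean `mu`
#' and dispersion `theta` (variance `mu + mu^2/theta`).
#'
#' @param x Vector of non-negative integers.
#' @param n Number of draws.
#' @param pi Zero-inflation probability in `[0, 1]`.
#' @param mu Negative binomial mean, positive.
#' @param theta Negative binomial dispersion, positive.
#' @param log Return log-density?
#' @return `dzinb` a density vector; `rzinb` an integer vector.
#' @export
dzinb <- function(x, pi, mu, theta, log = FALSE) {
  stopifnot(pi >= 0, pi <= 1, mu > 0, theta > 0)
  nb <- stats::dnbinom(x, size = theta, mu = mu)
  d <- (1 - pi) * nb + pi * (x == 0)
  if (log) base::log(d) else d
}

#' @rdname dzinb
#' @export
rzinb <- function(n, pi, mu, theta) {
  stopifnot(pi >= 0, pi <= 1, mu > 0, theta > 0)
  y <- stats::rnbinom(n, size = theta, mu = mu)
  y[stats::runif(n) < pi] <- 0L
  y
}

#' Fit a zero-inflated negative binomial by maximum likelihood
#'
#' EM over the latent structural-zero indicator: the E-step computes, for
#' each observed zero, the posterior probability of being structural; the
#' M-step updates `pi` from those posteriors and refits the negative
#' binomial on fractionally weighted data. Values are rounded to the
#' nearest integer for likelihood evaluation, so normalized count tables
#' can be fed directly.
#'
#' @param y Vector of non-negative reals, length at least 8.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return An object of class `zinb_fit`: list with `pi`, `mu`, `theta`,
#'   `loglik`, `n`, `iterations`, `boundary` (TRUE for the all-zero
#'   degenerate input, reported as `pi = 1`) and `converged`.
#' @export
fit_zinb <- function(y, max_iter = 200L, tol = 1e-8) {
  if (!is.numeric(y) || anyNA(y)) stop("y must be numeric without NA")
  if (any(y < 0)) stop("y contains negative values")
  if (length(y) < 8L) stop("need at least 8 observations")
  y <- round(y)
  n <- length(y)
  if (all(y == 0)) {
    return(structure(list(pi = 1, mu = 1, theta = 1, loglik = 0, n = n,
                          iterations = 0L, boundary = TRUE, converged = TRUE),
                     class = "zinb_fit"))
  }
  is0 <- y == 0
  pi <- 0.5 * mean(is0)
  mu <- max(mean(y) / max(1 - pi, 1e-6), 1e-3)
  theta <- 1
  obs_ll <- function(pi, mu, theta)
    sum(dzinb(y, pi, mu, theta, log = TRUE))
  wnll <- function(par, w) { # weighted NB negative loglik on (log mu, log theta)
    mu <- exp(par[1L]); th <- exp(par[2L])
    if (!is.finite(mu) || !is.finite(th) || mu <= 0 || th <= 0) return(1e10)
    -sum(w * stats::dnbinom(y, size = th, mu = mu, log = TRUE))
  }
  ll <- obs_ll(pi, mu, theta)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: posterior structural-zero probability for observed zeros
    p0 <- stats::dnbinom(0, size = theta, mu = mu)
    tau <- ifelse(is0, pi / (pi + (1 - pi) * p0), 0)
    # M-step
    pi <- mean(tau)
    w <- 1 - tau
    opt <- stats::optim(c(log(mu), log(theta)), wnll, w = w,
                        method = "Nelder-Mead",
                        control = list(maxit = 500L))
    mu <- exp(opt$par[1L]); theta <- exp(opt$par[2L])
    ll_new <- obs_ll(pi, mu, theta)
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  # joint polish of the EM solution on the observed likelihood
  nll_joint <- function(par) {
    pp <- stats::plogis(par[1L]); mm <- exp(par[2L]); tt <- exp(par[3L])
    if (!is.finite(mm) || !is.finite(tt) || mm <= 0 || tt <= 0) return(1e10)
    v <- -obs_ll(pp, mm, tt)
    if (!is.finite(v)) 1e10 else v
  }
  start <- c(stats::qlogis(min(max(pi, 1e-8), 1 - 1e-8)), log(mu), log(theta))
  opt <- tryCatch(stats::optim(start, nll_joint, method = "BFGS",
                               control = list(maxit = 500L,
                                              reltol = 1e-12)),
                  error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) && -opt$value >= ll) {
    pi <- stats::plogis(opt$par[1L])
    mu <- exp(opt$par[2L]); theta <- exp(opt$par[3L])
    ll <- -opt$value
  }
  structure(list(pi = pi, mu = mu, theta = theta, loglik = ll, n = n,
                 iterations = iter, boundary = FALSE, converged = converged),
            class = "zinb_fit")
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat(sprintf("ZINB fit (n = %d): pi = %.4f, mu = %.3f, theta = %.3f, loglik = %.2f%s\n",
              x$n, x$pi, x$mu, x$theta, x$loglik,
              if (x$boundary) " [boundary: all zeros]" else ""))
  invisible(x)
}
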