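#' Fit a two-component univariate normal mixture by EM
#'
#' Classic EM for a 2-component Gaussian mixture, the device used both to
#' separate marked from unmarked TSSs (bimodal TSS-region signal) and to
#' split each breadth axis into its "extended" and "not extended"
#' components. Initialization splits the data at the median; additional
#' restarts use jittered quantile splits. Components are returned ordered by
#' ascending mean and the log-likelihood trace is recorded (it is
#' non-decreasing by construction of EM).
#'
#' @param x Numeric vector (at least 10 finite values).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param restarts Number of restarts before giving up on a degenerate fit.
#' @param seed Integer seed controlling restart jitter.
#' @param sd_floor Minimal component standard deviation; a fit collapsing
#'   below it is declared degenerate.
#' @return List of class `"gmm2"`: `weights`, `means`, `sds`, `posterior`
#'   (probability of the upper component per point), `loglik` (trace),
#'   `n_iter`, `converged`.
#' @export
fit_gmm2 <- function(x, tol = 1e-8, max_iter = 1000L, restarts = 5L,
                     seed = 1L, sd_floor = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 10L) stop("need at least 10 finite values")
  sx <- stats::sd(x)
  if (!is.finite(sx) || sx == 0) stop("degenerate fit: all values identical")
  if (is.null(sd_floor)) sd_floor <- 1e-6 * sx

  run_em <- function(split_q) {
    s <- stats::quantile(x, split_q, names = FALSE)
    lower <- x <= s
    if (!any(lower) || all(lower)) return(NULL)
    mu <- c(mean(x[lower]), mean(x[!lower]))
    sig <- pmax(c(stats::sd(x[lower]), stats::sd(x[!lower])), sd_floor,
                na.rm = TRUE)
    sig[is.na(sig)] <- sx
    w <- c(mean(lower), 1 - mean(lower))
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      l1 <- log(w[1]) + stats::dnorm(x, mu[1], sig[1], log = TRUE)
      l2 <- log(w[2]) + stats::dnorm(x, mu[2], sig[2], log = TRUE)
      m <- pmax(l1, l2)
      ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
      ll_trace <- c(ll_trace, ll)
      g2 <- 1 / (1 + exp(l1 - l2))
      g1 <- 1 - g2
      w <- c(mean(g1), mean(g2))
      mu <- c(sum(g1 * x) / sum(g1), sum(g2 * x) / sum(g2))
      sig <- sqrt(c(sum(g1 * (x - mu[1])^2) / sum(g1),
                    sum(g2 * (x - mu[2])^2) / sum(g2)))
      if (any(!is.finite(sig)) || any(sig < sd_floor) ||
          any(!is.finite(mu)) || any(w < 1e-12)) {
        return(NULL)
      }
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
        break
      }
      ll_old <- ll
    }
    # posteriors consistent with the final parameter estimates
    l1 <- log(w[1]) + stats::dnorm(x, mu[1], sig[1], log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(x, mu[2], sig[2], log = TRUE)
    g2 <- 1 / (1 + exp(l1 - l2))
    g1 <- 1 - g2
    ord <- order(mu)
    post2 <- if (ord[1] == 1L) g2 else g1
    list(weights = w[ord], means = mu[ord], sds = sig[ord],
         posterior = post2, loglik = ll_trace,
         n_iter = length(ll_trace), converged = it < max_iter)
  }

  set.seed(seed)
  splits <- c(0.5, stats::runif(restarts - 1L, 0.2, 0.8))
  for (q in splits) {
    fit <- run_em(q)
    if (!is.null(fit)) {
      class(fit) <- "gmm2"
      return(fit)
    }
  }
  stop("degenerate fit: mixture collapsed in all ", restarts, " restarts")
}

#' @export
print.gmm2 <- function(x, ...) {
  cat(sprintf(
    "2-component normal mixture: w = (%.3f, %.3f), mu = (%.3f, %.3f), sd = (%.3f, %.3f)\n",
    x$weights[1], x$weights[2], x$means[1], x$means[2], x$sds[1], x$sds[2]
  ))
  cat(sprintf("  %d EM iterations, logLik %.3f\n", x$n_iter, utils::tail(x$loglik, 1)))
  invisible(x)
}

#' Posterior probability of the upper mixture component
#'
#' @param fit A [fit_gmm2()] result.
#' @param x New values (defaults to returning the fitted posteriors).
#' @return Numeric vector in `[0, 1]`.
#' @export
posterior_gmm2 <- function(fit, x = NULL) {
  if (is.null(x)) return(fit$posterior)
  l1 <- log(fit$weights[1]) + stats::dnorm(x, fit$means[1], fit$sds[1], log = TRUE)
  l2 <- log(fit$weights[2]) + stats::dnorm(x, fit$means[2], fit$sds[2], log = TRUE)
  1 / (1 + exp(l1 - l2))
}

#' Select H3K4me3-marked TSSs
#'
#' A TSS is marked when its TSS-region mean belongs to the upper component
#' of the marked/unmarked mixture with posterior at least `confidence`.
#'
#' @param fit Mixture fit on the TSS-region means.
#' @param values The TSS-region means (defaults to the fitted data order).
#' @param confidence Posterior threshold.
#' @return Logical vector of marked flags.
#' @export
select_marked <- function(fit, values = NULL, confidence = 0.95) {
  posterior_gmm2(fit, values) >= confidence
}
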