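#' Two-component Gaussian mixture by expectation-maximization
#'
#' Fits `w0 * N(mu0, sd0) + w1 * N(mu1, sd1)` to a 1-D sample by standard EM:
#' posterior responsibilities in the E-step, weighted means, variances and
#' weights in the M-step. Initialization is a deterministic median split with
#' moment matching of each half, so the fit is reproducible without a seed;
#' optional random restarts (seeded) guard against local optima. Components
#' are relabeled so `mu0 <= mu1`. The log-likelihood trace is monotone
#' non-decreasing.
#'
#' @param values numeric vector, at least 10 finite values.
#' @param tol stop when the log-likelihood improves by less than this.
#' @param max_iter iteration cap.
#' @param variance_floor lower bound on component variances; when both
#'   variances stay pinned at the floor the fit is flagged as collapsed
#'   (`converged = FALSE`). One pinned component is allowed: scores with a
#'   point mass (e.g. a spike of exact zeros) deconvolve into a spike null
#'   plus a spread signal component.
#' @param restarts number of additional random-start EM runs; the best
#'   log-likelihood wins.
#' @param seed RNG seed used only for the random restarts.
#' @return an object of class `mixture_fit`: `weights`, `means`, `sds`,
#'   `loglik` (final), `loglik_trace`, `n_iter`, `converged`, `n`.
#' @export
fit_gaussian_mixture <- function(values, tol = 1e-8, max_iter = 1000L,
                                 variance_floor = 1e-6, restarts = 0L,
                                 seed = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 10L) stop("need at least 10 finite values", call. = FALSE)

  run_em <- function(w, mu, v) {
    sd_floor <- sqrt(variance_floor)
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      sd0 <- pmax(sqrt(v), sd_floor)
      l0 <- log(w[1]) + stats::dnorm(x, mu[1], sd0[1], log = TRUE)
      l1 <- log(w[2]) + stats::dnorm(x, mu[2], sd0[2], log = TRUE)
      m <- pmax(l0, l1)
      lse <- m + log(exp(l0 - m) + exp(l1 - m))
      ll <- sum(lse)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && (ll - ll_old) < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ll_old <- ll
      r1 <- exp(l1 - lse)
      r0 <- 1 - r1
      n0 <- sum(r0); n1 <- sum(r1)
      if (n0 < 1e-12 || n1 < 1e-12) break  # a component lost all mass
      w <- c(n0, n1) / length(x)
      mu <- c(sum(r0 * x) / n0, sum(r1 * x) / n1)
      v <- c(sum(r0 * (x - mu[1])^2) / n0, sum(r1 * (x - mu[2])^2) / n1)
      v <- pmax(v, variance_floor)
    }
    # collapse = the whole fit degenerates (e.g. all values identical). A
    # single variance pinned at the floor with a healthy second component is a
    # legitimate deconvolution of a zero-inflated score and is kept.
    collapsed <- all(v <= variance_floor * (1 + 1e-9))
    list(w = w, mu = mu, sd = pmax(sqrt(v), sd_floor), loglik = ll,
         trace = trace, n_iter = iter, converged = converged && !collapsed)
  }

  med_init <- function() {
    med <- stats::median(x)
    lo <- x[x <= med]; hi <- x[x > med]
    if (length(hi) == 0L) hi <- lo  # all values at/below the median (ties)
    mu <- c(mean(lo), mean(hi))
    v <- pmax(c(stats::var(lo), stats::var(hi)), variance_floor)
    v[is.na(v)] <- variance_floor
    list(w = c(0.5, 0.5), mu = mu, v = v)
  }

  inits <- list(med_init())
  if (restarts > 0L) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(restarts)) {
      mu <- sort(sample(x, 2L))
      inits[[i + 1L]] <- list(w = c(0.5, 0.5), mu = mu,
                              v = rep(max(stats::var(x) / 4, variance_floor), 2L))
    }
  }
  fits <- lapply(inits, function(ini) run_em(ini$w, ini$mu, ini$v))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]

  ord <- order(best$mu)
  structure(list(weights = best$w[ord], means = best$mu[ord],
                 sds = best$sd[ord], loglik = best$loglik,
                 loglik_trace = best$trace, n_iter = best$n_iter,
                 converged = best$converged, n = length(x)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> w = (%.3f, %.3f), mu = (%.3f, %.3f), sd = (%.3f, %.3f)\n",
    x$weights[1], x$weights[2], x$means[1], x$means[2], x$sds[1], x$sds[2]))
  cat(sprintf("  loglik %.3f after %d iter (converged: %s, n = %d)\n",
              x$loglik, x$n_iter, x$converged, x$n))
  invisible(x)
}

#' Mixture density and FDR curve
#'
#' The local false discovery proportion above a cutoff `t`, treating the
#' lower-mean component as the null (ligand-like) population:
#' `FDR(t) = w0 S0(t) / (w0 S0(t) + w1 S1(t))` with `S_k` the upper-tail
#' Gaussian survival functions. Computed in log space for tail stability.
#'
#' @param fit a converged [fit_gaussian_mixture()].
#' @param t cutoff value(s).
#' @return FDR(t) in \[0, 1\].
#' @export
mixture_fdr <- function(fit, t) {
  ls0 <- log(fit$weights[1]) +
    stats::pnorm(t, fit$means[1], fit$sds[1], lower.tail = FALSE, log.p = TRUE)
  ls1 <- log(fit$weights[2]) +
    stats::pnorm(t, fit$means[2], fit$sds[2], lower.tail = FALSE, log.p = TRUE)
  m <- pmax(ls0, ls1)
  out <- exp(ls0 - (m + log(exp(ls0 - m) + exp(ls1 - m))))
  out[!is.finite(out)] <- 0  # both tails numerically empty
  out
}

#' FDR-controlled score threshold from a fitted mixture
#'
#' Smallest cutoff `t` at which the mixture-model FDR among values above `t`
#' is at most `alpha`, solved by bisection over
#' `[mu0 - 6 sd0, mu1 + 6 sd1]` (FDR decreases monotonically through the
#' inter-mode region). Returns `+Inf` when no cutoff attains `alpha` (nothing
#' callable) and `-Inf` when every cutoff does.
#'
#' @param fit a converged [fit_gaussian_mixture()].
#' @param alpha FDR level in (0, 1\]; default 0.05.
#' @return the threshold `t` (possibly infinite).
#' @export
fdr_threshold <- function(fit, alpha = 0.05) {
  if (!isTRUE(fit$converged)) stop("mixture fit did not converge", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (fit$weights[2] <= 0) return(Inf)
  lo <- fit$means[1] - 6 * fit$sds[1]
  hi <- fit$means[2] + 6 * fit$sds[2]
  if (mixture_fdr(fit, lo) <= alpha) return(-Inf)
  if (mixture_fdr(fit, hi) > alpha) return(Inf)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mixture_fdr(fit, mid) <= alpha) hi <- mid else lo <- mid
    if (hi - lo < 1e-12) break
  }
  hi
}
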