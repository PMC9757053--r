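# Row-wise log-sum-exp, guarded against -Inf rows.
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Deterministic (seedless) initialization: two components are started from
#' both a split of the data at its median and a nearest-center assignment to
#' the 10th/90th percentiles (the split at the median can trap EM in a local
#' optimum when the components are very unbalanced), keeping the fit with
#' the higher final log-likelihood; k components in general start from the
#' means at equally spaced quantiles (for three components the
#' 10th/50th/90th percentiles). Component standard deviations are floored at
#' `sd_floor_frac` times the overall sd so the likelihood cannot blow up on a
#' collapsing component; the log-likelihood is non-decreasing across
#' iterations up to that guard.
#'
#' @param x Numeric vector of observations (finite).
#' @param k Number of components.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param sd_floor_frac Component-sd floor as a fraction of `sd(x)`.
#' @return Object of class `"gaussian_mixture"`: list with `means`, `sds`,
#'   `lambda` (all ordered by increasing mean), `loglik`, `loglik_trace`,
#'   `iterations`, `converged`, `sd_floored`.
#' @export
gaussian_mixture_em <- function(x, k, tol = 1e-8, max_iter = 500,
                                sd_floor_frac = 1e-3) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2 * k) stop("too few observations for a ", k, "-component mixture")
  s_all <- stats::sd(x)
  if (s_all == 0) stop("zero variance; mixture unfit")
  floor_sd <- sd_floor_frac * s_all

  init_from_groups <- function(grp) {
    mu <- vapply(split(x, grp), mean, numeric(1))
    sds <- vapply(split(x, grp), stats::sd, numeric(1))
    sds[is.na(sds) | sds < floor_sd] <- s_all
    list(mu = unname(mu), sds = unname(sds),
         lambda = unname(table(grp)) / n)
  }
  inits <- if (k == 2) {
    q <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
    list(init_from_groups(x > stats::median(x)),
         init_from_groups(abs(x - q[1]) > abs(x - q[2])))
  } else {
    probs <- seq(0.1, 0.9, length.out = k)
    mu <- as.numeric(stats::quantile(x, probs, names = FALSE))
    if (any(duplicated(mu))) mu <- mu + seq_len(k) * 1e-6 * s_all
    list(list(mu = mu, sds = rep(s_all, k), lambda = rep(1 / k, k)))
  }

  run_em <- function(init) {
    mu <- init$mu
    sds <- init$sds
    lambda <- as.numeric(init$lambda)
    ll_old <- -Inf
    trace <- numeric(0)
    floored <- FALSE
    for (it in seq_len(max_iter)) {
      logp <- vapply(seq_len(k), function(j) {
        log(lambda[j]) + stats::dnorm(x, mu[j], sds[j], log = TRUE)
      }, numeric(n))
      lse <- row_logsumexp(logp)
      ll <- sum(lse)
      trace <- c(trace, ll)
      gamma <- exp(logp - lse)
      nk <- pmax(colSums(gamma), 1e-12)
      lambda <- nk / n
      mu <- colSums(gamma * x) / nk
      sds <- sqrt(colSums(gamma * (x - rep(mu, each = n))^2) / nk)
      if (any(sds < floor_sd)) {
        floored <- TRUE
        sds <- pmax(sds, floor_sd)
      }
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(mu = mu, sds = sds, lambda = lambda, trace = trace,
         floored = floored)
  }

  fits <- lapply(inits, run_em)
  best <- fits[[which.max(vapply(fits, function(f)
    f$trace[length(f$trace)], numeric(1)))]]
  if (best$floored)
    warning("component sd floored at ", signif(floor_sd, 3),
            " (near-degenerate component)")
  ord <- order(best$mu)
  trace <- best$trace
  structure(list(means = best$mu[ord], sds = best$sds[ord],
                 lambda = best$lambda[ord],
                 loglik = trace[length(trace)], loglik_trace = trace,
                 iterations = length(trace),
                 converged = length(trace) < max_iter,
                 sd_floored = best$floored),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat("Gaussian mixture,", length(x$means), "components\n")
  print(data.frame(mean = x$means, sd = x$sds, lambda = x$lambda))
  cat("log-likelihood:", format(x$loglik), "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Posterior component memberships under a fitted mixture
#'
#' @param x Numeric vector of observations.
#' @param fit A `"gaussian_mixture"` fit.
#' @return Matrix, `length(x)` rows by `k` columns (ordered by component
#'   mean), rows summing to 1.
#' @export
mixture_posteriors <- function(x, fit) {
  k <- length(fit$means)
  logp <- vapply(seq_len(k), function(j) {
    log(fit$lambda[j]) + stats::dnorm(x, fit$means[j], fit$sds[j], log = TRUE)
  }, numeric(length(x)))
  logp <- matrix(logp, nrow = length(x))
  exp(logp - row_logsumexp(logp))
}

#' Fit the three-status expression mixture for one gene
#'
#' Decomposes a gene's expression values across samples into downregulated,
#' neutral, and upregulated Gaussian components (means ordered low to high).
#' This per-gene observation model is the basis of the regulatory-status
#' posteriors consumed by the hierarchical dysregulation model.
#'
#' A free three-component EM fit is only meaningful when the expression
#' distribution actually is multimodal; on a unimodal gene it fragments the
#' neutral bulk into spurious up/down components and every ordinary sample
#' then looks mildly dysregulated, destroying the calibration of the
#' downstream inference. The fit is therefore guarded by model selection:
#' the three-component fit is kept only when its BIC beats a single
#' Gaussian; otherwise the gene's status model collapses to a robust
#' neutral Gaussian (median location, MAD scale, so that a minority of
#' shifted samples cannot inflate the neutral spread) plus canonical
#' outlier tails placed at `tail_offset` robust standard deviations on
#' either side with `tail_frac` mixing weight each, so that only genuinely
#' outlying expression counts as up- or downregulation.
#'
#' @param values Numeric expression vector (at least 10 finite values with
#'   nonzero variance).
#' @param tail_offset Offset (in robust neutral sd units) of the canonical
#'   down/up components when the single-Gaussian model is selected.
#' @param tail_frac Mixing weight of each canonical tail component.
#' @param ... Passed to [gaussian_mixture_em()].
#' @return Object of class `"status_mixture"`: list with `mu`, `sigma`,
#'   `lambda`, each a length-3 vector named down/neutral/up, a `model`
#'   field (`"mixture"` or `"canonical"`), plus the underlying EM fit.
#' @export
fit_status_mixture <- function(values, tail_offset = 2, tail_frac = 0.05,
                               ...) {
  v <- values[is.finite(values)]
  if (length(v) < 10) stop("need at least 10 finite values")
  if (stats::sd(v) == 0) stop("zero variance; status mixture unfit")
  n <- length(v)
  fit <- gaussian_mixture_em(v, k = 3, ...)
  m1 <- mean(v)
  s1 <- stats::sd(v) * sqrt((n - 1) / n)  # ML variance for the BIC
  ll1 <- sum(stats::dnorm(v, m1, s1, log = TRUE))
  bic3 <- -2 * fit$loglik + 8 * log(n)
  bic1 <- -2 * ll1 + 2 * log(n)
  nm <- c("down", "neutral", "up")
  if (bic1 <= bic3) {
    mu_r <- stats::median(v)
    s <- stats::mad(v)
    if (s == 0) s <- stats::sd(v)
    out <- list(mu = stats::setNames(mu_r + c(-1, 0, 1) * tail_offset * s, nm),
                sigma = stats::setNames(rep(s, 3), nm),
                lambda = stats::setNames(c(tail_frac, 1 - 2 * tail_frac,
                                           tail_frac), nm),
                model = "canonical", fit = fit)
  } else {
    out <- list(mu = stats::setNames(fit$means, nm),
                sigma = stats::setNames(fit$sds, nm),
                lambda = stats::setNames(fit$lambda, nm),
                model = "mixture", fit = fit)
  }
  structure(out, class = "status_mixture")
}

#' Regulatory-status posteriors for observed expression values
#'
#' Bayes posteriors of the down/neutral/up components for each value; the
#' gene regulatory status GRS is the posterior probability of being
#' non-neutral, `P(down) + P(up)`.
#'
#' @param y Numeric vector of expression values.
#' @param mix A `"status_mixture"`.
#' @return Matrix with columns `down`, `neutral`, `up` (rows sum to 1) and
#'   attribute `grs` (`1 - P(neutral)`).
#' @export
status_posteriors <- function(y, mix) {
  logp <- vapply(1:3, function(j) {
    log(mix$lambda[j]) + stats::dnorm(y, mix$mu[j], mix$sigma[j], log = TRUE)
  }, numeric(length(y)))
  logp <- matrix(logp, nrow = length(y),
                 dimnames = list(NULL, c("down", "neutral", "up")))
  post <- exp(logp - row_logsumexp(logp))
  attr(post, "grs") <- 1 - post[, "neutral"]
  post
}
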