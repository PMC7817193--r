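# Generic adaptive random-walk Metropolis sampler with standard convergence
# diagnostics. The model contract is diagnostics (split-Rhat, ESS), not a
# particular algorithm; an adaptive RWM is ample for the low-dimensional
# hierarchical posteriors used here.

#' Adaptive random-walk Metropolis sampling
#'
#' Multivariate Gaussian proposals whose covariance is adapted during
#' warmup (Haario-style empirical covariance with Robbins-Monro scale
#' tuning toward 23% acceptance), then frozen for the sampling phase.
#'
#' @param logpost function(theta) -> log posterior density.
#' @param init numeric initial value (names become parameter names).
#' @param n_chains number of chains (>= 2 for split-Rhat).
#' @param warmup,iter warmup and retained iterations per chain.
#' @param seed integer seed.
#' @param init_jitter sd of the per-chain initialization jitter.
#' @param moves optional list of extra symmetric proposal functions
#'   `function(theta) -> theta'` applied after each RWM step (used for
#'   model-specific ridge/recentering moves in hierarchical posteriors).
#' @return list of class `mcmc_draws`: `draws` (iter x chains x params
#'   array), `accept` (per chain).
#' @export
mh_sample <- function(logpost, init, n_chains = 4L, warmup = 1000L, iter = 1000L,
                      seed = 1L, init_jitter = 0.1, moves = NULL,
                      componentwise = TRUE) {
  d <- length(init)
  pn <- names(init)
  if (is.null(pn)) pn <- paste0("theta", seq_len(d))
  set.seed(as.integer(seed))
  draws <- array(NA_real_, dim = c(iter, n_chains, d),
                 dimnames = list(NULL, NULL, pn))
  accept <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    th <- init + stats::rnorm(d, 0, init_jitter)
    lp <- logpost(th)
    if (!is.finite(lp)) { th <- init; lp <- logpost(th) }
    log_s <- log(2.38 / sqrt(d))
    mu <- th; S <- diag(d) * 0.01
    chol_S <- chol(S)
    cw_log_s <- rep(log(0.2), d)
    n_acc <- 0L
    total <- warmup + iter
    for (it in seq_len(total)) {
      prop <- th + exp(log_s) * drop(stats::rnorm(d) %*% chol_S)
      lpp <- logpost(prop)
      a <- lpp - lp
      if (is.finite(lpp) && log(stats::runif(1)) < a) {
        th <- prop; lp <- lpp
        if (it > warmup) n_acc <- n_acc + 1L
      }
      if (componentwise) {
        for (j in seq_len(d)) {
          prop <- th
          prop[j] <- th[j] + exp(cw_log_s[j]) * stats::rnorm(1)
          lppj <- logpost(prop)
          acc <- is.finite(lppj) && log(stats::runif(1)) < lppj - lp
          if (acc) { th <- prop; lp <- lppj }
          if (it <= warmup)
            cw_log_s[j] <- cw_log_s[j] + (1 / sqrt(it + 10)) * ((if (acc) 1 else 0) - 0.44)
        }
      }
      if (!is.null(moves)) {
        for (mv in moves) {
          prop2 <- mv(th)
          logj <- 0
          if (is.list(prop2)) { logj <- prop2$logj; prop2 <- prop2$theta }
          lpp2 <- logpost(prop2)
          if (is.finite(lpp2) && log(stats::runif(1)) < lpp2 - lp + logj) {
            th <- prop2; lp <- lpp2
          }
        }
      }
      if (it <= warmup) {
        w <- 1 / (it + 10)
        log_s <- log_s + w * (min(exp(a), 1, na.rm = TRUE) - 0.234)
        dm <- th - mu
        mu <- mu + w * dm
        S <- S * (1 - w) + w * (dm %o% dm)
        if (it %% 50L == 0L)
          chol_S <- tryCatch(chol(S + diag(d) * 1e-9), error = function(e) chol_S)
      } else {
        draws[it - warmup, ch, ] <- th
      }
    }
    accept[ch] <- n_acc / iter
  }
  structure(list(draws = draws, accept = accept), class = "mcmc_draws")
}

#' Split-Rhat convergence diagnostic
#' @param x iterations x chains matrix of draws for one parameter.
#' @return potential scale reduction factor.
#' @export
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  mns <- colMeans(xs)
  B <- nn * stats::var(mns)
  W <- mean(apply(xs, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size (initial positive sequence estimator)
#' @param x iterations x chains matrix.
#' @return approximate bulk ESS.
#' @export
ess_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  rho <- sapply(seq_len(m), function(ch) {
    a <- stats::acf(x[, ch], lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
    a
  })
  rho <- rowMeans(matrix(rho, ncol = m))
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0.05) break
    s <- s + rho[k]
  }
  max(m * n / (1 + 2 * s), 1)
}

#' Summarize MCMC draws with credible intervals and diagnostics
#' @param fit an `mcmc_draws` object.
#' @param derived optional named list of functions applied draw-wise to the
#'   parameter vector to produce derived quantities.
#' @return object of class `posterior_summary`: `summary` (data.frame with
#'   mean, 50% and 95% credible intervals, Rhat, ESS), `draws` (matrix of
#'   pooled draws incl. derived columns), `flagged` (TRUE if any
#'   Rhat > 1.05).
#' @export
summarize_draws <- function(fit, derived = NULL) {
  dr <- fit$draws
  pn <- dimnames(dr)[[3]]
  n_it <- dim(dr)[1]; n_ch <- dim(dr)[2]
  if (!is.null(derived)) {
    ext <- array(NA_real_, dim = c(n_it, n_ch, length(pn) + length(derived)),
                 dimnames = list(NULL, NULL, c(pn, names(derived))))
    ext[, , pn] <- dr
    for (nm in names(derived)) for (ch in seq_len(n_ch)) {
      m <- matrix(dr[, ch, ], ncol = length(pn))
      ext[, ch, nm] <- apply(m, 1, derived[[nm]])
    }
    dr <- ext
  }
  all_n <- dimnames(dr)[[3]]
  pooled <- do.call(rbind, lapply(seq_len(n_ch), function(ch)
    matrix(dr[, ch, ], ncol = length(all_n))))
  colnames(pooled) <- all_n
  rows <- lapply(all_n, function(nm) {
    m <- matrix(dr[, , nm], nrow = n_it)
    rh <- split_rhat(m); es <- ess_basic(m)
    q <- stats::quantile(pooled[, nm], c(0.025, 0.25, 0.75, 0.975))
    data.frame(parameter = nm, mean = mean(pooled[, nm]),
               q2.5 = q[1], q25 = q[2], q75 = q[3], q97.5 = q[4],
               rhat = rh, ess = es)
  })
  summary <- do.call(rbind, rows); rownames(summary) <- NULL
  flagged <- any(summary$rhat > 1.05, na.rm = TRUE)
  structure(list(summary = summary, draws = pooled, flagged = flagged,
                 accept = fit$accept),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary>", if (x$flagged) "[NOT CONVERGED: Rhat > 1.05]" else "", "\n")
  print(x$summary, digits = 3)
  invisible(x)
}
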