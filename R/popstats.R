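#' Hierarchical Bayesian Poisson rate model across rats and phases
#'
#' Event counts per (rat, trial-or-cell, phase) with exposure times are
#' modeled as `count ~ Poisson(exposure * rate)` with
#' `log rate = beta[phase] + sigma * z[rat]` (non-centered rat random
#' intercepts, partial pooling). Priors: `beta ~ Normal(0, 1.5)`,
#' `z ~ Normal(0, 1)`, `sigma ~ half-Normal(1)`. The derived quantity
#' `pct_change_<phase>` is the percentage change of each phase's rate
#' versus the reference (first) phase:
#' `100 * (exp(beta_phase - beta_ref) - 1)`.
#'
#' @param data data.frame with columns `rat`, `phase`, `n_events` (counts),
#'   `exposure_s` (> 0).
#' @param ref_phase reference phase (default the first factor level;
#'   `"pre"` if present).
#' @param n_chains,warmup,iter MCMC settings.
#' @param seed integer seed.
#' @return a `posterior_summary` (see [summarize_draws()]) with elements
#'   `phases` and `ref_phase` attached. Non-convergence (any Rhat > 1.05)
#'   sets `$flagged` and emits a warning, never silently.
#' @export
fit_rate_model <- function(data, ref_phase = NULL, n_chains = 4L,
                           warmup = 800L, iter = 800L, seed = 1L) {
  stopifnot(all(c("rat", "phase", "n_events", "exposure_s") %in% names(data)))
  if (any(data$exposure_s <= 0)) stop("exposure must be positive")
  if (any(data$n_events < 0)) stop("counts must be non-negative")
  phases <- unique(as.character(data$phase))
  if (is.null(ref_phase)) ref_phase <- if ("pre" %in% phases) "pre" else phases[1]
  phases <- c(ref_phase, setdiff(phases, ref_phase))
  if (length(phases) < 2L) stop("need at least 2 phases")
  rats <- unique(data$rat)
  n_rats <- length(rats)
  hierarchical <- n_rats >= 2L
  if (!hierarchical)
    warning("single rat: fitting fixed effects only (no partial pooling)")

  # sufficient statistics per (rat, phase)
  agg <- stats::aggregate(cbind(n_events, exposure_s) ~ rat + phase, data, sum)
  ci <- agg$n_events; ei <- agg$exposure_s
  ri <- match(agg$rat, rats); pi_ <- match(as.character(agg$phase), phases)
  K <- length(phases)

  logpost <- function(th) {
    beta <- th[1:K]
    if (hierarchical) {
      z <- th[(K + 1):(K + n_rats)]
      sigma <- exp(th[K + n_rats + 1L])
      lr <- beta[pi_] + sigma * z[ri]
      prior <- sum(stats::dnorm(beta, 0, 1.5, log = TRUE)) +
        sum(stats::dnorm(z, 0, 1, log = TRUE)) +
        stats::dnorm(sigma, 0, 1, log = TRUE) + th[K + n_rats + 1L]
    } else {
      lr <- beta[pi_]
      prior <- sum(stats::dnorm(beta, 0, 1.5, log = TRUE))
    }
    sum(ci * lr - ei * exp(lr)) + prior
  }
  init <- log(pmax(vapply(seq_len(K), function(k)
    sum(ci[pi_ == k]) / sum(ei[pi_ == k]), numeric(1)), 1e-4))
  names(init) <- paste0("beta_", phases)
  if (hierarchical) {
    init <- c(init, stats::setNames(rep(0, n_rats), paste0("z_", rats)),
              log_sigma = log(0.3))
  }
  moves <- NULL
  if (hierarchical) {
    zi <- (K + 1):(K + n_rats); si <- K + n_rats + 1L
    moves <- list(
      # translate the beta/rat-intercept ridge (likelihood-invariant)
      function(th) {
        delta <- stats::rnorm(1, 0, 0.5)
        th[zi] <- th[zi] + delta
        th[1:K] <- th[1:K] - exp(th[si]) * delta
        th
      },
      # rescale sigma against z keeping u = sigma * z fixed (funnel move)
      function(th) {
        eps <- stats::rnorm(1, 0, 0.3)
        th[si] <- th[si] + eps
        th[zi] <- th[zi] * exp(-eps)
        list(theta = th, logj = -eps * length(zi))
      })
  }
  fit <- mh_sample(logpost, init, n_chains = n_chains, warmup = warmup,
                   iter = iter, seed = seed, moves = moves)
  derived <- stats::setNames(lapply(2:K, function(k) {
    force(k); function(th) 100 * (exp(th[k] - th[1]) - 1)
  }), paste0("pct_change_", phases[-1]))
  ps <- summarize_draws(fit, derived = derived)
  ps$phases <- phases; ps$ref_phase <- ref_phase
  if (ps$flagged) warning("MCMC not converged: max Rhat > 1.05")
  ps
}

#' Hierarchical Bayesian binomial proportion model
#'
#' Per-rat successes/totals are modeled as `k ~ Binomial(n, p)` with
#' `logit p = alpha + sigma * z[rat]`; priors `alpha ~ Normal(0, 1.5)`,
#' `sigma ~ half-Normal(1)`. The derived `prop` is the population-level
#' proportion `plogis(alpha)`. Cells with `n = 0` are dropped with a
#' warning. Used for forward/reverse directionality (is 0.5 in the 95% CI?)
#' and, per category, for represented-path proportions.
#'
#' @param data data.frame with columns `rat`, `k`, `n`.
#' @param n_chains,warmup,iter,seed MCMC settings.
#' @return a `posterior_summary` with derived column `prop`.
#' @export
fit_proportion_model <- function(data, n_chains = 4L, warmup = 600L,
                                 iter = 700L, seed = 1L) {
  stopifnot(all(c("rat", "k", "n") %in% names(data)))
  if (any(data$n == 0)) {
    warning("dropping cells with zero totals")
    data <- data[data$n > 0, ]
  }
  if (!nrow(data)) stop("no data")
  stopifnot(all(data$k <= data$n), all(data$k >= 0))
  rats <- unique(data$rat)
  n_rats <- length(rats)
  ri <- match(data$rat, rats)
  hierarchical <- n_rats >= 2L
  k <- data$k; n <- data$n

  logpost <- function(th) {
    alpha <- th[1]
    if (hierarchical) {
      z <- th[2:(1 + n_rats)]
      sigma <- exp(th[2 + n_rats])
      eta <- alpha + sigma * z[ri]
      prior <- stats::dnorm(alpha, 0, 1.5, log = TRUE) +
        sum(stats::dnorm(z, 0, 1, log = TRUE)) +
        stats::dnorm(sigma, 0, 1, log = TRUE) + th[2 + n_rats]
    } else {
      eta <- rep(alpha, length(k))
      prior <- stats::dnorm(alpha, 0, 1.5, log = TRUE)
    }
    sum(k * eta - n * log1p(exp(eta))) + prior
  }
  p0 <- min(max(sum(k) / sum(n), 0.02), 0.98)
  init <- c(alpha = stats::qlogis(p0))
  if (hierarchical)
    init <- c(init, stats::setNames(rep(0, n_rats), paste0("z_", rats)),
              log_sigma = log(0.3))
  moves <- NULL
  if (hierarchical) {
    zi <- 2:(1 + n_rats); si <- 2 + n_rats
    moves <- list(
      function(th) {
        delta <- stats::rnorm(1, 0, 0.5)
        th[zi] <- th[zi] + delta
        th[1] <- th[1] - exp(th[si]) * delta
        th
      },
      function(th) {
        eps <- stats::rnorm(1, 0, 0.3)
        th[si] <- th[si] + eps
        th[zi] <- th[zi] * exp(-eps)
        list(theta = th, logj = -eps * length(zi))
      })
  }
  fit <- mh_sample(logpost, init, n_chains = n_chains, warmup = warmup,
                   iter = iter, seed = seed, moves = moves)
  ps <- summarize_draws(fit, derived = list(prop = function(th) stats::plogis(th[1])))
  if (ps$flagged) warning("MCMC not converged: max Rhat > 1.05")
  ps
}

#' Multinomial-style represented-path proportions per phase window
#'
#' Fits [fit_proportion_model()] per category (path) within each phase
#' window and renormalizes the per-category posterior means to sum to one.
#'
#' @param events scored events with `rep_path` and a `window` column (e.g.
#'   pre, learn1..3, post) and a `rat` column.
#' @param categories path labels to include.
#' @param ... passed to [fit_proportion_model()].
#' @return data.frame: window, category, mean, q2.5, q97.5 (of the raw
#'   binomial proportion), norm_mean.
#' @export
path_proportion_posteriors <- function(events, categories = path_labels(), ...) {
  rows <- list()
  for (w in unique(events$window)) {
    ew <- events[events$window == w, ]
    tot <- stats::aggregate(list(n = rep(1L, nrow(ew))), by = list(rat = ew$rat), FUN = sum)
    means <- numeric(0)
    for (cat in categories) {
      kk <- stats::aggregate(list(k = as.integer(ew$rep_path == cat)),
                             by = list(rat = ew$rat), FUN = sum)
      d <- merge(tot, kk, by = "rat")
      ps <- fit_proportion_model(d, ...)
      s <- ps$summary[ps$summary$parameter == "prop", ]
      rows[[length(rows) + 1L]] <- data.frame(
        window = w, category = cat, mean = s$mean, q2.5 = s$q2.5, q97.5 = s$q97.5)
      means <- c(means, s$mean)
    }
  }
  out <- do.call(rbind, rows)
  out$norm_mean <- stats::ave(out$mean, out$window, FUN = function(v) v / sum(v))
  out
}

#' Overlap fraction between two posterior draw sets
#'
#' Estimates the integral of `min(density_A, density_B)` on a common
#' 256-bin histogram grid spanning the pooled 0.1-99.9 percentiles (values
#' outside clamped into the edge bins). Degenerate (constant) draws are
#' compared directly. The paper-style decision helper is `overlap < 0.05`.
#'
#' @param a,b numeric draw vectors.
#' @param n_bins histogram bins.
#' @return overlap fraction in `[0, 1]`.
#' @export
posterior_overlap <- function(a, b, n_bins = 256L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(as.numeric(a[1] == b[1]))
  pooled <- c(a, b)
  rng <- stats::quantile(pooled, c(0.001, 0.999), names = FALSE)
  if (diff(rng) <= 0) rng <- range(pooled) + c(-1e-9, 1e-9)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  clamp <- function(x) pmin(pmax(x, rng[1]), rng[2])
  ha <- tabulate(findInterval(clamp(a), edges, rightmost.closed = TRUE), n_bins) / length(a)
  hb <- tabulate(findInterval(clamp(b), edges, rightmost.closed = TRUE), n_bins) / length(b)
  sum(pmin(ha, hb))
}

#' Simulate rate-model input data (for calibration and recovery checks)
#'
#' @param n_rats,n_trials rats and trials per phase per rat.
#' @param base_rate reference-phase event rate, Hz.
#' @param fold multiplicative rate change in the second phase.
#' @param exposure_s immobile exposure per trial, s.
#' @param rat_sd sd of per-rat log-rate intercepts.
#' @param seed integer seed.
#' @return data.frame: rat, trial, phase, n_events, exposure_s.
#' @export
simulate_rate_data <- function(n_rats = 5L, n_trials = 30L, base_rate = 0.2,
                               fold = 2, exposure_s = 20, rat_sd = 0.3, seed = 1L) {
  set.seed(as.integer(seed))
  rows <- list()
  u <- stats::rnorm(n_rats, 0, rat_sd)
  for (r in seq_len(n_rats)) for (ph in c("pre", "post")) {
    rate <- base_rate * exp(u[r]) * if (ph == "post") fold else 1
    ex <- exposure_s * stats::runif(n_trials, 0.7, 1.3)
    rows[[length(rows) + 1L]] <- data.frame(
      rat = paste0("rat", r), trial = seq_len(n_trials), phase = ph,
      n_events = stats::rpois(n_trials, rate * ex), exposure_s = ex)
  }
  do.call(rbind, rows)
}
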