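#' Fit the Poisson encoding model from rate maps
#'
#' The encoder is the table of expected rates per unit and decoder state
#' (path, linearized bin), with a small floor added so zero-rate states keep
#' nonzero likelihood. Masked (unvisited) states are dropped from the state
#' space.
#'
#' @param rms a `rate_map_set`.
#' @param eps rate floor, Hz.
#' @return list: `lambda` (units x states), `states` (data.frame), `eps`.
#' @export
fit_encoder <- function(rms, eps = 0.01) {
  if (nrow(rms$rate) < 1L) stop("no units")
  keep <- !rms$mask
  if (!any(keep)) stop("all states masked")
  lambda <- rms$rate[, keep, drop = FALSE]
  lambda[is.na(lambda)] <- 0
  lambda <- lambda + eps
  states <- rms$binning$states[keep, , drop = FALSE]
  list(lambda = lambda, states = states, eps = eps, bin_cm = rms$binning$bin_cm)
}

#' Memoryless Bayesian position decoding
#'
#' Per time bin of width `tau`, the posterior over states x given spike
#' counts n is `P(x | n) \propto prior(x) * prod_i lambda_i(x)^{n_i} *
#' exp(-tau * sum_i lambda_i(x))`, computed in log space and normalized.
#'
#' @param counts units x time-bins matrix of non-negative integer spike
#'   counts.
#' @param encoder from [fit_encoder()].
#' @param tau time-bin width, s.
#' @param prior optional state prior (default flat).
#' @return list of class `decoded_posterior`: `posterior` (time-bins x
#'   states, rows sum to 1), `states`, `tau`, `map_state` (argmax per bin).
#' @export
decode <- function(counts, encoder, tau, prior = NULL) {
  stopifnot(tau > 0)
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1L)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  lam <- encoder$lambda
  stopifnot(nrow(counts) == nrow(lam))
  loglam <- log(lam)
  const <- -tau * colSums(lam)
  lp <- t(counts) %*% loglam
  lp <- sweep(lp, 2, const, "+")
  if (!is.null(prior)) {
    stopifnot(length(prior) == ncol(lam), all(prior >= 0))
    lp <- sweep(lp, 2, log(prior / sum(prior)), "+")
  }
  m <- apply(lp, 1, max)
  post <- exp(lp - m)
  post <- post / rowSums(post)
  structure(list(posterior = post, states = encoder$states, tau = tau,
                 map_state = apply(post, 1, which.max)),
            class = "decoded_posterior")
}

#' Bin spike trains into counts
#' @param spikes list of per-unit spike-time vectors.
#' @param edges time-bin edges (length nbins + 1).
#' @return units x nbins integer matrix.
#' @export
bin_spike_counts <- function(spikes, edges) {
  nb <- length(edges) - 1L
  out <- matrix(0L, length(spikes), nb)
  for (u in seq_along(spikes)) {
    s <- spikes[[u]]
    s <- s[s >= edges[1] & s < edges[nb + 1L]]
    if (length(s)) out[u, ] <- tabulate(findInterval(s, edges), nbins = nb)
  }
  out
}

#' Leave-one-out decoding position error
#'
#' For each held-out trial the encoder is refit on the remaining trials —
#' either within the same phase (`pooled = FALSE`, per-phase curves) or over
#' all phases (`pooled = TRUE`) — and the held-out trial's running periods
#' are decoded in `bin_s` bins. The error per bin is the linearized distance
#' between MAP and true position when the MAP state lies on the true path,
#' and the full true-path length otherwise (conservative cross-path
#' penalty). With `shuffle = TRUE` the encoder's unit identities are
#' permuted (chance control).
#'
#' @param session an `rk_session`.
#' @param bin_s decoding bin width, s.
#' @param bin_cm state bin size, cm.
#' @param pooled pool training trials across phases.
#' @param speed_threshold running gate, cm/s.
#' @param sigma_bins,min_occ rate-map parameters.
#' @param eps encoder rate floor, Hz.
#' @param shuffle permute unit identities in the encoder (control).
#' @param seed seed for the shuffle permutation.
#' @param ss optional precomputed [ratemap_suffstats()] (with its `lin`
#'   attribute) to avoid recomputation.
#' @return list: `median_cm`, `errors` (per-bin, pooled), `by_trial`
#'   (data.frame trial, phase, n_bins, median_cm).
#' @export
loo_position_error <- function(session, bin_s = 0.2, bin_cm = 5, pooled = FALSE,
                               speed_threshold = 4, sigma_bins = 2, min_occ = 0.1,
                               eps = 0.01, shuffle = FALSE, seed = 1L, ss = NULL) {
  binning <- make_binning(session$maze, bin_cm)
  lin <- linearized_samples(session)
  if (is.null(ss)) ss <- ratemap_suffstats(session, binning, lin = lin,
                                           speed_threshold = speed_threshold)
  lin_run <- lin[lin$speed > speed_threshold, ]
  trials <- session$trials
  phase_count <- table(trials$phase)
  if (any(phase_count < 2L)) stop("need at least 2 trials per phase")
  if (shuffle) { set.seed(as.integer(seed)); perm <- sample(length(session$spikes)) }

  plens <- vapply(path_labels(), function(p) path_length(session$maze, p), numeric(1))
  errs <- list(); rows <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials$trial[i]; ph <- trials$phase[i]
    train <- if (pooled) trials$trial[trials$trial != tr] else
      trials$trial[trials$trial != tr & trials$phase == ph]
    rms <- rate_map_set(ss, trials = train, sigma_bins = sigma_bins, min_occ = min_occ)
    enc <- fit_encoder(rms, eps = eps)
    if (shuffle) enc$lambda <- enc$lambda[perm, , drop = FALSE]

    ltr <- lin_run[lin_run$trial == tr, ]
    if (nrow(ltr) < 3L) next
    e_tr <- numeric(0)
    for (p in unique(ltr$path)) {
      lp <- ltr[ltr$path == p, ]
      # contiguous runs on this path
      brk <- c(0, which(diff(lp$t) > 0.5), nrow(lp))
      for (k in seq_len(length(brk) - 1L)) {
        seg <- lp[(brk[k] + 1L):brk[k + 1L], ]
        if (nrow(seg) < 3L || diff(range(seg$t)) < bin_s) next
        edges <- seq(min(seg$t), max(seg$t), by = bin_s)
        if (length(edges) < 2L) next
        cnt <- bin_spike_counts(session$spikes, edges)
        dp <- decode(cnt, enc, tau = bin_s)
        ctr <- (edges[-1] + edges[-length(edges)]) / 2
        true_lin <- stats::approx(seg$t, seg$lin, xout = ctr, rule = 2)$y
        map_path <- dp$states$path[dp$map_state]
        map_lin <- dp$states$center[dp$map_state]
        e <- ifelse(map_path == p, abs(map_lin - true_lin), plens[[p]])
        e_tr <- c(e_tr, e)
      }
    }
    if (length(e_tr)) {
      errs[[length(errs) + 1L]] <- e_tr
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr, phase = ph, n_bins = length(e_tr), median_cm = stats::median(e_tr))
    }
  }
  errors <- unlist(errs)
  list(median_cm = stats::median(errors), errors = errors,
       by_trial = do.call(rbind, rows))
}
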