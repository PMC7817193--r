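#' Detect synchronous population events during immobility
#'
#' Pooled multiunit spike counts in `bin_s` steps are Gaussian-smoothed and
#' z-scored against immobility bins. Candidates are excursions above
#' `z_thresh` during immobility, extended to the surrounding `z_ext`
#' crossings, merged across gaps shorter than `merge_gap`, duration-filtered
#' to `dur_range`, and required to recruit at least `min_frac_units` of the
#' population. If SWR intervals are supplied the events must overlap one.
#'
#' @param session an `rk_session`.
#' @param swr optional [detect_swr()] table; `NULL` skips the association.
#' @param bin_s MUA bin width, s.
#' @param smooth_s MUA smoothing (Gaussian sd), s.
#' @param z_thresh core detection threshold (z-units).
#' @param z_ext boundary-extension threshold.
#' @param min_frac_units minimum fraction of units with >= 1 spike.
#' @param speed_threshold immobility gate, cm/s.
#' @param merge_gap merge gap, s.
#' @param dur_range admissible durations, s.
#' @return data.frame (one row per event): event, t_start, t_end, trial,
#'   phase, area, x, y, n_units, n_spikes.
#' @export
detect_synchronous_events <- function(session, swr = NULL, bin_s = 0.01,
                                      smooth_s = 0.015, z_thresh = 3, z_ext = 0.5,
                                      min_frac_units = 0.1, speed_threshold = 4,
                                      merge_gap = 0.05, dur_range = c(0.05, 0.5)) {
  spikes <- session$spikes
  n_units <- length(spikes)
  if (n_units < 10L) stop("need at least 10 units")
  pos <- session$position
  speed <- position_speed(pos)
  t0 <- min(pos$t); t1 <- max(pos$t)
  edges <- seq(t0, t1, by = bin_s)
  nb <- length(edges) - 1L
  all_sp <- sort(unlist(spikes))
  all_sp <- all_sp[all_sp >= t0 & all_sp < edges[nb + 1L]]
  mua <- tabulate(findInterval(all_sp, edges), nbins = nb)
  k <- gauss_kernel(smooth_s / bin_s)
  smua <- if (length(k) > 1L) conv_same(mua, k) else mua
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  immob <- stats::approx(pos$t, as.numeric(speed < speed_threshold),
                         xout = ctr, method = "constant", rule = 2)$y > 0.5
  if (!any(immob)) stop("no immobility periods")
  z <- (smua - mean(smua[immob])) / stats::sd(smua[immob])

  core <- z > z_thresh & immob
  if (!any(core)) return(empty_events())
  above <- z > z_ext
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- list()
  for (kk in which(r$values)) {
    if (!any(core[starts[kk]:ends[kk]])) next
    iv[[length(iv) + 1L]] <- c(starts[kk], ends[kk])
  }
  if (!length(iv)) return(empty_events())
  m <- do.call(rbind, iv)
  merged <- list(m[1, ])
  if (nrow(m) > 1L) for (i in 2:nrow(m)) {
    last <- merged[[length(merged)]]
    if ((m[i, 1] - last[2]) * bin_s < merge_gap) {
      merged[[length(merged)]] <- c(last[1], m[i, 2])
    } else merged[[length(merged) + 1L]] <- m[i, ]
  }
  m <- do.call(rbind, merged)
  ev <- data.frame(t_start = edges[m[, 1]], t_end = edges[m[, 2] + 1L])
  dur <- ev$t_end - ev$t_start
  ev <- ev[dur >= dur_range[1] & dur <= dur_range[2], , drop = FALSE]
  if (!nrow(ev)) return(empty_events())

  # participation filter
  npart <- vapply(seq_len(nrow(ev)), function(i) {
    sum(vapply(spikes, function(s) any(s >= ev$t_start[i] & s < ev$t_end[i]),
               logical(1)))
  }, integer(1))
  nspk <- vapply(seq_len(nrow(ev)), function(i) {
    sum(vapply(spikes, function(s) sum(s >= ev$t_start[i] & s < ev$t_end[i]),
               numeric(1)))
  }, numeric(1))
  keep <- npart >= ceiling(min_frac_units * n_units)
  ev <- ev[keep, , drop = FALSE]; npart <- npart[keep]; nspk <- nspk[keep]
  if (!nrow(ev)) return(empty_events())

  if (!is.null(swr) && nrow(swr)) {
    ov <- vapply(seq_len(nrow(ev)), function(i) {
      any(swr$t_start < ev$t_end[i] & swr$t_end > ev$t_start[i])
    }, logical(1))
    ev <- ev[ov, , drop = FALSE]; npart <- npart[ov]; nspk <- nspk[ov]
  }
  if (!nrow(ev)) return(empty_events())

  tm <- (ev$t_start + ev$t_end) / 2
  xi <- stats::approx(pos$t, pos$x, xout = tm, rule = 2)$y
  yi <- stats::approx(pos$t, pos$y, xout = tm, rule = 2)$y
  reg <- region_of(session$maze, xi, yi)
  area <- ifelse(reg %in% c("c1", "c2", "field"), "field",
          ifelse(reg == "start", "start",
          ifelse(reg == "goal", "goal", "alleyway")))
  tri <- findInterval(tm, session$trials$t_start)
  tri <- pmin(pmax(tri, 1L), nrow(session$trials))
  data.frame(event = seq_len(nrow(ev)), t_start = ev$t_start, t_end = ev$t_end,
             trial = session$trials$trial[tri],
             phase = session$trials$phase[tri],
             area = area, x = xi, y = yi,
             n_units = npart, n_spikes = nspk)
}

empty_events <- function() {
  data.frame(event = integer(), t_start = numeric(), t_end = numeric(),
             trial = integer(), phase = character(), area = character(),
             x = numeric(), y = numeric(), n_units = integer(),
             n_spikes = numeric())
}

#' Event frequency maps and per-trial count/exposure tables
#'
#' Spatial map of synchronous-event frequency (events per second of
#' immobile occupancy per 2D bin) plus the per (trial, area, phase) event
#' counts and immobile exposure times consumed by the hierarchical rate
#' model.
#'
#' @param events table from [detect_synchronous_events()].
#' @param session an `rk_session`.
#' @param bin_cm 2D map bin size, cm.
#' @param speed_threshold immobility gate, cm/s.
#' @return list: `map` (x, y, exposure_s, n_events, rate_hz; zero-exposure
#'   bins masked NA), `table` (trial, phase, area, n_events, exposure_s).
#' @export
event_rate_maps <- function(events, session, bin_cm = 10, speed_threshold = 4) {
  pos <- session$position
  speed <- position_speed(pos)
  dt <- stats::median(diff(pos$t))
  immob <- speed < speed_threshold
  maze <- session$maze
  xr <- range(c(pos$x, maze$alley_box[1:2])); yr <- range(pos$y)
  xe <- seq(floor(xr[1]), ceiling(xr[2]) + bin_cm, by = bin_cm)
  ye <- seq(floor(yr[1]), ceiling(yr[2]) + bin_cm, by = bin_cm)
  xi <- findInterval(pos$x[immob], xe); yi <- findInterval(pos$y[immob], ye)
  occ <- matrix(0, length(xe) - 1L, length(ye) - 1L)
  tb <- table(factor(xi, seq_len(nrow(occ))), factor(yi, seq_len(ncol(occ))))
  occ[] <- as.numeric(tb) * dt
  evc <- matrix(0, nrow(occ), ncol(occ))
  if (nrow(events)) {
    exi <- findInterval(events$x, xe); eyi <- findInterval(events$y, ye)
    ok <- exi >= 1 & exi <= nrow(occ) & eyi >= 1 & eyi <= ncol(occ)
    tb2 <- table(factor(exi[ok], seq_len(nrow(occ))), factor(eyi[ok], seq_len(ncol(occ))))
    evc[] <- as.numeric(tb2)
  }
  rate <- ifelse(occ > 0, evc / occ, NA_real_)
  map <- data.frame(x = rep((xe[-1] + xe[-length(xe)]) / 2, times = ncol(occ)),
                    y = rep((ye[-1] + ye[-length(ye)]) / 2, each = nrow(occ)),
                    exposure_s = as.numeric(occ), n_events = as.numeric(evc),
                    rate_hz = as.numeric(rate))

  reg <- region_of(maze, pos$x, pos$y)
  area <- ifelse(reg %in% c("c1", "c2", "field"), "field",
          ifelse(reg == "start", "start",
          ifelse(reg == "goal", "goal", "alleyway")))
  tri <- findInterval(pos$t, session$trials$t_start)
  tri <- pmin(pmax(tri, 1L), nrow(session$trials))
  expo <- stats::aggregate(list(exposure_s = rep(dt, sum(immob))),
                           by = list(trial = session$trials$trial[tri][immob],
                                     area = area[immob]), FUN = sum)
  cnts <- if (nrow(events)) {
    stats::aggregate(list(n_events = rep(1L, nrow(events))),
                     by = list(trial = events$trial, area = events$area), FUN = sum)
  } else data.frame(trial = integer(), area = character(), n_events = integer())
  tabl <- merge(expo, cnts, by = c("trial", "area"), all.x = TRUE)
  tabl$n_events[is.na(tabl$n_events)] <- 0L
  tabl$phase <- session$trials$phase[match(tabl$trial, session$trials$trial)]
  list(map = map, table = tabl[order(tabl$trial, tabl$area),
                               c("trial", "phase", "area", "n_events", "exposure_s")])
}
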