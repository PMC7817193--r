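#' Default pipeline configuration
#'
#' All thresholds of every stage in one serializable list; a run is
#' reproducible from the config alone.
#' @param seed master seed.
#' @return named list (class `rk_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    n_units = 40L,
    n_trials = c(pre = 8L, learning = 15L, post = 8L),
    lfp = TRUE,
    maze = list(lattice_cols = 5L, lattice_rows = 5L, cell_size = 20,
                c1_cell = c(4L, 2L), c2_cell = c(2L, 4L)),
    behavior = list(window = 5L, distance_threshold = 2L),
    tuning = list(bin_cm = 2, sigma_bins = 2, speed_threshold = 4,
                  min_occ = 0.1, peak_floor = 1, frac = 0.2, min_bins = 3L,
                  tol_cm = 10),
    decoding = list(bin_cm = 5, run_bin_s = 0.2, event_bin_s = 0.02, eps = 0.01),
    theta = list(min_cycles = 20L, window_cm = 50, rel_bin_cm = 2),
    replay = list(n_shuffles = 200L, z_thresh = 3, min_frac_units = 0.1),
    stats = list(n_chains = 4L, warmup = 600L, iter = 700L)
  ), class = "rk_config")
}

#' Read/write a pipeline config as JSON
#' @param config an `rk_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$n_trials <- unlist(cfg$n_trials)
  structure(cfg, class = "rk_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic pipeline
#'
#' generate -> behavior -> tuning -> decode -> theta -> replay -> stats,
#' deterministic given the config seed. Writes all tables plus a
#' machine-readable `report.json` into `out_dir`; any stage failure raises
#' an error tagged with the stage name (partial outputs are preserved).
#'
#' @param config an `rk_config` (see [default_config()]).
#' @param out_dir run directory.
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("rkrun")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.json"))
  report <- list(seed = config$seed)
  if (config$n_units < 1L) stop("[stage:tuning] no units configured", call. = FALSE)

  session <- stage("simulate", {
    maze <- do.call(make_maze, config$maze)
    s <- simulate_session(seed = config$seed, n_units = config$n_units,
                          n_trials = config$n_trials, maze = maze,
                          lfp = isTRUE(config$lfp))
    write_session(s, file.path(out_dir, "session"), lfp = FALSE)
    s
  })

  beh <- stage("behavior", {
    ts <- trial_summaries(session)
    lc <- learning_point(ts$labels,
                         session$ground_truth$reward_replacement_trial,
                         window = config$behavior$window)
    props <- path_proportions(ts$labels)
    pbc <- prob_behavior_change(ts$cells, ts$labels,
                                threshold = config$behavior$distance_threshold)
    data.table::fwrite(ts$summary, file.path(out_dir, "trial_summary.tsv"), sep = "\t")
    list(ts = ts, lc = lc, props = props, pbc = pbc)
  })
  report$learning_point_detected <- beh$lc$learning_point
  report$learning_point_true <- session$ground_truth$learning_point_trial
  report$learning_point_error <- if (is.null(beh$lc$learning_point)) NA else
    beh$lc$learning_point - session$ground_truth$learning_point_trial
  report$path_proportions <- as.list(beh$props)
  report$prob_behavior_change <- beh$pbc

  tun <- stage("tuning", {
    tcfg <- config$tuning
    binning <- make_binning(session$maze, tcfg$bin_cm)
    lin <- linearized_samples(session)
    ss <- ratemap_suffstats(session, binning, lin = lin,
                            speed_threshold = tcfg$speed_threshold)
    phases <- c("pre", "learning", "post")
    rms <- lapply(stats::setNames(phases, phases), function(ph)
      rate_map_set(ss, trials = session$trials$trial[session$trials$phase == ph],
                   sigma_bins = tcfg$sigma_bins, min_occ = tcfg$min_occ))
    flds <- lapply(rms, detect_fields_all, peak_floor = tcfg$peak_floor,
                   frac = tcfg$frac, min_bins = tcfg$min_bins)
    jc <- joint_classify(flds$pre, flds$learning, session$maze, tol = tcfg$tol_cm)
    data.table::fwrite(do.call(rbind, Map(cbind, phase = names(flds), flds)),
                       file.path(out_dir, "place_fields.tsv"), sep = "\t")
    data.table::fwrite(jc$units, file.path(out_dir, "unit_classes.tsv"), sep = "\t")
    list(binning = binning, lin = lin, ss = ss, rms = rms, fields = flds, jc = jc)
  })
  report$unit_class_counts <- as.list(table(tun$jc$units$label))

  dec <- stage("decode", {
    loo <- loo_position_error(session, bin_s = config$decoding$run_bin_s,
                              bin_cm = config$decoding$bin_cm,
                              eps = config$decoding$eps)
    loo
  })
  report$decoding_median_error_cm <- dec$median_cm

  if (!is.null(session$lfp)) {
    th <- stage("theta", {
      binning5 <- make_binning(session$maze, config$decoding$bin_cm)
      ss5 <- ratemap_suffstats(session, binning5, lin = tun$lin)
      enc <- fit_encoder(rate_map_set(ss5))
      speed <- position_speed(session$position)
      cyc <- detect_theta_cycles(session$lfp, speed, session$position$t)
      qs <- lapply(stats::setNames(path_labels()[1:5], path_labels()[1:5]),
                   function(p) quadrant_score(session, p, encoder = enc,
                                              cycles = cyc, lin = tun$lin,
                                              min_cycles = config$theta$min_cycles)$score)
      qs
    })
    report$quadrant_scores <- th
  }

  rep_ <- stage("replay", {
    swr <- if (!is.null(session$lfp))
      detect_swr(session$lfp, position_speed(session$position), session$position$t)
    else NULL
    ev <- detect_synchronous_events(session, swr = swr,
                                    z_thresh = config$replay$z_thresh,
                                    min_frac_units = config$replay$min_frac_units)
    binning5 <- make_binning(session$maze, config$decoding$bin_cm)
    ss5 <- ratemap_suffstats(session, binning5, lin = tun$lin)
    enc <- fit_encoder(rate_map_set(ss5), eps = config$decoding$eps)
    scored <- score_events(session, ev, enc, bin_s = config$decoding$event_bin_s,
                           n_shuffles = config$replay$n_shuffles,
                           seed = config$seed)
    erm <- event_rate_maps(ev, session)
    data.table::fwrite(scored, file.path(out_dir, "events.tsv"), sep = "\t")
    data.table::fwrite(erm$table, file.path(out_dir, "event_rates.tsv"), sep = "\t")
    list(swr = swr, scored = scored, erm = erm, enc = enc)
  })
  report$n_events <- nrow(rep_$scored)
  report$n_swr <- if (is.null(rep_$swr)) NA else nrow(rep_$swr)
  report$direction_counts <- as.list(table(rep_$scored$direction))
  # represented-path majority per learning third
  lw <- learning_windows(session)
  sc <- rep_$scored
  sc$window <- lw[as.character(sc$trial)]
  maj <- vapply(c("learn1", "learn2", "learn3"), function(w) {
    v <- sc$rep_path[!is.na(sc$window) & sc$window == w & !is.na(sc$rep_path)]
    if (!length(v)) NA_character_ else names(sort(table(v), decreasing = TRUE))[1]
  }, character(1))
  report$represented_majority <- as.list(maj)

  stats_out <- stage("stats", {
    tab <- rep_$erm$table
    tab$rat <- "rat1"
    tab$phase2 <- ifelse(tab$phase == "pre", "pre", "learn_post")
    fit <- suppressWarnings(fit_rate_model(
      data.frame(rat = tab$rat, phase = tab$phase2,
                 n_events = tab$n_events, exposure_s = tab$exposure_s),
      n_chains = config$stats$n_chains, warmup = config$stats$warmup,
      iter = config$stats$iter, seed = config$seed))
    data.table::fwrite(fit$summary, file.path(out_dir, "rate_model.tsv"), sep = "\t")
    fit
  })
  pc <- stats_out$summary[stats_out$summary$parameter == "pct_change_learn_post", ]
  report$event_rate_pct_change <- list(mean = pc$mean, q2.5 = pc$q2.5, q97.5 = pc$q97.5)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Phase windows with the learning phase split into thirds
#'
#' @param session an `rk_session`.
#' @return named character vector mapping trial id to window
#'   (`pre`, `learn1`, `learn2`, `learn3`, `post`); ties go to the earlier
#'   third.
#' @export
learning_windows <- function(session) {
  ph <- session$ground_truth$phase_of_trial
  trials <- session$trials$trial
  lt <- which(ph == "learning")
  w <- ph
  if (length(lt)) {
    k <- findInterval(seq_along(lt) - 1L, length(lt) * c(1, 2) / 3) + 1L
    w[lt] <- paste0("learn", pmin(k, 3L))
  }
  stats::setNames(w, trials)
}
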