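#' Build a ground-truth tuning specification for a synthetic population
#'
#' Each unit gets a functional type:
#' \describe{
#'   \item{stable}{one Gaussian field at a fixed linearized position on one
#'     path, expressed in every phase.}
#'   \item{context}{a field at a fixed distance before the destination,
#'     expressed on every analogous path of its correspondence group
#'     (approaching a checkpoint, or approaching the goal) whenever that
#'     path is run.}
#'   \item{on}{field appears at the reward-replacement boundary (learning
#'     and post phases only).}
#'   \item{off}{field present in the pre phase only.}
#'   \item{nonplace}{spatially untuned low-rate unit.}
#' }
#'
#' @param maze a `maze_spec`.
#' @param n_units number of units.
#' @param type_probs named probabilities over
#'   `c(stable, context, on, off, nonplace)`.
#' @param peak_range uniform range of field peak rates, Hz.
#' @param sigma_range uniform range of field widths (Gaussian sd), cm.
#' @param max_fields maximum number of fields per stable/on/off unit
#'   (real place cells often have multiple fields).
#' @param nonplace_rate mean rate of untuned units, Hz.
#' @param seed integer seed.
#' @return data.frame (class `tuning_spec`): unit, type, group, path,
#'   center (cm on `path` for stable/on/off; distance-to-destination for
#'   context units), sigma, peak, plus path2/center2, path3/center3 for
#'   additional fields (NA if unused).
#' @export
make_tuning <- function(maze, n_units = 50L,
                        type_probs = c(stable = 0.40, context = 0.30,
                                       on = 0.10, off = 0.10, nonplace = 0.10),
                        peak_range = c(8, 20), sigma_range = c(8, 12),
                        max_fields = 3L, nonplace_rate = 1, seed = 1L) {
  stopifnot(n_units >= 1L)
  set.seed(as.integer(seed))
  type_probs <- type_probs / sum(type_probs)
  types <- sample(names(type_probs), n_units, replace = TRUE, prob = type_probs)
  groups <- names(path_correspondence())
  labs <- path_labels()
  plens <- vapply(labs, function(p) path_length(maze, p), numeric(1))

  # context units cycle through groups 3:2 (the checkpoint group serves
  # three analogous paths, the goal group two), so per-path coverage does
  # not collapse by sampling accident in small populations
  grp_cycle <- c("checkpoint", "goal", "checkpoint", "goal", "checkpoint")
  grp_i <- 0L
  df <- data.frame(unit = seq_len(n_units), type = types,
                   group = NA_character_, path = NA_character_,
                   center = NA_real_, sigma = NA_real_, peak = NA_real_,
                   path2 = NA_character_, center2 = NA_real_,
                   path3 = NA_character_, center3 = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n_units)) {
    ty <- types[i]
    if (ty == "nonplace") {
      df$peak[i] <- nonplace_rate
      next
    }
    df$sigma[i] <- stats::runif(1, sigma_range[1], sigma_range[2])
    df$peak[i] <- stats::runif(1, peak_range[1], peak_range[2])
    if (ty == "context") {
      grp_i <- grp_i + 1L
      g <- grp_cycle[(grp_i - 1L) %% length(grp_cycle) + 1L]
      df$group[i] <- g
      gl <- path_correspondence()[[g]]
      dmax <- 0.8 * min(plens[gl])
      df$center[i] <- stats::runif(1, 6, dmax)   # cm before the destination
    } else {
      nf <- if (max_fields > 1L)
        sample.int(max_fields, 1L, prob = c(0.45, 0.35, 0.20)[seq_len(max_fields)])
      else 1L
      # the primary field of stable/off units must lie on a path the animal
      # runs in every phase (S-C1, C1-G, return), otherwise stability is
      # unobservable; "on" units need a path run from the learning phase on
      primary_pool <- if (ty == "on") setdiff(labs, "S-C2") else
        c("S-C1", "C1-G", "return")
      p1 <- sample(primary_pool, 1L)
      pp <- c(p1, if (nf > 1L) sample(setdiff(labs, p1), nf - 1L))
      for (k in seq_len(nf)) {
        ctr <- stats::runif(1, 0.05, 0.95) * plens[[pp[k]]]
        if (k == 1L) { df$path[i] <- pp[k]; df$center[i] <- ctr }
        if (k == 2L) { df$path2[i] <- pp[k]; df$center2[i] <- ctr }
        if (k == 3L) { df$path3[i] <- pp[k]; df$center3[i] <- ctr }
      }
    }
  }
  class(df) <- c("tuning_spec", "data.frame")
  df
}

#' Active fields of one unit in one phase
#'
#' Resolves a tuning row to concrete `(path, center cm, sigma, peak)` fields
#' for the given learning phase, applying context-group expansion and the
#' on/off phase gating.
#'
#' @param trow one row of a `tuning_spec`.
#' @param maze a `maze_spec`.
#' @param phase one of `"pre"`, `"learning"`, `"post"`.
#' @return data.frame with columns path, center, sigma, peak (0 rows if the
#'   unit has no field in this phase).
#' @export
unit_fields <- function(trow, maze, phase) {
  empty <- data.frame(path = character(), center = numeric(),
                      sigma = numeric(), peak = numeric())
  ty <- trow$type
  if (ty == "nonplace") return(empty)
  if (ty == "on" && phase == "pre") return(empty)
  if (ty == "off" && phase != "pre") return(empty)
  if (ty == "context") {
    paths <- path_correspondence()[[trow$group]]
    data.frame(path = paths,
               center = vapply(paths, function(p) path_length(maze, p), numeric(1)) - trow$center,
               sigma = trow$sigma, peak = trow$peak, row.names = NULL)
  } else {
    g <- function(nm) if (nm %in% names(trow)) trow[[nm]] else NA
    pp <- c(trow$path, g("path2"), g("path3"))
    cc <- c(trow$center, g("center2"), g("center3"))
    keep <- !is.na(pp)
    data.frame(path = pp[keep], center = cc[keep],
               sigma = trow$sigma, peak = trow$peak, row.names = NULL)
  }
}

#' Simulate place-cell spike trains for a behavioral session
#'
#' Inhomogeneous Poisson spiking: rate = Gaussian spatial tuning on the
#' active path times a theta modulation `1 + depth * cos(theta - phi)`.
#' Phase precession is implemented as a preferred phase that advances
#' linearly from late (field entry) to early (field exit) over
#' `precess_range` degrees; with `precess = FALSE` the preferred phase is
#' fixed at the field center's value. Spikes are drawn by thinning on a
#' 2 ms grid, which also enforces the refractory period.
#'
#' @param behavior output of [simulate_behavior()].
#' @param tuning a `tuning_spec` from [make_tuning()].
#' @param maze the `maze_spec` used for the behavior.
#' @param theta_freq theta frequency, Hz.
#' @param theta_depth modulation depth in `[0, 1)`.
#' @param precess logical; disable to remove phase precession (control).
#' @param precess_range precession extent across the field, degrees.
#' @param baseline_rate spatially uniform background rate for every unit, Hz.
#' @param seed integer seed.
#' @return list with `spikes` (per-unit sorted numeric vectors, s),
#'   `tuning` (the spec), and `theta` (the generator's theta parameters).
#' @export
simulate_spikes <- function(behavior, tuning, maze,
                            theta_freq = 8, theta_depth = 0.7,
                            precess = TRUE, precess_range = 270,
                            baseline_rate = 0.15, seed = 1L) {
  stopifnot(nrow(tuning) >= 1L)
  if (any(tuning$peak < 0, na.rm = TRUE)) stop("negative peak rate")
  set.seed(as.integer(seed))
  smp <- behavior$samples
  phase_of_trial <- behavior$ground_truth$phase_of_trial
  smp_phase <- phase_of_trial[smp$trial]
  t_end <- max(smp$t)
  dt_pos <- stats::median(diff(smp$t[1:100]))
  k_fine <- 10L
  dt_f <- dt_pos / k_fine
  range_rad <- precess_range * pi / 180
  # Theta cycles are cut at troughs of sin(2*pi*f*t) (phase 3*pi/2), both in
  # the synthesized LFP and in the analysis. Preferred phase decreases with
  # progress through the field so that cells whose fields lie behind the
  # animal fire just after the trough (early) and cells with fields ahead
  # fire late in the cycle -- the forward theta sweep.
  phi_hi <- 3 * pi / 2 + (2 * pi + range_rad) / 2

  run_idx_by_path <- split(which(smp$running), smp$path[smp$running])

  spikes <- vector("list", nrow(tuning))
  for (i in seq_len(nrow(tuning))) {
    trow <- tuning[i, ]
    st <- numeric(0)
    rate0 <- if (trow$type == "nonplace") trow$peak else baseline_rate
    if (rate0 > 0) {
      nb <- stats::rpois(1, rate0 * t_end)
      st <- stats::runif(nb, 0, t_end)
    }
    if (trow$type != "nonplace") {
      for (phase in c("pre", "learning", "post")) {
        flds <- unit_fields(trow, maze, phase)
        if (nrow(flds) == 0L) next
        for (j in seq_len(nrow(flds))) {
          f <- flds[j, ]
          idx <- run_idx_by_path[[f$path]]
          if (is.null(idx)) next
          idx <- idx[smp_phase[idx] == phase]
          d <- smp$lin[idx] - f$center
          idx <- idx[abs(d) < 3.5 * f$sigma]
          if (!length(idx)) next
          lin <- smp$lin[idx]
          envl <- f$peak * exp(-(lin - f$center)^2 / (2 * f$sigma^2))
          # expand each position sample (covering (t - dt, t]) to the fine grid
          tf <- rep(smp$t[idx] - dt_pos, each = k_fine) + dt_f * rep(seq_len(k_fine), length(idx))
          lam <- rep(envl, each = k_fine)
          if (theta_depth > 0) {
            prog <- pmin(pmax((rep(lin, each = k_fine) - (f$center - 2 * f$sigma)) /
                                (4 * f$sigma), 0), 1)
            phi <- if (precess) phi_hi - range_rad * prog else phi_hi - range_rad * 0.5
            lam <- lam * (1 + theta_depth * cos(2 * pi * theta_freq * tf - phi))
          }
          hit <- stats::runif(length(lam)) < lam * dt_f
          if (any(hit)) st <- c(st, tf[hit])
        }
      }
    }
    st <- sort(st)
    if (length(st) > 1L) st <- st[c(TRUE, diff(st) >= 0.002)]  # refractory
    spikes[[i]] <- st
  }
  list(spikes = spikes, tuning = tuning,
       theta = list(freq = theta_freq, depth = theta_depth,
                    precess = precess, precess_range = precess_range))
}
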