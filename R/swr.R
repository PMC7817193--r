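#' Detect sharp-wave ripples from the LFP
#'
#' Band-pass 150-250 Hz, smoothed Hilbert envelope, z-scored against
#' immobility periods; candidate events are excursions above `z_hi`,
#' extended to the surrounding `z_lo` crossings, merged when separated by
#' less than `merge_gap`, and duration-filtered.
#'
#' @param lfp data.frame t, v with attribute `fs` (or pass `fs`).
#' @param speed running speed sampled at position times.
#' @param speed_t times of the speed samples.
#' @param fs LFP sampling rate, Hz (>= 600).
#' @param band ripple band, Hz.
#' @param z_hi,z_lo detection and boundary-extension thresholds (envelope
#'   z-units).
#' @param min_core_s minimum time the envelope must stay above `z_hi`
#'   (suppresses momentary noise excursions; a ripple sustains its power
#'   for tens of ms).
#' @param merge_gap merge events closer than this, s.
#' @param dur_range admissible event durations, s.
#' @param speed_threshold immobility gate, cm/s.
#' @param smooth_s envelope smoothing (Gaussian sd), s.
#' @return data.frame: t_start, t_end, t_peak, peak_z.
#' @export
detect_swr <- function(lfp, speed, speed_t, fs = attr(lfp, "fs"),
                       band = c(150, 250), z_hi = 3, z_lo = 0.5,
                       min_core_s = 0.02, merge_gap = 0.05,
                       dur_range = c(0.02, 0.5),
                       speed_threshold = 4, smooth_s = 0.0053) {
  if (is.null(lfp) || nrow(lfp) < 10L) stop("empty LFP")
  if (is.null(fs)) fs <- 1 / stats::median(diff(lfp$t))
  if (fs < 600) stop("LFP rate too low for the ripple band")
  v <- fir_bandpass(lfp$v, fs, band[1], band[2], taps = round(fs / 50) * 2 + 1)
  env <- hilbert_envelope(v)
  k <- gauss_kernel(smooth_s * fs)
  if (length(k) > 1L) env <- conv_same(env, k)

  immob <- stats::approx(speed_t, as.numeric(speed < speed_threshold),
                         xout = lfp$t, method = "constant", rule = 2)$y > 0.5
  if (!any(immob)) stop("no immobility baseline for z-scoring")
  mu <- mean(env[immob]); sdv <- stats::sd(env[immob])
  z <- (env - mu) / sdv

  core <- z > z_hi & immob
  # a core excursion must be sustained, not a momentary noise blip
  rc <- rle(core)
  short <- rc$values & rc$lengths < max(1L, round(min_core_s * fs))
  rc$values[short] <- FALSE
  core <- inverse.rle(rc)
  if (!any(core)) return(data.frame(t_start = numeric(), t_end = numeric(),
                                    t_peak = numeric(), peak_z = numeric()))
  above <- z > z_lo
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rows <- list()
  for (k2 in which(r$values)) {
    i0 <- starts[k2]; i1 <- ends[k2]
    if (!any(core[i0:i1])) next
    rows[[length(rows) + 1L]] <- c(i0, i1)
  }
  if (!length(rows)) return(data.frame(t_start = numeric(), t_end = numeric(),
                                       t_peak = numeric(), peak_z = numeric()))
  m <- do.call(rbind, rows)
  # merge close events
  merged <- list(m[1, ])
  if (nrow(m) > 1L) for (i in 2:nrow(m)) {
    last <- merged[[length(merged)]]
    if ((m[i, 1] - last[2]) / fs < merge_gap) {
      merged[[length(merged)]] <- c(last[1], m[i, 2])
    } else merged[[length(merged) + 1L]] <- m[i, ]
  }
  m <- do.call(rbind, merged)
  out <- data.frame(t_start = lfp$t[m[, 1]], t_end = lfp$t[m[, 2]])
  out$t_peak <- vapply(seq_len(nrow(m)), function(i) {
    ii <- m[i, 1]:m[i, 2]; lfp$t[ii[which.max(z[ii])]]
  }, numeric(1))
  out$peak_z <- vapply(seq_len(nrow(m)), function(i) max(z[m[i, 1]:m[i, 2]]), numeric(1))
  dur <- out$t_end - out$t_start
  out[dur >= dur_range[1] & dur <= dur_range[2], , drop = FALSE]
}
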