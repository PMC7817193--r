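# Plain-text session serialization. All coordinates cm, times s, time
# origin 0 at session start. Spikes/position/trials/LFP as TSV; ground
# truth and config as JSON.

#' Write a session to a directory of delimited-text files
#' @param session an `rk_session`.
#' @param dir output directory (created if needed).
#' @param lfp include the LFP table (large).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, lfp = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- data.table::rbindlist(lapply(seq_along(session$spikes), function(u)
    data.table::data.table(unit_id = u, t_s = session$spikes[[u]])))
  data.table::fwrite(sp, file.path(dir, "spikes.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(session$position),
                     file.path(dir, "position.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(session$trials),
                     file.path(dir, "trials.tsv"), sep = "\t")
  if (lfp && !is.null(session$lfp)) {
    data.table::fwrite(data.table::as.data.table(session$lfp),
                       file.path(dir, "lfp.tsv"), sep = "\t")
    jsonlite::write_json(list(rate_hz = attr(session$lfp, "fs"), units = "arbitrary"),
                         file.path(dir, "lfp_meta.json"), auto_unbox = TRUE)
  }
  gt <- session$ground_truth
  jsonlite::write_json(list(
    phase_of_trial = gt$phase_of_trial,
    reward_replacement_trial = gt$reward_replacement_trial,
    learning_point_trial = gt$learning_point_trial,
    tuning = gt$tuning, events = gt$events,
    maze = list(lattice_cols = session$maze$lattice_cols,
                lattice_rows = session$maze$lattice_rows,
                cell_size = session$maze$cell_size,
                c1_cell = session$maze$c1_cell, c2_cell = session$maze$c2_cell)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#' @param dir session directory.
#' @return an `rk_session` (ground truth restored from JSON; LFP if
#'   present).
#' @export
read_session <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  maze <- make_maze(gt$maze$lattice_cols, gt$maze$lattice_rows, gt$maze$cell_size,
                    gt$maze$c1_cell, gt$maze$c2_cell)
  sp <- data.table::fread(file.path(dir, "spikes.tsv"))
  n_units <- max(sp$unit_id)
  spikes <- lapply(seq_len(n_units), function(u) sort(sp$t_s[sp$unit_id == u]))
  lfp <- NULL
  if (file.exists(file.path(dir, "lfp.tsv"))) {
    lfp <- as.data.frame(data.table::fread(file.path(dir, "lfp.tsv")))
    meta <- jsonlite::read_json(file.path(dir, "lfp_meta.json"))
    attr(lfp, "fs") <- meta$rate_hz
  }
  tuning <- gt$tuning
  if (!is.null(tuning)) class(tuning) <- c("tuning_spec", "data.frame")
  structure(list(
    maze = maze,
    position = as.data.frame(data.table::fread(file.path(dir, "position.tsv"))),
    trials = as.data.frame(data.table::fread(file.path(dir, "trials.tsv"))),
    spikes = spikes, lfp = lfp,
    ground_truth = list(
      tuning = tuning, events = gt$events,
      phase_of_trial = gt$phase_of_trial,
      reward_replacement_trial = gt$reward_replacement_trial,
      learning_point_trial = gt$learning_point_trial)
  ), class = "rk_session")
}
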