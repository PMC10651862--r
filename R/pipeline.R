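# End-to-end orchestration: behavior -> maps -> trial matrices ->
# lever-frame -> remapping, with TSV outputs and a run manifest.

#' Run the full analysis pipeline on a session
#'
#' Executes trial/journey segmentation, the per-journey behavior table, per
#' neuron trial-matrix and lever-frame analyses, and the condition
#' remapping summary, writing one TSV per stage plus a YAML manifest (the
#' configuration and seed). Reruns with the same session and configuration
#' produce identical outputs. A stage failure aborts the run, names the
#' stage, and removes partial outputs.
#'
#' @param session A `homing_session`.
#' @param out_dir Output directory (created if needed).
#' @param n_shuffles Shuffle count for the significance tests.
#' @param frame Directional reference frame for the lever-frame stage.
#' @param seed RNG seed used by every stochastic stage.
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(session, out_dir, n_shuffles = 100,
                         frame = "cardinal", seed = 1) {
  stopifnot(n_shuffles >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e) fail(name, e))

  trials <- stage("segment", segment_trials(session))
  journeys <- stage("segment", segment_journeys(session, trials))
  emit(trials, "trials.tsv")
  emit(journeys, "journeys.tsv")

  behav <- stage("behavior", behavior_table(session, trials, journeys))
  emit(behav, "behavior.tsv")

  neurons <- names(session$spikes)
  unit_rows <- list()
  drift_rows <- list()
  for (id in neurons) {
    for (lt in unique(trials$light[!trials$excluded])) {
      row <- stage("lever_frame", {
        tmc_y <- tryCatch(trial_matrix_correlation(
          build_trial_matrix(session, trials, journeys, id, "y_coordinate",
                             "homing", light = lt))$value,
          error = function(e) NA_real_)
        tmc_d <- tryCatch(trial_matrix_correlation(
          build_trial_matrix(session, trials, journeys, id, "lever_distance",
                             "homing", light = lt))$value,
          error = function(e) NA_real_)
        la <- tryCatch(classify_lever_anchored(session, trials, journeys, id,
                                               light = lt, frame = frame,
                                               n_shuffles = n_shuffles,
                                               seed = seed),
                       error = function(e) NULL)
        cp <- NULL
        if (!is.null(la) && la$anchored) {
          cp <- tryCatch({
            dm <- build_trial_matrix(session, trials, journeys, id,
                                     "lever_direction", "at_lever",
                                     light = lt, frame = frame)
            dr <- trial_drift(dm)
            drift_rows[[length(drift_rows) + 1]] <<- data.frame(
              neuron_id = id, light = lt, trial_id = dm$meta$trial_id,
              journey_id = dm$meta$journey_id, drift = dr$delta,
              homing_direction = dm$meta$homing_direction)
            drift_homing_coupling(dr, n_shuffles = n_shuffles, seed = seed)
          }, error = function(e) NULL)
        }
        data.frame(neuron_id = id, light = lt,
                   n_spikes = length(session$spikes[[id]]),
                   tm_corr_y = tmc_y, tm_corr_dist = tmc_d,
                   anchored = if (is.null(la)) NA else la$anchored,
                   mvl = if (is.null(la)) NA_real_ else la$mvl,
                   preferred_direction = if (is.null(la)) NA_real_ else
                     la$preferred_direction,
                   map_peak_rate = if (is.null(la)) NA_real_ else
                     la$map_peak_rate,
                   drift_homing_r = if (is.null(cp)) NA_real_ else cp$r,
                   drift_homing_p = if (is.null(cp)) NA_real_ else cp$p,
                   drift_homing_slope = if (is.null(cp)) NA_real_ else cp$slope)
      })
      unit_rows[[length(unit_rows) + 1]] <- row
    }
  }
  units <- if (length(unit_rows)) do.call(rbind, unit_rows) else NULL
  if (!is.null(units)) emit(units, "lever_results.tsv")
  if (length(drift_rows)) emit(do.call(rbind, drift_rows), "trial_drift.tsv")

  remap <- stage("remapping", {
    parts <- condition_partition(session, trials, journeys)
    have <- intersect(c("SL1", "SL2", "SD1", "SD2", "SL", "SD", "HL", "HD"),
                      names(parts))
    if (length(have) >= 2 && length(session$spikes) >= 2) {
      maps <- condition_maps(session, parts[have])
      sims <- lapply(have, function(l) pair_similarity(maps[[l]], l))
      names(sims) <- have
      combs <- utils::combn(have, 2)
      data.frame(cond_a = combs[1, ], cond_b = combs[2, ],
                 r = apply(combs, 2, function(cc)
                   stability(sims[[cc[1]]], sims[[cc[2]]])$r))
    } else NULL
  })
  if (!is.null(remap)) emit(remap, "remapping.tsv")

  yaml::write_yaml(list(
    package = "homingfields",
    version = as.character(utils::packageVersion("homingfields")),
    seed = seed, n_shuffles = n_shuffles, frame = frame,
    n_trials = nrow(trials), n_neurons = length(neurons)),
    file.path(out_dir, "manifest.yaml"))

  invisible(list(trials = trials, journeys = journeys, behavior = behav,
                 units = units, remapping = remap))
}
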