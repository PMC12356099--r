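#' Write a synthetic session to disk
#'
#' Serializes a session as plain CSV/YAML: `trace.csv` (t, x, y, z, qw,
#' qx, qy, qz), `events.csv` (trial, target, source, t_light_on,
#' t_light_off, reward, catch, block), `labels.csv` (t, state, site,
#' gaze_site, gaze_eye), `saccades.csv` (ground-truth saccade table) and
#' `session.yaml` (arena/behavior/task/calibration configs plus
#' metadata). Times are seconds from session start, positions mm, angles
#' degrees.
#'
#' @param session a `synthetic_session`.
#' @param dir output directory (created if missing).
#' @param hemisphere recorded hemisphere stored in the metadata.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, hemisphere = "left") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- data.frame(t = session$trace$t,
                   x = session$trace$position[, 1],
                   y = session$trace$position[, 2],
                   z = session$trace$position[, 3],
                   qw = session$trace$orientation[, 1],
                   qx = session$trace$orientation[, 2],
                   qy = session$trace$orientation[, 3],
                   qz = session$trace$orientation[, 4])
  utils::write.csv(tr, file.path(dir, "trace.csv"), row.names = FALSE)
  utils::write.csv(session$events$trials, file.path(dir, "events.csv"),
                   row.names = FALSE)
  lb <- data.frame(t = session$trace$t, state = session$labels$state,
                   site = session$labels$site,
                   gaze_site = session$labels$gaze_site,
                   gaze_eye = session$labels$gaze_eye,
                   light = session$events$light)
  utils::write.csv(lb, file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(session$labels$saccades,
                   file.path(dir, "saccades.csv"), row.names = FALSE)
  meta <- list(hemisphere = hemisphere, rng_seed = session$rng_seed,
               variant = session$task$variant)
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  write_config(session$arena, file.path(dir, "arena.yaml"))
  write_config(session$beh, file.path(dir, "behavior.yaml"))
  write_config(session$task, file.path(dir, "task.yaml"))
  write_config(session$calib, file.path(dir, "calibration.yaml"))
  invisible(dir)
}

#' Write a spike population to disk
#'
#' `spikes.csv` (cell_id, spike_time), `waveforms.csv` (cell_id,
#' sample_index, amplitude), `cells.csv` (metadata incl. hemisphere).
#'
#' @param population a `spike_data`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_spikes <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- do.call(rbind, lapply(seq_along(population$spikes), function(j)
    if (length(population$spikes[[j]]))
      data.frame(cell_id = j, spike_time = population$spikes[[j]])
    else NULL))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  wf <- do.call(rbind, lapply(seq_along(population$waveforms), function(j)
    data.frame(cell_id = j,
               sample_index = seq_along(population$waveforms[[j]]$w),
               amplitude = population$waveforms[[j]]$w)))
  utils::write.csv(wf, file.path(dir, "waveforms.csv"), row.names = FALSE)
  utils::write.csv(population$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load and validate a session bundle
#'
#' Reads the files written by [write_session()] (and [write_spikes()] if
#' present), validating schemas and cross-file consistency: uniform
#' timestamps, unit quaternions, spike times within the trace time range,
#' matching cell ids between spikes and waveforms, and hemisphere
#' metadata.
#'
#' @param dir bundle directory.
#' @return list with `trace`, `events`, `labels`, `arena`, `beh`,
#'   `task`, `calib`, `hemisphere`, and (if present) `population`.
#' @export
load_session <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing session file: ", f)
    p
  }
  tr <- utils::read.csv(need("trace.csv"))
  req_cols <- c("t", "x", "y", "z", "qw", "qx", "qy", "qz")
  miss <- setdiff(req_cols, names(tr))
  if (length(miss))
    stop("trace.csv: missing column(s) ", paste(miss, collapse = ", "))
  q <- as.matrix(tr[, c("qw", "qx", "qy", "qz")])
  nrm <- abs(sqrt(rowSums(q^2)) - 1)
  if (any(nrm > 1e-6)) {
    bad <- which.max(nrm)
    stop(sprintf("trace.csv row %d: quaternion is not unit-norm", bad))
  }
  trace <- list(t = tr$t, position = as.matrix(tr[, c("x", "y", "z")]),
                orientation = q)
  events <- utils::read.csv(need("events.csv"))
  labels <- utils::read.csv(need("labels.csv"))
  meta <- yaml::read_yaml(need("metadata.yaml"))
  if (is.null(meta$hemisphere))
    stop("metadata.yaml: hemisphere is required (contra/ipsi undefined)")
  out <- list(trace = trace, events = events, labels = labels,
              arena = read_config(need("arena.yaml")),
              beh = read_config(need("behavior.yaml")),
              task = read_config(need("task.yaml")),
              calib = read_config(need("calibration.yaml")),
              hemisphere = meta$hemisphere)
  sp_path <- file.path(dir, "spikes.csv")
  if (file.exists(sp_path)) {
    sp <- utils::read.csv(sp_path)
    cells <- utils::read.csv(need("cells.csv"))
    wf <- utils::read.csv(need("waveforms.csv"))
    if (!setequal(unique(wf$cell_id), cells$cell_id))
      stop("waveforms.csv: cell ids do not match cells.csv")
    if (any(sp$spike_time < min(trace$t)) ||
        any(sp$spike_time > max(trace$t) + 1))
      stop(sprintf("spikes.csv row %d: spike time outside the trace range",
                   which(sp$spike_time > max(trace$t) + 1 |
                           sp$spike_time < min(trace$t))[1]))
    spikes <- lapply(cells$cell_id, function(id)
      sort(sp$spike_time[sp$cell_id == id]))
    wfs <- lapply(cells$cell_id, function(id)
      list(w = wf$amplitude[wf$cell_id == id], dt = 1 / 30000))
    out$population <- structure(list(spikes = spikes, cells = cells,
                                     waveforms = wfs,
                                     duration = max(trace$t)),
                                class = "spike_data")
  }
  out
}

#' Run the full analysis pipeline on one session
#'
#' Segments the trace, summarizes place and gaze tuning, fits the gaze
#' GLM, computes saccade-aligned PSTHs with early/late peaks, and
#' classifies cell types; writes result CSVs (with a provenance header
#' carrying the seed) into `out_dir`.
#'
#' @param session session list (from [generate_session()] or
#'   [load_session()]).
#' @param population a `spike_data`.
#' @param out_dir results directory.
#' @param seed analysis seed (shuffles).
#' @param n_shuffles shuffle repetitions for significance tests.
#' @return invisible list with `segments`, `tuning`, `glm`, `earlylate`,
#'   `classes`.
#' @export
run_pipeline <- function(session, population, out_dir, seed = 1L,
                         n_shuffles = 200) {
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arena <- session$arena
  calib <- session$calib
  segments <- segment_session(session$trace, arena, calib)
  tun <- tuning_summary(population, segments, arena,
                        n_shuffles = n_shuffles)
  glm_res <- gaze_glm_population(population, segments, session$trace,
                                 arena, calib)
  sac <- segments[segments$state == "saccade" & segments$gaze_included, ]
  psths <- lapply(population$spikes, event_aligned_rate,
                  event_times = sac$t_peak, window = c(-0.3, 0.5),
                  sigma = 0.03)
  el <- early_late_population(psths)
  feats <- lapply(seq_along(population$spikes), function(j)
    extract_waveform_features(population$waveforms[[j]]$w,
                              population$waveforms[[j]]$dt,
                              mean_rate = length(population$spikes[[j]]) /
                                population$duration,
                              n_spikes = length(population$spikes[[j]])))
  classes <- classify_ei_gmm(feats)
  write_with_header <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# remotegaze results; seed=%d", seed), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  write_with_header(as.data.frame(segments), "segments.csv")
  write_with_header(tun, "tuning.csv")
  write_with_header(glm_res, "glm.csv")
  write_with_header(cbind(cell_id = population$cells$cell_id,
                          as.data.frame(el)), "earlylate.csv")
  write_with_header(cbind(cell_id = population$cells$cell_id, classes),
                    "celltypes.csv")
  invisible(list(segments = segments, tuning = tun, glm = glm_res,
                 earlylate = el, classes = classes))
}
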