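read_run_config <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

write_provenance <- function(out_dir, step, config, seed = NULL) {
  prov <- list(step = step,
               package = "gazemend",
               version = as.character(utils::packageVersion("gazemend")),
               seed = seed,
               config = config,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(out_dir, paste0(step, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Run the cleaning step on a samples file
#'
#' Reads a sample CSV, applies [clean_recording()] and writes the cleaned
#' samples, the clean report (JSON) and the artifact table (TSV).
#'
#' @param in_path input samples CSV.
#' @param out_path cleaned samples CSV.
#' @param report_path optional clean-report JSON path.
#' @param artifacts_path optional artifact-table TSV path.
#' @param config optional run-config list (uses its `geometry` and `detector`
#'   blocks).
#' @return The [clean_recording()] result, invisibly.
#' @export
run_clean <- function(in_path, out_path, report_path = NULL,
                      artifacts_path = NULL, config = list()) {
  geom <- geometry_from_config(config$geometry)
  det <- config$detector
  cfg <- detector_config(
    speed_threshold = det$speed_threshold %||%
      deg_per_ms_to_px_per_ms(det$threshold_deg_per_ms %||% 0.9, geom),
    max_spike_ms = det$max_spike_ms %||% 10,
    max_displacement_ms = det$max_displacement_ms %||% 500,
    blink_pad_ms = det$blink_pad_ms %||% 200)
  rec <- read_samples_csv(in_path)
  res <- clean_recording(rec, cfg)
  write_samples_csv(res$recording, out_path)
  if (!is.null(report_path)) {
    rep <- res$report
    jsonlite::write_json(
      c(as.list(as.data.frame(rep)),
        list(config_used = unclass(rep$config_used))),
      report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(artifacts_path)) write_artifacts_tsv(res$artifacts,
                                                    artifacts_path)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the quantification step
#'
#' Computes the original-vs-filtered adherence table for one subject and
#' writes it as CSV.
#'
#' @param raw_path,cleaned_path original and cleaned sample CSVs.
#' @param out_path output adherence CSV.
#' @param schedule_path optional schedule config (default paradigm otherwise).
#' @param aoi_path optional AOI config (default layout otherwise).
#' @param config optional run-config list (its `geometry` block).
#' @return The adherence data frame, invisibly.
#' @export
run_quantify <- function(raw_path, cleaned_path, out_path,
                         schedule_path = NULL, aoi_path = NULL,
                         config = list()) {
  geom <- geometry_from_config(config$geometry)
  sched <- if (is.null(schedule_path)) build_default_schedule()
           else read_schedule_config(schedule_path)
  aois <- if (is.null(aoi_path)) default_aois(geom)
          else read_aoi_config(aoi_path)
  raw <- read_samples_csv(raw_path)
  cleaned <- read_samples_csv(cleaned_path)
  tab <- adherence_table(raw, cleaned, geom, sched, aois)
  utils::write.csv(tab, out_path, row.names = FALSE)
  invisible(tab)
}

#' Run the statistics step
#'
#' From a stacked adherence CSV (several subjects), runs the paired Wilcoxon
#' signed-rank test original-vs-filtered per condition on both rate columns,
#' writing results as JSON.
#'
#' @param adherence_path adherence CSV with columns
#'   `subject_id, condition, variant, onscreen_rate, task_rate`.
#' @param out_path output JSON path.
#' @return A list of test summaries, invisibly.
#' @export
run_stats <- function(adherence_path, out_path) {
  tab <- utils::read.csv(adherence_path, stringsAsFactors = FALSE)
  out <- list()
  for (cond in unique(tab$condition)) {
    for (metric in c("onscreen_rate", "task_rate")) {
      ori <- tab[tab$condition == cond & tab$variant == "original", ]
      fil <- tab[tab$condition == cond & tab$variant == "filtered", ]
      fil <- fil[match(ori$subject_id, fil$subject_id), ]
      res <- suppressWarnings(
        wilcoxon_signed_rank(fil[[metric]], ori[[metric]]))
      out[[paste(cond, metric, sep = ".")]] <-
        list(condition = cond, metric = metric,
             mean_original = mean(ori[[metric]]),
             mean_filtered = mean(fil[[metric]]),
             statistic = res$statistic, p_value = res$p_value, n = res$n,
             method = res$method_detail)
    }
  }
  jsonlite::write_json(out, out_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(out)
}

#' Simulate a validation protocol or session to disk
#'
#' Writes a dirty samples CSV, the clean truth CSV, the ground-truth artifact
#' TSV and a spec snapshot JSON into `out_dir`.
#'
#' @param protocol one of `"blink"`, `"spiral"`, `"session"`.
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed.
#' @param config optional list of generator overrides.
#' @return Paths of the written files, invisibly.
#' @export
run_simulate <- function(protocol = c("blink", "spiral", "session"), out_dir,
                         seed = 1, config = list()) {
  protocol <- match.arg(protocol)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- geometry_from_config(config$geometry)
  if (protocol == "blink") {
    truth <- generate_blink_protocol(seed = seed)
    items <- list(truth)
  } else if (protocol == "spiral") {
    rec <- generate_spiral_trace(geom = geom)
    items <- list(new_injection_truth(rec, rec, empty_artifacts(), seed))
  } else {
    spec <- config$artifact_spec %||%
      list(n_spikes = 4, n_displacements = 3, n_blinks = 8)
    items <- generate_group_session(
      n_subjects = config$n_subjects %||% 16, geom = geom,
      artifact_spec = spec, rate_hz = config$rate_hz %||% 1000, seed = seed)
  }
  paths <- character(0)
  for (it in items) {
    stem <- file.path(out_dir, it$dirty$subject_id)
    write_samples_csv(it$dirty, paste0(stem, "_samples.csv"))
    write_samples_csv(it$clean, paste0(stem, "_clean.csv"))
    write_artifacts_tsv(it$artifacts, paste0(stem, "_truth.tsv"))
    paths <- c(paths, paste0(stem, "_samples.csv"))
  }
  write_provenance(out_dir, "simulate",
                   c(list(protocol = protocol), config), seed)
  invisible(paths)
}

#' Raw-vs-cleaned QC panels
#'
#' Four-panel quality-control figure: raw and cleaned 2-D trajectories plus
#' raw and cleaned per-axis position over time.
#'
#' @param raw,cleaned [gaze_recording()]s on the same time base.
#' @param geom optional [screen_geometry()] for screen-bound overlays.
#' @return `NULL`, invisibly; draws on the active device.
#' @export
qc_plot <- function(raw, cleaned, geom = NULL) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel_traj <- function(rec, main) {
    xs <- ifelse(rec$valid, rec$x, NA); ys <- ifelse(rec$valid, rec$y, NA)
    graphics::plot(xs, ys, type = "l", xlab = "x (px)", ylab = "y (px)",
                   main = main, ylim = rev(range(ys, na.rm = TRUE)))
    if (!is.null(geom)) graphics::rect(0, geom$height_px, geom$width_px, 0,
                                       border = "grey50", lty = 2)
  }
  panel_time <- function(rec, main) {
    xs <- ifelse(rec$valid, rec$x, NA); ys <- ifelse(rec$valid, rec$y, NA)
    graphics::matplot(rec$t / 1000, cbind(xs, ys), type = "l", lty = 1,
                      col = c("black", "grey40"), xlab = "time (s)",
                      ylab = "position (px)", main = main)
  }
  panel_traj(raw, "raw trajectory")
  panel_traj(cleaned, "cleaned trajectory")
  panel_time(raw, "raw time series")
  panel_time(cleaned, "cleaned time series")
  invisible(NULL)
}
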