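#' Full-run configuration
#'
#' Bundles every sub-configuration of the per-frame processing chain
#' (segment -> depth -> pose). All sub-configs validate at construction;
#' [load_run_config()] additionally rejects unknown keys so a typo in a
#' config file cannot silently fall back to a default.
#'
#' @param segmentation a [segmentation_config()].
#' @param depth a [depth_filter_config()].
#' @param rig a [rig_config()].
#' @param near_region,far_region [region_spec()]s.
#' @param decision_table a `decision_table`.
#' @param out_dir optional output directory for reports.
#' @param log_level one of `"quiet"`, `"info"`, `"debug"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(segmentation = segmentation_config(),
                       depth = depth_filter_config(),
                       rig = rig_config(),
                       near_region = near_region_default(),
                       far_region = far_region_default(),
                       decision_table = default_decision_table(),
                       out_dir = NULL,
                       log_level = c("info", "quiet", "debug")) {
  stopifnot(inherits(segmentation, "segmentation_config"),
            inherits(depth, "depth_filter_config"),
            inherits(rig, "rig_config"),
            inherits(near_region, "region_spec"),
            inherits(far_region, "region_spec"))
  validate_decision_table(decision_table)
  structure(list(segmentation = segmentation, depth = depth, rig = rig,
                 near_region = near_region, far_region = far_region,
                 decision_table = decision_table, out_dir = out_dir,
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' Serialize / load a run configuration as JSON
#'
#' `write_run_config()` then `load_run_config()` is idempotent; loading
#' rejects unknown keys at any level.
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  x <- list(
    segmentation = unclass(config$segmentation),
    depth = unclass(config$depth),
    rig = unclass(config$rig),
    near_region = unclass(config$near_region),
    far_region = unclass(config$far_region),
    decision_table = list(
      near_bands = config$decision_table$near_bands,
      far_bands = config$decision_table$far_bands,
      rules = config$decision_table$rules),
    out_dir = config$out_dir,
    log_level = config$log_level)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @return `load_run_config()`: a validated [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort_parameter(sprintf("no such config file: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("segmentation", "depth", "rig", "near_region", "far_region",
             "decision_table", "out_dir", "log_level")
  reject_unknown <- function(got, want, where) {
    extra <- setdiff(got, want)
    if (length(extra))
      abort_teaprof(sprintf("unknown key(s) in %s: %s", where,
                            paste(extra, collapse = ", ")),
                    "teaprof_config_error")
  }
  reject_unknown(names(x), known, "run config")
  build <- function(fn, lst, where) {
    if (is.null(lst)) return(fn())
    reject_unknown(names(lst), names(formals(fn)), where)
    do.call(fn, lst)
  }
  run_config(
    segmentation = build(segmentation_config, x$segmentation, "segmentation"),
    depth = build(depth_filter_config, x$depth, "depth"),
    rig = build(rig_config, x$rig, "rig"),
    near_region = build(region_spec, x$near_region, "near_region"),
    far_region = build(region_spec, x$far_region, "far_region"),
    decision_table = if (is.null(x$decision_table)) default_decision_table()
                     else as_decision_table(x$decision_table),
    out_dir = x$out_dir,
    log_level = if (is.null(x$log_level)) "info" else x$log_level)
}

#' Process one RGB-D frame through the full chain
#'
#' segment -> depth-profile -> pose -> motion decision, returning one flat
#' report row. Deterministic: identical input and config give an identical
#' row.
#'
#' @param frame a [canopy_frame()], or `rgb` may be given as a file path
#'   together with `depth_path`.
#' @param config a [run_config()].
#' @param force_class optional lighting-class override passed to
#'   [segment_shoots()].
#' @return one-row tibble (class `frame_report`): `frame_id`, `ag`,
#'   `lighting`, `otsu_threshold`, `foreground_fraction`, `l_near`,
#'   `l_far`, `fallback_near`, `fallback_far`, `d`, `alpha`, `delta_x`,
#'   `vertical`, `rotation`, `no_op`.
#' @export
run_frame <- function(frame, config = run_config(), force_class = NULL) {
  stopifnot(inherits(frame, "canopy_frame"))
  seg <- segment_shoots(frame$rgb, config$segmentation, force_class = force_class)
  prof <- extract_l_values(frame, seg, config$near_region, config$far_region,
                           config$depth)
  pose <- pose_pipeline(config$rig, config$decision_table,
                        prof$l_near, prof$l_far)
  out <- tibble::tibble(
    frame_id = frame$frame_id,
    ag = seg$lighting$ag_value,
    lighting = seg$lighting$label,
    otsu_threshold = seg$threshold,
    foreground_fraction = seg$foreground_fraction,
    l_near = prof$l_near, l_far = prof$l_far,
    fallback_near = prof$fallback_near, fallback_far = prof$fallback_far,
    d = pose$d, alpha = pose$alpha, delta_x = pose$delta_x,
    vertical = pose$decision$vertical, rotation = pose$decision$rotation,
    no_op = pose$no_op)
  class(out) <- c("frame_report", class(out))
  out
}

#' @rdname run_frame
#' @param rgb_path,depth_path image file paths (see [read_rgb_png()],
#'   [read_depth_raster()]); shapes must match.
#' @export
run_frame_files <- function(rgb_path, depth_path, config = run_config(),
                            force_class = NULL) {
  rgb <- read_rgb_png(rgb_path)
  depth <- read_depth_raster(depth_path)
  frame <- canopy_frame(rgb, depth,
                        frame_id = tools::file_path_sans_ext(basename(rgb_path)))
  run_frame(frame, config, force_class = force_class)
}

#' Process a batch of frames, isolating per-frame failures
#'
#' Runs [run_frame()] over a list of frames (or a manifest of file pairs).
#' A failing frame is recorded with its error message and does not stop the
#' batch.
#'
#' @param frames list of [canopy_frame()] objects, or a data frame with
#'   columns `rgb` and `depth` of file paths.
#' @param config a [run_config()].
#' @return list with `reports` (tibble of successful frame rows),
#'   `failures` (tibble frame_id/error), and `summary` (list: `n`,
#'   `n_failed`, `mean_abs_d`, `decision_histogram`).
#' @export
run_batch <- function(frames, config = run_config()) {
  if (is.data.frame(frames)) {
    if (nrow(frames) == 0L) abort_parameter("empty batch manifest")
    items <- lapply(seq_len(nrow(frames)), function(i)
      list(id = tools::file_path_sans_ext(basename(frames$rgb[i])),
           run = function() run_frame_files(frames$rgb[i], frames$depth[i], config)))
  } else {
    if (length(frames) == 0L) abort_parameter("empty batch")
    items <- lapply(frames, function(f)
      list(id = f$frame_id, run = function() run_frame(f, config)))
  }
  reports <- list(); failures <- list()
  for (it in items) {
    res <- tryCatch(it$run(), error = function(e)
      structure(list(message = conditionMessage(e)), class = "teaprof_failure"))
    if (inherits(res, "teaprof_failure")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(frame_id = it$id, error = res$message)
    } else {
      reports[[length(reports) + 1L]] <- res
    }
  }
  reports <- if (length(reports)) do.call(rbind, reports) else
    tibble::tibble(frame_id = character())
  failures <- if (length(failures)) do.call(rbind, failures) else
    tibble::tibble(frame_id = character(), error = character())
  decisions <- if (nrow(reports))
    table(paste(reports$vertical, reports$rotation, sep = "/")) else table(character())
  list(reports = reports, failures = failures,
       summary = list(n = length(items), n_failed = nrow(failures),
                      mean_abs_d = if (nrow(reports)) mean(abs(reports$d)) else NA_real_,
                      decision_histogram = decisions))
}

#' Append frame reports to a CSV log
#'
#' Schema-versioned CSV (header comment `# teaprof-log v1`); floats are
#' printed at 4 decimals to keep rows byte-stable across runs.
#'
#' @param report a `frame_report` tibble (one or more rows).
#' @param path CSV file path; created with the header if absent.
#' @export
append_frame_log <- function(report, path) {
  fmt <- function(x) if (is.numeric(x)) sprintf("%.4f", x) else as.character(x)
  df <- as.data.frame(lapply(report, fmt), stringsAsFactors = FALSE)
  new <- !file.exists(path)
  con <- file(path, open = "a")
  on.exit(close(con))
  if (new) {
    writeLines("# teaprof-log v1", con)
    writeLines(paste(names(df), collapse = ","), con)
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
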