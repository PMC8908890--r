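# Run configuration and the end-to-end analysis pipeline:
# detect -> segment -> identify -> evaluate.

#' Read a run configuration
#'
#' YAML configuration with a \code{subject} block (\code{height_m},
#' \code{mass_kg}), an optional \code{thresholds} block (fields of
#' [detector_thresholds()]), an optional \code{controller} block
#' (\code{zeta1}/\code{zeta2} or \code{constraint_product}), and optional
#' \code{frame} (\code{global}/\code{local}), \code{seed} and
#' \code{sample_rate}.
#'
#' @param path YAML file path.
#' @return A validated list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(cfg)
}

#' @rdname read_run_config
#' @param config A raw configuration list.
#' @export
run_config <- function(config = list()) {
  cfg <- config
  cfg$frame <- if (is.null(cfg$frame)) "global" else match.arg(cfg$frame, c("global", "local"))
  cfg$seed <- if (is.null(cfg$seed)) 0L else as.integer(cfg$seed)
  cfg$sample_rate <- if (is.null(cfg$sample_rate)) 60 else cfg$sample_rate
  if (cfg$sample_rate <= 0) stop("sample_rate must be positive")
  if (!is.null(cfg$subject)) {
    if (is.null(cfg$subject$height_m) || is.null(cfg$subject$mass_kg))
      stop("subject block needs height_m and mass_kg")
  }
  if (!is.null(cfg$thresholds))
    cfg$thresholds_obj <- do.call(detector_thresholds, cfg$thresholds)
  else cfg$thresholds_obj <- detector_thresholds()
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline on a recording
#'
#' Sequencing of the balance-control model generation: gait-phase
#' detection, window segmentation, controller identification and
#' evaluation. Every default the run applied (thresholds, seed, frame) is
#' recorded in the returned report so a rerun from the report reproduces
#' the outputs.
#'
#' @param config A \code{run_config} (or plain list).
#' @param recording A \code{gait_recording}.
#' @return A list of class \code{pipeline_report}: effective config, phase
#'   statistics, fitted controller parameters and RMSE.
#' @export
run_pipeline <- function(config, recording) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (!inherits(recording, "gait_recording"))
    stop("stage input: `recording` must be a gait_recording")
  subject <- if (!is.null(config$subject))
    build_subject_model(config$subject$height_m, config$subject$mass_kg)
  else NULL

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  rec <- recording
  if (identical(config$frame, "local") &&
      !identical(attr(rec, "frame"), "local"))
    rec <- stage("local_frame", to_local_frame(rec))

  timelines <- stage("detect",
                     detect_phases(rec, model = subject,
                                   thresholds = config$thresholds_obj))
  stats <- stage("statistics",
                 tryCatch(cycle_statistics(timelines),
                          error = function(e) NULL))
  segments <- stage("segment",
                    segment_trials(timelines,
                                   t_end = rec$time_s[nrow(rec)]))
  cp <- if (!is.null(config$controller)) config$controller$constraint_product
        else NULL
  fit <- stage("identify",
               fit_balance_controller(rec, timelines = timelines,
                                      segments = segments,
                                      constraint_product = cp,
                                      seed = config$seed))
  trace <- stage("evaluate", model_zmp_trace(fit))

  report <- list(
    config = list(
      frame = config$frame, seed = config$seed,
      sample_rate = config$sample_rate,
      subject = config$subject,
      thresholds = unclass(config$thresholds_obj),
      constraint_product = cp),
    phases = if (!is.null(stats)) list(
      stance_percent = stats$stance_mean,
      swing_percent = stats$swing_mean,
      per_leg = stats$stance_swing,
      per_phase = stats$summary) else NULL,
    n_windows = nrow(segments),
    controller = list(zeta1 = fit$zeta1, zeta2 = fit$zeta2,
                      product = fit$zeta1 * fit$zeta2,
                      rmse_m = fit$rmse,
                      converged = fit$converged),
    anchors = fit$segments
  )
  structure(report, class = "pipeline_report", fit = fit, trace = trace)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("gait balance-control pipeline report\n")
  if (!is.null(x$phases))
    cat(sprintf("  stance/swing: %.1f%% / %.1f%%\n",
                x$phases$stance_percent, x$phases$swing_percent))
  cat(sprintf("  windows: %d\n", x$n_windows))
  cat(sprintf("  controller: zeta1 = %.3f, zeta2 = %.3f (product %.3f), rmse = %.4g m\n",
              x$controller$zeta1, x$controller$zeta2, x$controller$product,
              x$controller$rmse_m))
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report A \code{pipeline_report}.
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$phases$per_leg <- NULL; out$phases$per_phase <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
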