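#' End-to-end principal process analysis
#'
#' Runs the full chain -- entrainment burn-in, simulation, weights, activity
#' classification, always-inactive elimination, switching-time clustering,
#' sub-model schedule, and reduction errors -- and optionally writes every
#' artefact (CSV/JSON tables, figures) to a directory.
#'
#' The default protocol for forced models analyses the *entrained* cycle:
#' the system is integrated for `burn_in` forcing periods and the analysis
#' window is the following full period, re-based so that the forcing phase
#' (lights-on for the clock) starts at 0.
#'
#' @param model a [process_model()] or a built-in model name.
#' @param delta activity threshold (default 0.1).
#' @param grid_step analysis grid step in hours (default 0.01).
#' @param burn_in number of entrainment periods before the analysis window
#'   (default 2 for forced models, 0 for autonomous ones).
#' @param clusters_override force the cluster count instead of the
#'   activity-range rule.
#' @param propagate propagate sub-model states across windows in the error
#'   run.
#' @param out_dir artefact directory (`NULL` = compute only).
#' @param error_grid_step quadrature step for the error tables.
#' @param figures also render the three process maps (needs a display-less
#'   device; PNG).
#' @return A `ppa_result` with every intermediate object and a `summary`
#'   list.
#' @export
run_pipeline <- function(model = "clock", delta = 0.1, grid_step = 0.01,
                         burn_in = NULL, clusters_override = NULL,
                         propagate = FALSE, out_dir = NULL,
                         error_grid_step = 0.01, figures = !is.null(out_dir)) {
  if (is.character(model)) model <- builtin_model(model)
  if (is.null(burn_in)) burn_in <- if (is.null(model$forcing)) 0 else 2

  x0 <- entrained_state(model, periods = burn_in)
  span <- model$horizon
  tt <- seq(span[1], span[2], by = grid_step)
  traj <- simulate_model(model, tt, x0 = x0)
  w <- compute_weights(model, traj)
  cls <- classify_activity(w, delta = delta)
  activity <- cls$activity
  switching <- cls$switching
  reduced <- eliminate_always_inactive(model, activity)

  z <- if (!is.null(clusters_override)) as.integer(clusters_override)
       else choose_cluster_count(activity)
  clusters <- if (z >= 1 && nrow(switching) >= z)
    cluster_switching_times(switching$time, z)
  schedule <- build_schedule(model, activity, switching, clusters, x0 = x0)

  global_err <- {
    red_traj <- simulate_model(model, tt, x0 = x0, mask = reduced$mask)
    global_relative_error(evaluate_outputs(traj),
                          evaluate_outputs(red_traj), tt)
  }
  win_err <- windowed_errors(model, schedule, propagate = propagate,
                             grid_step = error_grid_step)

  summary <- list(
    model = model$name, delta = delta, grid_step = grid_step,
    burn_in_periods = burn_in,
    n_processes = length(model$labels),
    n_always_inactive = length(activity$always_inactive),
    always_inactive = activity$always_inactive,
    n_switching_times = nrow(switching),
    active_process_range = as.numeric(activity_extrema(activity)),
    n_clusters = z,
    cluster_means = if (!is.null(clusters)) clusters$means,
    window_boundaries = schedule$boundaries,
    global_errors = as.list(global_err),
    window_output_errors = apply(win_err$outputs, 1, as.list),
    tolerances = c(rtol = 1e-8, atol = 1e-10),
    propagate = propagate)

  res <- structure(
    list(model = model, trajectory = traj, weights = w,
         activity = activity, switching = switching, reduced = reduced,
         clusters = clusters, schedule = schedule,
         global_errors = global_err, window_errors = win_err,
         summary = summary),
    class = "ppa_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(out_dir, f)
    write_trajectory_csv(traj, fp("trajectory.csv"))
    write_weights_csv(w, activity, fp("weights.csv"))
    write_switching_csv(switching, fp("switching_times.csv"))
    write_schedule_json(schedule, fp("schedule.json"))
    err_df <- data.frame(
      window = rep(rownames(win_err$outputs), ncol(win_err$outputs)),
      output = rep(colnames(win_err$outputs), each = nrow(win_err$outputs)),
      propagate = propagate,
      error = as.vector(win_err$outputs))
    utils::write.csv(err_df, fp("window_errors.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, fp("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (figures) {
      render_boolean_map(activity, fp("boolean_map.png"))
      if (length(model$links))
        render_dynamical_map(model, schedule$masks[[min(3, length(schedule$masks))]],
                             fp("dynamical_map.png"))
      render_3d_map(w, length(model$variables), fp("weight_map.png"))
    }
  }
  res
}

#' @export
print.ppa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ppa_result> %s @ delta = %g\n", s$model, s$delta))
  cat(sprintf("  %d/%d processes always inactive; %d switching times; %d clusters\n",
              s$n_always_inactive, s$n_processes, s$n_switching_times,
              s$n_clusters))
  cat("  global output errors:",
      paste(sprintf("%s=%.4f", names(x$global_errors), x$global_errors),
            collapse = " "), "\n")
  invisible(x)
}

#' Factorial sensitivity analysis of a window's reduction error
#'
#' Builds the two-level resolution-V design over the varied parameters, runs
#' the reduction-error experiment for the requested window, computes the
#' PCA-generalised sensitivity indices and the neglected-parameter share of
#' the top-k tGSI.
#'
#' @param result a `ppa_result` from [run_pipeline()].
#' @param window window index `v`.
#' @param max_runs design size cap (default 4096).
#' @param factors parameter names to vary; default: every model parameter
#'   except those marked fixed in `model$meta$fixed_parameters`.
#' @param rel_levels low/high multipliers (default 0.8/1.2).
#' @param k top-factor count for the inactive-parameter ratio.
#' @param grid_step experiment quadrature step (hours).
#' @param out_dir optional artefact directory.
#' @param progress print progress dots.
#' @return A `ppa_sensitivity`: the design, experiment, `gsi`, per-factor
#'   index table and `ratio` (percentage).
#' @export
run_sensitivity <- function(result, window, max_runs = 4096,
                            factors = NULL, rel_levels = c(0.8, 1.2),
                            k = 10, grid_step = 0.05, out_dir = NULL,
                            progress = FALSE) {
  model <- result$model
  schedule <- result$schedule
  if (is.null(schedule)) stop("run_pipeline() result carries no schedule")
  if (is.null(factors)) {
    fixed <- model$meta$fixed_parameters
    factors <- setdiff(names(model$parameters), fixed)
  }
  k <- min(k, length(factors))
  design <- build_two_level_design(length(factors), max_runs = max_runs,
                                   factor_names = factors)
  exper <- run_error_experiment(model, schedule, design, window,
                                targets = "variables",
                                rel_levels = rel_levels,
                                grid_step = grid_step, progress = progress)
  gsi <- pca_generalised_indices(exper$errors, exper$design_matrix)
  inactive_par <- intersect(
    parameters_in_processes(model, schedule$dropped[[window]]), factors)
  ratio <- inactive_parameter_ratio(gsi, inactive_par, k = k)

  per_resp_tsi <- lapply(seq_len(ncol(exper$errors)), function(h) {
    total_sensitivity_indices(
      anova_decompose(exper$errors[, h], exper$design_matrix))
  })
  names(per_resp_tsi) <- colnames(exper$errors)

  table <- data.frame(window = window, factor = factors,
                      tGSI = gsi$tGSI[factors],
                      inactive_class = factors %in% inactive_par)
  table <- table[order(-table$tGSI), ]
  rownames(table) <- NULL

  res <- structure(list(design = design, experiment = exper, gsi = gsi,
                        per_response_tsi = per_resp_tsi,
                        inactive_parameters = inactive_par,
                        table = table, ratio = ratio, window = window,
                        k = k),
                   class = "ppa_sensitivity")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_design_csv(design, file.path(out_dir,
                                       sprintf("design_w%d.csv", window)))
    utils::write.csv(table,
                     file.path(out_dir, sprintf("tgsi_w%d.csv", window)),
                     row.names = FALSE, quote = FALSE)
    tsi_long <- do.call(rbind, lapply(names(per_resp_tsi), function(h)
      data.frame(window = window, response = h, factor = factors,
                 tSI = per_resp_tsi[[h]]$tSI[factors],
                 tSI_prime = per_resp_tsi[[h]]$tSI_prime[factors])))
    utils::write.csv(tsi_long,
                     file.path(out_dir, sprintf("tsi_w%d.csv", window)),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(window = window, k = k, ratio_percent = ratio,
           n_failed_runs = exper$n_failed,
           top_factors = utils::head(table$factor, k)),
      file.path(out_dir, sprintf("ratio_w%d.json", window)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.ppa_sensitivity <- function(x, ...) {
  cat(sprintf("<ppa_sensitivity> window %d: %d runs, %d PCA components\n",
              x$window, nrow(x$experiment$errors), x$gsi$n_components))
  cat(sprintf("  top-%d inactive-parameter tGSI share: %.2f%%\n",
              x$k, x$ratio))
  print(utils::head(x$table, 5))
  invisible(x)
}
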