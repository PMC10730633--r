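# Reproducibility shell: validated scenario configurations, bundled
# experiment definitions, a deterministic run pipeline and file writers.

default_config <- function() {
  list(
    model = list(variant = "apical", g_ChR2 = 0.3),
    tissue = list(nx = 100L, ny = 100L, dx = 0.025, D = 0.0014,
                  dt = 0.01, scheme = "split"),
    init = list(method = "phase_seed", s2_delay = 45, settle = 200,
                period = 66),
    protocol = list(mode = "none", fp = NA, width_ms = 33, intensity = 20,
                    electrode_xy_cm = c(NA, NA), Vc_mV = -40, n_max = Inf),
    analysis = list(trace_point_cm = c(0.625, 1.875), V_iso = -40),
    run = list(duration_ms = 1000, snapshot_interval_ms = 2,
               trace_dt_ms = 0.5, seed = 1L, stop_on_termination = TRUE)
  )
}

config_sections <- function() {
  lapply(default_config(), names)
}

#' Validate a scenario configuration
#'
#' Checks section and key names (unknown keys are rejected) and elementary
#' value constraints before a run starts.
#'
#' @param config A scenario configuration list (see [scenario_config()]).
#' @return The validated config, invisibly; errors mention the offending
#'   key path.
#' @export
validate_config <- function(config) {
  ref <- config_sections()
  bad <- setdiff(names(config), names(ref))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(config)) {
    unknown <- setdiff(names(config[[sec]]), ref[[sec]])
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0(sec, ".", unknown), collapse = ", "))
  }
  ts <- config$tissue
  if (!is.null(ts$dt) && !is.null(ts$dx) && !is.null(ts$D) &&
      ts$D > 0 && ts$dt >= ts$dx^2 / (4 * ts$D))
    stop(sprintf("tissue.dt = %g violates the diffusion stability bound %g ms",
                 ts$dt, ts$dx^2 / (4 * ts$D)))
  pr <- config$protocol
  if (!is.null(pr$mode) && !pr$mode %in% c("none", "open_loop", "feedback"))
    stop("protocol.mode must be one of none, open_loop, feedback")
  if (identical(pr$mode, "open_loop") && (is.null(pr$fp) || !is.finite(pr$fp)))
    stop("protocol.fp is required for open-loop pacing")
  if (identical(pr$mode, "feedback") && any(!is.finite(pr$electrode_xy_cm)))
    stop("protocol.electrode_xy_cm is required for feedback pacing")
  invisible(config)
}

merge_config <- function(base, override) {
  for (sec in names(override)) {
    if (is.list(override[[sec]]) && is.list(base[[sec]]))
      base[[sec]][names(override[[sec]])] <- override[[sec]]
    else base[[sec]] <- override[[sec]]
  }
  base
}

bundled_scenarios <- function() {
  fig3 <- function(xy) list(
    protocol = list(mode = "feedback", electrode_xy_cm = xy))
  list(
    fig1A_unpaced = list(
      protocol = list(mode = "none"),
      run = list(duration_ms = 400, stop_on_termination = FALSE)),
    fig1B_overdrive = list(protocol = list(mode = "open_loop", fp = 15.6)),
    fig1C_resonant = list(protocol = list(mode = "open_loop", fp = 13.33)),
    fig1D_underdrive = list(protocol = list(mode = "open_loop", fp = 12.5)),
    fig3A_feedback = fig3(c(1, 1)),
    fig3B_feedback = fig3(c(1.875, 1.25)),
    fig3C_feedback = fig3(c(1.25, 1.875)),
    fig3D_feedback_corner = fig3(c(2.4, 0.1))
  )
}

#' List the bundled experiment scenarios
#'
#' Eight named scenarios: the unpaced spiral, the three open-loop pacing
#' regimes (overdrive 15.6 Hz, resonant 13.33 Hz, underdrive 12.5 Hz) and
#' the four feedback-electrode placements (three bulk, one domain corner).
#'
#' @return Character vector of scenario names.
#' @export
list_scenarios <- function() names(bundled_scenarios())

#' Retrieve a scenario configuration
#'
#' @param name A scenario name from [list_scenarios()], or `NULL` for the
#'   default (unprotocolled) configuration skeleton.
#' @param overrides Named list of section-level overrides merged on top.
#' @return A validated configuration list.
#' @export
scenario_config <- function(name = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(name)) {
    sc <- bundled_scenarios()
    if (!name %in% names(sc))
      stop("unknown scenario '", name, "'; see list_scenarios()")
    cfg <- merge_config(cfg, sc[[name]])
    cfg$name <- NULL
    attr(cfg, "scenario") <- name
  }
  cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  cfg
}

#' Read / write a scenario configuration file
#'
#' YAML when the `yaml` package is available (the native format), JSON
#' otherwise; `read_config()` detects the format from the extension.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @param config Configuration list.
#' @return `read_config()` returns the validated configuration.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  # JSON serializes Inf as a string; restore the numeric pulse cap
  if (!is.null(cfg$protocol$n_max))
    cfg$protocol$n_max <- as.numeric(cfg$protocol$n_max)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to write YAML configs")
    yaml::write_yaml(config, path)
  } else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
  invisible(path)
}

upstroke_times <- function(t, V, thr = -40) {
  i <- which(V[-1] >= thr & V[-length(V)] < thr)
  t[i] + (thr - V[i]) / (V[i + 1] - V[i]) * (t[i + 1] - t[i])
}

#' Run a bundled or custom scenario
#'
#' Executes the full pipeline: settle resting tissue, initiate the spiral,
#' measure its dark rotation frequency, run the configured illumination
#' protocol (pulse onset anchored to the next predicted upstroke at the
#' domain center), and analyze the outcome (illuminated frequency, tip
#' trajectory, meander class, termination).  The pipeline is deterministic:
#' identical configurations produce identical outputs.
#'
#' @param config A scenario name (string) or configuration list.
#' @param overrides Named list of overrides (e.g.
#'   `list(run = list(duration_ms = 500))`).
#' @param output_dir Optional directory; when given, writes `trace.csv`,
#'   `trajectory.csv`, `events.csv`, `report.json` and `manifest.json`.
#' @param grid Optional pre-initiated spiral grid (skips settling and
#'   initiation; used to share one spiral across protocol runs).
#' @return A list of class `"run_manifest"`: configuration echo and hash,
#'   package version, timing, measured `fs_dark` and `fs_light`,
#'   `terminated`, `pulses_fired`, the `"tissue_sim"` result (`sim`), the
#'   tip trajectory and meander classification (when snapshots were
#'   recorded), and output paths.
#' @export
run_scenario <- function(config, overrides = list(), output_dir = NULL,
                         grid = NULL) {
  if (is.character(config)) config <- scenario_config(config, overrides)
  else config <- validate_config(merge_config(config, overrides))
  t_begin <- Sys.time()
  set.seed(config$run$seed)   # dynamics are deterministic; recorded for provenance

  cp <- cell_params(config$model$variant)
  qp <- chr2_params(g_ChR2 = config$model$g_ChR2)
  ts <- config$tissue

  if (is.null(grid)) {
    g <- tissue_grid(ts$nx, ts$ny, ts$dx, ts$D, params = cp, chr2 = qp)
    g <- initiate_spiral(g,
                         spiral_init_spec(s2_delay = config$init$s2_delay),
                         settle = config$init$settle, dt = ts$dt,
                         method = config$init$method,
                         period = config$init$period)
  } else g <- grid

  itr <- attr(g, "init_trace")
  ups <- upstroke_times(itr$t, itr$V)
  if (length(ups) < 3) stop("initiation trace shows fewer than 3 rotations")
  fs_dark <- 1000 * (length(ups) - 1) / diff(range(ups))
  # pulse onset anchored to the predicted next upstroke at the domain center
  t_anchor <- ups[length(ups)] + mean(diff(ups))

  pr <- config$protocol
  protocol <- switch(pr$mode,
    none = NULL,
    open_loop = pulse_train(pr$fp, width = pr$width_ms, Ee_on = pr$intensity,
                            t_start = max(g$t, t_anchor), n_max = pr$n_max),
    feedback = feedback_controller(pr$electrode_xy_cm, Vc = pr$Vc_mV,
                                   width = pr$width_ms, Ee_on = pr$intensity))

  tp <- config$analysis$trace_point_cm
  sensors <- rbind(tp, c((ts$nx - 1) * ts$dx / 2, (ts$ny - 1) * ts$dx / 2))
  if (pr$mode == "feedback") sensors <- rbind(sensors, pr$electrode_xy_cm)

  sim <- simulate_tissue(g, config$run$duration_ms, dt = ts$dt,
                         protocol = protocol, sensors = sensors,
                         trace_dt = config$run$trace_dt_ms,
                         snapshot_dt = config$run$snapshot_interval_ms,
                         stop_on_termination = config$run$stop_on_termination,
                         scheme = ts$scheme)

  # illuminated frequency from the trace point, within the protocol window
  tr <- sim$trace
  fs_light <- NA_real_
  if (pr$mode != "none") {
    lit <- tr$t >= (if (nrow(sim$events)) min(sim$events$t_on) else Inf)
    if (any(lit)) {
      u2 <- upstroke_times(tr$t[lit], tr$V1[lit])
      if (length(u2) >= 3)
        fs_light <- 1000 * (length(u2) - 1) / diff(range(u2))
    }
  }

  traj <- NULL; meander <- NULL
  if (!is.null(sim$snapshots) && dim(sim$snapshots)[3] >= 3) {
    traj <- track_tip(sim$snapshots, sim$snap_t, ts$dx,
                      V_iso = config$analysis$V_iso)
    if (nrow(sim$events) >= 4 && nrow(traj) > 10)
      meander <- tryCatch(
        classify_meander(traj, events = sim$events,
                         centroid = if (pr$mode == "feedback") pr$electrode_xy_cm),
        error = function(e) NULL)
  }

  outputs <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tr, file.path(output_dir, "trace.csv"), row.names = FALSE)
    outputs <- "trace.csv"
    if (!is.null(traj)) {
      write.csv(as.data.frame(traj), file.path(output_dir, "trajectory.csv"),
                row.names = FALSE)
      outputs <- c(outputs, "trajectory.csv")
    }
    write.csv(sim$events, file.path(output_dir, "events.csv"), row.names = FALSE)
    outputs <- c(outputs, "events.csv")
    report <- list(label = meander$label %||% NA, fs_dark = fs_dark,
                   fs_light = fs_light,
                   fp = if (pr$mode == "open_loop") pr$fp else NA,
                   terminated = sim$terminated,
                   pulses_fired = sim$pulses_fired)
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, "report.json")
  }

  manifest <- structure(list(
    scenario = attr(config, "scenario") %||% "custom",
    config = config, config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("optospiral")),
    started = format(t_begin, "%Y-%m-%d %H:%M:%OS3"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
    fs_dark = fs_dark, fs_light = fs_light,
    terminated = sim$terminated, t_terminated = sim$t_terminated,
    pulses_fired = sim$pulses_fired,
    meander = meander$label %||% NA_character_,
    outputs = outputs, sim = sim, trajectory = traj, meander_detail = meander),
    class = "run_manifest")

  if (!is.null(output_dir)) {
    mpath <- file.path(output_dir, "manifest.json")
    tmp <- paste0(mpath, ".tmp")
    slim <- manifest[setdiff(names(manifest), c("sim", "trajectory", "meander_detail"))]
    jsonlite::write_json(slim, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    file.rename(tmp, mpath)   # atomic manifest write
  }
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> scenario: %s (package %s)\n", x$scenario,
              x$package_version))
  cat(sprintf("  fs_dark = %.2f Hz;  fs_light = %s\n", x$fs_dark,
              if (is.finite(x$fs_light)) sprintf("%.2f Hz", x$fs_light) else "n/a"))
  cat(sprintf("  pulses fired: %d;  terminated: %s;  meander: %s\n",
              x$pulses_fired,
              if (x$terminated) sprintf("yes (t = %.0f ms)", x$t_terminated) else "no",
              x$meander))
  invisible(x)
}
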