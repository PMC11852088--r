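# Configuration files, result serialization.
#
# A run is fully described by one nested YAML configuration (strictly
# validated: unknown keys are rejected) plus a seed; results are written as
# a CSV time-series table with a JSON sidecar carrying the metrics and the
# fully resolved configuration, so that every run is reproducible from its
# outputs alone.

#' Default run configuration
#'
#' The nested parameter blocks with every simulation default: the internal
#' model (3 kg / 30 ms / 1000 N point-mass abstraction, 5 ms steps, N = 221,
#' dwell 21, 50 ms delay, noise covariances), the musculoskeletal arm
#' fixture overrides, the robot (0.3 m / 0.5 kg links), the synergy learning
#' settings, the controllers (NMPC horizon 50; impedance 50 N/m, 10 N s/m,
#' 50 ms advance), and the scenario block.
#'
#' @return nested list of class `run_config`
#' @export
default_config <- function() {
  structure(list(
    # 'steps' and 'dwell' are the horizon length and terminal dwell in
    # control ticks (bare N/D would parse as YAML booleans)
    internal = list(m = 3, tau = 0.030, fmax = 1000, dt = 0.005,
                    steps = 221L, dwell = 21L, delay = 0.050,
                    xi = 2e-7, omega = 1e-6, eta = 1e-9, mult_scale = 0.2),
    arm = list(hand_mass = 1.8, fl_width = 0.4, v_max = 10, fv_max = 1.5,
               tau_act = 0.015, tau_deact = 0.050,
               shoulder_x = 0, shoulder_y = 0),
    robot = list(l1 = 0.3, l2 = 0.3, m1 = 0.5, m2 = 0.5,
                 d1 = 0.15, d2 = 0.15, I1 = 5e-3, I2 = 5e-3,
                 base_x = 0, base_y = 0.75),
    synergies = list(n_directions = 16L, n_synergies = 4L, seed = 1L),
    nmpc = list(Np = 50L, beta_bound = 20, maxit = 8, tol = 1e-6),
    impedance = list(kp = 50, kd = 10, time_shift = 0.050),
    scenario = list(type = "reach", target_x = -0.25, target_y = 0.40,
                    robot_mode = "none", field_b = 0,
                    radius = 0.12, n_targets = 8L,
                    start_x = 0, start_y = 0.40,
                    noise = FALSE, seed = 1L)
  ), class = "run_config")
}

# Recursive merge with strict unknown-key and type checking.
.merge_config <- function(base, over, path = "") {
  for (nm in names(over)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      stop(sprintf("unknown configuration key '%s'", here), call. = FALSE)
    }
    if (is.list(base[[nm]])) {
      stop_if(!is.list(over[[nm]]), sprintf("key '%s' must be a block", here))
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]], here)
    } else {
      v <- over[[nm]]
      if (is.numeric(base[[nm]]) && !is.numeric(v)) {
        stop(sprintf("key '%s' must be numeric", here), call. = FALSE)
      }
      if (is.logical(base[[nm]]) && !is.logical(v)) {
        stop(sprintf("key '%s' must be logical", here), call. = FALSE)
      }
      base[[nm]] <- v
    }
  }
  base
}

.check_config <- function(cfg) {
  with(cfg$internal, {
    stop_if(dt <= 0, "internal.dt must be positive")
    stop_if(tau <= 0 || m <= 0 || fmax <= 0, "internal model constants must be positive")
    stop_if(steps <= dwell, "internal.steps must exceed internal.dwell")
  })
  stop_if(!cfg$scenario$type %in% c("reach", "center_out"),
          "scenario.type must be 'reach' or 'center_out'")
  stop_if(!cfg$scenario$robot_mode %in% c("none", "off", "nmpc", "impedance"),
          "scenario.robot_mode must be one of none/off/nmpc/impedance")
  invisible(cfg)
}

#' Load a run configuration
#'
#' Resolution precedence: package defaults, then the YAML file, then the
#' supplied overrides. Unknown keys anywhere raise an error naming the key.
#'
#' @param path YAML file path, or `NULL` for pure defaults
#' @param overrides named nested list of final overrides
#' @return resolved `run_config`
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    stop_if(!file.exists(path), sprintf("config file '%s' not found", path))
    fromfile <- yaml::read_yaml(path)
    if (length(fromfile)) cfg <- .merge_config(cfg, fromfile)
  }
  if (length(overrides)) cfg <- .merge_config(cfg, overrides)
  .check_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Write a resolved configuration to YAML
#'
#' @param cfg `run_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

# Instantiate the model objects a scenario needs from a run_config.
config_to_models <- function(cfg) {
  arm <- arm_model_default(
    shoulder_pos = c(cfg$arm$shoulder_x, cfg$arm$shoulder_y),
    hand_mass = cfg$arm$hand_mass, fl_width = cfg$arm$fl_width,
    v_max = cfg$arm$v_max, fv_max = cfg$arm$fv_max,
    tau_act = cfg$arm$tau_act, tau_deact = cfg$arm$tau_deact)
  robot <- robot_params(l1 = cfg$robot$l1, l2 = cfg$robot$l2,
                        m1 = cfg$robot$m1, m2 = cfg$robot$m2,
                        d1 = cfg$robot$d1, d2 = cfg$robot$d2,
                        I1 = cfg$robot$I1, I2 = cfg$robot$I2,
                        base = c(cfg$robot$base_x, cfg$robot$base_y))
  sc <- cfg$scenario
  int <- cfg$internal
  scen <- scenario_config(
    type = sc$type, target = c(sc$target_x, sc$target_y),
    robot_mode = sc$robot_mode, field_b = sc$field_b,
    N = int$steps, D = int$dwell, dt = int$dt,
    radius = sc$radius, n_targets = sc$n_targets,
    noise = sc$noise, seed = sc$seed,
    start_offset = c(sc$start_x, sc$start_y),
    internal = int[c("m", "tau", "fmax", "delay", "xi", "omega", "eta", "mult_scale")],
    nmpc = cfg$nmpc, impedance = cfg$impedance)
  list(arm = arm, robot = robot, scenario = scen)
}

# Column layout of the result CSV (documented, stable order).
.result_columns <- function() {
  c("time", "hand_x", "hand_y", "handv_x", "handv_y",
    "q1", "q2", "qd1", "qd2", "theta1", "theta2", "thetad1", "thetad2",
    paste0("a", 1:6), paste0("e", 1:6), "u1", "u2",
    paste0("xhat", 1:6), "T1", "T2", "Fint_x", "Fint_y", "gap", "effort")
}

#' Write a simulation result to disk
#'
#' Produces `<path>.csv` (the full time series, one row per control tick,
#' columns as documented in the CSV header order: time, hand kinematics,
#' human and robot joint states, activations, excitations, abstract
#' commands, belief, torques, interaction force, constraint gap, and
#' instantaneous squared excitation) and `<path>.json` (movement metrics,
#' the resolved scenario description, seed, and package version). The pair
#' can be reloaded losslessly at stored precision with [read_result()].
#'
#' @param result `simulation_result`
#' @param path output path prefix (without extension)
#' @param metrics optional precomputed `movement_metrics`
#' @param create_dirs create missing parent directories
#' @return named character vector with the two file paths, invisibly
#' @export
write_result <- function(result, path, metrics = NULL, create_dirs = TRUE) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_if(!create_dirs, sprintf("output directory '%s' does not exist", dir))
    dir.create(dir, recursive = TRUE)
  }
  metrics <- metrics %||% movement_metrics(result)
  tab <- cbind(result$time, result$hand_pos, result$hand_vel,
               result$q, result$qd, result$theta, result$thetad,
               result$a, result$e, result$u, result$xhat,
               result$torques, result$interaction, result$gap, result$effort)
  colnames(tab) <- .result_columns()
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(format(as.data.frame(tab), digits = 17, trim = TRUE,
                          scientific = TRUE),
                   csv, row.names = FALSE, quote = FALSE)
  sc <- result$config
  meta <- list(
    package = "reacharm",
    version = as.character(utils::packageVersion("reacharm")),
    scenario = list(type = sc$type, robot_mode = sc$robot_mode,
                    field_b = sc$field_b, N = sc$N, D = sc$D, dt = sc$dt,
                    noise = sc$noise, seed = sc$seed),
    target = result$target, start = result$start,
    metrics = unclass(metrics))
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = json))
}

#' Read a simulation result written by [write_result()]
#'
#' @param path the path prefix used when writing
#' @return a `simulation_result`
#' @export
read_result <- function(path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  stop_if(!file.exists(csv) || !file.exists(json),
          sprintf("result files '%s.{csv,json}' not found", path))
  tab <- utils::read.csv(csv)
  stop_if(!identical(names(tab), .result_columns()), "unexpected result CSV layout")
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  m <- function(cols) unname(as.matrix(tab[, cols, drop = FALSE]))
  res <- list(
    time = tab$time,
    hand_pos = m(c("hand_x", "hand_y")), hand_vel = m(c("handv_x", "handv_y")),
    q = m(c("q1", "q2")), qd = m(c("qd1", "qd2")),
    theta = m(c("theta1", "theta2")), thetad = m(c("thetad1", "thetad2")),
    a = m(paste0("a", 1:6)), e = m(paste0("e", 1:6)),
    u = m(c("u1", "u2")), xhat = m(paste0("xhat", 1:6)),
    torques = m(c("T1", "T2")), interaction = m(c("Fint_x", "Fint_y")),
    gap = tab$gap, effort = tab$effort,
    config = utils::modifyList(scenario_config(), meta$scenario),
    target = meta$target, start = meta$start)
  class(res$config) <- "scenario_config"
  structure(res, class = "simulation_result")
}
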