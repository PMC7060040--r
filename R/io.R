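#' Read a localization table from CSV
#'
#' Expects a header with columns `frame`, `x_um`, `y_um` and optionally
#' `sigma_um` and `source_id`. Rows with non-finite coordinates are
#' rejected with a message. Unknown columns are an error so schema drift is
#' caught early.
#'
#' @param path CSV file path.
#' @param field_size field size, um (scalar or `c(w, h)`).
#' @param frame_interval frame interval, s.
#' @return A `localization_table`.
#' @export
read_localizations <- function(path, field_size = NA_real_,
                               frame_interval = NA_real_) {
  df <- fread(path)
  known <- c("frame", "x_um", "y_um", "sigma_um", "source_id")
  unknown <- setdiff(names(df), known)
  missing <- setdiff(c("frame", "x_um", "y_um"), names(df))
  if (length(missing) || length(unknown))
    stop_invariant("localization schema mismatch: missing [%s], unknown [%s]",
                   paste(missing, collapse = ", "),
                   paste(unknown, collapse = ", "))
  bad <- !is.finite(df$x_um) | !is.finite(df$y_um)
  if (any(bad)) {
    message(sprintf("rejected %d rows with non-finite coordinates", sum(bad)))
    df <- df[!bad]
  }
  setnames(df, c("x_um", "y_um"), c("x", "y"))
  if ("sigma_um" %in% names(df)) setnames(df, "sigma_um", "precision")
  localization_table(df, field_size = field_size,
                     frame_interval = frame_interval)
}

#' Write a localization table to CSV
#' @param locs a `localization_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_localizations <- function(locs, path) {
  out <- as.data.table(locs)[, .(frame, x_um = x, y_um = y)]
  if ("precision" %in% names(locs)) out[, sigma_um := locs$precision]
  if ("source_id" %in% names(locs)) out[, source_id := locs$source_id]
  fwrite(out, path)
  invisible(path)
}

#' Write trajectories to CSV
#'
#' Columns: `traj_id`, `frame`, `x_um`, `y_um` and `true_state` when
#' present. The frame interval and field size are not part of the table;
#' supply them again when reading.
#'
#' @param trajs a `trajectory_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  tk <- trajs$tracks
  out <- data.table(traj_id = tk$traj_id, frame = tk$frame,
                    x_um = tk$x, y_um = tk$y)
  if ("true_state" %in% names(tk)) out[, true_state := tk$true_state]
  fwrite(out, path)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Inverse of [write_trajectories()]. Frames must be consecutive within
#' every trajectory (no gaps); violations are a schema error.
#'
#' @param path CSV path with header `traj_id, frame, x_um, y_um[, true_state]`.
#' @param frame_interval frame interval, s.
#' @param field_size field size, um.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(path, frame_interval, field_size = NA_real_) {
  df <- fread(path)
  missing <- setdiff(c("traj_id", "frame", "x_um", "y_um"), names(df))
  if (length(missing))
    stop_invariant("trajectory schema mismatch: missing [%s]",
                   paste(missing, collapse = ", "))
  setnames(df, c("x_um", "y_um"), c("x", "y"))
  trajectory_set(df, frame_interval = frame_interval,
                 field_size = field_size)
}

#' Write a diffusion model as canonical JSON
#'
#' Canonical serialization: fixed field order, full double precision, no
#' length-1 arrays for scalars. Writing, reading and re-writing a model
#' yields byte-identical files.
#'
#' @param model a `diffusion_model` (or `hmm_fit`, whose model and score
#'   are stored).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_model_json <- function(model, path) {
  score <- NULL; n_traj <- NULL; n_steps <- NULL
  if (inherits(model, "hmm_fit")) {
    score <- model$score; n_traj <- model$n_traj; n_steps <- model$n_steps
    model <- model$model
  }
  validate_diffusion_model(model)
  obj <- list(
    K = model$n_states,
    D = model$diff_coeffs,
    occupancies = model$occupancies,
    transition_matrix = model$transition_matrix,
    dt_s = model$frame_interval,
    sigma_um = model$loc_sigma)
  if (!is.null(score))
    obj <- c(obj, list(score = score, n_traj = n_traj, n_steps = n_steps))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Read a diffusion model from JSON
#' @param path JSON path written by [write_model_json()].
#' @return A `diffusion_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  diffusion_model(diff_coeffs = obj$D, occupancies = obj$occupancies,
                  transition_matrix = obj$transition_matrix,
                  frame_interval = obj$dt_s, loc_sigma = obj$sigma_um)
}

#' Write a flux report as JSON
#' @param report a `flux_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_flux_report <- function(report, path) {
  obj <- list(
    source = report$source,
    occupancies = report$occupancies,
    transition_matrix = report$transition_matrix,
    net_flow_per_state = report$net_flow_per_state,
    net_flow_per_state_per_s = report$net_flow_per_state_per_s,
    flux_ratio = report$flux_ratio,
    net_flow_per_arm = as.list(report$net_flow_per_arm),
    stationary_distribution = report$stationary_distribution,
    detailed_balance_max_abs_residual =
      report$detailed_balance$max_abs_residual,
    detailed_balance_holds = report$detailed_balance$balanced,
    frame_interval = report$frame_interval)
  if (!is.null(report$bootstrap_ci))
    obj$bootstrap_ci <- as.data.frame(report$bootstrap_ci)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects all stage parameters with the defaults appropriate for membrane
#' GTPase spt-PALM at a 12 ms frame interval: linking threshold 0.5 um
#' (0.8 um at 35 ms), per-frame density cap 0.03 um^-2, g(r) bin width
#' 10 nm, analysis intervals 1/5/10/20 min, localization error 0.04 um
#' (0.02 um at 35 ms). Every numeric parameter is validated before any
#' stage runs. Configs round-trip losslessly through YAML.
#'
#' @param ... overrides of the default parameters (see defaults in the
#'   function definition).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    frame_interval = 0.012,
    loc_sigma = 0.04,
    max_step = 0.5,
    density_cap = 0.03,
    dr = 0.01,
    r_max = 1.0,
    intervals_min = c(1, 5, 10, 20),
    K_max = 5,
    n_traj = 5000,
    mean_track_len = 5,
    density = 0.02,
    n_boot = 200)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_invariant("unknown config parameter(s): %s",
                   paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop_invariant("invalid config: %s", what)
  chk(cfg$frame_interval > 0, "frame_interval must be > 0")
  chk(cfg$loc_sigma >= 0, "loc_sigma must be >= 0")
  chk(cfg$max_step > 0, "max_step must be > 0")
  chk(cfg$density_cap > 0, "density_cap must be > 0")
  chk(cfg$dr > 0 && cfg$r_max > cfg$dr, "dr/r_max inconsistent")
  chk(all(cfg$intervals_min > 0), "intervals must be > 0")
  chk(cfg$K_max >= 1, "K_max must be >= 1")
  chk(cfg$n_traj >= 1, "n_traj must be >= 1")
  chk(cfg$mean_track_len >= 2, "mean_track_len must be >= 2")
  chk(cfg$density > 0, "density must be > 0")
  chk(cfg$n_boot >= 0, "n_boot must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Read/write pipeline configuration as YAML
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @return the path, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Simulate -> (render + link) -> infer (HMM model-size selection) ->
#' assign -> flux, writing every artifact and a provenance manifest to
#' `out_dir`. Identical config and seed yield identical outputs. If the
#' linked data violate the density gate the run halts with a per-frame
#' report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param model generating `diffusion_model` for the simulation stage;
#'   default [demo_three_state_model()] at the configured frame interval.
#' @param link if `TRUE` (default) exercise the render + link stages and
#'   analyze re-linked trajectories; otherwise analyze the simulated
#'   trajectories directly.
#' @return list with the fitted selection report, assignment, flux report
#'   and artifact paths.
#' @export
run_pipeline <- function(config, out_dir, model = NULL, link = TRUE) {
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- model %||% demo_three_state_model(
    frame_interval = cfg$frame_interval, loc_sigma = cfg$loc_sigma)

  trajs <- simulate_markov_trajectories(
    model, n_traj = cfg$n_traj, mean_track_len = cfg$mean_track_len,
    density = cfg$density, seed = derive_seed(cfg$seed, 1))
  trajs <- add_localization_noise(trajs, cfg$loc_sigma,
                                  seed = derive_seed(cfg$seed, 2))
  write_trajectories(trajs, file.path(out_dir, "simulated_trajectories.csv"))

  if (link) {
    locs <- render_localization_table(trajs)
    gate <- frame_density(locs, cap = cfg$density_cap)
    if (!gate$pass) {
      fwrite(gate$density[above_cap == TRUE],
             file.path(out_dir, "density_violations.csv"))
      stop_invariant("density gate failed: %d frame(s) at/above %g um^-2 (see density_violations.csv)",
                     sum(gate$density$above_cap), cfg$density_cap)
    }
    write_localizations(locs, file.path(out_dir, "localizations.csv"))
    trajs <- link_trajectories(locs, max_step = cfg$max_step)
    write_trajectories(trajs, file.path(out_dir, "linked_trajectories.csv"))
  }

  sel <- select_hmm_K(trajs, K_max = cfg$K_max, loc_sigma = cfg$loc_sigma,
                      seed = derive_seed(cfg$seed, 3))
  fit <- sel$fits[[sel$selected_K]]
  write_model_json(fit, file.path(out_dir, "model.json"))

  assignment <- assign_states(trajs, fit)
  fwrite(assignment, file.path(out_dir, "state_assignment.csv"))

  flux <- flux_report(assignment = assignment, n_boot = cfg$n_boot,
                      frame_interval = cfg$frame_interval,
                      seed = derive_seed(cfg$seed, 4))
  write_flux_report(flux, file.path(out_dir, "flux_report.json"))

  manifest <- list(
    package = "sptdomains",
    version = as.character(packageVersion("sptdomains")),
    seed = cfg$seed,
    config = unclass(cfg),
    stages = c("simulate", if (link) c("render", "link"),
               "infer", "assign", "flux"),
    selected_K = sel$selected_K)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))

  list(selection = sel, fit = fit, assignment = assignment, flux = flux,
       out_dir = out_dir)
}
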