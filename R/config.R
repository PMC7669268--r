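config_keys <- c(
  "well_diameter", "tumouroid_diameter", "height",
  "n_agents", "agent_diameter", "dt", "record_interval",
  "record_plane_z", "duration", "scenario", "seed",
  "intratumoural_speed", "secretion_rate", "diffusion_coefficient",
  "actuation_median", "desensitisation_median", "sigma_log",
  "event_coalescing_window",
  "undirected_n_tracks", "undirected_duration", "undirected_speed_mean",
  "undirected_speed_sd", "undirected_persistence",
  "chemotactic_n_tracks", "chemotactic_duration",
  "chemotactic_speed_mean", "chemotactic_speed_sd",
  "chemotactic_persistence", "chemotactic_drift_weight")

default_walk_settings <- function() {
  list(undirected_n_tracks = 100L, undirected_duration = 30,
       undirected_speed_mean = 8, undirected_speed_sd = 2,
       undirected_persistence = 0.5,
       chemotactic_n_tracks = 100L, chemotactic_duration = 30,
       chemotactic_speed_mean = 8, chemotactic_speed_sd = 2,
       chemotactic_persistence = 0.5, chemotactic_drift_weight = 0.5)
}

#' Derive a module sub-seed from a global seed
#'
#' One global seed fans out to per-module substreams (synthetic pools,
#' simulation, analyses) through this fixed affine map modulo a Mersenne
#' prime, so each module is independently reproducible from the run seed.
#'
#' @param seed Global integer seed.
#' @param stream Small non-negative integer naming the substream.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 44488 * 48271 + stream) %% 2147483647)
}

#' Parse a flat YAML run configuration
#'
#' Reads a flat key-value YAML document; every key is optional and missing
#' keys take the full-scale study defaults (see [simulation_config()]).
#' Walk-generator keys prefixed `undirected_` / `chemotactic_` configure
#' the two synthetic motility pools. Unknown keys are rejected by name, as
#' are constraint violations.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return List with `sim` (a [simulation_config()]), `undirected_walk`
#'   and `chemotactic_walk` ([walk_params()]) and `raw` (the merged
#'   key-value list).
#' @export
parse_config <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    unknown <- setdiff(names(vals), config_keys)
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste(unknown, collapse = ", "))
  }
  get <- function(key, default) if (!is.null(vals[[key]])) vals[[key]]
    else default
  arena <- arena_config(
    well_diameter = get("well_diameter", 6800),
    tumouroid_diameter = get("tumouroid_diameter", 2400),
    height = get("height", 60))
  tp <- threshold_params(
    actuation_median = get("actuation_median", 1e-7),
    desensitisation_median = get("desensitisation_median", 1e-2),
    sigma_log = get("sigma_log", 0.5))
  seed <- as.integer(get("seed", 1L))
  sim <- simulation_config(
    arena = arena,
    n_agents = get("n_agents", 35000),
    agent_diameter = get("agent_diameter", 12),
    dt = get("dt", 20),
    record_interval = get("record_interval", 5),
    record_plane_z = get("record_plane_z", 30),
    duration = get("duration", 480),
    scenario = get("scenario", "no_attraction"),
    seed = seed,
    intratumoural_speed = get("intratumoural_speed", 0.15),
    secretion_rate = get("secretion_rate", 1000),
    diffusion_coefficient = get("diffusion_coefficient", 250),
    threshold_params = tp,
    event_coalescing_window = get("event_coalescing_window", 5))
  wd <- default_walk_settings()
  for (key in names(wd)) wd[[key]] <- get(key, wd[[key]])
  und <- walk_params(
    n_tracks = wd$undirected_n_tracks,
    duration = wd$undirected_duration,
    dt = sim$dt / 60,
    speed_mean = wd$undirected_speed_mean,
    speed_sd = wd$undirected_speed_sd,
    persistence = wd$undirected_persistence,
    drift_weight = 0,
    seed = derive_seed(seed, 1L))
  che <- walk_params(
    n_tracks = wd$chemotactic_n_tracks,
    duration = wd$chemotactic_duration,
    dt = sim$dt / 60,
    speed_mean = wd$chemotactic_speed_mean,
    speed_sd = wd$chemotactic_speed_sd,
    persistence = wd$chemotactic_persistence,
    drift_direction = c(-1, 0, 0),
    drift_weight = wd$chemotactic_drift_weight,
    seed = derive_seed(seed, 2L))
  merged <- vals
  for (key in setdiff(config_keys, names(vals)))
    merged[[key]] <- switch(key,
      well_diameter = arena$well_diameter,
      tumouroid_diameter = arena$tumouroid_diameter,
      height = arena$height,
      n_agents = sim$n_agents,
      agent_diameter = sim$agent_diameter,
      dt = sim$dt,
      record_interval = sim$record_interval,
      record_plane_z = sim$record_plane_z,
      duration = sim$duration,
      scenario = sim$scenario,
      seed = sim$seed,
      intratumoural_speed = sim$intratumoural_speed,
      secretion_rate = sim$secretion_rate,
      diffusion_coefficient = sim$diffusion_coefficient,
      actuation_median = tp$actuation_median,
      desensitisation_median = tp$desensitisation_median,
      sigma_log = tp$sigma_log,
      event_coalescing_window = sim$event_coalescing_window,
      wd[[key]])
  list(sim = sim, undirected_walk = und, chemotactic_walk = che,
       raw = merged[config_keys])
}

#' Serialise a parsed configuration back to YAML
#'
#' `parse_config(serialise_config(cfg, path))` reproduces `cfg`.
#'
#' @param cfg A [parse_config()] result.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
serialise_config <- function(cfg, path) {
  stopifnot(is.list(cfg), !is.null(cfg$raw))
  yaml::write_yaml(cfg$raw, path)
  invisible(path)
}
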