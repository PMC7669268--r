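#' Arena geometry: a cylindrical well with a concentric tumouroid
#'
#' The whole-well assay geometry: a cylindrical well of 6.8 mm diameter
#' containing a concentric tumouroid region of 2.4 mm diameter, both 60 um
#' high. All lengths are in micrometres.
#'
#' @param well_diameter Well diameter (um).
#' @param tumouroid_diameter Tumouroid diameter (um); must be smaller than
#'   the well diameter.
#' @param height Height of the well (um).
#' @param centre Numeric length-2 xy coordinate of the common centre (um).
#' @return An object of class `arena_config`.
#' @examples
#' arena <- arena_config()
#' radial_distance(c(0, 0), arena)
#' @export
arena_config <- function(well_diameter = 6800, tumouroid_diameter = 2400,
                         height = 60, centre = c(0, 0)) {
  stopifnot(is.numeric(well_diameter), length(well_diameter) == 1L,
            is.numeric(tumouroid_diameter), length(tumouroid_diameter) == 1L,
            is.numeric(height), length(height) == 1L,
            is.numeric(centre), length(centre) == 2L, all(is.finite(centre)))
  if (!is.finite(well_diameter) || well_diameter <= 0)
    stop("`well_diameter` must be a positive finite length (um)")
  if (!is.finite(tumouroid_diameter) || tumouroid_diameter <= 0)
    stop("`tumouroid_diameter` must be a positive finite length (um)")
  if (!is.finite(height) || height <= 0)
    stop("`height` must be a positive finite length (um)")
  if (tumouroid_diameter >= well_diameter)
    stop("`tumouroid_diameter` (", tumouroid_diameter,
         ") must be smaller than `well_diameter` (", well_diameter, ")")
  structure(list(well_diameter = well_diameter,
                 tumouroid_diameter = tumouroid_diameter,
                 height = height,
                 centre = as.numeric(centre)),
            class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat("<arena_config> well", x$well_diameter, "um, tumouroid",
      x$tumouroid_diameter, "um, height", x$height, "um, centre (",
      x$centre[1], ",", x$centre[2], ")\n")
  invisible(x)
}

well_radius <- function(arena) arena$well_diameter / 2
tumouroid_radius <- function(arena) arena$tumouroid_diameter / 2

as_xy_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  if (!is.matrix(p)) p <- matrix(as.numeric(p), ncol = 2L)
  if (ncol(p) < 2L) stop("points must have x and y columns")
  storage.mode(p) <- "double"
  p[, 1:2, drop = FALSE]
}

#' Signed radial distance from the tumouroid interface
#'
#' Distance of an xy point from the tumouroid interface circle, negative
#' strictly inside the tumouroid, zero on the interface, positive outside.
#' This is the radial coordinate used by the swarming index, infiltration
#' statistics and density kymographs.
#'
#' @param p A length-2 xy point, an n x 2 matrix, or a data frame with
#'   columns `x`, `y` (um).
#' @param arena An [arena_config()].
#' @return Numeric vector of signed distances (um).
#' @export
radial_distance <- function(p, arena) {
  stopifnot(inherits(arena, "arena_config"))
  p <- as_xy_matrix(p)
  if (!all(is.finite(p))) stop("non-finite coordinates")
  rho <- sqrt((p[, 1] - arena$centre[1])^2 + (p[, 2] - arena$centre[2])^2)
  rho - tumouroid_radius(arena)
}

#' Is a point strictly inside the tumouroid?
#'
#' Points exactly on the interface count as outside (strict inequality), so
#' "infiltrated" always means strictly interior.
#'
#' @inheritParams radial_distance
#' @return Logical vector.
#' @export
inside_tumouroid <- function(p, arena) {
  radial_distance(p, arena) < 0
}

#' Per-agent chemokine sensing thresholds
#'
#' Agents sample an actuation and a desensitisation concentration threshold
#' from log-normal distributions sharing a log-space standard deviation.
#' An agent behaves chemotactically only while the maximum concentration it
#' perceives lies strictly between its two thresholds. The medians here are
#' calibration defaults (molecules/um^3): the actuation median sits well
#' below the signal a single secreting cell projects across the arena
#' within minutes, and the desensitisation median above the near-interface
#' concentration scale reached late in a run, so that attraction is both
#' engaged early and sustained; the heterogeneity model is log-normal so
#' sensitivities vary over orders of magnitude across the population. See
#' the methods vignette for the calibration reasoning.
#'
#' @param actuation_median Median of the actuation threshold
#'   (molecules/um^3).
#' @param desensitisation_median Median of the desensitisation threshold
#'   (molecules/um^3); must exceed the actuation median.
#' @param sigma_log Shared log-space standard deviation (dimensionless).
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(actuation_median = 1e-7,
                             desensitisation_median = 1e-2,
                             sigma_log = 0.5) {
  stopifnot(is.numeric(actuation_median), is.numeric(desensitisation_median),
            is.numeric(sigma_log))
  if (!(actuation_median > 0 && actuation_median < desensitisation_median))
    stop("need 0 < `actuation_median` < `desensitisation_median`")
  if (sigma_log < 0) stop("`sigma_log` must be >= 0")
  structure(list(actuation_median = actuation_median,
                 desensitisation_median = desensitisation_median,
                 sigma_log = sigma_log),
            class = "threshold_params")
}

#' Simulation configuration
#'
#' Bundles arena geometry, agent parameters, chemokine parameters and run
#' control. Defaults are the full-scale study conditions: 35,000 agents of
#' 12 um diameter in the 6.8 mm well, 20 s dynamics steps, recording every
#' 5 min of the xy plane at depth 30 um, chemokine secretion at 1000
#' molecules/min with diffusion coefficient 250 um^2/s, and intratumoural
#' drift toward the centre at 0.15 um/min. See [desk_simulation_config()]
#' for a reduced configuration suitable for interactive use.
#'
#' @param arena An [arena_config()].
#' @param n_agents Number of simulated agents.
#' @param agent_diameter Agent diameter (um); agents are non-overlapping
#'   spheres.
#' @param dt Dynamics time step (seconds).
#' @param record_interval Frame recording interval (minutes); must be a
#'   multiple of `dt`.
#' @param record_plane_z Depth of the recording plane (um); agents whose
#'   sphere intersects this plane are recorded.
#' @param duration Simulated duration (minutes).
#' @param scenario `"no_attraction"` (no secretion) or
#'   `"positive_attraction"` (intratumoural agents secrete chemokine).
#' @param seed Integer seed controlling every stochastic element of the run.
#' @param intratumoural_speed Speed of drift toward the tumouroid centre for
#'   agents inside the tumouroid (um/min).
#' @param secretion_rate Chemokine secretion rate of intratumoural agents
#'   (molecules/min).
#' @param diffusion_coefficient Chemokine diffusion coefficient (um^2/s).
#' @param threshold_params A [threshold_params()] object.
#' @param event_coalescing_window Window (minutes) within which successive
#'   secretion events from one agent are merged; set 0 to disable.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(arena = arena_config(),
                              n_agents = 35000,
                              agent_diameter = 12,
                              dt = 20,
                              record_interval = 5,
                              record_plane_z = 30,
                              duration = 480,
                              scenario = c("no_attraction",
                                           "positive_attraction"),
                              seed = 1L,
                              intratumoural_speed = 0.15,
                              secretion_rate = 1000,
                              diffusion_coefficient = 250,
                              threshold_params = ctlswarm::threshold_params(),
                              event_coalescing_window = 5) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(arena, "arena_config"),
            inherits(threshold_params, "threshold_params"))
  if (!is.numeric(n_agents) || n_agents < 1)
    stop("`n_agents` must be >= 1")
  if (agent_diameter <= 0) stop("`agent_diameter` must be positive")
  if (dt <= 0) stop("`dt` must be positive (seconds)")
  if (record_interval <= 0) stop("`record_interval` must be positive (min)")
  if (abs((record_interval * 60) %% dt) > 1e-9)
    stop("`dt` (", dt, " s) must divide `record_interval` (",
         record_interval, " min)")
  if (!(record_plane_z > 0 && record_plane_z < arena$height))
    stop("`record_plane_z` must lie strictly between 0 and the arena height")
  if (duration <= 0) stop("`duration` must be positive (min)")
  if (duration * 60 %% dt > 1e-9)
    stop("`dt` must divide `duration`")
  if (intratumoural_speed < 0) stop("`intratumoural_speed` must be >= 0")
  if (secretion_rate < 0) stop("`secretion_rate` must be >= 0")
  if (diffusion_coefficient <= 0)
    stop("`diffusion_coefficient` must be positive")
  if (event_coalescing_window < 0)
    stop("`event_coalescing_window` must be >= 0")
  structure(list(arena = arena,
                 n_agents = as.integer(n_agents),
                 agent_diameter = agent_diameter,
                 dt = dt,
                 record_interval = record_interval,
                 record_plane_z = record_plane_z,
                 duration = duration,
                 scenario = scenario,
                 seed = as.integer(seed),
                 intratumoural_speed = intratumoural_speed,
                 secretion_rate = secretion_rate,
                 diffusion_coefficient = diffusion_coefficient,
                 threshold_params = threshold_params,
                 event_coalescing_window = event_coalescing_window),
            class = "simulation_config")
}

#' Desk-scale simulation configuration
#'
#' The full study conditions (35,000 agents, 6.8 mm well) are sized for a
#' cluster run. This reduced configuration keeps every rate, threshold and
#' density-relevant ratio but scales the well to one quarter of the area
#' (3.4 mm well, 1.2 mm tumouroid) with 2,000 agents, which runs on a
#' single core in minutes.
#'
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
desk_simulation_config <- function(...) {
  args <- list(...)
  defaults <- list(arena = arena_config(well_diameter = 3400,
                                        tumouroid_diameter = 1200),
                   n_agents = 2000)
  args <- utils::modifyList(defaults, args)
  do.call(simulation_config, args)
}

#' Convert a diffusion coefficient from um^2/s to cm^2/s
#'
#' @param x Diffusion coefficient in um^2/s.
#' @return The same coefficient in cm^2/s (1 um = 1e-4 cm).
#' @examples
#' um2s_to_cm2s(250) # 2.5e-6
#' @export
um2s_to_cm2s <- function(x) x * 1e-8
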