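engine_config_list <- function(config) {
  arena <- config$arena
  list(seed = config$seed,
       well_radius = arena$well_diameter / 2,
       tumouroid_radius = arena$tumouroid_diameter / 2,
       height = arena$height,
       cx = arena$centre[1], cy = arena$centre[2],
       agent_diameter = config$agent_diameter,
       dt = config$dt,
       scenario = if (config$scenario == "positive_attraction") 1L else 0L,
       intratumoural_speed = config$intratumoural_speed,
       secretion_rate = config$secretion_rate,
       diffusion_coefficient = config$diffusion_coefficient,
       coalescing_window_s = config$event_coalescing_window * 60,
       actuation_median = config$threshold_params$actuation_median,
       desensitisation_median =
         config$threshold_params$desensitisation_median,
       sigma_log = config$threshold_params$sigma_log,
       n_agents = config$n_agents)
}

check_pool <- function(pool, kind, config) {
  stopifnot(inherits(pool, "block_pool"))
  if (pool$kind != kind)
    stop("expected a ", kind, " pool, got ", pool$kind)
  if (abs(pool$dt * 60 - config$dt) > 0.01 * config$dt)
    stop("pool sampling interval (", signif(pool$dt * 60, 4),
         " s) does not match the simulation `dt` (", config$dt, " s)")
  pool
}

#' Initialise a swarming simulation
#'
#' Places agents uniformly at random in the annular region between
#' tumouroid and well wall (rejecting overlapping placements), samples
#' per-agent sensing thresholds, and returns a stateful simulation object
#' ready for stepping. The whole run is determined by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param undirected_pool A [build_block_pool()] result of kind
#'   `"undirected"`.
#' @param chemotactic_pool A pool of kind `"chemotactic"`; its blocks are
#'   reoriented toward the sensed gradient at replay time.
#' @return An object of class `swarm_sim`.
#' @export
initialise_simulation <- function(config, undirected_pool,
                                  chemotactic_pool) {
  stopifnot(inherits(config, "simulation_config"))
  check_pool(undirected_pool, "undirected", config)
  check_pool(chemotactic_pool, "chemotactic", config)
  if (ncol(undirected_pool$steps) != ncol(chemotactic_pool$steps))
    stop("pools must have the same block duration")
  ptr <- engine_create(engine_config_list(config),
                       undirected_pool$steps, chemotactic_pool$steps,
                       undirected_pool$reference_direction,
                       chemotactic_pool$reference_direction)
  structure(list(ptr = ptr, config = config,
                 undirected_pool = undirected_pool,
                 chemotactic_pool = chemotactic_pool),
            class = "swarm_sim")
}

#' @export
print.swarm_sim <- function(x, ...) {
  st <- engine_state(x$ptr)
  cat("<swarm_sim>", x$config$n_agents, "agents,", x$config$scenario,
      "scenario, t =", st$t / 60, "min,", nrow(st$events),
      "field event(s)\n")
  invisible(x)
}

#' Advance a simulation by whole dynamics steps
#'
#' Each step advances simulated time by `config$dt` seconds: agents are
#' visited in a fresh seeded random order; intratumoural agents drift
#' toward the centre (secreting in the positive-attraction scenario),
#' extratumoural agents re-enact their current motility block, re-probing
#' the chemokine field and resampling a block whenever the current one is
#' exhausted.
#'
#' @param sim A `swarm_sim`.
#' @param n Number of steps to take.
#' @return The simulation object, invisibly (state advances in place).
#' @export
step_simulation <- function(sim, n = 1L) {
  stopifnot(inherits(sim, "swarm_sim"), n >= 1)
  engine_steps(sim$ptr, as.integer(n))
  invisible(sim)
}

#' Inspect simulation state
#'
#' @param sim A `swarm_sim`.
#' @return List with `t` (minutes), `agents` (data frame of positions,
#'   behavioural mode, thresholds, block cursor), `events` (the chemokine
#'   secretion log; times in seconds), `total_secreted` (molecules),
#'   `chemotactic_steps` (cumulative agent-steps taken in chemotactic
#'   mode) and `blocked_moves` (moves rejected by collisions).
#' @export
sim_state <- function(sim) {
  stopifnot(inherits(sim, "swarm_sim"))
  st <- engine_state(sim$ptr)
  agents <- data.frame(
    x = st$positions[, 1], y = st$positions[, 2], z = st$positions[, 3],
    mode = c("undirected", "chemotactic", "intratumoural")[st$mode + 1L],
    actuation = st$actuation, desensitisation = st$desensitisation,
    block_cursor = st$cursor, stringsAsFactors = FALSE)
  list(t = st$t / 60, agents = agents,
       events = as.data.frame(st$events),
       total_secreted = st$total_secreted,
       chemotactic_steps = st$chemotactic_steps,
       blocked_moves = st$blocked_moves)
}

#' Overwrite agent positions
#'
#' Low-level hook used for checkpoint restore and for constructing specific
#' spatial configurations (e.g. agents already inside the tumouroid).
#' Behavioural modes are re-evaluated from the new positions at the next
#' step.
#'
#' @param sim A `swarm_sim`.
#' @param positions An `n_agents x 3` matrix of centres (um).
#' @return The simulation object, invisibly.
#' @export
set_agent_positions <- function(sim, positions) {
  stopifnot(inherits(sim, "swarm_sim"))
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  engine_set_positions(sim$ptr, positions)
  invisible(sim)
}

record_frame <- function(sim) {
  m <- engine_frame(sim$ptr, sim$config$record_plane_z,
                    sim$config$agent_diameter / 2)
  st_t <- engine_state(sim$ptr)$t / 60
  if (nrow(m) == 0L)
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0)))
  data.frame(t = st_t, x = m[, 1], y = m[, 2])
}

#' Run a simulation and record frames
#'
#' Executes `duration/dt` dynamics steps, recording a frame at t = 0 and
#' after every `record_interval` minutes. A frame holds the xy positions of
#' agents whose sphere intersects the recording plane
#' (|z - record_plane_z| <= agent radius), mirroring the restricted imaging
#' depth of whole-well microscopy. Identical `(config, pools, seed)` give a
#' bit-identical frame sequence.
#'
#' @inheritParams initialise_simulation
#' @param sim Optionally, an already-initialised `swarm_sim` (then `config`
#'   and pools are taken from it).
#' @return A `frame_table`: data frame with columns `t` (min), `x`, `y`
#'   (um), with the per-frame agent counts as attribute `"frame_counts"`
#'   and the finished `swarm_sim` as attribute `"sim"`.
#' @export
run_simulation <- function(config, undirected_pool, chemotactic_pool,
                           sim = NULL) {
  if (is.null(sim))
    sim <- initialise_simulation(config, undirected_pool, chemotactic_pool)
  config <- sim$config
  steps_per_rec <- round(config$record_interval * 60 / config$dt)
  n_rec <- round(config$duration / config$record_interval)
  frames <- vector("list", n_rec + 1L)
  frames[[1L]] <- record_frame(sim)
  for (r in seq_len(n_rec)) {
    step_simulation(sim, steps_per_rec)
    frames[[r + 1L]] <- record_frame(sim)
  }
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  class(out) <- c("frame_table", "data.frame")
  counts <- vapply(frames, nrow, integer(1))
  attr(out, "frame_counts") <- data.frame(
    t = seq(0, by = config$record_interval, length.out = n_rec + 1L),
    n = counts)
  attr(out, "sim") <- sim
  out
}

#' Resolve a proposed agent move against walls and neighbours
#'
#' Applies the simulator's movement rules to a single proposed
#' displacement: the proposed position is first projected to the nearest
#' point of the well cylinder (sliding along walls, floor and ceiling);
#' if the projected position would put the agent centre within one agent
#' diameter of any other agent's centre, the move is rejected and the
#' original position returned.
#'
#' @param position Current centre, numeric 3-vector (um).
#' @param displacement Proposed displacement, numeric 3-vector (um).
#' @param others Matrix (m x 3) of other agents' centres, or `NULL`.
#' @param arena An [arena_config()].
#' @param agent_diameter Agent diameter (um).
#' @return List with `position` (the accepted centre) and `accepted`
#'   (logical; `FALSE` when the move was rejected by a collision).
#' @export
resolve_move <- function(position, displacement, others = NULL,
                         arena = arena_config(), agent_diameter = 12) {
  position <- as.numeric(position)
  displacement <- as.numeric(displacement)
  stopifnot(length(position) == 3L, length(displacement) == 3L,
            all(is.finite(position)), all(is.finite(displacement)),
            inherits(arena, "arena_config"))
  p <- position + displacement
  p[3] <- min(max(p[3], 0), arena$height)
  dxy <- p[1:2] - arena$centre
  r <- sqrt(sum(dxy^2))
  if (r > well_radius(arena))
    p[1:2] <- arena$centre + dxy * well_radius(arena) / r
  if (!is.null(others) && length(others)) {
    others <- matrix(as.numeric(others), ncol = 3L)
    d2 <- (others[, 1] - p[1])^2 + (others[, 2] - p[2])^2 +
      (others[, 3] - p[3])^2
    if (any(d2 < agent_diameter^2))
      return(list(position = position, accepted = FALSE))
  }
  list(position = p, accepted = TRUE)
}
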