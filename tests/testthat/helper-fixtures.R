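# shared fixtures, all built in code

full_arena <- function() arena_config() # 6800 / 2400 / 60 um

desk_arena <- function() arena_config(well_diameter = 3400,
                                      tumouroid_diameter = 1200)

# a deterministic straight-line track: n samples at 20 s spacing
straight_track <- function(id = "tr1", n = 31, step = c(2, 0, 0),
                           start = c(0, 0, 0), dt = 1 / 3) {
  idx <- 0:(n - 1)
  as_track_table(data.frame(
    track_id = id, t = idx * dt,
    x = start[1] + idx * step[1],
    y = start[2] + idx * step[2],
    z = start[3] + idx * step[3]))
}

small_pools <- function(seed = 101, drift_weight = 0.5) {
  und <- build_block_pool(
    generate_walks(walk_params(10, 20, seed = seed)), "undirected")
  che <- build_block_pool(
    generate_walks(walk_params(10, 20, drift_direction = c(-1, 0, 0),
                               drift_weight = drift_weight,
                               seed = seed + 1)), "chemotactic")
  list(und = und, che = che)
}

# cells evenly spaced on a circle of radius r
circle_frame <- function(n, r, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  data.frame(x = centre[1] + r * cos(th), y = centre[2] + r * sin(th))
}

# cells uniform by area between radii r0 and r1
uniform_annulus_frame <- function(n, r0, r1) {
  rho <- sqrt(stats::runif(n, r0^2, r1^2))
  th <- stats::runif(n, 0, 2 * pi)
  data.frame(x = rho * cos(th), y = rho * sin(th))
}
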