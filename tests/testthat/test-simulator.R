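test_that("initial placement is outside the tumouroid and non-overlapping", {
  pools <- small_pools()
  cfg <- desk_simulation_config(n_agents = 400, duration = 10, seed = 2)
  sim <- initialise_simulation(cfg, pools$und, pools$che)
  a <- sim_state(sim)$agents
  expect_equal(nrow(a), 400)
  rd <- radial_distance(a[, c("x", "y")], cfg$arena)
  expect_true(all(rd > 0))
  expect_true(all(rd <= 1100 + 1e-9)) # inside the well
  expect_true(all(a$z >= 0 & a$z <= 60))
  dmin <- min(stats::dist(as.matrix(a[, c("x", "y", "z")])))
  expect_gte(dmin, cfg$agent_diameter)
  expect_true(all(a$actuation < a$desensitisation))
  # same seed reproduces the initial state exactly
  sim2 <- initialise_simulation(cfg, pools$und, pools$che)
  expect_identical(sim_state(sim2)$agents, a)
  # packing an impossible number of agents fails loudly
  tiny <- simulation_config(
    arena = arena_config(well_diameter = 100, tumouroid_diameter = 50,
                         height = 20),
    n_agents = 5000, duration = 10, seed = 1, record_plane_z = 10)
  expect_error(initialise_simulation(tiny, pools$und, pools$che),
               "packing infeasible")
})

test_that("intratumoural agents drift 0.05 um per 20 s step with z held", {
  pools <- small_pools()
  cfg <- desk_simulation_config(n_agents = 1, duration = 10,
                                scenario = "positive_attraction", seed = 3)
  sim <- initialise_simulation(cfg, pools$und, pools$che)
  set_agent_positions(sim, matrix(c(100, 0, 27), 1))
  step_simulation(sim, 1)
  st <- sim_state(sim)
  expect_equal(sqrt(st$agents$x^2 + st$agents$y^2), 99.95)
  expect_equal(st$agents$z, 27)
  expect_equal(st$agents$mode, "intratumoural")
  # secretion: 1000 molecules/min -> 1000 molecules after 3 steps (1 min)
  step_simulation(sim, 2)
  st <- sim_state(sim)
  expect_equal(st$total_secreted, 1000)
  expect_equal(nrow(st$events), 1) # coalesced within the 5-min window
  expect_equal(sum(st$events$q), 1000)
})

test_that("the no-attraction scenario never secretes", {
  pools <- small_pools()
  cfg <- desk_simulation_config(n_agents = 20, duration = 30,
                                scenario = "no_attraction", seed = 4)
  sim <- initialise_simulation(cfg, pools$und, pools$che)
  set_agent_positions(sim, cbind(seq(20, 400, length.out = 20), 0, 30))
  run_simulation(sim = sim)
  st <- sim_state(sim)
  expect_equal(nrow(st$events), 0)
  expect_equal(st$total_secreted, 0)
})

test_that("resolve_move projects at walls and rejects collisions", {
  arena <- desk_arena()
  # through the well wall: projected back onto the wall radius
  res <- resolve_move(c(1690, 0, 30), c(50, 0, 0), NULL, arena)
  expect_true(res$accepted)
  expect_equal(res$position, c(1700, 0, 30))
  # ceiling/floor clamp
  expect_equal(resolve_move(c(0, 900, 58), c(0, 0, 10), NULL,
                            arena)$position[3], 60)
  # moving 1 um toward an agent exactly 12 um away is rejected
  res <- resolve_move(c(0, 800, 30), c(1, 0, 0),
                      matrix(c(12, 800, 30), 1), arena)
  expect_false(res$accepted)
  expect_equal(res$position, c(0, 800, 30))
  # unobstructed moves land exactly at position + displacement
  res <- resolve_move(c(5, 800, 30), c(-3, 2, 1),
                      matrix(c(30, 800, 30), 1), arena)
  expect_true(res$accepted)
  expect_equal(res$position, c(2, 802, 31))
})

test_that("runs record the right frames and are bit-reproducible", {
  pools <- small_pools()
  cfg <- desk_simulation_config(n_agents = 150, duration = 60,
                                scenario = "positive_attraction", seed = 6)
  fr1 <- run_simulation(cfg, pools$und, pools$che)
  counts <- attr(fr1, "frame_counts")
  expect_equal(nrow(counts), 13) # 60 / 5 + 1 including t = 0
  expect_equal(counts$t, seq(0, 60, by = 5))
  expect_true(all(sort(unique(fr1$t)) %in% counts$t))
  fr2 <- run_simulation(cfg, pools$und, pools$che)
  strip <- function(fr) data.frame(t = fr$t, x = fr$x, y = fr$y)
  expect_identical(strip(fr1), strip(fr2))
  fr3 <- run_simulation(desk_simulation_config(
    n_agents = 150, duration = 60, scenario = "positive_attraction",
    seed = 7), pools$und, pools$che)
  expect_false(identical(nrow(fr1), nrow(fr3)) &&
                 identical(fr1$x, fr3$x))
})

test_that("only agents whose sphere cuts the recording plane are recorded", {
  pools <- small_pools()
  cfg <- desk_simulation_config(n_agents = 3, duration = 10, seed = 8,
                                intratumoural_speed = 0)
  sim <- initialise_simulation(cfg, pools$und, pools$che)
  # z = 35 (|35-30| <= 6, in), z = 37 (out), z = 24 (boundary, in)
  set_agent_positions(sim, cbind(c(100, 200, 300), 0, c(35, 37, 24)))
  fr <- ctlswarm:::record_frame(sim)
  expect_setequal(fr$x, c(100, 300))
})

test_that("agents never overlap after stepping", {
  pools <- small_pools()
  cfg <- desk_simulation_config(n_agents = 300, duration = 30,
                                scenario = "positive_attraction", seed = 9)
  sim <- initialise_simulation(cfg, pools$und, pools$che)
  for (i in 1:6) {
    step_simulation(sim, 15)
    p <- as.matrix(sim_state(sim)$agents[, c("x", "y", "z")])
    expect_gte(min(stats::dist(p)), cfg$agent_diameter - 1e-9)
    rxy <- sqrt(p[, 1]^2 + p[, 2]^2)
    expect_true(all(rxy <= 1700 + 1e-9))
    expect_true(all(p[, 3] >= 0 & p[, 3] <= 60))
  }
})

test_that("raising the desensitisation threshold allows more chemotactic steps", {
  pools <- small_pools()
  chemo_steps <- function(des_median) {
    tp <- threshold_params(1e-7, des_median, 0.5)
    cfg <- desk_simulation_config(n_agents = 300, duration = 120,
                                  scenario = "positive_attraction",
                                  seed = 9, threshold_params = tp)
    sim <- initialise_simulation(cfg, pools$und, pools$che)
    run_simulation(sim = sim)
    sim_state(sim)$chemotactic_steps
  }
  counts <- vapply(c(3e-7, 1e-5, 1e-3), chemo_steps, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1]) # strictly more at the widest band
})
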