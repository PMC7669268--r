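test_that("swarming index hits its three anchors", {
  arena <- full_arena()
  expect_equal(swarming_index(circle_frame(1000, 3400), arena), -1)
  inside <- withr::with_seed(1, uniform_annulus_frame(1000, 0, 1199))
  expect_equal(swarming_index(inside, arena), 1)
  uni <- withr::with_seed(2, uniform_annulus_frame(1e5, 1200, 3400))
  expect_lt(abs(swarming_index(uni, arena)), 0.01)
  # half at perimeter, half inside -> exactly 0
  half <- rbind(circle_frame(100, 3400), circle_frame(100, 100))
  expect_equal(swarming_index(half, arena), 0)
  expect_error(swarming_index(circle_frame(0, 1), arena), "empty")
  expect_error(swarming_index(data.frame(x = 5000, y = 0), arena),
               "within the well")
})

test_that("swarming index is rotation-invariant and monotone under inward moves", {
  arena <- full_arena()
  fr <- withr::with_seed(3, uniform_annulus_frame(500, 800, 3400))
  m0 <- swarming_index(fr, arena)
  th <- 1.234
  rot <- data.frame(x = fr$x * cos(th) - fr$y * sin(th),
                    y = fr$x * sin(th) + fr$y * cos(th))
  expect_equal(swarming_index(rot, arena), m0, tolerance = 1e-12)
  withr::with_seed(4, for (i in 1:25) {
    j <- sample(nrow(fr), 1)
    shrink <- runif(1, 0.2, 0.95)
    fr2 <- fr
    fr2[j, ] <- fr[j, ] * shrink # strictly smaller radius
    expect_gte(swarming_index(fr2, arena), m0)
  })
})

test_that("FMI is the cosine with the target direction", {
  u <- c(-1, 0, 0)
  straight <- cbind(x = seq(0, -60, length.out = 7), y = 0, z = 0)
  expect_equal(fmi(straight, u), 1)
  expect_equal(fmi(straight[, c(1, 2, 3)] * c(-1, 1, 1), u), -1)
  # net displacement (-3, 4, 0) against -x: 3/5
  track <- rbind(c(0, 0, 0), c(5, 5, 2), c(-3, 4, 0))
  expect_equal(fmi(track, u), 0.6)
  expect_error(fmi(rbind(c(1, 1, 1), c(1, 1, 1)), u), "zero net")
  # property: |FMI| <= 1 and reversal flips the sign
  withr::with_seed(5, for (i in 1:200) {
    m <- matrix(rnorm(15), ncol = 3)
    v <- fmi(m, u)
    expect_lte(abs(v), 1 + 1e-12)
    expect_equal(fmi(m[nrow(m):1, ], u), -v, tolerance = 1e-12)
  })
})

test_that("track summaries report displacement, speed and duration", {
  # square path returning to start: D = 0, mean speed 10 um/min
  sq <- as_track_table(data.frame(
    track_id = "sq", t = 0:4,
    x = c(0, 10, 10, 0, 0), y = c(0, 0, 10, 10, 0), z = 0))
  s <- track_summary(sq, c(-1, 0, 0))
  expect_equal(s$D, 0)
  expect_equal(s$mean_speed, 10)
  expect_true(is.na(s$fmi))
  # straight 60 um in 10 min
  st <- straight_track("st", n = 31, step = c(-2, 0, 0)) # 60 um toward -x
  s2 <- track_summary(st, c(-1, 0, 0))
  expect_equal(s2$D, 60)
  expect_equal(s2$mean_speed, 6)
  expect_equal(s2$fmi, 1)
  expect_equal(track_summary(st, c(1, 0, 0))$fmi, -1)
  # mean speed >= net displacement / duration for random tracks
  tr <- generate_walks(walk_params(50, 15, seed = 12))
  stats <- track_summary(tr, c(0, 0, 1))
  expect_true(all(stats$mean_speed >= stats$D / stats$duration - 1e-9))
})

test_that("infiltration statistics measure depth from the tumouroid edge", {
  arena <- full_arena()
  out <- infiltration_stats(circle_frame(50, 2000), arena)
  expect_equal(out$fraction_infiltrated, 0)
  expect_equal(out$depths, numeric(0))
  expect_true(is.na(out$mean_depth))
  fr <- rbind(data.frame(x = 0, y = 0),          # centre: depth 1200
              data.frame(x = 1199.5, y = 0),     # just inside: ~0
              circle_frame(2, 3000))
  res <- infiltration_stats(fr, arena)
  expect_equal(res$fraction_infiltrated, 0.5)
  expect_equal(sort(res$depths), c(0.5, 1200))
  expect_equal(res$mean_depth, 600.25)
})

test_that("kymograph cumulative counts match a brute-force oracle exactly", {
  arena <- full_arena()
  fr <- withr::with_seed(6, rbind(
    cbind(t = 0, uniform_annulus_frame(400, 600, 3400)),
    cbind(t = 5, uniform_annulus_frame(300, 1200, 2000))))
  ky <- density_kymograph(fr, arena, r_grid = seq(0, 2200, by = 100))
  for (j in 1:2) {
    tt <- c(0, 5)[j]
    d <- radial_distance(fr[fr$t == tt, c("x", "y")], arena)
    brute <- vapply(ky$r, function(r) sum(d >= 0 & d <= r), numeric(1))
    expect_identical(ky$cumulative[, j], brute)
  }
  # total conservation: cells outside the tumouroid, exactly
  expect_equal(ky$cumulative[nrow(ky$cumulative), 1],
               sum(radial_distance(fr[fr$t == 0, c("x", "y")], arena) >= 0))
  expect_true(all(apply(ky$cumulative, 2, function(v) all(diff(v) >= 0))))
  expect_true(all(ky$density >= 0))
})

test_that("kymograph density peaks where the cells are", {
  arena <- full_arena()
  r0 <- 800
  fr <- withr::with_seed(7, {
    rho <- 1200 + r0 + rnorm(4000, 0, 5)
    th <- runif(4000, 0, 2 * pi)
    data.frame(t = 0, x = rho * cos(th), y = rho * sin(th))
  })
  ky <- density_kymograph(fr, arena)
  peak_r <- ky$r[which.max(ky$density_per_r[, 1])]
  expect_lt(abs(peak_r - r0), diff(ky$r)[1] + 1e-9)
})

test_that("instantaneous FMI kymograph scores steps against the inward direction", {
  arena <- full_arena()
  # radially inward tracks: every non-empty bin scores 1
  inward <- do.call(rbind, lapply(1:12, function(i) {
    th <- i * pi / 6
    r <- seq(3000, 2000, by = -100)
    data.frame(track_id = sprintf("in%d", i), t = seq_along(r) - 1,
               x = r * cos(th), y = r * sin(th), z = 0)
  }))
  g <- instantaneous_fmi_kymograph(as_track_table(inward), arena)
  vals <- g$mean_fmi[g$n > 0]
  expect_true(length(vals) > 0)
  expect_equal(vals, rep(1, length(vals)), tolerance = 1e-9)
  expect_true(any(g$n == 0)) # empty bins are NA, not zero
  expect_true(all(is.na(g$mean_fmi[g$n == 0])))
  # isotropic tracks: grand mean near zero
  tr <- generate_walks(walk_params(200, 20, seed = 13))
  tr$x <- tr$x + 2300 # shift the bundle into the annulus
  g2 <- instantaneous_fmi_kymograph(as_track_table(tr), arena)
  grand <- sum(g2$mean_fmi * g2$n, na.rm = TRUE) / sum(g2$n)
  expect_lt(abs(grand), 0.03)
})

test_that("transmigration and cytotoxicity indices follow their formulas", {
  expect_equal(transmigration_index(500, 250), 2)
  expect_equal(transmigration_index(300, 300), 1)
  expect_equal(transmigration_index(0, 250), 0)
  expect_error(transmigration_index(10, 0), "undefined")
  expect_equal(cytotoxicity_index(100, 100, 50, 100), 50)
  expect_equal(cytotoxicity_index(80, 120, 40, 60), 0) # ratios unchanged
  expect_equal(cytotoxicity_index(100, 100, 0, 90), 100)
  expect_error(cytotoxicity_index(100, 0, 50, 100), "positive")
})
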