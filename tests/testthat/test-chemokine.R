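test_that("single-event concentration matches the closed-form heat kernel", {
  f <- chemokine_field(D = 250, coalescing_window = 0)
  expect_equal(concentration(f, c(0, 0, 0), 100), 0) # empty field
  f <- record_secretion(f, c(0, 0, 0), 0, 1000)
  # independent evaluation of q * (4 pi D tau)^{-3/2} exp(-r^2 / (4 D tau))
  oracle <- function(q, r, tau, D = 250)
    q * (4 * pi * D * tau)^(-1.5) * exp(-r^2 / (4 * D * tau))
  expect_equal(concentration(f, c(0, 0, 0), 60), oracle(1000, 0, 60),
               tolerance = 1e-12)
  expect_equal(concentration(f, c(30, -40, 120), 200),
               oracle(1000, sqrt(30^2 + 40^2 + 120^2), 200),
               tolerance = 1e-12)
  # events at or after the query time contribute nothing
  expect_equal(concentration(f, c(0, 0, 0), 0), 0)
})

test_that("each event's spatial integral recovers its quantity (mass conservation)", {
  f <- chemokine_field(D = 250, coalescing_window = 0)
  f <- record_secretion(f, c(10, 20, 30), 5, 777)
  for (t in c(20, 300)) {
    shell <- function(r) {
      pts <- cbind(10 + r, 20, 30) # radial symmetry about the source
      4 * pi * r^2 * concentration(f, pts, t)
    }
    mass <- stats::integrate(function(r) vapply(r, shell, numeric(1)),
                             0, Inf, rel.tol = 1e-9)$value
    expect_equal(mass, 777, tolerance = 1e-3)
  }
})

test_that("superposition is linear; coalescing merges same-source events", {
  exact <- chemokine_field(coalescing_window = 0)
  exact <- record_secretion(exact, c(0, 0, 0), 0, 400)
  exact <- record_secretion(exact, c(50, 0, 0), 30, 600)
  single1 <- record_secretion(chemokine_field(coalescing_window = 0),
                              c(0, 0, 0), 0, 400)
  single2 <- record_secretion(chemokine_field(coalescing_window = 0),
                              c(50, 0, 0), 30, 600)
  p <- c(20, 10, -5)
  expect_equal(concentration(exact, p, 120),
               concentration(single1, p, 120) +
                 concentration(single2, p, 120), tolerance = 1e-12)
  # 15 events of 1000/3 molecules in one 5-min window -> one 5000-molecule event
  f <- chemokine_field(coalescing_window = 5)
  for (i in 0:14) f <- record_secretion(f, c(0, 0, 0), i * 20, 1000 / 3)
  expect_equal(nrow(f$events), 1)
  expect_equal(f$events$q, 5000, tolerance = 1e-9)
  # events 20 min apart never merge
  f2 <- chemokine_field(coalescing_window = 5)
  f2 <- record_secretion(f2, c(0, 0, 0), 0, 10)
  f2 <- record_secretion(f2, c(0, 0, 0), 1200, 10)
  expect_equal(nrow(f2$events), 2)
  expect_error(record_secretion(f2, c(0, 0, 0), 0, -1), "positive")
})

test_that("gradient probe converges to the analytic kernel gradient", {
  f <- chemokine_field(D = 250, coalescing_window = 0)
  expect_null(gradient_probe(f, c(0, 0, 0), 6, 10)$direction)
  src <- c(400, 250, 30)
  f <- record_secretion(f, src, 0, 5000)
  agent <- c(100, -50, 25)
  exact_dir <- (src - agent) / sqrt(sum((src - agent)^2))
  angle_deg <- function(a, b) acos(min(1, sum(a * b))) * 180 / pi
  for (r in c(6, 3, 1.5)) {
    g <- gradient_probe(f, agent, r, 600)
    expect_lt(angle_deg(g$direction, exact_dir), 5)
  }
  # finer probes approximate the true gradient better
  errs <- vapply(c(6, 3, 1.5), function(r)
    angle_deg(gradient_probe(f, agent, r, 600)$direction, exact_dir),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  # mirror-symmetric sources cancel: no direction
  f2 <- chemokine_field(coalescing_window = 0)
  f2 <- record_secretion(f2, c(100, 0, 0), 0, 1000)
  f2 <- record_secretion(f2, c(-100, 0, 0), 0, 1000)
  g2 <- gradient_probe(f2, c(0, 0, 0), 6, 60)
  expect_null(g2$direction)
  expect_gt(g2$max_concentration, 0)
})

test_that("threshold sampling honours medians and the ordering constraint", {
  tp0 <- threshold_params(1e-7, 1e-5, sigma_log = 0)
  th0 <- withr::with_seed(1, sample_thresholds(tp0, 10))
  expect_equal(th0$actuation, rep(1e-7, 10))
  expect_equal(th0$desensitisation, rep(1e-5, 10))
  tp <- threshold_params(1e-7, 1e-5, sigma_log = 0.5)
  th <- withr::with_seed(2, sample_thresholds(tp, 1e5))
  expect_true(all(th$actuation < th$desensitisation))
  expect_lt(abs(stats::median(th$actuation) / 1e-7 - 1), 0.02)
  expect_lt(abs(stats::median(th$desensitisation) / 1e-5 - 1), 0.02)
})
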