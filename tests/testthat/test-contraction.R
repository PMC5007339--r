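times_400 <- seq(0, 400, by = 10)

test_that("strain timecourse integrates a steady linear sink to 2at exactly", {
  a <- 0.001
  f <- linear_sink_field(a = a, xs = seq(-10, 10, by = 1), times = times_400)
  reg <- activation_region(0, 0, 5)
  tc <- strain_timecourse(f, reg)
  # velocity constant in time: trapezoidal integral exact; divergence of the
  # linear displacement exact; epsilon(t) = 2 a t
  expect_all_equal(tc$strain, 2 * a * tc$time, tol = 1e-12)
  expect_equal(tc$strain[1], 0)
  # spatial-average and time-integration commute on this field
  expect_lt(attr(tc, "commute_gap"), 1e-12)

  f0 <- make_field(function(x, y) 0 * x, function(x, y) 0 * x, times = times_400)
  expect_all_equal(strain_timecourse(f0, reg)$strain, 0)

  expect_error(
    strain_timecourse(linear_sink_field(times = 0), reg),
    "at least 2 frames"
  )
})

test_that("phase segmentation matches the 100/300 s windows", {
  tc <- tibble::tibble(time = times_400, strain = 0.001 * times_400)
  seg <- segment_phases(tc)
  expect_equal(seg$phase[seg$time < 100], factor(rep("P1", 10), c("P1", "P2", "P3")))
  expect_true(all(seg$phase[seg$time >= 100 & seg$time <= 300] == "P2"))
  expect_true(all(seg$phase[seg$time > 300] == "P3"))

  # series ending before t2: empty P3 with a warning
  short <- tibble::tibble(time = seq(0, 250, 10), strain = 0)
  expect_warning(seg2 <- segment_phases(short), "P3 is empty")
  expect_equal(sum(seg2$phase == "P3"), 0)

  # t1 = 0 gives an empty lag phase
  seg3 <- segment_phases(tc, t1 = 0, t2 = 300)
  expect_equal(sum(seg3$phase == "P1"), 0)

  expect_error(segment_phases(tc, t1 = 300, t2 = 100), "t1 < t2")
  expect_error(segment_phases(tibble::tibble(time = c(0, 50), strain = 0)),
               "beyond t1")
})

test_that("strain rate is the least-squares P2 slope", {
  # exact line
  tc <- segment_phases(tibble::tibble(time = times_400, strain = 0.003 * times_400))
  expect_equal(as.numeric(strain_rate(tc)), 0.003, tolerance = 1e-12)

  # saturating curve: compare against the OLS slope computed from first
  # principles (explicit normal-equation sums) on the P2 samples
  eps0 <- 1.2; tau <- 150
  y <- eps0 * (1 - exp(-times_400 / tau))
  tc2 <- segment_phases(tibble::tibble(time = times_400, strain = y))
  p2 <- times_400 >= 100 & times_400 <= 300
  tbar <- mean(times_400[p2]); ybar <- mean(y[p2])
  slope_oracle <- sum((times_400[p2] - tbar) * (y[p2] - ybar)) /
    sum((times_400[p2] - tbar)^2)
  expect_equal(as.numeric(strain_rate(tc2)), slope_oracle, tolerance = 1e-12)

  # noisy line: recovered slope within ~2 standard errors of truth
  set.seed(11)
  b <- 0.003
  yn <- b * times_400 + rnorm(length(times_400), 0, 0.05)
  tc3 <- segment_phases(tibble::tibble(time = times_400, strain = yn))
  sr <- strain_rate(tc3)
  expect_lt(abs(as.numeric(sr) - b), 2.5 * attr(sr, "se"))

  expect_error(
    strain_rate(segment_phases(tibble::tibble(time = c(0, 150, 400), strain = 0),
                               t1 = 100, t2 = 300)),
    "3 samples"
  )
})

test_that("maximum strain is the P3 plateau mean", {
  y <- ifelse(times_400 > 300, 1.4, 0.001 * times_400)
  tc <- segment_phases(tibble::tibble(time = times_400, strain = y))
  expect_equal(max_strain(tc), 1.4)

  # saturating curve with tau << t2: plateau mean ~ eps0, and equals the
  # analytic mean of the sampled values over P3
  eps0 <- 1.1; tau <- 40
  y2 <- eps0 * (1 - exp(-times_400 / tau))
  tc2 <- segment_phases(tibble::tibble(time = times_400, strain = y2))
  expect_equal(max_strain(tc2), mean(y2[times_400 > 300]), tolerance = 1e-14)
  expect_lt(abs(max_strain(tc2) - eps0), 1e-3 * eps0)

  # monotone series: plateau mean at least the strain entering P3
  y3 <- sqrt(times_400)
  tc3 <- segment_phases(tibble::tibble(time = times_400, strain = y3))
  expect_gte(max_strain(tc3), y3[times_400 == 300] * (1 - 1e-12))

  expect_warning(tc4 <- segment_phases(tibble::tibble(time = seq(0, 250, 10), strain = 0)))
  expect_error(max_strain(tc4), "P3 is empty")
})

test_that("time reversal flips the strain sign exactly", {
  reg <- activation_region(0, 0, 5)
  f <- make_field(function(x, y) -0.002 * x + 0.001 * y,
                  function(x, y) -0.001 * y,
                  times = times_400)
  fneg <- field_series(
    tibble::tibble(time = f$time, x = f$x, y = f$y, vx = -f$vx, vy = -f$vy),
    quiet = TRUE
  )
  tc <- strain_timecourse(f, reg)
  tcn <- strain_timecourse(fneg, reg)
  expect_all_equal(tc$strain, -tcn$strain)
})

test_that("strain metrics are invariant to rigid rotation about the centre", {
  reg <- activation_region(0, 0, 5)
  f <- make_field(function(x, y) -0.002 * x, function(x, y) -0.002 * y,
                  xs = seq(-10, 10, 1), times = times_400)
  fr <- rotate_field_90(f)
  tc <- strain_timecourse(f, reg)
  tcr <- strain_timecourse(fr, reg)
  expect_equal(as.numeric(strain_rate(tc)), as.numeric(strain_rate(tcr)),
               tolerance = 1e-10)
  expect_equal(max_strain(tc), max_strain(tcr), tolerance = 1e-10)
})

test_that("contraction summary gathers the per-condition scalars", {
  f <- linear_sink_field(a = 0.001, times = times_400)
  reg <- activation_region(0, 0, 5)
  s <- contraction_summary(f, reg, rho = 0.7)
  expect_equal(s$xi, 5)
  expect_equal(s$rho, 0.7)
  expect_equal(s$strain_rate, 0.002, tolerance = 1e-10)
  expect_gt(s$eps_max, 0.6)
  # boundary velocity of the linear sink is xi on average (v_r = a r)
  expect_equal(s$v_boundary_peak, 0.001 * 5, tolerance = 0.1)
})
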