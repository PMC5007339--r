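test_that("divergence reproduces analytic derivatives on polynomial fields", {
  # linear sink: divergence exactly -2a at every node (one-sided edges too,
  # since the components are linear)
  f <- linear_sink_field(a = 0.01)
  d <- divergence(f)
  expect_all_equal(d$value, -0.02)

  # uniform translation: divergence identically zero
  f2 <- make_field(function(x, y) 0.5 + 0 * x, function(x, y) 0 * x)
  expect_all_equal(divergence(f2)$value, 0)

  # v = (x^2, 0): central differences are exact for quadratics, so the
  # interior divergence equals the analytic 2x
  f3 <- make_field(function(x, y) x^2, function(x, y) 0 * x,
                   xs = seq(-5, 5, by = 1))
  d3 <- divergence(f3)
  interior <- d3$x > min(d3$x) & d3$x < max(d3$x)
  expect_all_equal(d3$value[interior], 2 * d3$x[interior])
})

test_that("divergence of solenoidal polynomial fields vanishes in the interior", {
  # vx = dpsi/dy, vy = -dpsi/dx for cubic psi => exactly divergence-free,
  # with quadratic components for which central differences are exact:
  # psi = x^2 y + y^3 - x y^2  and  psi = x^3 - 2 x^2 y + x y^2
  psi_fields <- list(
    c(function(x, y) x^2 + 3 * y^2 - 2 * x * y,
      function(x, y) -2 * x * y + y^2),
    c(function(x, y) -2 * x^2 + 2 * x * y,
      function(x, y) -(3 * x^2 - 4 * x * y + y^2))
  )
  for (ff in psi_fields) {
    f <- make_field(ff[[1]], ff[[2]], xs = seq(-6, 6, by = 1))
    d <- divergence(f)
    interior <- d$x > min(d$x) & d$x < max(d$x) & d$y > min(d$y) & d$y < max(d$y)
    expect_all_equal(d$value[interior], 0, tol = 1e-10)
  }
})

test_that("divergence rejects grids smaller than 3x3", {
  f <- make_field(function(x, y) 0 * x, function(x, y) 0 * x, xs = c(0, 1))
  expect_error(divergence(f), "3 x 3")
})

test_that("radial decomposition follows the inward-positive convention", {
  reg <- activation_region(0, 0, 5)

  # pure sink: v_r = +a off-centre, v_t = 0
  f <- sink_field(a = 0.02)
  dec <- decompose_radial(f, reg)
  off <- sqrt(dec$v_r$x^2 + dec$v_r$y^2) > 0.5
  expect_all_equal(dec$v_r$value[off], 0.02)
  expect_all_equal(dec$v_t$value[off], 0)
  expect_equal(dec$v_r$value[!off], 0)

  # rigid rotation: v_r = 0, v_t = omega r
  fr <- rotation_field(omega = 0.003)
  decr <- decompose_radial(fr, reg)
  r <- sqrt(decr$v_t$x^2 + decr$v_t$y^2)
  expect_all_equal(decr$v_r$value[off], 0)
  expect_all_equal(decr$v_t$value[off], (0.003 * r)[off])
})

test_that("decomposition preserves speed and recomposes the field exactly", {
  reg <- activation_region(0.3, -0.2, 4)
  set.seed(42)
  f <- make_field(function(x, y) sin(x / 3) + 0.1 * y,
                  function(x, y) cos(y / 4) - 0.05 * x)
  dec <- decompose_radial(f, reg)
  r <- sqrt((f$x - reg$x)^2 + (f$y - reg$y)^2)
  off <- r >= attr(f, "spacing") / 2
  # pointwise identity v_r^2 + v_t^2 = |v|^2
  expect_all_equal((dec$v_r$value^2 + dec$v_t$value^2)[off],
                   (f$vx^2 + f$vy^2)[off])
  # recompose: v = -v_r r_hat + v_t theta_hat
  rx <- (f$x - reg$x) / r; ry <- (f$y - reg$y) / r
  vx_rec <- -dec$v_r$value * rx + dec$v_t$value * (-ry)
  vy_rec <- -dec$v_r$value * ry + dec$v_t$value * rx
  expect_all_equal(vx_rec[off], f$vx[off])
  expect_all_equal(vy_rec[off], f$vy[off])
})

test_that("radial profiles bin annular means with flagged empty bins", {
  reg <- activation_region(0, 0, 5)
  f <- make_field(function(x, y) 0 * x, function(x, y) 0 * x,
                  xs = seq(-10, 10, by = 0.5))

  # constant scalar field: every non-empty bin mean equals the constant
  s <- scalar_field_series(tibble::tibble(time = f$time, x = f$x, y = f$y,
                                          value = 3.7))
  pr <- radial_profile(s, reg, bin_width = 1)
  expect_all_equal(pr$mean[pr$n > 0], 3.7)

  # f = r on a fine grid: bin means within half a spacing of bin centres
  s2 <- scalar_field_series(tibble::tibble(time = f$time, x = f$x, y = f$y,
                                           value = sqrt(f$x^2 + f$y^2)))
  pr2 <- radial_profile(s2, reg, bin_width = 1)
  ok <- pr2$n > 0
  expect_lt(max(abs(pr2$mean[ok] - pr2$r[ok])), 0.5)

  # bin width larger than the grid: single occupied bin holding the mean
  pr3 <- radial_profile(s2, reg, bin_width = 1000)
  expect_equal(sum(pr3$n > 0), 1)
  expect_equal(pr3$mean[pr3$n > 0], mean(s2$value))

  # bins are contiguous from zero and empty bins are NA, not zero
  expect_equal(pr2$r, (seq_along(pr2$r) - 0.5) * 1)
  expect_true(all(is.na(pr2$mean[pr2$n == 0])))
})

test_that("boundary velocity averages the annulus about the activation circumference", {
  reg <- activation_region(0, 0, 8)
  f <- sink_field(a = 0.015, xs = seq(-15, 15, by = 0.5))
  # v_r = a everywhere: annulus mean is a for any window
  expect_all_equal(boundary_velocity(f, reg)$v_boundary, 0.015)
  expect_all_equal(boundary_velocity(f, reg, window = 6)$v_boundary, 0.015)

  # v_r(r) = r (outward-increasing inward speed): narrow annulus mean ~ xi
  fv <- make_field(function(x, y) -x, function(x, y) -y,
                   xs = seq(-15, 15, by = 0.25))
  vb <- boundary_velocity(fv, reg, window = 0.6)
  expect_lt(abs(vb$v_boundary - 8), 0.2)

  # zero field
  f0 <- make_field(function(x, y) 0 * x, function(x, y) 0 * x)
  expect_all_equal(boundary_velocity(f0, activation_region(0, 0, 5))$v_boundary, 0)

  # empty annulus names the geometry
  expect_error(boundary_velocity(f, activation_region(0, 0, 14.9), window = 1e-6),
               "annulus")
})

test_that("region mean averages nodes inside the disc", {
  reg <- activation_region(0, 0, 5)
  base <- make_field(function(x, y) 0 * x, function(x, y) 0 * x)
  s <- scalar_field_series(tibble::tibble(time = base$time, x = base$x,
                                          y = base$y, value = 2.5))
  expect_equal(region_mean(s, reg)$value, 2.5)

  # indicator(r <= xi) averages to 1 inside
  r <- sqrt(base$x^2 + base$y^2)
  si <- scalar_field_series(tibble::tibble(time = base$time, x = base$x,
                                           y = base$y, value = as.numeric(r <= 5)))
  expect_equal(region_mean(si, reg)$value, 1)

  # odd field about the centre averages to zero by symmetry
  sx <- scalar_field_series(tibble::tibble(time = base$time, x = base$x,
                                           y = base$y, value = base$x))
  expect_lt(abs(region_mean(sx, reg)$value), 1e-12)
})

test_that("radial profiles of a sink divergence are rotation invariant", {
  reg <- activation_region(0, 0, 5)
  f <- sink_field(a = 0.02, xs = seq(-10, 10, by = 0.5))
  p1 <- radial_profile(divergence(f), reg, bin_width = 1)
  p2 <- radial_profile(divergence(rotate_field_90(f)), reg, bin_width = 1)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-10)
  expect_equal(p1$n, p2$n)
})

test_that("missing vectors are flagged and infilled before differentiation", {
  g <- expand.grid(x = 0:10, y = 0:10)
  df <- data.frame(time = 0, g, vx = -0.01 * g$x, vy = -0.01 * g$y)
  df$vx[c(17, 60)] <- NA
  df$vy[c(17, 60)] <- NA
  expect_message(f <- field_series(df), "gap fraction")
  expect_equal(sum(f$gap), 2)
  expect_true(all(is.finite(f$vx)))
  # infilled values are local medians, so the linear field is restored closely
  expect_lt(max(abs(f$vx - (-0.01 * f$x))), 0.011)
})
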