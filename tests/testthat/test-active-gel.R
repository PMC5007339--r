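# shared moderate-resolution solution for several checks
gel_cache <- new.env()
default_sol <- function() {
  if (is.null(gel_cache$sol)) {
    gel_cache$p <- gel_params(n_grid = 400, t_total = 600, save_dt = 5)
    gel_cache$sol <- solve_gel(gel_cache$p)
  }
  gel_cache$sol
}

test_that("the closed-form inclusion solution satisfies its matching conditions", {
  p <- gel_params(n_grid = 2000)
  ss <- gel_steady_state(p)
  m <- actoflow:::gel_moduli(p)
  A <- attr(ss, "A"); B <- attr(ss, "B"); Cc <- attr(ss, "Cc")

  # in-disc areal strain u' + u/r = 2A is spatially uniform
  inside <- ss$r > 0 & ss$r < p$xi
  strain_in <- 2 * A
  du <- diff(ss$u) / diff(ss$r)
  areal <- du[inside[-1]] + (ss$u / ss$r)[-1][inside[-1]]
  expect_all_equal(areal, strain_in, tol = 1e-8)

  # u and sigma_rr continuous at xi; hoop stress jumps by (1 - nu) sigma0
  u_in <- A * p$xi
  u_out <- B * p$xi + Cc / p$xi
  expect_equal(u_in, u_out, tolerance = 1e-12)
  srr_in <- m$C * (1 + m$nu) * A + p$sigma0
  srr_out <- m$C * ((1 + m$nu) * B - (1 - m$nu) * Cc / p$xi^2)
  expect_equal(srr_in, srr_out, tolerance = 1e-10)
  stt_in <- m$C * (1 + m$nu) * A + p$sigma0
  stt_out <- m$C * ((1 + m$nu) * B + (1 - m$nu) * Cc / p$xi^2)
  expect_equal(stt_in - stt_out, (1 - p$nu) * p$sigma0, tolerance = 1e-10)

  # at nu = 0 the hoop jump equals the active stress itself
  p0 <- gel_params(nu = 0)
  ss0 <- gel_steady_state(p0)
  m0 <- actoflow:::gel_moduli(p0)
  jump0 <- (m0$C * attr(ss0, "A") + p0$sigma0) -
    m0$C * (attr(ss0, "B") + attr(ss0, "Cc") / p0$xi^2)
  expect_equal(jump0, p0$sigma0, tolerance = 1e-10)

  # the closer the clamped edge, the more constrained the disc: shrinking
  # R/xi from 10 to the minimum 5 reduces the steady strain magnitude
  eps10 <- attr(gel_steady_state(gel_params(r_domain = 100)), "eps_ss")
  eps5 <- attr(gel_steady_state(gel_params(r_domain = 50)), "eps_ss")
  expect_lt(eps5, eps10)
})

test_that("zero active stress leaves the gel exactly at rest", {
  p <- gel_params(sigma0 = 1e-300, n_grid = 150, t_total = 20, dt = 1, save_dt = 5)
  sol <- solve_gel(p)
  expect_lt(max(abs(sol$u)), 1e-250)
  expect_lt(max(abs(sol$strain$strain)), 1e-250)
})

test_that("the long-time solver state matches the closed-form inclusion solution", {
  sol <- default_sol()
  ss <- gel_steady_state(gel_cache$p)
  u_num <- sol$u[, ncol(sol$u)]
  rel_l2 <- sqrt(sum((u_num - ss$u)^2) / sum(ss$u^2))
  expect_lt(rel_l2, 0.02)   # N = 400; the N = 800 bound is checked in acceptance
  expect_equal(tail(sol$strain$strain, 1), attr(ss, "eps_ss"), tolerance = 0.02)
})

test_that("strain rises monotonically to a plateau and flow arrests", {
  sol <- default_sol()
  eps <- sol$strain$strain
  expect_true(all(diff(eps) > -1e-12))
  expect_gt(eps[length(eps)], 0)
  # plateau: last 100 s change under 1%
  n <- length(eps)
  expect_lt(abs(eps[n] - eps[n - 20]) / eps[n], 0.01)
  # viscoelastic-solid arrest: boundary velocity decays to ~0
  vb <- sol$boundary_velocity$v_boundary
  expect_lt(abs(vb[n]), 0.02 * max(vb))
})

test_that("the response is linear in the active stress amplitude", {
  p1 <- gel_params(n_grid = 200, t_total = 100, dt = 1, save_dt = 10)
  p2 <- gel_params(sigma0 = 3, E = 1, n_grid = 200, t_total = 100, dt = 1, save_dt = 10)
  s1 <- solve_gel(p1); s2 <- solve_gel(p2)
  expect_all_equal(s2$u, 3 * s1$u, tol = 1e-9)
  expect_all_equal(s2$strain$strain, 3 * s1$strain$strain, tol = 1e-9)
})

test_that("refining time and space leaves the plateau strain essentially unchanged", {
  # in the converged regime (the interface is first-order, so the asymptotic
  # window starts around N ~ 3000 for the default geometry)
  base <- glance(solve_gel(gel_params(n_grid = 3200, t_total = 400, dt = 1, save_dt = 10)))
  fine <- glance(solve_gel(gel_params(n_grid = 6400, t_total = 400, dt = 0.5, save_dt = 10)))
  expect_lt(abs(fine$eps_max - base$eps_max) / base$eps_max, 0.001)
})

test_that("clamped and stress-free outer boundaries agree at R = 10 xi", {
  pc <- gel_params(n_grid = 300, t_total = 500, dt = 1, save_dt = 10)
  pf <- gel_params(n_grid = 300, t_total = 500, dt = 1, save_dt = 10, bc = "free")
  gc_ <- glance(solve_gel(pc)); gf <- glance(solve_gel(pf))
  expect_lt(abs(gc_$eps_max - gf$eps_max) / gc_$eps_max, 0.02)
  # and the stress-free run agrees with its own closed form
  expect_equal(gf$eps_max, attr(gel_steady_state(pf), "eps_ss"), tolerance = 0.03)
})

test_that("instability detection trips on a grossly excessive time step", {
  p <- gel_params(zeta = 1e-5, eta = 1e-3, dt = 50, t_total = 200,
                  n_grid = 150, tau_a = 1, save_dt = 50)
  expect_error(solve_gel(p), "instability|singular")
})

test_that("exported Cartesian fields round-trip the radial velocity profile", {
  sol <- default_sol()
  f <- export_velocity_field(sol, spacing = 0.5, interval = 10, extent = 25)
  expect_s3_class(f, "field_series")
  expect_equal(unique(diff(sort(unique(f$time)))), 10)
  reg <- attr(f, "region")
  expect_equal(reg$radius, 10)

  dec <- decompose_radial(f, reg)
  vr <- scalar_field_series(dec$v_r[dec$v_r$time == 60, ], spacing = 0.5)
  prof <- radial_profile(vr, reg, bin_width = 1)
  prof <- prof[prof$n > 0 & prof$r < 20, ]
  # inward-positive bin means equal the (negated) solver profile at bin centres
  k <- which(sol$times == 60)
  truth <- -approx(sol$r, sol$v[, k], xout = prof$r)$y
  expect_lt(max(abs(prof$mean - truth)), 0.05 * max(abs(truth)) + 1e-6)

  # zero solution exports a zero field
  p0 <- gel_params(sigma0 = 1e-300, n_grid = 150, t_total = 20, dt = 1, save_dt = 10)
  f0 <- export_velocity_field(solve_gel(p0), spacing = 2, interval = 10)
  expect_lt(max(abs(c(f0$vx, f0$vy))), 1e-250)
})

test_that("parameter validation guards the gel model", {
  expect_error(gel_params(E = -1), "positive")
  expect_error(gel_params(nu = 1), "Poisson")
  expect_error(gel_params(r_domain = 20), "5 \\* xi")
  expect_error(gel_params(n_grid = 10), "at least 100")
})
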