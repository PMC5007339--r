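# small, fast parameterisations for unit checks
small_params <- function(...) {
  args <- utils::modifyList(
    list(n_filaments = 60, t_total = 1, snap_dt = 0.5), list(...)
  )
  do.call(abm_params, args)
}

# hand-built two-filament + one-motor state for contract tests
two_filament_state <- function(p, gap = 20, pre_bind = TRUE) {
  seg <- p$segment_length * 1000
  nb <- 11
  x <- seq(0, by = seg, length.out = nb) + 500
  mid <- p$box * 500
  b1 <- cbind(x, rep(mid - gap / 2, nb))        # barbed end at +x
  b2 <- cbind(rev(x), rep(mid + gap / 2, nb))   # antiparallel: barbed at -x
  arms <- matrix(c(0, 1, 1, 0), 8, 4, byrow = TRUE)
  if (pre_bind) {
    ctr_x <- mean(range(x))
    # arm 1 -> filament 1, arm 3 (other node) -> filament 2, both mid-segment
    arms[1, ] <- c(1, 1, 5, 140)
    arms[3, ] <- c(1, 2, 5, 140)
  }
  structure(list(
    bead_pos = rbind(b1, b2), fil_first = c(1L, nb + 1L),
    fil_len = c(nb, nb), anchored = rep(FALSE, 2 * nb),
    mot_pos = cbind(mean(range(x)) + ((0:3) - 1.5) * 42, rep(mid, 4)),
    arms = arms, params = p, seed = 1
  ), class = "network_state")
}

test_that("network builds are reproducible and match the target geometry", {
  p <- small_params()
  n1 <- build_network(p, seed = 5)
  n2 <- build_network(p, seed = 5)
  expect_identical(n1$bead_pos, n2$bead_pos)
  expect_identical(n1$mot_pos, n2$mot_pos)
  n3 <- build_network(p, seed = 6)
  expect_false(identical(n1$bead_pos, n3$bead_pos))

  # disordered orientations: nematic order at the null scale
  p_big <- abm_params(n_filaments = 600, box = 200, rim = 1)
  fil <- gen_filament_set(600, seed = 3)
  expect_lt(nematic_order(fil$theta), 3 / sqrt(600))

  # empirical mean contour length within 5% of 7.1 um at >= 500 filaments
  d <- gen_filament_set(500, seed = 21)
  expect_lt(abs(mean(d$length) - 7.1) / 7.1, 0.05)
})

test_that("a motor-free noise-free network is a fixed point", {
  p <- small_params(rm = 0)
  net <- build_network(p, seed = 2)
  out <- abm_step(net, p, n_steps = 200, seed = 1)
  expect_equal(out$bead_pos, net$bead_pos, tolerance = 1e-12)
})

test_that("internal forces sum to zero (action-reaction across all couplings)", {
  p <- small_params()
  net <- build_network(p, seed = 4)
  # deform the network so every force term is non-trivially engaged,
  # and bind every arm to a random nearby segment
  set.seed(7)
  net$bead_pos <- net$bead_pos + matrix(rnorm(length(net$bead_pos), 0, 30),
                                        ncol = 2)
  n_arms <- nrow(net$arms)
  segs_per_fil <- net$fil_len - 1L
  fil_pick <- sample(seq_along(net$fil_first), n_arms, replace = TRUE)
  net$arms[, 1] <- 1
  net$arms[, 2] <- fil_pick
  net$arms[, 3] <- vapply(fil_pick, function(f) sample(segs_per_fil[f], 1), 1L)
  net$arms[, 4] <- runif(n_arms, 0, 280)
  f <- network_forces(net, p)
  expect_gt(max(abs(f$f_bead)), 1)   # forces are genuinely non-zero
  total <- colSums(f$f_bead) + colSums(f$f_mot)
  expect_lt(max(abs(total)), 1e-8)
})

test_that("a single motor slides antiparallel filaments at up to twice the motor speed", {
  # near-zero load: low drag, stability preserved by a smaller step
  p <- abm_params(box = 8, activation_radius = 3.9, n_filaments = 2,
                  rm = 0, rim = 1e-6, gamma_bead = 1e-4, gamma_mot = 1e-4,
                  dt = 1e-5, k_on = 1e-9)
  st <- two_filament_state(p)
  # let the pre-stretched linkers relax, then measure motor-driven sliding
  st1 <- abm_step(st, p, n_steps = 20000, seed = 1)   # 0.2 s
  st2 <- abm_step(st1, p, n_steps = 100000, seed = 2) # 1.0 s window
  d1 <- mean(st2$bead_pos[1:11, 1] - st1$bead_pos[1:11, 1])
  d2 <- mean(st2$bead_pos[12:22, 1] - st1$bead_pos[12:22, 1])
  v_rel <- abs(d1 - d2) / 1.0
  expect_lt(v_rel, 2 * p$v0 * 1.15)   # bounded by 2 v0 (stochastic stepping)
  expect_gt(v_rel, 2 * p$v0 * 0.5)    # approaches 2 v0 at near-zero load
  # contractile direction: filament 1 (barbed +x) slides -x relative to 2
  expect_lt(d1 - d2, 0)
})

test_that("motors outside the activation disc detach at the non-processive rate", {
  # many bound arms on one anchored filament far outside the disc; k_on = 0
  # so unbinding is a pure exponential decay at k_off_out
  p <- abm_params(box = 40, activation_radius = 2, n_filaments = 2, rm = 0,
                  rim = 1e-6, k_on = 1e-12, v0 = 1e-9, dt = 1e-3)
  seg <- 280; nb <- 101
  x <- seq(0, by = seg, length.out = nb) + 2000
  st <- structure(list(
    bead_pos = cbind(x, rep(35000, nb)),
    fil_first = 1L, fil_len = nb, anchored = rep(TRUE, nb),
    mot_pos = NULL, arms = NULL, params = p, seed = 1
  ), class = "network_state")
  n_mot <- 50
  mp <- matrix(0, 4 * n_mot, 2)
  arms <- matrix(0, 8 * n_mot, 4)
  for (mI in seq_len(n_mot)) {
    cx <- 2000 + (mI * 500)
    mp[(4 * mI - 3):(4 * mI), 1] <- cx + ((0:3) - 1.5) * 42
    mp[(4 * mI - 3):(4 * mI), 2] <- 35000
    for (a in 1:8) {
      node_x <- mp[4 * (mI - 1) + (a - 1) %/% 2 + 1, 1]
      seg_i <- min(nb - 1, max(1, floor((node_x - 2000) / seg) + 1))
      arms[8 * (mI - 1) + a, ] <- c(1, 1, seg_i, node_x - 2000 - (seg_i - 1) * seg)
    }
  }
  st$mot_pos <- mp; st$arms <- arms
  # survival after t = 1/k_off_out should be ~ exp(-1)
  t_probe <- 1 / p$k_off_out
  out <- with(list(), abm_step(st, p, n_steps = round(t_probe / p$dt), seed = 3))
  frac <- mean(out$arms[, 1])
  expect_lt(abs(frac - exp(-1)), 0.08)
})

test_that("trajectories are deterministic given parameters and seed", {
  p <- small_params()
  t1 <- abm_run(p, seed = 3)
  t2 <- abm_run(p, seed = 3)
  expect_identical(t1$snap_bead, t2$snap_bead)
  expect_identical(t1$state$arms, t2$state$arms)
})

test_that("motor-free runs show no net strain", {
  p <- small_params(rm = 0, t_total = 2)
  traj <- abm_run(p, seed = 1)
  tc <- measure_strain(traj)
  expect_lt(max(abs(tc$strain)), 1e-10)
})

test_that("strain measurement recovers affine and rigid test trajectories", {
  p <- abm_params(n_filaments = 2, rm = 0)
  centers <- seq(0.5, 19.5, by = 1)
  g <- as.matrix(expand.grid(x = centers, y = centers)) * 1000   # nm
  a <- 0.04
  affine <- g
  affine[, 1] <- g[, 1] - a * (g[, 1] - 10000)
  affine[, 2] <- g[, 2] - a * (g[, 2] - 10000)
  traj <- list(times = c(0, 10),
               snap_bead = array(c(g, affine), dim = c(nrow(g), 2, 2)),
               params = p)
  tc <- measure_strain(traj, t1 = 2, t2 = 8)
  expect_equal(tail(tc$strain, 1), 2 * a, tolerance = 1e-10)

  rigid <- g + 500  # uniform translation
  traj2 <- list(times = c(0, 10),
                snap_bead = array(c(g, rigid), dim = c(nrow(g), 2, 2)),
                params = p)
  tc2 <- measure_strain(traj2, t1 = 2, t2 = 8)
  expect_lt(max(abs(tc2$strain)), 1e-10)
})

test_that("force maps report per-segment spring tension", {
  p <- abm_params(n_filaments = 2, rm = 0)
  seg <- 280
  x <- c(0, seg, 2 * seg + 15)  # last segment stretched by 15 nm
  st <- structure(list(
    bead_pos = cbind(x + 5000, rep(5000, 3)),
    fil_first = 1L, fil_len = 3L, anchored = rep(FALSE, 3),
    mot_pos = matrix(0, 0, 2), arms = matrix(0, 0, 4),
    params = p, seed = 1
  ), class = "network_state")
  fm <- force_map(st, p)
  expect_equal(fm$tension, c(0, p$k_seg * 15), tolerance = 1e-10)
})

test_that("contracting networks localise tension inside the activation disc", {
  p <- abm_params(n_filaments = 400, t_total = 30, snap_dt = 10)
  traj <- abm_run(p, seed = 11)
  fm <- force_map(traj$state, p)
  r <- sqrt((fm$x - p$box / 2)^2 + (fm$y - p$box / 2)^2)
  expect_gt(mean(abs(fm$tension[r < p$activation_radius])),
            mean(abs(fm$tension[r > p$activation_radius])))
})

test_that("segment lengths stay within the stiff-spring tolerance during contraction", {
  p <- abm_params(n_filaments = 300, t_total = 20, snap_dt = 10)
  traj <- abm_run(p, seed = 2)
  fm <- force_map(traj$state, p)
  rest <- p$segment_length * 1000
  stretch <- abs(fm$tension) / p$k_seg / rest
  expect_lt(max(stretch), 0.10)
})
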