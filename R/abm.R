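#' Parameters for the agent-based actomyosin simulator
#'
#' Reduced-scale Brownian-dynamics model of a 2D disordered actomyosin
#' network: semiflexible F-actin bead-spring chains (280 nm segments, 7 nm
#' sites) connected *only* by bipolar myosin thick filaments (three 42 nm
#' backbone segments with elastic hinges, two motor arms per backbone node,
#' eight arms in all). Inside the circular activation disc motors have
#' catch-like load-dependent unbinding (`k_off = k0 exp(-F/F0)`); outside it
#' they are non-processive (constant fast off-rate), representing
#' blebbistatin-inhibited myosin. Defaults are the reduced scale used for
#' routine runs: 20 um box, 6 um activation radius, 100 s simulated at
#' dt = 1 ms with softened segment stiffness; kinetic constants follow
#' standard non-muscle myosin II modelling practice. The default filament
#' count gives a dense network (mesh size ~0.25 um, total contour length
#' ~14 um per um^2), the regime in which myosin crosslinking percolates
#' force across the activation disc.
#'
#' @param box Box width (um). The activation disc is centred in the box.
#' @param activation_radius Activation radius (um); the disc must fit in
#'   the box.
#' @param n_filaments Number of filaments.
#' @param mean_length Mean filament contour length (um).
#' @param trunc Length truncation bounds (um).
#' @param lp Persistence length (um); 20 for F-actin, up to 2600 for the
#'   stiff-filament comparison.
#' @param rm Motor:actin ratio R_M (motors per actin segment).
#' @param t_total Simulated time (s).
#' @param dt Time step (s).
#' @param snap_dt Snapshot interval (s).
#' @param segment_length Actin segment length (um).
#' @param rim Width of the immobile anchoring rim at the box edge (um),
#'   mimicking the quiescent surrounding network.
#' @param v0 Unloaded motor speed (nm/s). @param f_stall Stall force (pN).
#' @param k_on Binding rate (1/s) within `capture` nm.
#' @param k0 Unloaded off-rate inside the activation disc (1/s).
#' @param f0 Unbinding force scale (pN). @param k_off_out Off-rate outside
#'   the disc (1/s).
#' @param capture Binding capture radius (nm). @param step_nm Motor step
#'   (nm, the binding-site spacing).
#' @param k_seg Actin segment extensional stiffness (pN/nm; softened for
#'   the ms time step). @param k_back,kappa_back Motor backbone spring
#'   (pN/nm) and hinge bending (pN nm) stiffness. @param k_arm Arm linker
#'   stiffness (pN/nm).
#' @param gamma_bead,gamma_mot Drag coefficients (pN s/nm).
#' @param noise_kbt Thermal energy for Brownian noise (pN nm); 0 (default)
#'   disables noise, 4.11 is kT at room temperature.
#' @param rebuild_every Steps between neighbour-list rebuilds.
#' @return A validated list of class `abm_params`.
#' @export
abm_params <- function(box = 20, activation_radius = 6, n_filaments = 800,
                       mean_length = 7.1, trunc = c(0.56, 25), lp = 20,
                       rm = 0.04, t_total = 100, dt = 1e-3, snap_dt = 5,
                       segment_length = 0.28, rim = 1,
                       v0 = 140, f_stall = 4, k_on = 40, k0 = 0.35, f0 = 4,
                       k_off_out = 20, capture = 20, step_nm = 7,
                       k_seg = 1.5, k_back = 1.5, kappa_back = 1000, k_arm = 0.3,
                       gamma_bead = 0.01, gamma_mot = 0.01, noise_kbt = 0,
                       rebuild_every = 20) {
  p <- as.list(environment())
  for (nm_ in c("box", "activation_radius", "n_filaments", "mean_length", "lp",
                "t_total", "dt", "snap_dt", "segment_length", "rim", "v0",
                "f_stall", "k_on", "k0", "f0", "k_off_out", "capture",
                "step_nm", "k_seg", "k_back", "kappa_back", "k_arm",
                "gamma_bead", "gamma_mot")) {
    v <- p[[nm_]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("abm parameter `%s` must be a single positive number", nm_))
    }
  }
  if (rm < 0) abort("motor:actin ratio rm must be >= 0")
  if (activation_radius > box / 2) abort("activation disc must lie inside the box")
  structure(p, class = "abm_params")
}

KBT_PNNM <- 4.114  # kT at 25 C, pN nm

cpp_params <- function(p) {
  list(
    dt = p$dt, k_seg = p$k_seg, rest_seg = p$segment_length * 1000,
    kappa_fil = p$lp * 1000 * KBT_PNNM,
    k_back = p$k_back, rest_back = 42, kappa_back = p$kappa_back,
    k_arm = p$k_arm, gamma_bead = p$gamma_bead, gamma_mot = p$gamma_mot,
    v0 = p$v0, f_stall = p$f_stall, k_on = p$k_on, k0 = p$k0, f0 = p$f0,
    k_off_out = p$k_off_out, capture = p$capture,
    act_x = p$box * 500, act_y = p$box * 500, act_r = p$activation_radius * 1000,
    step_nm = p$step_nm, noise_kbt = p$noise_kbt,
    rebuild_every = as.integer(p$rebuild_every)
  )
}

#' Build a disordered actomyosin network
#'
#' Filaments get truncated-exponential contour lengths and uniform random
#' positions and orientations (nematic order ~ 0); beads are laid out in
#' straight chains ordered pointed end to barbed end. Motor thick filaments
#' polymerise onto the network: `rm` motors per actin segment, each centred
#' on a uniformly chosen point of the actin contour with random orientation
#' and all eight arms unbound. Beads within `rim` of the box edge (or
#' outside it) are anchored.
#' The build is a pure function of (parameters, seed).
#'
#' @param p An [abm_params()].
#' @param seed Integer seed.
#' @return A list of class `network_state`: `bead_pos` (nm), `fil_first`,
#'   `fil_len`, `anchored`, `mot_pos` (nm), `arms` (bound, filament,
#'   segment, offset), plus `params` and `seed`.
#' @export
build_network <- function(p, seed = 1) {
  stopifnot(inherits(p, "abm_params"))
  fils <- gen_filament_set(p$n_filaments, mean_length = p$mean_length,
                           trunc = p$trunc, seed = seed)
  seg_nm <- p$segment_length * 1000
  box_nm <- p$box * 1000
  n_seg <- pmax(2L, as.integer(round(fils$length * 1000 / seg_nm)))
  n_beads <- n_seg + 1L
  if (sum(n_beads) > 2e6) abort("infeasible density: network would exceed the bead memory guard")
  state <- with_seed(seed + 1L, {
    cx <- runif(p$n_filaments, 0, box_nm)
    cy <- runif(p$n_filaments, 0, box_nm)
    bead_pos <- matrix(0, sum(n_beads), 2)
    fil_first <- integer(p$n_filaments)
    at <- 1L
    for (f in seq_len(p$n_filaments)) {
      fil_first[f] <- at
      s <- (seq_len(n_beads[f]) - 1) - (n_beads[f] - 1) / 2
      bead_pos[at:(at + n_beads[f] - 1L), 1] <- cx[f] + s * seg_nm * cos(fils$theta[f])
      bead_pos[at:(at + n_beads[f] - 1L), 2] <- cy[f] + s * seg_nm * sin(fils$theta[f])
      at <- at + n_beads[f]
    }
    n_mot <- as.integer(round(p$rm * sum(n_seg)))
    mot_pos <- matrix(0, 4L * n_mot, 2)
    if (n_mot > 0) {
      # thick filaments polymerise onto the F-actin network: each motor
      # centre sits on a uniformly chosen point of the actin contour
      seg_fil <- rep(seq_len(p$n_filaments), n_seg)
      seg_idx <- sequence(n_seg)
      pick <- sample.int(length(seg_fil), n_mot, replace = TRUE)
      along <- runif(n_mot)
      th <- runif(n_mot, 0, pi)
      for (mI in seq_len(n_mot)) {
        f <- seg_fil[pick[mI]]
        a <- fil_first[f] + seg_idx[pick[mI]] - 1L
        ctr <- (1 - along[mI]) * bead_pos[a, ] + along[mI] * bead_pos[a + 1L, ]
        s <- ((0:3) - 1.5) * 42
        mot_pos[(4 * mI - 3):(4 * mI), 1] <- ctr[1] + s * cos(th[mI])
        mot_pos[(4 * mI - 3):(4 * mI), 2] <- ctr[2] + s * sin(th[mI])
      }
    }
    arms <- matrix(0, 8L * n_mot, 4)
    arms[, 2] <- 1; arms[, 3] <- 1  # placeholder refs while unbound
    rim_nm <- p$rim * 1000
    anchored <- bead_pos[, 1] < rim_nm | bead_pos[, 1] > box_nm - rim_nm |
      bead_pos[, 2] < rim_nm | bead_pos[, 2] > box_nm - rim_nm
    list(bead_pos = bead_pos, fil_first = fil_first, fil_len = n_beads,
         anchored = anchored, mot_pos = mot_pos, arms = arms)
  })
  structure(c(state, list(params = p, seed = seed)), class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(
    "<network_state> %d filaments (%d beads, %d anchored), %d motors, box %g um\n",
    length(x$fil_first), nrow(x$bead_pos), sum(x$anchored),
    nrow(x$mot_pos) / 4, x$params$box
  ))
  invisible(x)
}

#' Advance a network state
#'
#' Runs `n_steps` overdamped Brownian-dynamics steps (forces, positions,
#' then binding/stepping/unbinding kinetics) and returns the updated state.
#' Aborts with a diagnostic if any bead moves more than one segment length
#' in a step.
#'
#' @param state A [build_network()] state.
#' @param p An [abm_params()] (defaults to the state's own).
#' @param n_steps Number of time steps.
#' @param seed Optional seed for the kinetic randomness.
#' @return The updated `network_state`.
#' @export
abm_step <- function(state, p = state$params, n_steps = 1, seed = NULL) {
  run1 <- function() abm_simulate_cpp(state, cpp_params(p), as.integer(n_steps), 0L)
  res <- if (is.null(seed)) run1() else with_seed(seed, run1())
  out <- state
  out$bead_pos <- res$bead_pos
  out$mot_pos <- res$mot_pos
  out$arms <- res$arms
  out
}

#' Run an agent-based contraction simulation
#'
#' Builds the network and integrates it for `t_total`, storing periodic
#' snapshots of bead/motor positions, per-segment tensions and arm binding
#' states. Identical (parameters, seed) give identical trajectories.
#'
#' @param p An [abm_params()].
#' @param seed Integer seed.
#' @return An object of class `abm_trajectory`: `times` (s), 3D snapshot
#'   arrays `snap_bead` and `snap_mot` (nm), `snap_tension` (pN),
#'   `snap_bound`, the final `state`, the initial network, `params`, `seed`.
#' @export
abm_run <- function(p, seed = 1) {
  stopifnot(inherits(p, "abm_params"))
  net <- build_network(p, seed = seed)
  n_steps <- as.integer(round(p$t_total / p$dt))
  snap_every <- max(1L, as.integer(round(p$snap_dt / p$dt)))
  res <- with_seed(seed + 2L,
    abm_simulate_cpp(net, cpp_params(p), n_steps, snap_every))
  structure(
    list(
      times = res$snap_steps * p$dt,
      snap_bead = res$snap_bead, snap_mot = res$snap_mot,
      snap_tension = res$snap_tension, snap_bound = res$snap_bound,
      state = structure(c(res[c("bead_pos", "mot_pos", "arms")],
                          net[c("fil_first", "fil_len", "anchored")],
                          list(params = p, seed = seed)),
                        class = "network_state"),
      network = net, params = p, seed = seed
    ),
    class = "abm_trajectory"
  )
}

#' @export
print.abm_trajectory <- function(x, ...) {
  cat(sprintf(
    "<abm_trajectory> %d snapshots over %g s; %d filaments, %d motors, box %g um, xi %g um\n",
    length(x$times), max(x$times), length(x$network$fil_first),
    nrow(x$network$mot_pos) / 4, x$params$box, x$params$activation_radius
  ))
  invisible(x)
}

default_abm_region <- function(p) {
  activation_region(p$box / 2, p$box / 2, p$activation_radius)
}

#' Strain timecourse of an agent-based trajectory
#'
#' Makes ABM output commensurate with the experimental pipeline: bead
#' displacements since t = 0 are binned onto a regular grid (mean per cell,
#' empty cells infilled by local medians), the areal strain field is the
#' divergence of the binned displacement, and the contraction-positive
#' strain is its negated mean over the activation disc.
#'
#' @param traj An [abm_run()] trajectory (>= 2 snapshots).
#' @param region An [activation_region()]; defaults to the activation disc.
#' @param spacing Binning grid pitch (um).
#' @param t1,t2 Phase boundaries; default to the experimental 100 s / 300 s
#'   windows when the run is long enough, otherwise to the same fractions
#'   (25% / 75%) of the simulated span.
#' @return A [strain_timecourse()].
#' @export
measure_strain <- function(traj, region = NULL, spacing = 1, t1 = NULL, t2 = NULL) {
  if (length(traj$times) < 2) abort("measure_strain needs at least 2 snapshots")
  p <- traj$params
  region <- region %||% default_abm_region(p)
  tmax <- max(traj$times)
  t1 <- t1 %||% (if (tmax > 300) 100 else 0.25 * tmax)
  t2 <- t2 %||% (if (tmax > 300) 300 else 0.75 * tmax)
  disp <- displacement_fields(traj, spacing)
  tc_field <- field_series(disp, spacing = spacing, quiet = TRUE)
  eps <- -region_mean(divergence(tc_field), region)$value
  tc <- tibble(time = traj$times, strain = eps,
               tangential_fraction = NA_real_)
  tc <- structure(tc, region = region,
                  class = c("strain_timecourse", class(tibble())))
  segment_phases(tc, t1 = t1, t2 = t2)
}

# mean bead displacement since t = 0 per grid cell, long format (vx, vy hold
# the displacement components in um)
displacement_fields <- function(traj, spacing) {
  p <- traj$params
  centers <- seq(spacing / 2, p$box - spacing / 2, by = spacing)
  nxy <- length(centers)
  pos0 <- traj$snap_bead[, , 1] / 1000
  ix <- pmin(pmax(floor(pos0[, 1] / spacing), 0), nxy - 1) + 1
  iy <- pmin(pmax(floor(pos0[, 2] / spacing), 0), nxy - 1) + 1
  cell <- (iy - 1L) * nxy + ix
  frames <- purrr::map(seq_along(traj$times), function(k) {
    d <- (traj$snap_bead[, , k] - traj$snap_bead[, , 1]) / 1000
    ux <- tapply(d[, 1], factor(cell, levels = seq_len(nxy^2)), mean)
    uy <- tapply(d[, 2], factor(cell, levels = seq_len(nxy^2)), mean)
    tibble(
      time = traj$times[k],
      x = rep(centers, times = nxy), y = rep(centers, each = nxy),
      vx = as.numeric(ux), vy = as.numeric(uy)
    )
  })
  list_rbind(frames)
}

#' Mean inward boundary velocity of an ABM trajectory
#'
#' Measures the boundary velocity the way the experimental pipeline does:
#' bead velocities between consecutive snapshots are binned onto a regular
#' grid (cell means, median-infilled gaps, i.e. a PIV-like velocity field
#' that weights space uniformly rather than beads), decomposed into the
#' inward radial component, and averaged over the boundary annulus
#' (`|r - xi| <= window/2`) with [boundary_velocity()]; the per-interval
#' values are then averaged over the run.
#'
#' @param traj An [abm_run()] trajectory.
#' @param region Defaults to the activation disc.
#' @param window Annulus width (um).
#' @param spacing Velocity-binning grid pitch (um).
#' @return Mean inward boundary velocity (um/s).
#' @export
abm_boundary_velocity <- function(traj, region = NULL, window = 2.65,
                                  spacing = 1) {
  p <- traj$params
  region <- region %||% default_abm_region(p)
  nt <- length(traj$times)
  if (nt < 2) abort("need at least 2 snapshots")
  centers <- seq(spacing / 2, p$box - spacing / 2, by = spacing)
  nxy <- length(centers)
  per <- purrr::map_dbl(seq_len(nt - 1), function(k) {
    pos <- traj$snap_bead[, , k] / 1000
    dtk <- traj$times[k + 1] - traj$times[k]
    v <- (traj$snap_bead[, , k + 1] - traj$snap_bead[, , k]) / 1000 / dtk
    ix <- pmin(pmax(floor(pos[, 1] / spacing), 0), nxy - 1) + 1
    iy <- pmin(pmax(floor(pos[, 2] / spacing), 0), nxy - 1) + 1
    cell <- factor((iy - 1L) * nxy + ix, levels = seq_len(nxy^2))
    f <- field_series(tibble(
      time = 0,
      x = rep(centers, times = nxy), y = rep(centers, each = nxy),
      vx = as.numeric(tapply(v[, 1], cell, mean)),
      vy = as.numeric(tapply(v[, 2], cell, mean))
    ), spacing = spacing, quiet = TRUE)
    boundary_velocity(f, region, window = window)$v_boundary
  })
  mean(per, na.rm = TRUE)
}

#' Per-segment tension map of a network state
#'
#' Axial tension of every filament segment (positive = stretched), with the
#' segment midpoint, for force-map visualisation and the local-stress
#' comparison between the activation disc and its surroundings.
#'
#' @param state A `network_state`.
#' @param p An [abm_params()] (defaults to the state's own).
#' @return A tibble: `fil`, `seg`, `x`, `y` (um), `tension` (pN).
#' @export
force_map <- function(state, p = state$params) {
  seg_nm <- p$segment_length * 1000
  rows <- purrr::map(seq_along(state$fil_first), function(f) {
    fb <- state$fil_first[f]
    nbf <- state$fil_len[f]
    i1 <- fb:(fb + nbf - 2); i2 <- i1 + 1
    d <- state$bead_pos[i2, , drop = FALSE] - state$bead_pos[i1, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    tibble(
      fil = f, seg = seq_len(nbf - 1),
      x = (state$bead_pos[i1, 1] + state$bead_pos[i2, 1]) / 2000,
      y = (state$bead_pos[i1, 2] + state$bead_pos[i2, 2]) / 2000,
      tension = p$k_seg * (len - seg_nm)
    )
  })
  list_rbind(rows)
}

#' Instantaneous forces on all beads and motor nodes
#'
#' Evaluates the full internal force field (extensional, bending, backbone
#' and motor-arm springs) without advancing time; used for force-balance
#' audits (all internal forces must sum to zero).
#'
#' @param state A `network_state`.
#' @param p An [abm_params()].
#' @return A list with `f_bead`, `f_mot` (pN) and per-segment `tension`.
#' @export
network_forces <- function(state, p = state$params) {
  abm_forces_cpp(state, cpp_params(p))
}

#' One-row summary of an ABM run
#'
#' Final strain, maximum strain rate (largest snapshot-to-snapshot slope)
#' and mean inward boundary velocity, tagged with the run's R_M,
#' persistence length and activation radius.
#'
#' @param traj An [abm_run()] trajectory.
#' @param spacing Strain-binning pitch (um).
#' @return A one-row tibble.
#' @export
abm_summary <- function(traj, spacing = 1) {
  tc <- measure_strain(traj, spacing = spacing)
  rate <- diff(tc$strain) / diff(tc$time)
  tibble(
    eps_final = tc$strain[nrow(tc)],
    max_rate = max(rate),
    v_boundary = abm_boundary_velocity(traj),
    rm = traj$params$rm, lp = traj$params$lp,
    activation_radius = traj$params$activation_radius
  )
}
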