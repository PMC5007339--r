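#' Parameters for the active viscoelastic gel model
#'
#' The disordered actomyosin film is modelled as a homogeneous, isotropic
#' Kelvin-Voigt solid (Young's modulus E, Poisson ratio nu, viscosity eta in
#' parallel) lying on a substrate that exerts friction (coefficient zeta) on
#' the overdamped network. Myosin activity adds an isotropic contractile
#' stress `sigma_a(r, t) = sigma0 * (1 - exp(-t / tau_a))` inside the disc
#' `r <= xi` and zero outside. Defaults are dimensionless (sigma0 = 1 sets
#' the stress scale) with `E / sigma0 = 1`, the regime in which active and
#' elastic stresses are comparable and the model reproduces the experimental
#' contraction dynamics.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio, in \[0, 1).
#' @param eta Viscosity (Pa s).
#' @param zeta Substrate friction coefficient (Pa s / um^2).
#' @param sigma0 Active stress amplitude (Pa), contraction-positive (network
#'   tension).
#' @param tau_a Active stress accumulation timescale (s).
#' @param xi Activation radius (um).
#' @param r_domain Outer radius of the annular computational domain (um),
#'   at least 5 xi (default 10 xi).
#' @param n_grid Number of radial grid intervals (>= 100).
#' @param t_total Simulated time (s).
#' @param dt Time step (s).
#' @param save_dt Interval at which fields are stored (s).
#' @param bc Outer boundary condition: `"clamped"` (u = 0, quiescent far
#'   field) or `"free"` (sigma_rr = 0).
#' @param plane `"stress"` (thin free-standing film, the default) or
#'   `"strain"`; affects only the effective 2D modulus.
#' @return A validated list of class `gel_params`.
#' @export
gel_params <- function(E = 1, nu = 0.3, eta = 10, zeta = 0.03, sigma0 = 1,
                       tau_a = 60, xi = 10, r_domain = 10 * xi,
                       n_grid = 800, t_total = 600, dt = 0.5, save_dt = 2,
                       bc = c("clamped", "free"),
                       plane = c("stress", "strain")) {
  bc <- match.arg(bc)
  plane <- match.arg(plane)
  for (nm in c("E", "eta", "zeta", "sigma0", "tau_a", "xi", "t_total", "dt", "save_dt")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("gel parameter `%s` must be a single positive number", nm))
    }
  }
  if (nu < 0 || nu >= 1) abort("Poisson ratio nu must lie in [0, 1)")
  if (r_domain < 5 * xi) abort("r_domain must be at least 5 * xi")
  if (n_grid < 100) abort("n_grid must be at least 100")
  structure(
    list(E = E, nu = nu, eta = eta, zeta = zeta, sigma0 = sigma0,
         tau_a = tau_a, xi = xi, r_domain = r_domain, n_grid = as.integer(n_grid),
         t_total = t_total, dt = dt, save_dt = save_dt, bc = bc, plane = plane),
    class = "gel_params"
  )
}

# Effective 2D modulus C and Poisson ratio so that
# sigma_rr = C (u' + nu_eff u/r), sigma_tt = C (u/r + nu_eff u').
gel_moduli <- function(p) {
  if (p$plane == "stress") {
    list(C = p$E / (1 - p$nu^2), nu = p$nu)
  } else {
    list(C = p$E * (1 - p$nu) / ((1 + p$nu) * (1 - 2 * p$nu)), nu = p$nu / (1 - p$nu))
  }
}

#' Solve the active gel dynamics
#'
#' Integrates, in radial symmetry, the overdamped force balance
#' `zeta du/dt = d sigma_rr / dr + (sigma_rr - sigma_theta) / r`
#' with the Kelvin-Voigt constitutive law
#' `sigma_rr = C (u' + nu u/r) + eta d/dt (u' + nu u/r) + sigma_a(r, t)` and
#' the analogous hoop stress, C the effective 2D modulus. Because the
#' isotropic active stress cancels from the hoop-difference term, the active
#' forcing reduces to `d sigma_a / dr`, a contractile pull concentrated at
#' the activation boundary that drives inward flow. Displacement is
#' outward-positive internally; the derived strain timecourse is
#' contraction-positive. Time stepping is Crank-Nicolson with a banded
#' direct solve per step (the viscosity couples du/dt into the stress flux,
#' so each step is implicit); u(0) = 0 at the pole, and the outer edge is
#' clamped or stress-free per `p$bc`.
#'
#' The areal strain of the activation disc follows from the divergence
#' theorem: `epsilon(t) = -2 u(xi, t) / xi`.
#'
#' @param p A [gel_params()].
#' @return An object of class `gel_solution`: radial grid `r`, saved `times`,
#'   matrices `u`, `v`, `sigma_rr`, `sigma_tt` (nodes x frames), a
#'   contraction-positive `strain` tibble and an inward-positive
#'   `boundary_velocity` tibble.
#' @export
solve_gel <- function(p) {
  stopifnot(inherits(p, "gel_params"))
  m <- gel_moduli(p)
  N <- p$n_grid
  dr <- p$r_domain / N
  r <- seq(0, p$r_domain, length.out = N + 1)
  free <- p$bc == "free"
  # unknown nodes: 2..N (clamped) or 2..N+1 (free outer edge)
  un <- if (free) 2:(N + 1) else 2:N
  nu_n <- length(un)
  ri <- r[un]

  # Navier operator L[u] = u'' + u'/r - u/r^2 on the unknowns (homogeneous
  # Dirichlet closure at dropped neighbours)
  ii <- integer(0); jj <- integer(0); vv <- double(0)
  for (q in seq_len(nu_n)) {
    i <- un[q]
    if (free && i == N + 1) next  # boundary row handled separately
    cm <- 1 / dr^2 - 1 / (2 * r[i] * dr)
    c0 <- -2 / dr^2 - 1 / r[i]^2
    cp <- 1 / dr^2 + 1 / (2 * r[i] * dr)
    ii <- c(ii, q); jj <- c(jj, q); vv <- c(vv, c0)
    if (i - 1 >= un[1]) { ii <- c(ii, q); jj <- c(jj, q - 1); vv <- c(vv, cm) }
    if (i + 1 <= un[nu_n]) { ii <- c(ii, q); jj <- c(jj, q + 1); vv <- c(vv, cp) }
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nu_n, nu_n))
  I <- Matrix::Diagonal(nu_n)

  A <- p$zeta * I - (p$eta + p$dt * m$C / 2) * L
  B <- p$zeta * I - (p$eta - p$dt * m$C / 2) * L

  # Active body force in conservative (flux) form,
  # f = (1/r) d(r s)/dr - s/r, with s sampled at half nodes so the
  # activation step is centred on r = xi to second order:
  s_prof <- ifelse(r <= p$xi + 1e-12, p$sigma0, 0)
  r_half <- r + dr / 2                              # r_{i+1/2}
  s_half <- ifelse(r_half <= p$xi + 1e-12, p$sigma0, 0)
  grad_s <- numeric(N + 1)
  i <- 2:N
  grad_s[i] <- (r_half[i] * s_half[i] - r_half[i - 1] * s_half[i - 1]) / (r[i] * dr) -
    s_prof[i] / r[i]
  f_base <- grad_s[un]

  if (free) {
    # Robin row at r = R: sigma_rr(R) = 0 with one-sided 2nd-order derivative
    q <- nu_n
    Dcoef <- c(1 / (2 * dr), -4 / (2 * dr), 3 / (2 * dr) + m$nu / p$r_domain)
    rowA <- rowB <- numeric(nu_n)
    rowA[(q - 2):q] <- (m$C + p$eta / p$dt) * Dcoef
    rowB[(q - 2):q] <- (p$eta / p$dt) * Dcoef
    A[q, ] <- rowA
    B[q, ] <- rowB
    f_base[q] <- 0
  }
  A <- methods::as(A, "CsparseMatrix")
  fa <- Matrix::lu(A)

  ramp <- function(t) 1 - exp(-t / p$tau_a)
  # exact mean of the ramp over a step
  ramp_mean <- function(t0, t1) 1 - p$tau_a * (exp(-t0 / p$tau_a) - exp(-t1 / p$tau_a)) / (t1 - t0)

  nsteps <- ceiling(p$t_total / p$dt)
  save_every <- max(1L, as.integer(round(p$save_dt / p$dt)))
  n_save <- floor(nsteps / save_every) + 1L
  U <- matrix(0, N + 1, n_save)
  V <- matrix(0, N + 1, n_save)
  t_save <- numeric(n_save)

  u <- numeric(nu_n)
  u_full <- numeric(N + 1)
  eps_prev <- 0
  ks <- 1L
  for (k in seq_len(nsteps)) {
    t0 <- (k - 1) * p$dt; t1 <- k * p$dt
    rhs <- as.numeric(B %*% u) + p$dt * f_base * ramp_mean(t0, t1)
    u_new <- as.numeric(Matrix::solve(fa, rhs))
    u_full_new <- u_full
    u_full_new[un] <- u_new
    eps <- -2 * approx(r, u_full_new, xout = p$xi)$y / p$xi
    if (abs(eps - eps_prev) > 0.1) {
      abort(sprintf(
        "time-step instability: strain increment %.3g at t = %.3g s exceeds 10%% per step; reduce dt",
        abs(eps - eps_prev), t1
      ))
    }
    v_full <- (u_full_new - u_full) / p$dt
    u_full <- u_full_new
    u <- u_new
    eps_prev <- eps
    if (k %% save_every == 0) {
      ks <- ks + 1L
      U[, ks] <- u_full
      V[, ks] <- v_full
      t_save[ks] <- t1
    }
  }
  U <- U[, 1:ks, drop = FALSE]; V <- V[, 1:ks, drop = FALSE]; t_save <- t_save[1:ks]

  # stresses at saved frames
  Srr <- Stt <- matrix(0, N + 1, ks)
  for (q in seq_len(ks)) {
    st <- gel_stresses(r, U[, q], V[, q], m, p$eta, s_prof * ramp(t_save[q]))
    Srr[, q] <- st$srr; Stt[, q] <- st$stt
  }
  strain <- tibble(time = t_save,
                   strain = -2 * apply(U, 2, function(col) approx(r, col, xout = p$xi)$y) / p$xi)
  vb <- tibble(time = t_save,
               v_boundary = -apply(V, 2, function(col) approx(r, col, xout = p$xi)$y))
  structure(
    list(r = r, times = t_save, u = U, v = V, sigma_rr = Srr, sigma_tt = Stt,
         strain = strain, boundary_velocity = vb, params = p),
    class = "gel_solution"
  )
}

# constitutive stresses from displacement + velocity profiles
gel_stresses <- function(r, u, v, m, eta, s_act) {
  n <- length(r)
  dr <- r[2] - r[1]
  d1 <- function(f) {
    g <- f
    g[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * dr)
    g[1] <- (f[2] - f[1]) / dr
    g[n] <- (f[n] - f[n - 1]) / dr
    g
  }
  up <- d1(u); vp <- d1(v)
  uor <- c(up[1], u[-1] / r[-1])  # u/r -> u'(0) at the pole
  vor <- c(vp[1], v[-1] / r[-1])
  list(
    srr = m$C * (up + m$nu * uor) + eta * (vp + m$nu * vor) + s_act,
    stt = m$C * (uor + m$nu * up) + eta * (vor + m$nu * vp) + s_act
  )
}

#' Closed-form steady state of the disc-inclusion problem
#'
#' The t -> infinity equilibrium of [solve_gel()]: with a constant active
#' stress sigma0 in `r <= xi`, mechanical equilibrium gives `u = A r` inside
#' and `u = B r + Cc / r` outside, the constants fixed by continuity of u and
#' sigma_rr at xi together with the outer boundary condition. For the
#' clamped edge: `B = sigma0 xi^2 / (2 C R^2)`, `Cc = -B R^2`,
#' `A = B (1 - R^2 / xi^2)`. The in-disc areal strain `u' + u/r = 2A` is
#' spatially uniform, sigma_rr is continuous at xi, and the hoop stress
#' jumps by `(1 - nu) sigma0` across the activation boundary. This solution
#' is the solver's analytic oracle.
#'
#' @param p A [gel_params()].
#' @return A tibble with columns `r`, `u`, `sigma_rr`, `sigma_tt`;
#'   attributes `A`, `B`, `Cc` and `eps_ss` (the contraction-positive
#'   steady-state strain -2A).
#' @export
gel_steady_state <- function(p) {
  stopifnot(inherits(p, "gel_params"))
  m <- gel_moduli(p)
  R <- p$r_domain; xi <- p$xi; s0 <- p$sigma0
  if (p$bc == "clamped") {
    B <- s0 * xi^2 / (2 * m$C * R^2)
    Cc <- -B * R^2
    A <- B * (1 - R^2 / xi^2)
  } else {
    Cc <- -s0 * xi^2 / (2 * m$C)
    B <- Cc * (1 - m$nu) / (R^2 * (1 + m$nu))
    A <- B + Cc / xi^2
  }
  r <- seq(0, R, length.out = p$n_grid + 1)
  inside <- r <= xi + 1e-12
  u <- ifelse(inside, A * r, B * r + Cc / pmax(r, 1e-12))
  srr <- ifelse(inside, m$C * (1 + m$nu) * A + s0,
                m$C * ((1 + m$nu) * B - (1 - m$nu) * Cc / pmax(r, 1e-12)^2))
  stt <- ifelse(inside, m$C * (1 + m$nu) * A + s0,
                m$C * ((1 + m$nu) * B + (1 - m$nu) * Cc / pmax(r, 1e-12)^2))
  structure(tibble(r = r, u = u, sigma_rr = srr, sigma_tt = stt),
            A = A, B = B, Cc = Cc, eps_ss = -2 * A,
            class = c("gel_steady_state", class(tibble())))
}

#' @export
glance.gel_solution <- function(x, t1 = 100, t2 = 300, ...) {
  tc <- segment_phases(x$strain, t1 = t1, t2 = t2)
  p3 <- any(tc$phase == "P3")
  tibble(
    xi = x$params$xi,
    stiffness = x$params$E / x$params$sigma0,
    v_max = max(x$boundary_velocity$v_boundary),
    strain_rate = as.numeric(strain_rate(tc)),
    max_rate = max(diff(x$strain$strain) / diff(x$strain$time)),
    eps_max = if (p3) max_strain(tc) else NA_real_
  )
}

#' @export
tidy.gel_solution <- function(x, ...) {
  nt <- length(x$times)
  tibble(
    time = rep(x$times, each = length(x$r)),
    r = rep(x$r, nt),
    u = as.vector(x$u), v = as.vector(x$v),
    sigma_rr = as.vector(x$sigma_rr), sigma_tt = as.vector(x$sigma_tt)
  )
}

#' @export
print.gel_solution <- function(x, ...) {
  cat(sprintf(
    "<gel_solution> xi = %g um, R = %g um, N = %d, t = 0..%g s (%d frames), E/sigma0 = %g\n",
    x$params$xi, x$params$r_domain, x$params$n_grid,
    max(x$times), length(x$times), x$params$E / x$params$sigma0
  ))
  invisible(x)
}

#' Activation-size / stiffness sweep of the gel model
#'
#' Runs [solve_gel()] for every combination of activation radius and
#' stiffness ratio `E / sigma0`, holding the domain ratio `r_domain / xi`
#' and all other parameters fixed, and extracts the telescopic summary
#' metrics: peak inward boundary velocity, the P2-window strain rate, the
#' maximum instantaneous strain rate, and the plateau strain eps_max.
#'
#' @param p Baseline [gel_params()].
#' @param xi Activation radii to sweep (um).
#' @param stiffness Values of E / sigma0.
#' @return A tibble (class `gel_sweep`) with one row per (xi, stiffness):
#'   `xi`, `stiffness`, `v_max`, `strain_rate`, `max_rate`, `eps_max`.
#' @export
sweep_activation <- function(p, xi = c(5, 10, 20, 40), stiffness = 1) {
  if (!length(xi) || !length(stiffness)) abort("xi and stiffness lists must be non-empty")
  ratio <- p$r_domain / p$xi
  grid <- tidyr::expand_grid(xi = xi, stiffness = stiffness)
  res <- purrr::pmap(grid, function(xi, stiffness) {
    pi <- gel_params(
      E = stiffness * p$sigma0, nu = p$nu, eta = p$eta, zeta = p$zeta,
      sigma0 = p$sigma0, tau_a = p$tau_a, xi = xi, r_domain = ratio * xi,
      n_grid = p$n_grid, t_total = p$t_total, dt = p$dt, save_dt = p$save_dt,
      bc = p$bc, plane = p$plane
    )
    glance(solve_gel(pi))
  }) |> list_rbind()
  structure(res, class = c("gel_sweep", class(tibble())))
}

#' Rasterise a gel solution onto a Cartesian PIV-like grid
#'
#' Bridges the continuum model to the field-analysis pipeline: samples the
#' radial velocity v(r, t) (linear interpolation in r and t) onto a square
#' grid centred on the activation zone, at the stated frame interval
#' (default 10 s, the experimental acquisition cadence). Inward flow points
#' toward the origin; nodes beyond the solved domain get zero velocity.
#'
#' @param sol A [gel_solution][solve_gel()].
#' @param spacing Grid pitch h (um).
#' @param interval Frame interval (s).
#' @param extent Half-width of the grid (um); default 2 xi.
#' @return A [field_series()]; the matching [activation_region()] (centred
#'   at the origin) is attached as attribute `region`.
#' @export
export_velocity_field <- function(sol, spacing = 1, interval = 10, extent = NULL) {
  p <- sol$params
  extent <- extent %||% (2 * p$xi)
  xs <- seq(-extent, extent, by = spacing)
  g <- expand.grid(x = xs, y = xs)
  rr <- sqrt(g$x^2 + g$y^2)
  times <- seq(0, max(sol$times), by = interval)
  frames <- purrr::map(times, function(t) {
    # linear interpolation between saved frames
    kk <- findInterval(t, sol$times, rightmost.closed = TRUE)
    kk <- max(1, min(kk, length(sol$times) - 1))
    w <- (t - sol$times[kk]) / (sol$times[kk + 1] - sol$times[kk])
    w <- max(0, min(1, w))
    vr_prof <- (1 - w) * sol$v[, kk] + w * sol$v[, kk + 1]
    v_at <- approx(sol$r, vr_prof, xout = rr, rule = 1)$y
    v_at[is.na(v_at)] <- 0
    dir_x <- ifelse(rr > 0, g$x / rr, 0)
    dir_y <- ifelse(rr > 0, g$y / rr, 0)
    tibble(time = t, x = g$x, y = g$y, vx = v_at * dir_x, vy = v_at * dir_y)
  })
  f <- field_series(list_rbind(frames), spacing = spacing, quiet = TRUE)
  attr(f, "region") <- activation_region(0, 0, p$xi)
  f
}
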