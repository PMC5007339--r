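#' Generate a synthetic PIV velocity-field series
#'
#' Emulates the statistical structure of PIV output from a light-activated
#' contraction experiment: a scenario velocity field sampled on a regular
#' grid at a fixed frame interval (default 10 s), i.i.d. Gaussian
#' measurement noise added per component, and a configurable fraction of
#' vectors dropped (NA) to emulate rejected PIV correlations, which
#' exercises the gap-infilling path. Scenarios:
#'
#' * `"gel"` — rasterised radial flow from a [solve_gel()] solution (pass
#'   `sol`); the realistic end-to-end input.
#' * `"sink"` — uniform inward speed `v = -a r_hat` (v_r = +a everywhere).
#' * `"rotation"` — rigid rotation `v = omega r theta_hat` (v_r = 0).
#' * `"mixed"` — sum of the sink and rotation fields.
#'
#' All generators are pure functions of their arguments and `seed`.
#'
#' @param scenario One of `"gel"`, `"sink"`, `"rotation"`, `"mixed"`.
#' @param sol A `gel_solution` (required for `scenario = "gel"`).
#' @param spacing Grid pitch (um).
#' @param interval Frame interval (s).
#' @param n_frames Number of frames (ignored for `"gel"`, which covers the
#'   solved time span).
#' @param extent Half-width of the grid (um).
#' @param a Inward speed of the sink scenario (um/s).
#' @param omega Angular velocity of the rotation scenario (1/s).
#' @param noise_sd Gaussian measurement noise per velocity component (um/s).
#' @param gap_frac Fraction of vectors dropped and re-infilled.
#' @param seed Integer seed; same seed, same series.
#' @return A [field_series()] with attribute `region` (the activation
#'   region of the gel solution, or a disc of radius `extent / 2` for the
#'   analytic scenarios).
#' @export
gen_piv_series <- function(scenario = c("gel", "sink", "rotation", "mixed"),
                           sol = NULL, spacing = 1, interval = 10,
                           n_frames = 40, extent = 20,
                           a = 0.01, omega = 0.002,
                           noise_sd = 0.002, gap_frac = 0.05, seed = 1) {
  scenario <- match.arg(scenario)
  if (noise_sd < 0 || gap_frac < 0 || gap_frac >= 1) {
    abort("noise_sd must be >= 0 and gap_frac in [0, 1)")
  }
  if (scenario == "gel") {
    if (is.null(sol)) abort("scenario 'gel' needs a gel_solution in `sol`")
    clean <- export_velocity_field(sol, spacing = spacing, interval = interval)
    region <- attr(clean, "region")
  } else {
    xs <- seq(-extent, extent, by = spacing)
    g <- expand.grid(x = xs, y = xs)
    rr <- sqrt(g$x^2 + g$y^2)
    rx <- ifelse(rr > 0, g$x / rr, 0); ry <- ifelse(rr > 0, g$y / rr, 0)
    vx <- vy <- rep(0, nrow(g))
    if (scenario %in% c("sink", "mixed")) { vx <- vx - a * rx; vy <- vy - a * ry }
    if (scenario %in% c("rotation", "mixed")) {
      vx <- vx - omega * rr * ry; vy <- vy + omega * rr * rx
    }
    times <- (seq_len(n_frames) - 1) * interval
    df <- tibble(
      time = rep(times, each = nrow(g)),
      x = rep(g$x, n_frames), y = rep(g$y, n_frames),
      vx = rep(vx, n_frames), vy = rep(vy, n_frames)
    )
    clean <- field_series(df, spacing = spacing, quiet = TRUE)
    region <- activation_region(0, 0, extent / 2)
  }
  if (noise_sd == 0 && gap_frac == 0) {
    attr(clean, "region") <- region
    return(clean)
  }
  df <- with_seed(seed, {
    n <- nrow(clean)
    df <- as_tibble(clean)[, c("time", "x", "y", "vx", "vy")]
    df$vx <- df$vx + rnorm(n, 0, noise_sd)
    df$vy <- df$vy + rnorm(n, 0, noise_sd)
    if (gap_frac > 0) {
      drop <- runif(n) < gap_frac
      df$vx[drop] <- NA_real_
      df$vy[drop] <- NA_real_
      # keep at least one valid vector per frame so infilling is defined
      for (t in unique(df$time)) {
        sel <- df$time == t
        if (all(is.na(df$vx[sel]))) {
          first <- which(sel)[1]
          df$vx[first] <- 0; df$vy[first] <- 0
        }
      }
    }
    df
  })
  out <- field_series(df, spacing = attr(clean, "spacing"), quiet = TRUE)
  attr(out, "region") <- region
  out
}

#' Generate a synthetic maximum-strain vs density dataset
#'
#' Draws densities uniformly on \[0.2, 1.2\] per um^2 (bracketing the
#' critical density and the experimental low/medium/high conditions),
#' evaluates the Hill curve, and applies multiplicative lognormal noise
#' (strain magnitudes span an order of magnitude across the transition, so
#' additive noise would distort the sub-critical branch). The default curve
#' parameters are the fitted experimental values rho_half = 0.56 per um^2
#' and n = 11, with saturation strain 1.4 (a generator choice consistent
#' with eps_max > 1 above the critical density).
#'
#' @param n Number of points (>= 5).
#' @param eps_sat,rho_half,n_hill Hill-curve parameters.
#' @param noise Multiplicative noise level as a coefficient of variation
#'   (0.05 = 5%); lognormal with `sdlog = sqrt(log(1 + noise^2))`.
#' @param rho_range Density range sampled (1/um^2).
#' @param seed Integer seed.
#' @return A tibble with columns `rho` (1/um^2) and `eps_max`.
#' @export
gen_hill_dataset <- function(n = 50, eps_sat = 1.4, rho_half = 0.56, n_hill = 11,
                             noise = 0.05, rho_range = c(0.2, 1.2), seed = 1) {
  if (n < 5) abort("gen_hill_dataset needs n >= 5")
  with_seed(seed, {
    rho <- sort(runif(n, rho_range[1], rho_range[2]))
    eps <- hill(rho, eps_sat, rho_half, n_hill)
    if (noise > 0) {
      sdlog <- sqrt(log(1 + noise^2))
      eps <- eps * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    tibble(rho = rho, eps_max = eps)
  })
}

#' Generate a disordered filament set (lengths + orientations)
#'
#' Contour lengths are drawn from a truncated exponential distribution whose
#' rate is solved (numerically) so that the *truncated* mean equals the
#' requested mean; orientations are uniform on \[0, pi), i.e. apolar and
#' fully disordered (nematic order ~ 0 at large n).
#'
#' @param n Number of filaments (>= 1).
#' @param mean_length Mean contour length (um; default 7.1).
#' @param trunc Truncation bounds (um; default c(0.56, 25)).
#' @param seed Integer seed.
#' @return A tibble with columns `length` (um) and `theta` (rad in
#'   \[0, pi)).
#' @export
gen_filament_set <- function(n, mean_length = 7.1, trunc = c(0.56, 25), seed = 1) {
  if (n < 1) abort("need at least one filament")
  lambda <- trunc_exp_rate(mean_length, trunc[1], trunc[2])
  with_seed(seed, {
    # inverse-CDF sampling of the truncated exponential
    u <- runif(n)
    Fa <- 1 - exp(-lambda * trunc[1]); Fb <- 1 - exp(-lambda * trunc[2])
    len <- -log(1 - (Fa + u * (Fb - Fa))) / lambda
    tibble(length = len, theta = runif(n, 0, pi))
  })
}

# rate of an exponential truncated to [a, b] with the given mean
trunc_exp_rate <- function(target_mean, a, b) {
  if (target_mean <= a || target_mean >= b) {
    abort("mean must lie inside the truncation bounds")
  }
  mean_fun <- function(lam) {
    ea <- exp(-lam * a); eb <- exp(-lam * b)
    1 / lam + (a * ea - b * eb) / (ea - eb)
  }
  uniroot(function(l) mean_fun(l) - target_mean,
          interval = c(1e-6, 100), tol = 1e-12)$root
}

#' 2D nematic order parameter of a set of orientations
#'
#' `q = sqrt(<cos 2 theta>^2 + <sin 2 theta>^2)`, the apolar orientational
#' order of a filament population: 1 for perfect alignment, ~1/sqrt(n) for
#' fully disordered orientations, and invariant under theta -> theta + pi.
#'
#' @param theta Orientations in radians (>= 2 values).
#' @return q in \[0, 1\].
#' @export
nematic_order <- function(theta) {
  if (length(theta) < 2) abort("nematic_order needs at least 2 orientations")
  sqrt(mean(cos(2 * theta))^2 + mean(sin(2 * theta))^2)
}
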