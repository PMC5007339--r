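#' Strain timecourse of the activation region
#'
#' Integrates the velocity field over time (cumulative trapezoidal rule) to
#' obtain the displacement field, takes its divergence, and averages over the
#' activation disc. Strain is reported **contraction-positive**:
#' `epsilon(t) = -<div u(t)>_disc`, so inward flow gives a rising strain
#' curve, `epsilon(0) = 0`, and strains may exceed 1 as material flows into
#' the region. Two audit quantities are attached per frame: the region-mean
#' tangential flow fraction `|v_t| / (|v_r| + |v_t|)` (large in the lag phase
#' P1, which is excluded from rate estimates for that reason) and, as an
#' attribute, the maximum discrepancy between this estimate and the
#' time-integral of the divergence of velocity (the two commute on a uniform
#' grid with central differences; the gap is a numerical self-check).
#'
#' @param field A [field_series()] with at least 2 frames.
#' @param region An [activation_region()].
#' @param t1,t2 Phase boundaries (s) passed to [segment_phases()].
#' @return A tibble of class `strain_timecourse` with columns `time`,
#'   `strain`, `tangential_fraction` and `phase`; attributes `t1`, `t2`,
#'   `region`, `commute_gap`.
#' @export
strain_timecourse <- function(field, region, t1 = 100, t2 = 300) {
  arr <- field_arrays(field)
  nt <- length(arr$times)
  if (nt < 2) abort("strain_timecourse needs at least 2 frames")
  ux <- array(0, dim = dim(arr$vx))
  uy <- array(0, dim = dim(arr$vy))
  for (k in 2:nt) {
    dt <- arr$times[k] - arr$times[k - 1]
    ux[, , k] <- ux[, , k - 1] + dt * (arr$vx[, , k] + arr$vx[, , k - 1]) / 2
    uy[, , k] <- uy[, , k - 1] + dt * (arr$vy[, , k] + arr$vy[, , k - 1]) / 2
  }
  div_u <- array(0, dim = dim(ux))
  for (k in seq_len(nt)) {
    div_u[, , k] <- diff_x(ux[, , k], arr$h) + diff_y(uy[, , k], arr$h)
  }
  eps <- -region_mean(scalar_from_arrays(arr, div_u, "divergence of displacement"), region)$value

  # self-check: time-integral of region-mean strain rate must agree
  rate <- region_mean(divergence(field), region)$value
  eps_alt <- -cumtrapz(arr$times, rate)
  commute_gap <- max(abs(eps - eps_alt))

  dec <- decompose_radial(field, region)
  absr <- dec$v_r; absr$value <- abs(absr$value)
  abst <- dec$v_t; abst$value <- abs(abst$value)
  mr <- region_mean(absr, region)$value
  mt <- region_mean(abst, region)$value
  tf <- ifelse(mr + mt > 0, mt / (mr + mt), 0)

  tc <- tibble(time = arr$times, strain = eps, tangential_fraction = tf)
  tc <- structure(tc, region = region, commute_gap = commute_gap,
                  class = c("strain_timecourse", class(tibble())))
  segment_phases(tc, t1 = t1, t2 = t2)
}

cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

#' Segment a strain timecourse into lag/linear/plateau phases
#'
#' Labels each sample P1 (`0 <= t < t1`, lag phase with significant
#' tangential flow), P2 (`t1 <= t <= t2`, linear condensation phase) or P3
#' (`t > t2`, plateau). Defaults follow the experimental windows t1 = 100 s,
#' t2 = 300 s. A warning is emitted when the series ends before t2 (empty
#' P3).
#'
#' @param tc A `strain_timecourse` (or any tibble with a `time` column).
#' @param t1,t2 Phase boundaries in s, `t1 < t2`.
#' @return `tc` with a `phase` factor column and attributes `t1`, `t2`.
#' @export
segment_phases <- function(tc, t1 = 100, t2 = 300) {
  if (!is.numeric(t1) || !is.numeric(t2) || t1 >= t2) {
    abort("phase boundaries must satisfy t1 < t2")
  }
  if (max(tc$time) <= t1) abort("series must extend beyond t1 to segment phases")
  phase <- factor(
    ifelse(tc$time < t1, "P1", ifelse(tc$time <= t2, "P2", "P3")),
    levels = c("P1", "P2", "P3")
  )
  tc$phase <- phase
  if (!any(phase == "P3")) {
    warn("series ends before t2: plateau phase P3 is empty (max_strain unavailable)")
  }
  attr(tc, "t1") <- t1
  attr(tc, "t2") <- t2
  if (!inherits(tc, "strain_timecourse")) {
    class(tc) <- c("strain_timecourse", class(tibble()))
  }
  tc
}

#' Contractile strain rate (slope of the linear phase)
#'
#' Ordinary least-squares slope of strain versus time restricted to P2,
#' the definition used for all rate comparisons. Requires at least 3 P2
#' samples.
#'
#' @param tc A [strain_timecourse()].
#' @return Strain rate in 1/s, with the OLS standard error as attribute
#'   `se`.
#' @export
strain_rate <- function(tc) {
  p2 <- tc[tc$phase == "P2", ]
  if (nrow(p2) < 3) abort("strain_rate needs at least 3 samples in P2")
  fit <- lm(strain ~ time, data = p2)
  structure(unname(coef(fit)[2]), se = summary(fit)$coefficients[2, 2])
}

#' Maximum strain (plateau value)
#'
#' Mean strain over the plateau phase P3, the maximum-strain summary
#' epsilon_max.
#'
#' @param tc A [strain_timecourse()].
#' @return epsilon_max (dimensionless).
#' @export
max_strain <- function(tc) {
  p3 <- tc[tc$phase == "P3", ]
  if (nrow(p3) == 0) {
    abort("P3 is empty: acquire a longer series (or lower t2) before taking epsilon_max")
  }
  mean(p3$strain)
}

#' One-row contraction summary for a field series
#'
#' Convenience wrapper producing the per-condition scalars: P2 strain rate,
#' epsilon_max, peak boundary velocity, the activation radius and (when
#' supplied) the myosin thick-filament density.
#'
#' @param field A [field_series()].
#' @param region An [activation_region()].
#' @param rho Optional myosin thick-filament density (1/um^2).
#' @param t1,t2 Phase boundaries (s).
#' @param window Boundary-velocity annulus width (um).
#' @return A one-row tibble: `strain_rate`, `eps_max`, `v_boundary_peak`,
#'   `xi`, `rho`.
#' @export
contraction_summary <- function(field, region, rho = NA_real_,
                                t1 = 100, t2 = 300, window = 2.65) {
  tc <- strain_timecourse(field, region, t1 = t1, t2 = t2)
  vb <- boundary_velocity(field, region, window = window)
  tibble(
    strain_rate = as.numeric(strain_rate(tc)),
    eps_max = max_strain(tc),
    v_boundary_peak = max(vb$v_boundary),
    xi = region$radius,
    rho = rho
  )
}

#' @export
glance.strain_timecourse <- function(x, ...) {
  tibble(
    strain_rate = as.numeric(strain_rate(x)),
    eps_max = if (any(x$phase == "P3")) max_strain(x) else NA_real_,
    n_frames = nrow(x),
    t1 = attr(x, "t1"), t2 = attr(x, "t2"),
    commute_gap = attr(x, "commute_gap") %||% NA_real_
  )
}
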