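#' Radial stress profile from force balance
#'
#' Reconstructs the radial distribution of network stress from the inward
#' radial velocity profile, assuming (i) overdamped dynamics with frictional
#' coupling of coefficient zeta to the substrate and (ii) radially symmetric
#' deformation with isotropic in-plane stress (sigma_rr ~ sigma_theta,
#' the minimal closure that makes the 1D force balance integrable from v_r
#' alone). Under these assumptions d sigma / d r = -zeta v_r(r) (with v_r
#' inward-positive), so
#' `sigma(r) = zeta * integral_r^R_out v_r(r') dr'` (trapezoidal), which is
#' zero at the outer radius by construction and, for inward flow, peaks at
#' the centre and decays outward. No elastic or viscous moduli enter.
#'
#' @param profile A [radial_profile()] of inward-positive v_r (may contain
#'   several frames; each is inverted separately).
#' @param zeta Friction coefficient (> 0). The default 1 reports stress in
#'   friction-normalised units of zeta um^2/s.
#' @param r_out Outer radius where stress vanishes; defaults to the largest
#'   sampled (non-empty) bin centre, since stress extends into the passive
#'   medium beyond the activation disc.
#' @return A tibble of class `stress_profile` with columns `time`, `r`,
#'   `sigma`; attributes `zeta`, `r_out`.
#' @export
radial_stress <- function(profile, zeta = 1, r_out = NULL) {
  if (!is.numeric(zeta) || length(zeta) != 1 || zeta <= 0) {
    abort("friction coefficient zeta must be a single positive number")
  }
  if (!"time" %in% names(profile)) profile$time <- 0
  res <- profile |>
    as_tibble() |>
    group_by(.data$time) |>
    group_modify(function(d, key) invert_one_profile(d, zeta, r_out)) |>
    ungroup()
  structure(res, zeta = zeta, r_out = r_out,
            class = c("stress_profile", class(tibble())))
}

invert_one_profile <- function(d, zeta, r_out) {
  d <- arrange(d, .data$r)
  last_ok <- max(which(d$n > 0))
  if (is.null(r_out)) r_out <- d$r[last_ok]
  d <- d[d$r <= r_out + 1e-9, ]
  if (any(d$n == 0)) {
    abort("radial profile has empty interior bins; refine bin_width or infill first")
  }
  r <- d$r; v <- d$mean
  n <- length(r)
  # trapezoidal tail integral from each bin centre to r_out
  seg <- diff(r) * (v[-1] + v[-n]) / 2
  sigma <- zeta * rev(c(0, cumsum(rev(seg))))
  tibble(r = r, sigma = sigma)
}

#' Radial-symmetry applicability check for stress inference
#'
#' The force-balance inversion assumes tangential flow is negligible. This
#' check computes, per frame, the region-mean tangential flow fraction
#' `|v_t| / (|v_r| + |v_t|)` and flags frames where it exceeds the threshold
#' (default 0.25). Experimentally the assumption holds once the flow has
#' become pronounced at the boundary (roughly 60-300 s after activation) and
#' fails in the early lag phase.
#'
#' @param field A [field_series()].
#' @param region An [activation_region()].
#' @param threshold Maximum admissible tangential fraction.
#' @return A tibble of class `applicability_report` with columns `time`,
#'   `tangential_fraction`, `ok`; attribute `pass` (all frames ok).
#' @export
applicability_check <- function(field, region, threshold = 0.25) {
  dec <- decompose_radial(field, region)
  ar <- dec$v_r; ar$value <- abs(ar$value)
  at <- dec$v_t; at$value <- abs(at$value)
  mr <- region_mean(ar, region)
  mt <- region_mean(at, region)
  tf <- ifelse(mr$value + mt$value > 0, mt$value / (mr$value + mt$value), 0)
  rep <- tibble(time = mr$time, tangential_fraction = tf, ok = tf < threshold)
  structure(rep, pass = all(rep$ok), threshold = threshold,
            class = c("applicability_report", class(tibble())))
}

#' @export
print.applicability_report <- function(x, ...) {
  cat(sprintf("<applicability_report> radial-symmetry check (threshold %g): %s\n",
              attr(x, "threshold"),
              if (attr(x, "pass")) "all frames admissible" else "some frames inadmissible"))
  bad <- x$time[!x$ok]
  if (length(bad)) {
    cat("  offending frames (t, s): ", paste(signif(bad, 4), collapse = ", "), "\n")
  }
  NextMethod()
}
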