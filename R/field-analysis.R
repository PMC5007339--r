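#' Divergence of a velocity-field series
#'
#' Computes the 2D divergence dvx/dx + dvy/dy per frame by second-order
#' central differences in the grid interior and one-sided differences at the
#' edges. For a velocity field the divergence is the local areal strain rate
#' (1/s); applied to a displacement field it gives the local areal strain.
#'
#' @param field A [field_series()].
#' @return A [scalar_field_series()] (units 1/s for velocity input).
#' @export
divergence <- function(field) {
  arr <- field_arrays(field)
  if (length(arr$xs) < 3 || length(arr$ys) < 3) {
    abort("divergence needs a grid of at least 3 x 3 nodes")
  }
  out <- array(0, dim = dim(arr$vx))
  for (k in seq_along(arr$times)) {
    out[, , k] <- diff_x(arr$vx[, , k], arr$h) + diff_y(arr$vy[, , k], arr$h)
  }
  scalar_from_arrays(arr, out, label = "divergence (1/s)")
}

# d/dx along the first (x) dimension; central interior, one-sided edges.
diff_x <- function(m, h) {
  n <- nrow(m)
  d <- m
  d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
  d[1, ] <- (m[2, ] - m[1, ]) / h
  d[n, ] <- (m[n, ] - m[n - 1, ]) / h
  d
}

diff_y <- function(m, h) t(diff_x(t(m), h))

#' Radial/tangential decomposition about the activation centre
#'
#' Projects each velocity vector onto the local radial and azimuthal unit
#' vectors of the activation region. Following the experimental convention
#' for contracting networks, the radial component `v_r` is
#' **inward-positive**: motion toward the centre gives v_r > 0. The
#' tangential component `v_t` is the signed counterclockwise azimuthal
#' component. At nodes closer to the centre than half a grid spacing the
#' direction is singular and both components are set to 0.
#'
#' @param field A [field_series()].
#' @param region An [activation_region()] (its centre defines the pole).
#' @return A list with elements `v_r` and `v_t`, each a
#'   [scalar_field_series()] in um/s.
#' @export
decompose_radial <- function(field, region) {
  r <- node_radii(field, region)
  dx <- field$x - region$x
  dy <- field$y - region$y
  h <- attr(field, "spacing")
  core <- r < h / 2
  rs <- ifelse(core, 1, r)   # avoid 0/0; core values overwritten below
  v_r <- -(field$vx * dx + field$vy * dy) / rs
  v_t <- (-field$vx * dy + field$vy * dx) / rs
  v_r[core] <- 0
  v_t[core] <- 0
  base <- field[, c("time", "x", "y")]
  list(
    v_r = scalar_field_series(tibble(base, value = v_r), spacing = h,
                              label = "radial velocity, inward-positive (um/s)"),
    v_t = scalar_field_series(tibble(base, value = v_t), spacing = h,
                              label = "tangential velocity (um/s)")
  )
}

#' Radial profile of a scalar field
#'
#' Bins grid nodes into contiguous annuli about the activation centre
#' (bins `[0, w), [w, 2w), ...` out to the most distant node) and reports the
#' per-bin mean and node count per frame. Empty bins are kept with `n = 0`
#' and `mean = NA`, never silently zeroed.
#'
#' @param field A [scalar_field_series()].
#' @param region An [activation_region()].
#' @param bin_width Annulus width in um (> 0).
#' @return A tibble of class `radial_profile` with columns `time`, `r`
#'   (bin centre, um), `mean`, `n`; attribute `bin_width`.
#' @export
radial_profile <- function(field, region, bin_width) {
  if (!is.numeric(bin_width) || bin_width <= 0) abort("bin_width must be positive")
  r <- node_radii(field, region)
  nb <- ceiling((max(r) + 1e-9) / bin_width)
  bin <- pmin(floor(r / bin_width), nb - 1) + 1L
  out <- field |>
    mutate(.bin = bin) |>
    group_by(.data$time, .data$.bin) |>
    summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(time = attr(field, "times"), .bin = seq_len(nb),
                    fill = list(n = 0L)) |>
    mutate(r = (.data$.bin - 0.5) * bin_width) |>
    select("time", "r", "mean", "n") |>
    arrange(.data$time, .data$r)
  structure(out, bin_width = bin_width, region = region,
            class = c("radial_profile", class(tibble())))
}

#' Mean inward velocity at the activation boundary
#'
#' Averages the inward radial velocity over the annulus of the stated width
#' centred on the activation circumference (`r` in
#' `[xi - window/2, xi + window/2]`), per frame. The default window is
#' 2.65 um.
#'
#' @param field A [field_series()] (decomposed internally) or a
#'   [scalar_field_series()] already holding inward-positive v_r.
#' @param region An [activation_region()].
#' @param window Annulus width in um.
#' @return A tibble with columns `time` and `v_boundary` (um/s,
#'   inward-positive).
#' @export
boundary_velocity <- function(field, region, window = 2.65) {
  if (!is.numeric(window) || window <= 0) abort("window must be positive")
  v_r <- if (inherits(field, "field_series")) decompose_radial(field, region)$v_r else field
  if (!inherits(v_r, "scalar_field_series")) {
    abort("field must be a field_series or a scalar_field_series of v_r")
  }
  r <- node_radii(v_r, region)
  sel <- abs(r - region$radius) <= window / 2
  if (!any(sel)) {
    abort(sprintf(
      "no grid nodes in the boundary annulus [%.3g, %.3g] um (xi = %g, window = %g)",
      region$radius - window / 2, region$radius + window / 2, region$radius, window
    ))
  }
  v_r[sel, ] |>
    group_by(.data$time) |>
    summarise(v_boundary = mean(.data$value), .groups = "drop")
}

#' Mean of a scalar field over the activation disc
#'
#' Arithmetic mean over all grid nodes with r <= xi, per frame (the
#' "averaged over the activation area" reduction used for divergence and
#' strain).
#'
#' @param field A [scalar_field_series()].
#' @param region An [activation_region()].
#' @return A tibble with columns `time` and `value`.
#' @export
region_mean <- function(field, region) {
  r <- node_radii(field, region)
  sel <- r <= region$radius
  if (!any(sel)) abort("no grid nodes inside the activation disc")
  field[sel, ] |>
    group_by(.data$time) |>
    summarise(value = mean(.data$value), .groups = "drop")
}
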