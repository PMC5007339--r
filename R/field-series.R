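#' Velocity-field time series on a regular grid
#'
#' `field_series()` validates and canonicalises a time series of 2D velocity
#' fields, the universal input of the analysis chain (typically PIV output).
#' The data must contain one row per grid node per frame with columns `time`
#' (s), `x`, `y` (um) and the velocity components `vx`, `vy` (um/s). Missing
#' vectors (`NA`, the usual signature of rejected PIV correlations) are
#' flagged in a `gap` column and infilled by the local median of valid
#' neighbours before any differentiation, and the per-frame gap fraction is
#' reported.
#'
#' @param data A data frame with columns `time`, `x`, `y`, `vx`, `vy`.
#' @param spacing Grid spacing h in um. If `NULL`, inferred from the node
#'   coordinates (must be uniform and equal in x and y).
#' @param quiet Suppress the gap-fraction message.
#'
#' @return A tibble of class `field_series`, ordered by (time, y, x), with a
#'   logical `gap` column and attributes `spacing`, `nx`, `ny`, `times`.
#' @examples
#' g <- expand.grid(x = 0:10, y = 0:10)
#' f <- field_series(data.frame(time = 0, g, vx = -0.01 * g$x, vy = -0.01 * g$y))
#' divergence(f)
#' @export
field_series <- function(data, spacing = NULL, quiet = FALSE) {
  df <- as_tibble(data)
  need <- c("time", "x", "y", "vx", "vy")
  if (!all(need %in% names(df))) {
    abort(paste0("field_series data needs columns: ", paste(need, collapse = ", ")))
  }
  df <- arrange(df, .data$time, .data$y, .data$x)
  grid <- check_grid(df, spacing)
  nx <- grid$nx; ny <- grid$ny
  times <- grid$times
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  gap <- !complete.cases(df[, c("vx", "vy")])
  df$gap <- gap
  if (any(gap)) {
    per_frame <- tapply(gap, df$time, mean)
    if (!quiet) {
      inform(sprintf(
        "infilled %d missing vectors (gap fraction per frame: %s)",
        sum(gap), paste(sprintf("%.1f%%", 100 * per_frame), collapse = ", ")
      ))
    }
    for (comp in c("vx", "vy")) {
      arr <- array(df[[comp]], dim = c(nx, ny, length(times)))
      for (k in seq_along(times)) arr[, , k] <- infill_matrix(arr[, , k, drop = TRUE])
      df[[comp]] <- as.vector(arr)
    }
  }
  if (!all(is.finite(df$vx)) || !all(is.finite(df$vy))) {
    abort("non-finite velocities remain after infilling (a frame may be entirely missing)")
  }
  new_field_series(df, grid$spacing, nx, ny, times)
}

new_field_series <- function(df, spacing, nx, ny, times) {
  structure(df,
    spacing = spacing, nx = nx, ny = ny, times = times,
    class = c("field_series", class(tibble())))
}

#' Scalar-field time series on a regular grid
#'
#' Container for per-node scalar quantities derived from a [field_series()]
#' (divergence in 1/s, radial/tangential velocity components in um/s,
#' displacement components in um, strain fields). Shares the grid layout and
#' conventions of `field_series`.
#'
#' @param data A data frame with columns `time`, `x`, `y`, `value`.
#' @param spacing Grid spacing in um (inferred when `NULL`).
#' @param label Optional unit/meaning label carried as an attribute.
#' @return A tibble of class `scalar_field_series`.
#' @export
scalar_field_series <- function(data, spacing = NULL, label = NULL) {
  df <- as_tibble(data)
  need <- c("time", "x", "y", "value")
  if (!all(need %in% names(df))) {
    abort(paste0("scalar_field_series data needs columns: ", paste(need, collapse = ", ")))
  }
  df <- arrange(df, .data$time, .data$y, .data$x)
  grid <- check_grid(df, spacing)
  structure(df,
    spacing = grid$spacing, nx = grid$nx, ny = grid$ny, times = grid$times,
    label = label,
    class = c("scalar_field_series", class(tibble())))
}

# Checks that every frame covers the same full regular grid; returns geometry.
check_grid <- function(df, spacing = NULL) {
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  times <- sort(unique(df$time))
  nx <- length(xs); ny <- length(ys)
  if (nrow(df) != nx * ny * length(times)) {
    abort("data does not cover a full regular grid at every frame")
  }
  hx <- unique(round(diff(xs), 9)); hy <- unique(round(diff(ys), 9))
  if (length(hx) > 1 || length(hy) > 1 || (nx > 1 && ny > 1 && !isTRUE(all.equal(hx, hy)))) {
    abort("grid spacing must be uniform and equal in x and y")
  }
  h <- if (nx > 1) hx[1] else if (ny > 1) hy[1] else spacing %||% 1
  if (!is.null(spacing)) {
    if (!isTRUE(all.equal(spacing, h))) abort("supplied spacing disagrees with node coordinates")
    h <- spacing
  }
  if (h <= 0) abort("grid spacing must be positive")
  list(xs = xs, ys = ys, times = times, nx = nx, ny = ny, spacing = h)
}

# Iterative local-median infill of NA nodes (8-neighbourhood of valid nodes).
infill_matrix <- function(m) {
  while (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    filled_any <- FALSE
    repl <- rep(NA_real_, nrow(idx))
    for (q in seq_len(nrow(idx))) {
      i <- idx[q, 1]; j <- idx[q, 2]
      ii <- max(1, i - 1):min(nrow(m), i + 1)
      jj <- max(1, j - 1):min(ncol(m), j + 1)
      nb <- m[ii, jj]
      nb <- nb[!is.na(nb)]
      if (length(nb)) { repl[q] <- median(nb); filled_any <- TRUE }
    }
    if (!filled_any) abort("cannot infill: a frame has no valid vectors")
    m[idx[!is.na(repl), , drop = FALSE]] <- repl[!is.na(repl)]
  }
  m
}

# --- array views ------------------------------------------------------------

field_arrays <- function(f) {
  stopifnot(inherits(f, "field_series"))
  nx <- attr(f, "nx"); ny <- attr(f, "ny"); times <- attr(f, "times")
  list(
    times = times,
    xs = sort(unique(f$x)), ys = sort(unique(f$y)),
    h = attr(f, "spacing"),
    vx = array(f$vx, dim = c(nx, ny, length(times))),
    vy = array(f$vy, dim = c(nx, ny, length(times)))
  )
}

scalar_arrays <- function(s) {
  stopifnot(inherits(s, "scalar_field_series"))
  nx <- attr(s, "nx"); ny <- attr(s, "ny"); times <- attr(s, "times")
  list(
    times = times,
    xs = sort(unique(s$x)), ys = sort(unique(s$y)),
    h = attr(s, "spacing"),
    v = array(s$value, dim = c(nx, ny, length(times)))
  )
}

scalar_from_arrays <- function(arr, values, label = NULL) {
  grid <- expand.grid(x = arr$xs, y = arr$ys)
  df <- tibble(
    time = rep(arr$times, each = nrow(grid)),
    x = rep(grid$x, times = length(arr$times)),
    y = rep(grid$y, times = length(arr$times)),
    value = as.vector(values)
  )
  scalar_field_series(df, spacing = arr$h, label = label)
}

#' Circular myosin activation region
#'
#' The disc (radius xi) in which light de-inhibits myosin; the geometric
#' reference for all radial decompositions, profiles and region averages.
#'
#' @param x,y Centre coordinates (um).
#' @param radius Radius xi (um), > 0.
#' @return An object of class `activation_region`.
#' @export
activation_region <- function(x = 0, y = 0, radius) {
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) || radius <= 0) {
    abort("activation radius must be a single positive number")
  }
  structure(list(x = x, y = y, radius = radius), class = "activation_region")
}

#' @export
print.activation_region <- function(x, ...) {
  cat(sprintf("<activation_region> centre (%g, %g) um, radius %g um\n", x$x, x$y, x$radius))
  invisible(x)
}

# Warn if the disc is clipped by the grid; returns node distances to centre.
node_radii <- function(obj, region) {
  xs <- range(obj$x); ys <- range(obj$y)
  if (region$x < xs[1] || region$x > xs[2] || region$y < ys[1] || region$y > ys[2]) {
    abort("activation centre lies outside the grid")
  }
  if (region$x - region$radius < xs[1] || region$x + region$radius > xs[2] ||
      region$y - region$radius < ys[1] || region$y + region$radius > ys[2]) {
    warn("activation disc is clipped by the grid extent")
  }
  sqrt((obj$x - region$x)^2 + (obj$y - region$y)^2)
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf(
    "<field_series> %d x %d grid (h = %g um), %d frames, t = %g..%g s\n",
    attr(x, "nx"), attr(x, "ny"), attr(x, "spacing"),
    length(attr(x, "times")), min(attr(x, "times")), max(attr(x, "times"))
  ))
  NextMethod()
}

#' @export
print.scalar_field_series <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf(
    "<scalar_field_series>%s %d x %d grid (h = %g um), %d frames\n",
    if (is.null(lab)) "" else paste0(" [", lab, "]"),
    attr(x, "nx"), attr(x, "ny"), attr(x, "spacing"), length(attr(x, "times"))
  ))
  NextMethod()
}
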