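# Analytic velocity fields on regular grids, used as oracles throughout.

# build a field_series from vector-valued function(s) of (x, y)
make_field <- function(fx, fy, xs = seq(-10, 10, by = 1), ys = xs,
                       times = 0, spacing = NULL) {
  g <- expand.grid(x = xs, y = ys)
  df <- purrr::map(times, function(t) {
    tibble::tibble(time = t, x = g$x, y = g$y,
                   vx = fx(g$x, g$y), vy = fy(g$x, g$y))
  }) |> purrr::list_rbind()
  field_series(df, spacing = spacing, quiet = TRUE)
}

# uniform inward sink of speed a: v = -a * r_hat
sink_field <- function(a = 0.01, ...) {
  make_field(
    fx = function(x, y) { r <- sqrt(x^2 + y^2); ifelse(r > 0, -a * x / r, 0) },
    fy = function(x, y) { r <- sqrt(x^2 + y^2); ifelse(r > 0, -a * y / r, 0) },
    ...
  )
}

# linear sink v = (-a x, -a y): divergence -2a everywhere
linear_sink_field <- function(a = 0.01, ...) {
  make_field(function(x, y) -a * x, function(x, y) -a * y, ...)
}

# rigid rotation v = omega r theta_hat
rotation_field <- function(omega = 0.002, ...) {
  make_field(function(x, y) -omega * y, function(x, y) omega * x, ...)
}

rotate_field_90 <- function(field) {
  # rotate both node positions and vectors by +90 degrees about the origin
  df <- tibble::tibble(
    time = field$time, x = -field$y, y = field$x,
    vx = -field$vy, vy = field$vx
  )
  field_series(df, spacing = attr(field, "spacing"), quiet = TRUE)
}

expect_all_equal <- function(x, y, tol = 1e-12) {
  expect_lt(max(abs(x - y)), tol)
}
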