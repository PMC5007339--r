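#' Write / read a field series as a directory of delimited grids
#'
#' The on-disk text layout mirrors common PIV exports: one whitespace-free
#' TSV matrix per frame per component (`vx_0001.tsv`, `vy_0001.tsv`, rows =
#' y index, columns = x index) plus a `meta.yaml` sidecar holding grid
#' spacing (um), frame times (s) and the origin. `read_field_series()`
#' inverts the layout exactly.
#'
#' @param field A [field_series()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; `read_field_series()` returns the
#'   [field_series()].
#' @export
write_field_series <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- field_arrays(field)
  meta <- list(
    spacing_um = arr$h,
    origin_um = c(min(arr$xs), min(arr$ys)),
    times_s = as.numeric(arr$times),
    nx = length(arr$xs), ny = length(arr$ys)
  )
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  for (k in seq_along(arr$times)) {
    # rows = y, columns = x
    utils::write.table(t(arr$vx[, , k]), file.path(dir, sprintf("vx_%04d.tsv", k)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(t(arr$vy[, , k]), file.path(dir, sprintf("vy_%04d.tsv", k)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_field_series
#' @export
read_field_series <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  xs <- meta$origin_um[1] + (seq_len(meta$nx) - 1) * meta$spacing_um
  ys <- meta$origin_um[2] + (seq_len(meta$ny) - 1) * meta$spacing_um
  g <- expand.grid(x = xs, y = ys)
  frames <- purrr::map(seq_along(meta$times_s), function(k) {
    vx <- t(as.matrix(utils::read.table(file.path(dir, sprintf("vx_%04d.tsv", k)))))
    vy <- t(as.matrix(utils::read.table(file.path(dir, sprintf("vy_%04d.tsv", k)))))
    tibble(time = meta$times_s[k], x = g$x, y = g$y,
           vx = as.vector(vx), vy = as.vector(vy))
  })
  field_series(list_rbind(frames), spacing = meta$spacing_um, quiet = TRUE)
}

#' Single-file container round trip for a field series
#'
#' Stores the whole series (all frames, long format) in one Apache Parquet
#' file, the package's hierarchical single-container format; the grid
#' geometry is recovered from the node coordinates on read. Requires the
#' `arrow` package.
#'
#' @param field A [field_series()].
#' @param path Output `.parquet` path.
#' @return `path` invisibly; `read_field_parquet()` returns the
#'   [field_series()].
#' @export
write_field_parquet <- function(field, path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    abort("the container format needs the 'arrow' package")
  }
  arrow::write_parquet(as_tibble(field)[, c("time", "x", "y", "vx", "vy")], path)
  invisible(path)
}

#' @rdname write_field_parquet
#' @export
read_field_parquet <- function(path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    abort("the container format needs the 'arrow' package")
  }
  field_series(arrow::read_parquet(path), quiet = TRUE)
}

#' Write analysis results as unit-annotated CSV
#'
#' Writers for the standard result tables. Column headers carry units
#' (`time_s`, `r_um`, `strain_rate_per_s`, ...) so the files are
#' self-describing.
#'
#' @param x The object to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(x, path) {
  stopifnot(inherits(x, "strain_timecourse"))
  out <- tibble(time_s = x$time, strain = x$strain,
                tangential_fraction = x$tangential_fraction,
                phase = as.character(x$phase))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
write_profile_csv <- function(x, path) {
  stopifnot(inherits(x, "radial_profile"))
  out <- tibble(time_s = x$time, r_um = x$r, mean = x$mean, n = x$n)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
write_stress_csv <- function(x, path) {
  stopifnot(inherits(x, "stress_profile"))
  out <- tibble(time_s = x$time, r_um = x$r, sigma_zeta_um2_per_s = x$sigma)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a maximum-strain vs density CSV
#'
#' Expects columns `rho_per_um2` and `epsilon_max` (optionally
#' `strain_rate_per_s`), the interchange format for cooperativity fits.
#'
#' @param path CSV path.
#' @return A tibble with columns `rho`, `eps_max` (and `strain_rate` when
#'   present).
#' @export
read_strain_density_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("rho_per_um2", "epsilon_max") %in% names(d))) {
    abort("expected columns rho_per_um2 and epsilon_max")
  }
  out <- tibble(rho = d$rho_per_um2, eps_max = d$epsilon_max)
  if ("strain_rate_per_s" %in% names(d)) out$strain_rate <- d$strain_rate_per_s
  out
}
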