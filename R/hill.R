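#' Hill equation for strain-density cooperativity
#'
#' `eps_sat / (1 + (rho_half / rho)^n)`: saturating, sigmoidal dependence of
#' maximum strain on myosin thick-filament density. At `rho = rho_half` the
#' curve is at half saturation for any Hill coefficient `n`; `n = 1` is the
#' hyperbolic (non-cooperative) limit, and large `n` a switch-like
#' connectivity transition.
#'
#' @param rho Myosin thick-filament density (1/um^2), all > 0; vectorised.
#' @param eps_sat Saturation strain (> 0).
#' @param rho_half Half-saturation density (> 0, 1/um^2).
#' @param n Hill coefficient (> 0).
#' @return Strain values, same length as `rho`.
#' @export
hill <- function(rho, eps_sat, rho_half, n) {
  if (any(!is.finite(rho)) || any(rho <= 0)) abort("densities rho must be positive")
  if (eps_sat <= 0 || rho_half <= 0 || n <= 0) abort("Hill parameters must be positive")
  eps_sat / (1 + (rho_half / rho)^n)
}

#' Fit the Hill equation to maximum strain vs myosin density
#'
#' Bounded nonlinear least squares with multiple starts. Steep Hill fits are
#' multi-modal in (rho_half, n), so the optimiser is started from Hill
#' coefficients {1, 2, 5, 10, 20} and the best fit by residual sum of
#' squares is kept. Bounds: `n` in \[0.5, 30\], `eps_sat` in (0, 10\],
#' `rho_half` within the data range widened by 50%. Standard errors come
#' from the Jacobian at the optimum. Degenerate data (constant strain, or no
#' convergent start) yields `converged = FALSE` with a message rather than a
#' silent bad fit.
#'
#' @param data A data frame with the density and maximum-strain columns.
#' @param rho,eps_max Column names (tidy-eval) holding density (1/um^2) and
#'   maximum strain; defaults `rho`, `eps_max`.
#' @return An object of class `hill_fit`: use [tidy()] for the parameter
#'   table, [glance()] for the one-row summary, `predict()` for the fitted
#'   curve.
#' @examples
#' d <- gen_hill_dataset(50, noise = 0, seed = 1)
#' fit <- fit_hill(d)
#' glance(fit)
#' @export
fit_hill <- function(data, rho = "rho", eps_max = "eps_max") {
  rho_v <- data[[rho]]
  eps_v <- data[[eps_max]]
  if (length(rho_v) < 5) abort("fit_hill needs at least 5 points")
  if (any(rho_v <= 0)) abort("densities rho must be positive")
  out <- list(
    data = tibble(rho = rho_v, eps_max = eps_v),
    converged = FALSE, message = NULL, estimate = NULL, rss = Inf, fit = NULL
  )
  class(out) <- "hill_fit"
  if (sd(eps_v) < 1e-12) {
    out$message <- "degenerate data: strain is constant, Hill parameters unidentifiable"
    return(out)
  }
  lower <- c(eps_sat = 1e-8, rho_half = 0.5 * min(rho_v), n = 0.5)
  upper <- c(eps_sat = 10, rho_half = 1.5 * max(rho_v), n = 30)
  d <- tibble(rho = rho_v, eps = eps_v)
  best <- NULL
  for (n0 in c(1, 2, 5, 10, 20)) {
    start <- c(eps_sat = min(max(eps_v), 10), rho_half = median(rho_v), n = n0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        eps ~ eps_sat / (1 + (rho_half / rho)^n),
        data = d, start = as.list(start),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    out$message <- "no start converged: data may not span the transition"
    return(out)
  }
  cf <- summary(best$fit)$coefficients
  est <- tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"])
  )
  # flag boundary-pinned fits of the transition as suspect, not converged-clean
  if (est$estimate[est$term == "n"] >= upper["n"] - 1e-6 &&
      est$std.error[est$term == "n"] > est$estimate[est$term == "n"]) {
    out$message <- "Hill coefficient pinned at its upper bound with large uncertainty"
  }
  out$converged <- TRUE
  out$estimate <- est
  out$rss <- best$rss
  out$fit <- best$fit
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> eps_max = eps_sat / (1 + (rho_half/rho)^n)\n")
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$message, "\n")
  } else {
    print(as.data.frame(x$estimate), row.names = FALSE)
    cat(sprintf("  RSS %.4g on %d points", x$rss, nrow(x$data)))
    if (!is.null(x$message)) cat("  [", x$message, "]", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' @export
tidy.hill_fit <- function(x, ...) {
  if (!x$converged) return(tibble(term = character(), estimate = double(), std.error = double()))
  x$estimate
}

#' @export
glance.hill_fit <- function(x, ...) {
  g <- function(term, col = "estimate") {
    if (!x$converged) return(NA_real_)
    unname(x$estimate[[col]][x$estimate$term == term])
  }
  tibble(
    eps_sat = g("eps_sat"), rho_half = g("rho_half"), n_hill = g("n"),
    se_eps_sat = g("eps_sat", "std.error"), se_rho_half = g("rho_half", "std.error"),
    se_n_hill = g("n", "std.error"),
    rss = if (x$converged) x$rss else NA_real_,
    nobs = nrow(x$data), converged = x$converged
  )
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) abort("cannot predict from a non-converged hill_fit")
  rho <- if (is.null(newdata)) object$data$rho else newdata$rho
  p <- setNames(object$estimate$estimate, object$estimate$term)
  hill(rho, p["eps_sat"], p["rho_half"], p["n"])
}

#' @export
augment.hill_fit <- function(x, ...) {
  d <- x$data
  if (x$converged) {
    d$.fitted <- predict(x)
    d$.resid <- d$eps_max - d$.fitted
  }
  d
}

#' Linear fit of contractile strain rate vs myosin density
#'
#' Ordinary least-squares line through (rho, strain rate); the strain rate
#' grows linearly with thick-filament density in contrast with the
#' switch-like maximum strain.
#'
#' @param data A data frame.
#' @param rho,rate Column names for density and strain rate.
#' @return A one-row tibble: `slope`, `intercept`, `r.squared`,
#'   `se_slope`, `nobs`.
#' @export
linear_rate_fit <- function(data, rho = "rho", rate = "rate") {
  x <- data[[rho]]; y <- data[[rate]]
  if (length(x) < 2) abort("linear_rate_fit needs at least 2 points")
  if (sd(x) < 1e-14) abort("rank-deficient input: all densities equal")
  fit <- lm(y ~ x)
  s <- summary(fit)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r.squared = if (length(x) == 2) 1 else s$r.squared,
    se_slope = s$coefficients[2, 2],
    nobs = length(x)
  )
}

#' Classify a contraction by its maximum strain
#'
#' `"high"` for eps_max > 1 (large condensation above the critical myosin
#' density), `"low"` for eps_max < 0.5 (sub-critical), `"intermediate"`
#' otherwise. Vectorised.
#'
#' @param eps_max Finite maximum strain value(s).
#' @return Character vector of labels.
#' @export
classify_contractile <- function(eps_max) {
  if (any(!is.finite(eps_max))) abort("eps_max must be finite")
  ifelse(eps_max > 1, "high", ifelse(eps_max < 0.5, "low", "intermediate"))
}
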