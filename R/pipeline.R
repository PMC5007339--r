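#' Run a config-driven experiment bundle
#'
#' Orchestrates end-to-end runs (simulate, analyse, fit, report) from a
#' declarative configuration: an R list (or path to a YAML file) with a
#' `scenarios` element, each scenario a list with a `type` and its
#' parameter blocks:
#'
#' * `type = "gel_sweep"` — [sweep_activation()] over `xi` / `stiffness`
#'   with gel parameters in `gel`; writes the sweep table CSV.
#' * `type = "hill"` — [gen_hill_dataset()] (`data` block) +
#'   [fit_hill()]; writes the dataset CSV, fit CSV and fit JSON.
#' * `type = "analyze"` — [gen_piv_series()] (`piv` block; for the gel
#'   scenario a `gel` block parameterises [solve_gel()]) followed by
#'   [contraction_summary()]; writes the summary CSV with seed and
#'   config-hash columns.
#' * `type = "abm"` — [abm_run()] with parameters in `abm`; writes the
#'   [abm_summary()] CSV.
#'
#' Outputs land in `outdir` together with `manifest.json` (package version,
#' seed, config hash, the full config and the output list), so a bundle can
#' be regenerated exactly from its manifest. Any stage failure aborts with
#' a stage-named error; partial outputs are retained next to a
#' `<stage>.FAILED` marker.
#'
#' @param config Configuration list or YAML path.
#' @param outdir Output directory.
#' @param seed Global integer seed used by every stochastic stage.
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(config, outdir, seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  scenarios <- config$scenarios %||% list()
  cfg_hash <- rlang::hash(config)
  outputs <- character()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    nm <- sc$name %||% paste0(sc$type, "_", i)
    outputs <- c(outputs, tryCatch(
      run_stage(sc, outdir, nm, seed, cfg_hash),
      error = function(e) {
        writeLines(paste0("FAILED: ", conditionMessage(e)),
                   file.path(outdir, paste0(nm, ".FAILED")))
        abort(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)))
      }
    ))
  }
  manifest <- list(
    package = "actoflow",
    version = as.character(packageVersion("actoflow")),
    seed = seed, config_hash = cfg_hash,
    config = config, outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

run_stage <- function(sc, outdir, nm, seed, cfg_hash) {
  type <- sc$type %||% abort("scenario without a type")
  switch(
    type,
    gel_sweep = {
      p <- do.call(gel_params, sc$gel %||% list())
      tab <- sweep_activation(p,
        xi = unlist(sc$xi %||% c(5, 10, 20, 40)),
        stiffness = unlist(sc$stiffness %||% 1))
      out <- tibble(
        xi_um = tab$xi, e_over_sigma0 = tab$stiffness,
        v_max_um_per_s = tab$v_max, strain_rate_per_s = tab$strain_rate,
        eps_max = tab$eps_max
      )
      f <- file.path(outdir, paste0(nm, "_sweep.csv"))
      readr::write_csv(out, f)
      f
    },
    hill = {
      d <- do.call(gen_hill_dataset, c(sc$data %||% list(), list(seed = seed)))
      f1 <- file.path(outdir, paste0(nm, "_data.csv"))
      readr::write_csv(tibble(rho_per_um2 = d$rho, epsilon_max = d$eps_max), f1)
      fit <- fit_hill(d)
      f2 <- file.path(outdir, paste0(nm, "_fit.csv"))
      readr::write_csv(glance(fit), f2)
      f3 <- file.path(outdir, paste0(nm, "_fit.json"))
      jsonlite::write_json(as.list(glance(fit)), f3, auto_unbox = TRUE, digits = NA)
      c(f1, f2, f3)
    },
    analyze = {
      piv <- sc$piv %||% list()
      if ((piv$scenario %||% "gel") == "gel") {
        sol <- solve_gel(do.call(gel_params, sc$gel %||% list()))
        field <- do.call(gen_piv_series,
                         c(list(scenario = "gel", sol = sol, seed = seed),
                           piv[setdiff(names(piv), "scenario")]))
      } else {
        field <- do.call(gen_piv_series, c(piv, list(seed = seed)))
      }
      region <- attr(field, "region")
      summ <- contraction_summary(field, region) |>
        mutate(seed = seed, config_hash = cfg_hash)
      f <- file.path(outdir, paste0(nm, "_summary.csv"))
      readr::write_csv(summ, f)
      f
    },
    abm = {
      p <- do.call(abm_params, sc$abm %||% list())
      summ <- abm_summary(abm_run(p, seed = seed)) |>
        mutate(seed = seed, config_hash = cfg_hash)
      f <- file.path(outdir, paste0(nm, "_abm_summary.csv"))
      readr::write_csv(summ, f)
      f
    },
    abort(sprintf("unknown scenario type '%s'", type))
  )
}

#' Pairwise condition comparison by t-tests
#'
#' Two-sample t-tests per metric for every pair of groups, with the
#' significance-star convention used for condition comparisons: `"*"` for
#' p < 0.05, `"***"` for p < 0.001. Welch's unequal-variance test is the
#' default because group sizes typically differ between activation-size
#' conditions; set `var_equal = TRUE` for the pooled-variance variant.
#'
#' @param data A data frame of per-replicate summaries.
#' @param group Name of the grouping column.
#' @param metrics Character vector of metric columns (default: all numeric
#'   columns except the group).
#' @param var_equal Use the pooled-variance t-test.
#' @return A tibble: `metric`, `group1`, `group2`, `mean1`, `mean2`,
#'   `p.value`, `stars`.
#' @export
compare_conditions <- function(data, group, metrics = NULL, var_equal = FALSE) {
  g <- data[[group]]
  if (is.null(g)) abort(sprintf("no grouping column '%s'", group))
  lv <- unique(g)
  if (length(lv) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("every group needs at least 2 replicates for a t-test")
  metrics <- metrics %||% setdiff(names(data)[vapply(data, is.numeric, TRUE)], group)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- purrr::map(metrics, function(m) {
    purrr::map(pairs, function(pr) {
      x <- data[[m]][g == pr[1]]
      y <- data[[m]][g == pr[2]]
      p <- if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) 1
           else t.test(x, y, var.equal = var_equal)$p.value
      tibble(metric = m, group1 = as.character(pr[1]), group2 = as.character(pr[2]),
             mean1 = mean(x), mean2 = mean(y), p.value = p,
             stars = significance_stars(p))
    }) |> list_rbind()
  }) |> list_rbind()
  rows
}

# the figure convention: * below 0.05, *** below 0.001
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", ""))
}
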