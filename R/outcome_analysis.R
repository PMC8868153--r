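#' Annual genetic gain of a replicate, per trait and total
#'
#' Per trait, the yearly slope of the slaughter-cohort mean true breeding
#' value is estimated by ordinary least squares over the analysis window
#' (default years 4-10, i.e. time steps 8-20) and converted to EUR per
#' slaughtered organic pig per year by the economic values (by convention
#' those of the current organic goal, whatever goal drove selection). The
#' total gain is the sum over traits. A per-trait gain in genetic-standard-
#' deviation units (slope divided by the additive SD) is reported alongside.
#'
#' The slaughter cohort of a birth year contains the organic-line animals
#' born that year that leave the population for slaughter: under OS both
#' sexes; under CS all males plus the females never retained for breeding.
#'
#' @param result A [run_replicate()] result.
#' @param panel A [trait_panel()].
#' @param weights Goal name or economic-value vector used to price the
#'   gains (default `"curOBG"`).
#' @param years Analysis window `c(first, last)` in years.
#' @return Tibble with one row per trait (`trait`, `unit`, `slope` in trait
#'   units/year, `gain_eur` in EUR/pig/year, `gain_sigma` in additive-SD
#'   units/year) and attribute `total` (sum of `gain_eur`).
#' @export
genetic_gain <- function(result, panel, weights = "curOBG", years = c(4, 10)) {
  stopifnot(inherits(result, "replicate_result"))
  v <- goal_vector(panel, weights)
  an <- result$animals
  org <- an[an$line == "org" & an$birth >= 1, , drop = FALSE]
  if (result$config$scheme == "CS") {
    org <- org[org$sex == "M" | !org$selected, , drop = FALSE]
  }
  org$year <- ceiling(org$birth / 2)
  org <- org[org$year >= years[1] & org$year <= years[2], , drop = FALSE]
  tbv_cols <- paste0("tbv_", panel$traits$code)
  cohorts <- dplyr::summarise(
    dplyr::group_by(org, .data$year),
    dplyr::across(dplyr::all_of(tbv_cols), mean), .groups = "drop"
  )
  if (nrow(cohorts) < 3) {
    stop("fewer than 3 yearly cohorts in the analysis window")
  }
  yr <- cohorts$year
  slopes <- vapply(tbv_cols, function(cl) {
    unname(coef(lm(cohorts[[cl]] ~ yr))[2])
  }, numeric(1))
  tibble::new_tibble(
    tibble::tibble(
      trait = panel$traits$code,
      unit = panel$traits$unit,
      slope = unname(slopes),
      gain_eur = as.numeric(slopes * v),
      gain_sigma = as.numeric(slopes / sqrt(panel$traits$sa2))
    ),
    total = sum(as.numeric(slopes * v)),
    class = "gain_table"
  )
}

#' Rate of inbreeding per generation of a replicate
#'
#' The yearly slope of mean inbreeding in the living organic-line population
#' is estimated by OLS over the analysis window, the realized generation
#' interval `L` is the mean parent age (years) at offspring birth over the
#' same window, and the per-generation rate is `slope * L`, in percent.
#'
#' By default the rate is the absolute slope of mean F (the convention of
#' the published comparison table). With `relative = TRUE` the slope is
#' divided by `1 - Fbar` (mean inbreeding over the window), giving the
#' relative rate that idealized-population formulas such as Wright's
#' `1/(8 Nm) + 1/(8 Nf)` predict.
#'
#' @inheritParams genetic_gain
#' @param relative Report the relative rate `slope / (1 - Fbar)` instead of
#'   the absolute slope.
#' @return One-row tibble: `dF_pct_per_generation`, `dF_per_year` (on the
#'   inbreeding scale), `generation_interval_years`.
#' @export
inbreeding_rate <- function(result, years = c(4, 10), relative = FALSE) {
  stopifnot(inherits(result, "replicate_result"))
  tr <- result$trajectory
  tr <- tr[tr$line == "org" & tr$year >= years[1] & tr$year <= years[2], ]
  if (nrow(tr) < 3) stop("fewer than 3 time points in the analysis window")
  slope <- unname(coef(lm(tr$mean_f ~ tr$year))[2])
  if (relative) slope <- slope / (1 - mean(tr$mean_f))
  mt <- result$matings
  mt <- mt[mt$line == "org" & mt$step >= 2 * years[1] & mt$step <= 2 * years[2], ]
  ages <- c(mt$step - mt$sire_birth, mt$step - mt$dam_birth) / 2
  L <- mean(ages)
  tibble::tibble(
    dF_pct_per_generation = 100 * slope * L,
    dF_per_year = slope,
    generation_interval_years = L
  )
}

# One-row endpoint summary of a replicate (wide).
replicate_endpoints <- function(result, panel, weights = "curOBG",
                                years = c(4, 10)) {
  gg <- genetic_gain(result, panel, weights = weights, years = years)
  fr <- inbreeding_rate(result, years = years)
  wide <- setNames(as.list(gg$gain_eur), paste0("gain_", gg$trait))
  wide_sd <- setNames(as.list(gg$gain_sigma), paste0("gain_sd_", gg$trait))
  tibble::tibble(
    gain_total = attr(gg, "total"),
    !!!wide, !!!wide_sd,
    dF_pct = fr$dF_pct_per_generation,
    L_years = fr$generation_interval_years
  )
}

#' Aggregate per-replicate endpoints into means and standard errors
#'
#' @param endpoints Tibble of per-replicate endpoint rows (one row per
#'   replicate, numeric columns).
#' @return Tibble with one row per endpoint: `metric`, `mean`,
#'   `se` (= sd / sqrt(n)), `n`.
#' @export
aggregate_replicates <- function(endpoints) {
  if (nrow(endpoints) < 2) stop("need at least 2 replicates to aggregate")
  num <- endpoints[vapply(endpoints, is.numeric, logical(1))]
  num <- num[setdiff(names(num), "replicate")]
  tibble::tibble(
    metric = names(num),
    mean = unname(vapply(num, mean, numeric(1))),
    se = unname(vapply(num, function(x) sd(x) / sqrt(length(x)), numeric(1))),
    n = nrow(endpoints)
  )
}

#' Run a scenario: replicated simulation plus endpoint aggregation
#'
#' @param cfg A [scheme_config()]; its `seed` field is ignored in favour of
#'   per-replicate seeds derived from `base_seed` and `scenario_id`.
#' @param panel A [trait_panel()].
#' @param n_replicates Number of independent replicates.
#' @param base_seed Base seed.
#' @param scenario_id Integer distinguishing scenarios run from the same
#'   base seed.
#' @param weights,years Passed to the endpoint computations.
#' @return An object of class `scenario_result`: `summary` (aggregated
#'   endpoints), `per_replicate` (one endpoint row per replicate), and the
#'   scenario metadata.
#' @export
run_scenario <- function(cfg, panel, n_replicates = 10, base_seed = 1,
                         scenario_id = 0, weights = "curOBG",
                         years = c(4, 10)) {
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- replicate_seed(base_seed, scenario_id, r)
    res <- run_replicate(cfg_r, panel)
    dplyr::mutate(replicate_endpoints(res, panel, weights, years),
                  replicate = r, seed = cfg_r$seed, .before = 1)
  })
  per_rep <- dplyr::bind_rows(reps)
  structure(
    list(summary = aggregate_replicates(per_rep),
         per_replicate = per_rep,
         scheme = cfg$scheme, goal = cfg$goal, intensity = cfg$intensity,
         n_replicates = n_replicates, base_seed = base_seed,
         scenario_id = scenario_id, config = cfg),
    class = "scenario_result"
  )
}

replicate_seed <- function(base_seed, scenario_id, replicate) {
  as.integer((as.numeric(base_seed) * 97 + scenario_id * 131071 +
                replicate * 7919) %% 2147483629)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$scheme, "/", x$goal, " intensity ", x$intensity,
      " (", x$n_replicates, " replicates)\n", sep = "")
  print(head(x$summary, 4))
  invisible(x)
}

#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  dplyr::mutate(x$summary, scheme = x$scheme, goal = x$goal,
                intensity = x$intensity, .before = 1)
}

#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  s <- x$summary
  pick <- function(m, col) s[[col]][s$metric == m]
  tibble::tibble(
    scheme = x$scheme, goal = x$goal, intensity = x$intensity,
    gain_total = pick("gain_total", "mean"), gain_total_se = pick("gain_total", "se"),
    dF_pct = pick("dF_pct", "mean"), dF_pct_se = pick("dF_pct", "se"),
    L_years = pick("L_years", "mean"),
    n_replicates = x$n_replicates
  )
}

#' Scenario comparison table (one row per scenario)
#'
#' Collects per-trait and total annual genetic gain (EUR/pig/year), the
#' per-generation rate of inbreeding (%), and the generational gain per 1%
#' of inbreeding. The last column converts the annual gain to the half-year
#' reproductive cycle (`gain_total / 2`) before dividing by the inbreeding
#' rate, which is the convention of the published comparison table.
#'
#' @param results List of [run_scenario()] results.
#' @return Tibble with one row per scenario; missing scenarios are simply
#'   absent rows.
#' @export
scenario_table <- function(results) {
  rows <- purrr::map(results, function(x) {
    s <- x$summary
    means <- setNames(s$mean, s$metric)
    gains <- means[grep("^gain_(?!sd_)", names(means), perl = TRUE)]
    gains <- gains[names(gains) != "gain_total"]
    dF <- unname(means["dF_pct"])
    tibble::tibble(
      scheme = x$scheme, intensity = x$intensity, goal = x$goal,
      !!!as.list(gains),
      gain_total = unname(means["gain_total"]),
      dF_pct = dF,
      gain_per_pct_dF = if (is.finite(dF) && dF > 0) {
        unname(means["gain_total"]) / 2 / dF
      } else NA_real_,
      n_replicates = x$n_replicates
    )
  })
  dplyr::bind_rows(rows)
}

#' Enumerate the scenario grid of the study design
#'
#' The default plan is the full 12-scenario grid: two schemes, two
#' phenotyping intensities and three organic breeding goals.
#'
#' @param schemes,intensities,goals Grid axes.
#' @param n_replicates Replicates per scenario.
#' @param base_seed Base seed; replicate `r` of scenario `s` gets an
#'   independent derived seed.
#' @param config_args Named list of extra arguments passed to
#'   [scheme_config()] (e.g. reduced population sizes).
#' @return Tibble with one row per scenario (`scenario_id`, `scheme`,
#'   `intensity`, `goal`, `n_replicates`, `base_seed`).
#' @export
experiment_plan <- function(schemes = c("OS", "CS"),
                            intensities = c(0.2, 1),
                            goals = c("curOBG", "altOBG", "altOBG+"),
                            n_replicates = 100, base_seed = 1,
                            config_args = list()) {
  grid <- tidyr::expand_grid(scheme = schemes, intensity = intensities,
                             goal = goals)
  dplyr::mutate(grid,
                scenario_id = dplyr::row_number(),
                n_replicates = n_replicates,
                base_seed = base_seed,
                config_args = list(config_args),
                .before = 1)
}

#' Run an experiment plan and build the comparison table
#'
#' @param plan An [experiment_plan()] tibble.
#' @param panel A [trait_panel()].
#' @param out_dir Optional directory; when given, the scenario table, the
#'   per-replicate endpoints and the goal-correlation table are written as
#'   CSV files.
#' @param weights,years Passed to the endpoint computations.
#' @return List with `results` (scenario results), `table`
#'   ([scenario_table()]), and the `plan`.
#' @export
run_experiment <- function(plan, panel, out_dir = NULL, weights = "curOBG",
                           years = c(4, 10)) {
  results <- purrr::pmap(
    list(plan$scenario_id, plan$scheme, plan$intensity, plan$goal,
         plan$n_replicates, plan$base_seed, plan$config_args),
    function(sid, scheme, intensity, goal, n_rep, base_seed, extra) {
      cfg <- do.call(scheme_config,
                     c(list(scheme = scheme, goal = goal,
                            intensity = intensity), extra))
      run_scenario(cfg, panel, n_replicates = n_rep, base_seed = base_seed,
                   scenario_id = sid, weights = weights, years = years)
    }
  )
  tab <- scenario_table(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "scenario_table.csv"),
                     row.names = FALSE)
    per_rep <- dplyr::bind_rows(purrr::map(results, function(x) {
      dplyr::mutate(x$per_replicate, scheme = x$scheme, goal = x$goal,
                    intensity = x$intensity, .before = 1)
    }))
    utils::write.csv(per_rep, file.path(out_dir, "replicate_endpoints.csv"),
                     row.names = FALSE)
    utils::write.csv(goal_correlation_table(panel),
                     file.path(out_dir, "goal_correlations.csv"),
                     row.names = FALSE)
  }
  list(results = results, table = tab, plan = plan)
}
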