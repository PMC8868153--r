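panel <- trait_panel()

# Hand-built replicate with exactly linear cohort trends: trait LG rises
# 0.01 units/year, all other traits flat; mean F rises 0.02/year; parents
# always 3 steps old at mating (L = 1.5 years).
fake_replicate <- function(lg_slope = 0.01, f_slope = 0.02, scheme = "OS") {
  years <- 1:10
  tbv0 <- setNames(rep(0, 10), paste0("tbv_", panel$traits$code))
  animals <- dplyr::bind_rows(lapply(years, function(y) {
    tb <- tbv0
    tb["tbv_LG"] <- lg_slope * y
    tibble::tibble(id = y, sex = "M", line = "org", birth = 2L * y,
                   sire = 0L, dam = 0L, f = 0, phenotyped = TRUE,
                   selected = FALSE, alive = TRUE, culled = NA_integer_,
                   !!!as.list(tb))
  }))
  steps <- 1:20
  trajectory <- tibble::tibble(
    step = steps, year = steps / 2, line = "org", n_alive = 100,
    mean_f = f_slope * steps / 2,
    !!!setNames(as.list(rep(0, 10)), paste0("tbv_", panel$traits$code))
  )
  matings <- tibble::tibble(sire = 1L, dam = 2L, step = steps, line = "org",
                            sire_birth = steps - 3L, dam_birth = steps - 3L)
  structure(list(animals = animals, trajectory = trajectory,
                 matings = matings, selection = tibble::tibble(),
                 config = scheme_config(scheme, "curOBG", seed = 1)),
            class = "replicate_result")
}

test_that("genetic gain prices cohort slopes by the economic values", {
  gg <- genetic_gain(fake_replicate(), panel)
  expect_equal(gg$gain_eur[gg$trait == "LG"], 0.01 * 11.333,
               tolerance = 1e-9)
  expect_equal(gg$gain_eur[gg$trait == "LG"], 0.11333, tolerance = 1e-6)
  expect_true(all(gg$gain_eur[gg$trait != "LG"] == 0))
  expect_equal(attr(gg, "total"), sum(gg$gain_eur), tolerance = 1e-9)
  expect_equal(gg$gain_sigma[gg$trait == "LG"], 0.01 / sqrt(0.028),
               tolerance = 1e-9)
  flat <- genetic_gain(fake_replicate(lg_slope = 0), panel)
  expect_true(all(flat$gain_eur == 0))
})

test_that("the analysis window must contain at least three cohorts", {
  expect_error(genetic_gain(fake_replicate(), panel, years = c(4, 5)),
               "fewer than 3")
  expect_error(inbreeding_rate(fake_replicate(), years = c(4, 4.5)),
               "fewer than 3")
})

test_that("inbreeding rate converts the yearly slope per generation", {
  fr <- inbreeding_rate(fake_replicate())
  expect_equal(fr$generation_interval_years, 1.5)
  expect_equal(fr$dF_per_year, 0.02, tolerance = 1e-12)
  expect_equal(fr$dF_pct_per_generation, 3, tolerance = 1e-9) # 0.02 * 1.5 * 100
  # relative rate divides by 1 - mean F over the window
  frr <- inbreeding_rate(fake_replicate(), relative = TRUE)
  fbar <- mean(0.02 * (8:20) / 2)
  expect_equal(frr$dF_pct_per_generation, 3 / (1 - fbar), tolerance = 1e-9)
  flat <- inbreeding_rate(fake_replicate(f_slope = 0))
  expect_equal(flat$dF_pct_per_generation, 0)
})

test_that("replicate aggregation computes means and standard errors", {
  two <- tibble::tibble(replicate = 1:2, gain_total = c(1, 2), dF_pct = c(4, 4))
  agg <- aggregate_replicates(two)
  expect_equal(agg$mean[agg$metric == "gain_total"], 1.5)
  expect_equal(agg$se[agg$metric == "gain_total"], 0.5) # sd/sqrt(2)
  expect_equal(agg$se[agg$metric == "dF_pct"], 0)
  expect_error(aggregate_replicates(two[1, ]), "at least 2")
  set.seed(12)
  x <- tibble::tibble(gain_total = rnorm(50))
  agg2 <- aggregate_replicates(x)
  expect_equal(agg2$se, sd(x$gain_total) / sqrt(50))
})

test_that("the scenario table sums per-trait gains and guards the ratio", {
  fake_scen <- function(gain_by_trait, dF, scheme = "OS", goal = "curOBG",
                        intensity = 1) {
    per_rep <- tibble::tibble(
      replicate = 1:2,
      gain_total = sum(gain_by_trait),
      !!!setNames(as.list(gain_by_trait), paste0("gain_", panel$traits$code)),
      dF_pct = dF, L_years = 1.5
    )
    structure(list(summary = aggregate_replicates(per_rep),
                   per_replicate = per_rep, scheme = scheme, goal = goal,
                   intensity = intensity, n_replicates = 2),
              class = "scenario_result")
  }
  g <- seq(0.1, 1, by = 0.1)
  tab <- scenario_table(list(fake_scen(g, dF = 4), fake_scen(g, dF = 0)))
  gain_cols <- paste0("gain_", panel$traits$code)
  expect_equal(rowSums(as.matrix(tab[, gain_cols])), tab$gain_total,
               tolerance = 1e-9)
  # generational gain per 1% inbreeding: half the annual gain over dF
  expect_equal(tab$gain_per_pct_dF[1], sum(g) / 2 / 4, tolerance = 1e-9)
  expect_true(is.na(tab$gain_per_pct_dF[2]))
})

test_that("scenario runs aggregate endpoints and are seed-stable", {
  cfg <- scaled_cfg("OS", "curOBG", intensity = 1, n_steps = 10)
  sc1 <- run_scenario(cfg, panel, n_replicates = 2, base_seed = 3,
                      scenario_id = 1, years = c(2, 5))
  sc2 <- run_scenario(cfg, panel, n_replicates = 2, base_seed = 3,
                      scenario_id = 1, years = c(2, 5))
  expect_equal(sc1$summary, sc2$summary)
  expect_equal(nrow(sc1$per_replicate), 2)
  expect_equal(glance(sc1)$gain_total,
               metric_of(sc1, "gain_total"))
  td <- tidy(sc1)
  expect_true(all(c("scheme", "goal", "intensity", "metric") %in% names(td)))
})
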