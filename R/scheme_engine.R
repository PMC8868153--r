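#' Configure a breeding-program scenario
#'
#' Two scheme designs are supported. `OS` keeps a single organic nucleus:
#' each half-year time step 10 sires and 100 dams are truncation-selected
#' among phenotyped organic candidates on the organic-goal index and mated
#' at random. `CS` runs a conventional nucleus (10 sires, 100 dams selected
#' on the conventional goal) next to an organic line whose sires are the
#' best conventional male candidates *not* selected for the conventional
#' nucleus, ranked by the organic goal, mated to 50 organic dams; organic
#' males are slaughtered at candidate age and never enter selection.
#'
#' Defaults are the published study design: 20 half-year steps, litter size
#' 10 with a 1:1 sex ratio, males in four age classes and females in five,
#' candidates between ages 1-2 years (males) and 1-2.5 years (females), and
#' phenotyping of 20% or 100% of newborn organic pigs. Any sizes can be
#' overridden, e.g. for scaled-down experiments.
#'
#' @param scheme `"OS"` (organic sires) or `"CS"` (conventional sires).
#' @param goal Organic breeding goal used to select the organic line's
#'   parents: `"curOBG"`, `"altOBG"` or `"altOBG+"`.
#' @param goal_conventional Goal selecting the conventional nucleus in CS
#'   (fixed to `"CBG"` in the study design).
#' @param intensity Fraction of newborn organic pigs phenotyped, in (0, 1].
#' @param n_steps Number of half-year time steps.
#' @param n_sires_conv,n_dams_conv Conventional nucleus quotas (CS only).
#' @param n_sires_org,n_dams_org Organic-line quotas; `n_dams_org` defaults
#'   to 100 (OS) or 50 (CS).
#' @param litter_size Piglets per litter (sex ratio 1:1; with an odd litter
#'   size the extra piglet's sex alternates between litters).
#' @param male_window,female_window Candidate age windows in time steps
#'   (also the age-class spans; animals are culled when they age out).
#' @param selection `"blup"` (truncation on the BLUP index) or `"random"`
#'   (parents drawn uniformly among eligible candidates; no evaluation run).
#' @param mendelian_scale Passed to [sample_offspring_tbv()].
#' @param solver_tol BLUP solver tolerance.
#' @param seed Seed for the replicate's random stream.
#' @return A `scheme_config` list.
#' @export
scheme_config <- function(scheme = c("OS", "CS"),
                          goal = c("curOBG", "altOBG", "altOBG+"),
                          goal_conventional = "CBG",
                          intensity = 1,
                          n_steps = 20L,
                          n_sires_conv = 10L, n_dams_conv = 100L,
                          n_sires_org = 10L, n_dams_org = NULL,
                          litter_size = 10L,
                          male_window = c(2L, 4L),
                          female_window = c(2L, 5L),
                          selection = c("blup", "random"),
                          mendelian_scale = c("sqrt", "linear"),
                          solver_tol = 1e-8,
                          seed = 1L) {
  scheme <- match.arg(scheme)
  goal <- goal[1]
  selection <- match.arg(selection)
  mendelian_scale <- match.arg(mendelian_scale)
  if (is.null(n_dams_org)) n_dams_org <- if (scheme == "CS") 50L else 100L
  stopifnot(intensity > 0, intensity <= 1, n_steps >= 1, litter_size >= 1,
            male_window[1] >= 1, male_window[2] >= male_window[1],
            female_window[1] >= 1, female_window[2] >= female_window[1])
  structure(
    list(scheme = scheme, goal = goal, goal_conventional = goal_conventional,
         intensity = intensity, n_steps = as.integer(n_steps),
         n_sires_conv = as.integer(n_sires_conv),
         n_dams_conv = as.integer(n_dams_conv),
         n_sires_org = as.integer(n_sires_org),
         n_dams_org = as.integer(n_dams_org),
         litter_size = as.integer(litter_size),
         male_window = as.integer(male_window),
         female_window = as.integer(female_window),
         selection = selection, mendelian_scale = mendelian_scale,
         solver_tol = solver_tol, seed = as.integer(seed)),
    class = "scheme_config"
  )
}

#' @export
print.scheme_config <- function(x, ...) {
  cat("<scheme_config> ", x$scheme, " / ", x$goal, " / intensity ",
      x$intensity, " / ", x$n_steps, " steps / seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# ---- population state -------------------------------------------------------

new_population <- function() {
  list(sex = character(0), line = character(0), birth = integer(0),
       sire = integer(0), dam = integer(0), f = numeric(0),
       phenotyped = logical(0), alive = logical(0), culled = rep(NA_integer_, 0),
       selected = logical(0), tbv = NULL, obs = NULL)
}

pop_size <- function(pop) length(pop$sex)

pop_append <- function(pop, sex, line, birth, sire, dam, f, phenotyped,
                       tbv, obs) {
  n <- length(sex)
  pop$sex <- c(pop$sex, sex)
  pop$line <- c(pop$line, line)
  pop$birth <- c(pop$birth, as.integer(birth))
  pop$sire <- c(pop$sire, as.integer(sire))
  pop$dam <- c(pop$dam, as.integer(dam))
  pop$f <- c(pop$f, f)
  pop$phenotyped <- c(pop$phenotyped, phenotyped)
  pop$alive <- c(pop$alive, rep(TRUE, n))
  pop$culled <- c(pop$culled, rep(NA_integer_, n))
  pop$selected <- c(pop$selected, rep(FALSE, n))
  pop$tbv <- rbind(pop$tbv, tbv)
  pop$obs <- rbind(pop$obs, obs)
  pop
}

#' Initialize the unrelated base population of a scenario
#'
#' Founders are unrelated and non-inbred, spread uniformly over the
#' sex-specific age classes (one cohort per class, each sized at the
#' per-step selection quota of its line and sex), all phenotyped, with TBVs
#' drawn from the base genetic covariance.
#'
#' @param cfg A [scheme_config()].
#' @param panel A [trait_panel()].
#' @param factors Result of [chol_factors()] (recomputed when `NULL`).
#' @return Population state (internal list) with founders in place.
#' @export
initialize_base_population <- function(cfg, panel, factors = NULL) {
  if (is.null(factors)) factors <- chol_factors(panel)
  pop <- new_population()
  groups <- if (cfg$scheme == "OS") {
    list(list(sex = "M", line = "org", quota = cfg$n_sires_org,
              classes = cfg$male_window[2]),
         list(sex = "F", line = "org", quota = cfg$n_dams_org,
              classes = cfg$female_window[2]))
  } else {
    list(list(sex = "M", line = "conv", quota = cfg$n_sires_conv,
              classes = cfg$male_window[2]),
         list(sex = "F", line = "conv", quota = cfg$n_dams_conv,
              classes = cfg$female_window[2]),
         list(sex = "F", line = "org", quota = cfg$n_dams_org,
              classes = cfg$female_window[2]))
  }
  for (g in groups) {
    n <- g$quota * g$classes
    birth <- rep(1L - seq_len(g$classes), each = g$quota) # age a at step 1
    tbv <- sample_base_tbv(n, factors)
    obs <- tbv + sample_environment(n, factors)
    pop <- pop_append(pop, rep(g$sex, n), rep(g$line, n), birth,
                      rep(0L, n), rep(0L, n), rep(0, n), rep(TRUE, n),
                      tbv, obs)
  }
  pop
}

# ---- candidacy, records, evaluation ----------------------------------------

sex_window <- function(cfg, sex) {
  if (sex == "M") cfg$male_window else cfg$female_window
}

#' Eligible selection candidates at a time step
#'
#' Living, phenotyped animals of the given sex and line whose age (in time
#' steps) lies inside the sex-specific candidate window.
#'
#' @param pop Population state.
#' @param cfg A [scheme_config()].
#' @param step Current time step.
#' @param sex `"M"` or `"F"`.
#' @param line `"org"` or `"conv"`.
#' @return Integer vector of animal ids.
#' @export
eligible_candidates <- function(pop, cfg, step, sex, line) {
  win <- sex_window(cfg, sex)
  age <- step - pop$birth
  which(pop$alive & pop$phenotyped & pop$sex == sex & pop$line == line &
          age >= win[1] & age <= win[2])
}

# Long record table of all phenotypes available to an evaluation at `step`.
# Core traits (both-sexes, and female-only on females) become available when
# the animal reaches candidate age; cull-only traits are recorded at culling
# of never-selected candidates and enter the data from the next step on.
build_records <- function(pop, cfg, panel, step) {
  rec_type <- panel$traits$sex_recording
  both_idx <- which(rec_type == "both_sexes")
  fem_idx <- which(rec_type %in% c("both_sexes", "female_only"))
  cull_idx <- which(rec_type == "cull_only")

  win1 <- ifelse(pop$sex == "M", cfg$male_window[1], cfg$female_window[1])
  rec_step <- pmax(pop$birth + win1, 1L)
  has_core <- pop$phenotyped & rec_step <= step

  ids_m <- which(has_core & pop$sex == "M")
  ids_f <- which(has_core & pop$sex == "F")
  ids_c <- which(pop$phenotyped & !pop$selected & !is.na(pop$culled) &
                   pop$culled < step)

  expand <- function(ids, traits, steps) {
    if (!length(ids) || !length(traits)) {
      return(tibble::tibble(id = integer(0), trait = integer(0),
                            value = numeric(0), step = integer(0)))
    }
    id <- rep(ids, each = length(traits))
    tr <- rep(traits, times = length(ids))
    tibble::tibble(id = id, trait = tr,
                   value = pop$obs[cbind(id, tr)],
                   step = rep(steps, each = length(traits)))
  }
  dplyr::bind_rows(
    expand(ids_m, both_idx, rec_step[ids_m]),
    expand(ids_f, fem_idx, rec_step[ids_f]),
    expand(ids_c, cull_idx, pmax(pop$culled[ids_c], 1L))
  )
}

# Full re-evaluation of the population at `step`. The pedigree is pruned to
# animals that are phenotyped or have offspring (a set closed under
# ancestry); animals pruned out carry no information and are not needed for
# selection. Returns an indexing closure over EBVs.
evaluate_population <- function(pop, cfg, panel, step) {
  rec <- build_records(pop, cfg, panel, step)
  n <- pop_size(pop)
  has_off <- logical(n)
  has_off[setdiff(unique(c(pop$sire, pop$dam)), 0L)] <- TRUE
  keep <- which(pop$phenotyped | has_off)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  ped <- tibble::tibble(
    id = seq_along(keep),
    sire = ifelse(pop$sire[keep] > 0, map[pmax(pop$sire[keep], 1)], 0L),
    dam = ifelse(pop$dam[keep] > 0, map[pmax(pop$dam[keep], 1)], 0L)
  )
  rec$id <- map[rec$id]
  sys <- assemble_mme(ped, rec, panel, f = pop$f[keep])
  fit <- solve_mme(sys, tol = cfg$solver_tol)
  list(
    fit = fit,
    index = function(ids, values) {
      as.numeric(fit$ebv[map[ids], , drop = FALSE] %*% values)
    }
  )
}

#' Truncation selection of the top-k candidates
#'
#' @param candidates Integer ids.
#' @param index Index values aligned with `candidates`.
#' @param k Number to select; exceeding the candidate count is an error
#'   (the configuration is infeasible).
#' @return Sorted ids of the selected animals; ties broken by lower id.
#' @export
truncation_select <- function(candidates, index, k) {
  if (k > length(candidates)) {
    stop("cannot select ", k, " parents from ", length(candidates),
         " candidates")
  }
  ord <- order(-index, candidates)
  sort(candidates[ord[seq_len(k)]])
}

random_select <- function(candidates, k) {
  if (k > length(candidates)) {
    stop("cannot select ", k, " parents from ", length(candidates),
         " candidates")
  }
  sort(candidates[sample.int(length(candidates), k)])
}

# Balanced random allocation of dams to sires, one litter per dam.
make_matings <- function(sires, dams) {
  dams <- dams[sample.int(length(dams))]
  assign <- rep(seq_along(sires), length.out = length(dams))
  tibble::tibble(sire = sires[assign], dam = dams)
}

add_litters <- function(pop, matings, cfg, panel, factors, line, step,
                        phenotype_sexes) {
  lsz <- cfg$litter_size
  nm <- nrow(matings)
  half <- lsz %/% 2
  litter_sex <- function(j) {
    s <- c(rep("M", half), rep("F", half))
    if (lsz %% 2 == 1) s <- c(s, if (j %% 2 == 1) "M" else "F")
    s
  }
  sex <- unlist(lapply(seq_len(nm), litter_sex), use.names = FALSE)
  sire <- rep(matings$sire, each = lsz)
  dam <- rep(matings$dam, each = lsz)
  n_new <- nm * lsz

  tbv <- sample_offspring_tbv(pop$tbv[sire, , drop = FALSE],
                              pop$tbv[dam, , drop = FALSE],
                              pop$f[sire], pop$f[dam],
                              factors, scale = cfg$mendelian_scale)
  f_new <- ped_inbreeding_cpp(c(pop$sire, sire), c(pop$dam, dam), pop$f)
  f_new <- f_new[pop_size(pop) + seq_len(n_new)]

  phen <- logical(n_new)
  for (sx in c("M", "F")) {
    grp <- which(sex == sx)
    if (!length(grp)) next
    frac <- phenotype_sexes[[sx]]
    if (is.null(frac) || frac <= 0) next
    k <- round(frac * length(grp))
    if (k > 0) phen[grp[sample.int(length(grp), k)]] <- TRUE
  }
  obs <- matrix(NA_real_, n_new, ncol(pop$tbv))
  if (any(phen)) {
    obs[phen, ] <- tbv[phen, , drop = FALSE] +
      sample_environment(sum(phen), factors)
  }
  pop_append(pop, sex, rep(line, n_new), rep(step, n_new), sire, dam,
             f_new, phen, tbv, obs)
}

# Cull animals that age out of their last age class at the end of `step`.
# In CS, organic males are slaughtered at candidate age and never selected.
cull_old <- function(pop, cfg, step) {
  age <- step - pop$birth
  max_age <- ifelse(pop$sex == "M", cfg$male_window[2], cfg$female_window[2])
  if (cfg$scheme == "CS") {
    om <- pop$sex == "M" & pop$line == "org"
    max_age[om] <- cfg$male_window[1]
  }
  out <- pop$alive & age >= max_age
  pop$alive[out] <- FALSE
  pop$culled[out] <- step
  pop
}

# ---- per-step drivers -------------------------------------------------------

step_OS <- function(pop, cfg, panel, factors, step, log) {
  mcand <- eligible_candidates(pop, cfg, step, "M", "org")
  fcand <- eligible_candidates(pop, cfg, step, "F", "org")
  if (cfg$selection == "blup") {
    ev <- evaluate_population(pop, cfg, panel, step)
    v <- goal_vector(panel, cfg$goal)
    im <- ev$index(mcand, v)
    iff <- ev$index(fcand, v)
    sires <- truncation_select(mcand, im, cfg$n_sires_org)
    dams <- truncation_select(fcand, iff, cfg$n_dams_org)
    log$selection[[length(log$selection) + 1L]] <- tibble::tibble(
      step = step, line = "org", sex = c("M", "F"),
      n_candidates = c(length(mcand), length(fcand)),
      mean_index_candidates = c(mean(im), mean(iff)),
      mean_index_selected = c(mean(im[mcand %in% sires]),
                              mean(iff[fcand %in% dams]))
    )
  } else {
    sires <- random_select(mcand, cfg$n_sires_org)
    dams <- random_select(fcand, cfg$n_dams_org)
  }
  pop$selected[c(sires, dams)] <- TRUE
  matings <- make_matings(sires, dams)
  log$matings[[length(log$matings) + 1L]] <- dplyr::mutate(
    matings, step = step, line = "org",
    sire_birth = pop$birth[.data$sire], dam_birth = pop$birth[.data$dam]
  )
  pop <- add_litters(pop, matings, cfg, panel, factors, "org", step,
                     list(M = cfg$intensity, F = cfg$intensity))
  pop <- cull_old(pop, cfg, step)
  list(pop = pop, log = log)
}

step_CS <- function(pop, cfg, panel, factors, step, log) {
  mc <- eligible_candidates(pop, cfg, step, "M", "conv")
  fc <- eligible_candidates(pop, cfg, step, "F", "conv")
  fo <- eligible_candidates(pop, cfg, step, "F", "org")

  if (cfg$selection == "blup") {
    ev <- evaluate_population(pop, cfg, panel, step)
    vc <- goal_vector(panel, cfg$goal_conventional)
    vo <- goal_vector(panel, cfg$goal)
    sires_conv <- truncation_select(mc, ev$index(mc, vc), cfg$n_sires_conv)
    dams_conv <- truncation_select(fc, ev$index(fc, vc), cfg$n_dams_conv)
    # organic sires: conventional male candidates not selected above,
    # ranked by the organic goal
    pool <- setdiff(mc, sires_conv)
    sires_org <- truncation_select(pool, ev$index(pool, vo), cfg$n_sires_org)
    dams_org <- truncation_select(fo, ev$index(fo, vo), cfg$n_dams_org)
    log$selection[[length(log$selection) + 1L]] <- tibble::tibble(
      step = step, line = c("conv", "conv", "org", "org"),
      sex = c("M", "F", "M", "F"),
      n_candidates = c(length(mc), length(fc), length(pool), length(fo)),
      mean_index_candidates = c(mean(ev$index(mc, vc)), mean(ev$index(fc, vc)),
                                mean(ev$index(pool, vo)), mean(ev$index(fo, vo))),
      mean_index_selected = c(mean(ev$index(sires_conv, vc)),
                              mean(ev$index(dams_conv, vc)),
                              mean(ev$index(sires_org, vo)),
                              mean(ev$index(dams_org, vo)))
    )
  } else {
    sires_conv <- random_select(mc, cfg$n_sires_conv)
    dams_conv <- random_select(fc, cfg$n_dams_conv)
    pool <- setdiff(mc, sires_conv)
    sires_org <- random_select(pool, cfg$n_sires_org)
    dams_org <- random_select(fo, cfg$n_dams_org)
  }
  pop$selected[c(sires_conv, dams_conv, sires_org, dams_org)] <- TRUE

  m_conv <- make_matings(sires_conv, dams_conv)
  m_org <- make_matings(sires_org, dams_org)
  log$matings[[length(log$matings) + 1L]] <- dplyr::bind_rows(
    dplyr::mutate(m_conv, step = step, line = "conv",
                  sire_birth = pop$birth[.data$sire],
                  dam_birth = pop$birth[.data$dam]),
    dplyr::mutate(m_org, step = step, line = "org",
                  sire_birth = pop$birth[.data$sire],
                  dam_birth = pop$birth[.data$dam])
  )
  pop <- add_litters(pop, m_conv, cfg, panel, factors, "conv", step,
                     list(M = 1, F = 1))
  # organic newborns: only females are phenotyped in CS; males are
  # slaughtered at candidate age
  pop <- add_litters(pop, m_org, cfg, panel, factors, "org", step,
                     list(M = 0, F = cfg$intensity))
  pop <- cull_old(pop, cfg, step)
  list(pop = pop, log = log)
}

# ---- replicate driver -------------------------------------------------------

#' Run one replicate of a breeding-program scenario
#'
#' Simulates the configured scheme over `n_steps` half-year time steps:
#' evaluation (multivariate BLUP over all accumulated records), truncation
#' selection, balanced random mating, litter sampling, phenotyping, and
#' age-based culling, starting from an unrelated base population.
#'
#' @param cfg A [scheme_config()].
#' @param panel A [trait_panel()].
#' @return An object of class `replicate_result`: tibbles `animals` (the
#'   full pedigree with sex, line, birth step, inbreeding, flags and TBV
#'   columns), `trajectory` (per step and line: size, mean inbreeding, mean
#'   TBV per trait), `matings`, `selection` (per-step candidate/selected
#'   index means under BLUP selection), and the `config`.
#' @examples
#' \donttest{
#' panel <- trait_panel()
#' cfg <- scheme_config("OS", "curOBG", intensity = 1, n_steps = 4,
#'                      n_sires_org = 4, n_dams_org = 12, litter_size = 4,
#'                      seed = 42)
#' res <- run_replicate(cfg, panel)
#' res$trajectory
#' }
#' @export
run_replicate <- function(cfg, panel) {
  stopifnot(inherits(cfg, "scheme_config"))
  set.seed(cfg$seed)
  factors <- chol_factors(panel)
  pop <- initialize_base_population(cfg, panel, factors)
  log <- list(matings = list(), selection = list())
  traj <- list()
  step_fn <- if (cfg$scheme == "OS") step_OS else step_CS

  for (t in seq_len(cfg$n_steps)) {
    out <- step_fn(pop, cfg, panel, factors, t, log)
    pop <- out$pop
    log <- out$log
    for (ln in unique(pop$line)) {
      al <- pop$alive & pop$line == ln
      traj[[length(traj) + 1L]] <- tibble::tibble(
        step = t, year = t / 2, line = ln, n_alive = sum(al),
        mean_f = mean(pop$f[al]),
        !!!setNames(as.list(colMeans(pop$tbv[al, , drop = FALSE])),
                    paste0("tbv_", panel$traits$code))
      )
    }
  }

  animals <- tibble::tibble(
    id = seq_len(pop_size(pop)), sex = pop$sex, line = pop$line,
    birth = pop$birth, sire = pop$sire, dam = pop$dam, f = pop$f,
    phenotyped = pop$phenotyped, selected = pop$selected,
    alive = pop$alive, culled = pop$culled
  )
  tbv_tab <- tibble::as_tibble(pop$tbv, .name_repair = "minimal")
  names(tbv_tab) <- paste0("tbv_", panel$traits$code)
  animals <- dplyr::bind_cols(animals, tbv_tab)

  structure(
    list(animals = animals,
         trajectory = dplyr::bind_rows(traj),
         matings = dplyr::bind_rows(log$matings),
         selection = dplyr::bind_rows(log$selection),
         config = cfg),
    class = "replicate_result"
  )
}

#' @export
print.replicate_result <- function(x, ...) {
  cfg <- x$config
  cat("<replicate_result> ", cfg$scheme, "/", cfg$goal, " intensity ",
      cfg$intensity, ", ", cfg$n_steps, " steps, ",
      nrow(x$animals), " animals (seed ", cfg$seed, ")\n", sep = "")
  invisible(x)
}
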