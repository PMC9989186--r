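# Synthetic EMR generator with Gompertz-Makeham ground-truth mortality.
#
# Hazard per group: h(t) = lambda + alpha * exp(beta t) + excess * 1{t < 1}
# (Makeham background + Gompertz senescence + first-year excess), the
# canonical mammalian shape able to mimic the published U-shaped q(x):
# elevated q(0), minimum at 1-3 years, exponential rise thereafter.
#
# Visit histories: first clinic visit at a young age (vaccination visit),
# then log-normal inter-visit gaps parameterised by their median. Each
# visit carries a per-visit probability of permanent dropout (client
# churn); a death is clinically recorded only if the pet was still an
# active patient and with probability death_recording_prob. Unrecorded
# deaths and dropped-out survivors produce the "excluded" class during
# cohort construction, exactly as in the clinical data.

cumulative_hazard <- function(t, lambda, alpha, beta, excess) {
  g <- if (beta > 0) alpha / beta * (exp(beta * t) - 1) else alpha * t
  lambda * t + g + excess * pmin(t, 1)
}

#' Analytic life expectancy of a Gompertz-Makeham-plus-excess hazard
#'
#' e(x) = integral_x^Inf S(t) dt / S(x) with S(t) = exp(-H(t)), evaluated
#' by adaptive quadrature.
#'
#' @param params list with `lambda`, `alpha`, `beta`, `excess`
#'   (all per-year rates; `beta` may be 0 for pure exponential).
#' @param x age (years) at which remaining life expectancy is taken.
#' @return expected remaining years of life at age `x`.
#' @export
analytic_life_expectancy <- function(params, x = 0) {
  p <- params
  if (p$lambda + p$alpha + p$excess <= 0)
    stop("hazard is zero everywhere: immortal pets, divergent integral")
  Sx <- exp(-cumulative_hazard(x, p$lambda, p$alpha, p$beta, p$excess))
  # upper limit where survival is numerically zero
  upper <- x + 1
  while (cumulative_hazard(upper, p$lambda, p$alpha, p$beta, p$excess) < 45 &&
         upper < 1e4) upper <- upper * 2
  if (upper >= 1e4 &&
      cumulative_hazard(upper, p$lambda, p$alpha, p$beta, p$excess) < 45)
    stop("hazard too small; life-expectancy integral effectively divergent")
  integrate(function(t)
    exp(-cumulative_hazard(t, p$lambda, p$alpha, p$beta, p$excess)) / Sx,
    x, upper, rel.tol = 1e-10)$value
}

#' Analytic conditional death probabilities q(x) of a scenario hazard
#'
#' @param params hazard parameter list (see [analytic_life_expectancy()]).
#' @param ages integer vector of exact ages x; returns
#'   q(x) = 1 - S(x+1)/S(x).
#' @export
analytic_death_probability <- function(params, ages) {
  p <- params
  Hx  <- cumulative_hazard(ages,     p$lambda, p$alpha, p$beta, p$excess)
  Hx1 <- cumulative_hazard(ages + 1, p$lambda, p$alpha, p$beta, p$excess)
  1 - exp(-(Hx1 - Hx))
}

# inverse-transform sampling of death ages: solve H(t) = E, E ~ Exp(1),
# by vectorised bisection (H is strictly increasing)
draw_death_ages <- function(n, lambda, alpha, beta, excess, t_max = 500) {
  if (lambda + alpha + excess <= 0)
    stop("hazard is zero everywhere: immortal pets")
  E <- rexp(n)
  if (cumulative_hazard(t_max, lambda, alpha, beta, excess) < max(E))
    stop("hazard too small to produce finite lifetimes within ", t_max, " years")
  lo <- numeric(n); hi <- rep(t_max, n)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    below <- cumulative_hazard(mid, lambda, alpha, beta, excess) < E
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Default per-group hazard and bodyweight parameters
#'
#' One mortality group per species, calibrated by eye to the magnitude of
#' the published global tables (dog e(0) about 12.9 years with q(0) about
#' 0.027; cat about 11.1 years with q(0) about 0.055).
#'
#' @param species "dog" or "cat".
#' @return data.table of group parameters usable as `groups` in
#'   [sim_scenario()].
#' @export
default_groups <- function(species = c("dog", "cat")) {
  species <- match.arg(species)
  if (species == "dog")
    data.table(name = "dog", species = "dog", breed = "mixed breed",
               proportion = 1, lambda = 0.0045, alpha = 0.001, beta = 0.40,
               excess = 0.021, bw_mean_kg = 20)
  else
    data.table(name = "cat", species = "cat", breed = "Domestic Short Hair",
               proportion = 1, lambda = 0.025, alpha = 0.001, beta = 0.40,
               excess = 0.030, bw_mean_kg = 4.5)
}

#' Simulation scenario
#'
#' Defaults emulate the descriptive structure of the clinical dataset the
#' pipeline was designed for: median inter-visit gap 70 days (dogs) or 90
#' days (cats); first clinic visit at a median age of 0.15 years (the first
#' vaccination visit); per-visit client dropout and a death-recording
#' probability jointly producing roughly a quarter (dogs) / a third (cats)
#' of active pets per year whose status cannot be confirmed; median BCS 3
#' for about 73% of dogs and 59% of cats with obesity prevalence 1.5% /
#' 3.6%; male fraction 0.52 / 0.498; cleaning-defect rates of 1.74% / 1.82%.
#'
#' @param n_pets number of pets to simulate.
#' @param species "dog" or "cat" (sets all species-level defaults).
#' @param groups data.table of mortality groups (columns `name`, `species`,
#'   `breed`, `proportion`, `lambda`, `alpha`, `beta`, `excess`,
#'   `bw_mean_kg`); proportions must sum to 1.
#' @param gap_median_days median inter-visit gap.
#' @param gap_sdlog log-scale SD of the log-normal gap distribution.
#' @param first_visit_median_years,first_visit_sdlog log-normal first-visit
#'   age.
#' @param death_recording_prob probability an active patient's death enters
#'   the record.
#' @param dropout_prob per-visit probability the client never returns.
#' @param bcs_probs length-5 probability vector over median BCS 1..5.
#' @param male_prob male sex ratio.
#' @param birth_window two dates bounding birth dates (uniform).
#' @param dataset_start,horizon_end EMR coverage window; only visits and
#'   deaths inside it are serialised.
#' @param scale9_after visits on/after this date report BCS on the 9-point
#'   scale.
#' @param defect_rate fraction of pets given one injected cleaning defect.
#' @param seed RNG seed.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_pets = 20000,
                         species = c("dog", "cat"),
                         groups = default_groups(species),
                         gap_median_days = if (species == "dog") 70 else 90,
                         gap_sdlog = 1.0,
                         first_visit_median_years = 0.15,
                         first_visit_sdlog = 0.75,
                         death_recording_prob = if (species == "dog") 0.75 else 0.66,
                         dropout_prob = if (species == "dog") 0.08 else 0.14,
                         bcs_probs = if (species == "dog")
                             c(0.005, 0.030, 0.727, 0.223, 0.015)
                           else c(0.010, 0.050, 0.585, 0.319, 0.036),
                         male_prob = if (species == "dog") 0.52 else 0.498,
                         birth_window = c("1996-01-01", "2021-12-31"),
                         dataset_start = "2013-01-01",
                         horizon_end = "2022-07-31",
                         scale9_after = "2018-06-01",
                         defect_rate = if (species == "dog") 0.0174 else 0.0182,
                         seed = 1L) {
  species <- match.arg(species)
  groups <- as.data.table(groups)
  stopifnot(abs(sum(groups$proportion) - 1) < 1e-8,
            all(groups$lambda >= 0), all(groups$alpha >= 0),
            all(groups$beta >= 0), all(groups$excess >= 0),
            abs(sum(bcs_probs) - 1) < 1e-8, length(bcs_probs) == 5,
            gap_median_days > 0, defect_rate >= 0, defect_rate < 1,
            death_recording_prob >= 0, death_recording_prob <= 1,
            dropout_prob >= 0, dropout_prob < 1)
  structure(list(n_pets = as.integer(n_pets), species = species,
                 groups = groups, gap_median_days = gap_median_days,
                 gap_sdlog = gap_sdlog,
                 first_visit_median_years = first_visit_median_years,
                 first_visit_sdlog = first_visit_sdlog,
                 death_recording_prob = death_recording_prob,
                 dropout_prob = dropout_prob, bcs_probs = bcs_probs,
                 male_prob = male_prob,
                 birth_window = as.Date(birth_window),
                 dataset_start = as.Date(dataset_start),
                 horizon_end = as.Date(horizon_end),
                 scale9_after = as.Date(scale9_after),
                 defect_rate = defect_rate, seed = as.integer(seed)),
            class = "sim_scenario")
}

# representative 5-point -> 9-point values (convert_bcs maps them back
# exactly: 1->1, 3->2, 4->3, 6->4, 8->5)
BCS_5_TO_9_REP <- c(1L, 3L, 4L, 6L, 8L)

#' Simulate an EMR-like visit dataset with known ground truth
#'
#' Death ages are drawn from the group hazard by inverse-transform
#' sampling; visit histories run from the first-visit age until death or
#' client dropout; deaths of active patients are recorded with
#' `death_recording_prob`; only visits (and recorded deaths) inside the
#' EMR coverage window are serialised; cleaning defects are injected at
#' `defect_rate`. Fully reproducible given the scenario seed.
#'
#' @param scenario `sim_scenario`.
#' @return list with `records` (validated visit-record table), `truth`
#'   (per-pet death ages and per-group analytic e(0) and q(x)), and
#'   `scenario`.
#' @export
simulate_population <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  n <- sc$n_pets
  g <- sc$groups
  grp <- sample.int(nrow(g), n, replace = TRUE, prob = g$proportion)

  death_age <- numeric(n)
  for (j in seq_len(nrow(g))) {
    idx <- which(grp == j)
    if (length(idx))
      death_age[idx] <- draw_death_ages(length(idx), g$lambda[j], g$alpha[j],
                                        g$beta[j], g$excess[j])
  }
  birth <- sc$birth_window[1] +
    floor(runif(n, 0, as.numeric(diff(sc$birth_window)) + 1))
  sex <- ifelse(runif(n) < sc$male_prob, "male", "female")
  bcs_cat <- sample.int(5L, n, replace = TRUE, prob = sc$bcs_probs)
  bw <- exp(log(g$bw_mean_kg[grp]) + rnorm(n, 0, 0.15))

  # visit process: rounds of log-normal gaps until death or dropout
  first_age <- rlnorm(n, log(sc$first_visit_median_years), sc$first_visit_sdlog)
  meanlog_gap <- log(sc$gap_median_days / 365.25)
  t_cur <- first_age
  alive_at_visit <- t_cur < death_age
  active <- alive_at_visit                       # pets still visiting
  dropped_before_death <- rep(FALSE, n)
  visit_pet <- vector("list", 256L); visit_age <- vector("list", 256L)
  round_i <- 0L
  while (any(active)) {
    round_i <- round_i + 1L
    if (round_i > length(visit_pet)) {           # grow collectors
      visit_pet <- c(visit_pet, vector("list", length(visit_pet)))
      visit_age <- c(visit_age, vector("list", length(visit_age)))
    }
    ids <- which(active)
    visit_pet[[round_i]] <- ids
    visit_age[[round_i]] <- t_cur[ids]
    drop_now <- runif(length(ids)) < sc$dropout_prob
    dropped_before_death[ids[drop_now]] <- TRUE
    active[ids[drop_now]] <- FALSE
    ids <- ids[!drop_now]
    if (length(ids)) {
      t_cur[ids] <- t_cur[ids] + rlnorm(length(ids), meanlog_gap, sc$gap_sdlog)
      dead_now <- t_cur[ids] >= death_age[ids]
      active[ids[dead_now]] <- FALSE
    }
  }
  visits <- data.table(idx = unlist(visit_pet), age = unlist(visit_age))
  setorder(visits, idx, age)

  # a death is recorded only for pets still active patients at death
  death_recorded <- !dropped_before_death & alive_at_visit &
    runif(n) < sc$death_recording_prob
  death_date <- as.Date(ifelse(death_recorded,
                               birth + round(death_age * 365.25),
                               NA), origin = "1970-01-01")

  visits[, visit_date := birth[idx] + round(age * 365.25)]
  # recorded death date must not precede the last visit (rounding guard)
  visits[!is.na(death_date[idx]) & visit_date > death_date[idx],
         visit_date := death_date[idx]]
  # EMR coverage window
  visits <- visits[visit_date >= sc$dataset_start & visit_date <= sc$horizon_end]
  death_in_window <- !is.na(death_date) &
    death_date >= sc$dataset_start & death_date <= sc$horizon_end
  death_date[!death_in_window] <- NA
  keep <- sort(unique(c(visits$idx, which(death_in_window))))
  # deceased pets keep a terminal record at the death date (the visit at
  # which the death was recorded), so every kept pet has >= 1 row
  terminal <- data.table(idx = which(death_in_window),
                         age = death_age[death_in_window])
  terminal[, visit_date := death_date[idx]]
  visits <- rbind(visits, terminal)
  setorder(visits, idx, visit_date)

  per_visit_bcs <- function(k, cat5) {
    jitter <- sample(c(-1L, 0L, 1L), k, replace = TRUE, prob = c(0.1, 0.8, 0.1))
    pmin(pmax(cat5 + jitter, 1L), 5L)
  }
  visits[, bcs5 := per_visit_bcs(.N, bcs_cat[idx])]
  visits[, bcs_scale := fifelse(visit_date >= sc$scale9_after, 9L, 5L)]
  visits[, bcs_value := fifelse(bcs_scale == 9L, BCS_5_TO_9_REP[bcs5], bcs5)]

  records <- visits[, .(
    pet_id = sprintf("pet%06d", idx),
    species = g$species[grp[idx]],
    breed = g$breed[grp[idx]],
    sex = sex[idx],
    birth_date = birth[idx],
    death_date = death_date[idx],
    visit_date = visit_date,
    bodyweight_kg = bw[idx],
    bcs_value, bcs_scale)]

  # inject cleaning defects on a random subset of kept pets
  if (sc$defect_rate > 0 && length(keep)) {
    n_def <- round(sc$defect_rate * length(keep))
    if (n_def > 0) {
      def_ids <- sprintf("pet%06d", sample(keep, n_def))
      kinds <- rep_len(c("no_birth", "anomalous", "too_old", "no_sex", "no_bcs"),
                       n_def)
      for (k in seq_len(n_def)) {
        id <- def_ids[k]
        switch(kinds[k],
          no_birth  = records[pet_id == id, birth_date := as.Date(NA)],
          anomalous = records[pet_id == id,
                              death_date := min(visit_date) - 30L],
          too_old   = records[pet_id == id,
                              birth_date := birth_date - 35L * 365L],
          no_sex    = records[pet_id == id, sex := NA_character_],
          no_bcs    = records[pet_id == id,
                              `:=`(bcs_value = NA_integer_,
                                   bcs_scale = NA_integer_)])
      }
      defects <- data.table(pet_id = def_ids, defect = kinds)
    } else defects <- data.table(pet_id = character(), defect = character())
  } else defects <- data.table(pet_id = character(), defect = character())

  group_truth <- g[, .(name, species, lambda, alpha, beta, excess, proportion)]
  group_truth[, e0_analytic := vapply(seq_len(.N), function(j)
    analytic_life_expectancy(list(lambda = lambda[j], alpha = alpha[j],
                                  beta = beta[j], excess = excess[j])),
    numeric(1))]

  truth <- list(
    pets = data.table(pet_id = sprintf("pet%06d", seq_len(n)),
                      group = g$name[grp], death_age = death_age,
                      death_recorded = death_recorded,
                      dropped_before_death = dropped_before_death,
                      median_bcs_true = bcs_cat)[pet_id %in% records$pet_id],
    groups = group_truth,
    defects = defects,
    e0_population = sum(group_truth$proportion * group_truth$e0_analytic))

  list(records = visit_records(records), truth = truth, scenario = sc)
}

#' Mixture q(x) implied by a scenario's group hazards
#'
#' Population-level conditional death probabilities of the scenario mixture
#' (survival-weighted across groups).
#'
#' @param scenario `sim_scenario`.
#' @param ages integer ages.
#' @export
scenario_death_probability <- function(scenario, ages) {
  g <- scenario$groups
  Smix <- function(t) {
    s <- 0
    for (j in seq_len(nrow(g)))
      s <- s + g$proportion[j] *
        exp(-cumulative_hazard(t, g$lambda[j], g$alpha[j], g$beta[j], g$excess[j]))
    s
  }
  1 - Smix(ages + 1) / Smix(ages)
}

#' End-to-end parameter-recovery experiment
#'
#' Runs simulate -> clean -> per-year cohorts -> pooled counts -> life
#' table, and compares the estimated life expectancy at birth and q(x)
#' against the analytic ground truth of the generating hazard. Requires
#' full death recording (the calibration condition under which the
#' estimator should be unbiased); censoring biases can be studied by
#' relaxing it and inspecting the report.
#'
#' @param scenario `sim_scenario` with `death_recording_prob = 1`.
#' @param survey_years integer years to pool (default 2013:2019).
#' @param terminal_age open-interval age (default 17).
#' @param require_full_recording error if the scenario records deaths
#'   with probability < 1 (set `FALSE` to study censoring bias).
#' @return list with `e0_hat`, `e0_true`, `e0_error`, `q_hat`, `q_true`,
#'   `lifetable`, `cleaning_report`, `n_excluded_by_year`.
#' @export
recovery_experiment <- function(scenario, survey_years = 2013:2019,
                                terminal_age = 17L,
                                require_full_recording = TRUE) {
  if (require_full_recording && scenario$death_recording_prob < 1)
    stop("recovery_experiment requires death_recording_prob = 1 ",
         "(set require_full_recording = FALSE to study censoring bias)")
  sim <- simulate_population(scenario)
  cleaned <- clean_records(sim$records)
  pops <- lapply(survey_years, function(y)
    build_study_population(cleaned$records, y,
                           horizon_end = scenario$horizon_end))
  counts <- pool_counts(lapply(pops, tabulate_counts,
                               terminal_age = terminal_age))
  lt <- build_life_table(counts)
  e0_true <- sim$truth$e0_population
  ages <- seq_len(nrow(lt)) - 1L
  list(e0_hat = life_expectancy_at_birth(lt),
       e0_true = e0_true,
       e0_error = life_expectancy_at_birth(lt) - e0_true,
       q_hat = lt$q,
       q_true = scenario_death_probability(scenario, ages),
       lifetable = lt,
       cleaning_report = cleaned$report,
       n_excluded_by_year = setNames(vapply(pops, `[[`, numeric(1),
                                            "n_excluded"),
                                     survey_years))
}
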