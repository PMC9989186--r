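# Survey-year cohort construction and age-interval tabulation.
#
# For a survey year Y the study population is:
#   deceased  - pets with a recorded death date inside Y;
#   survivors - pets with >=1 visit in Y, no death in Y, confirmed alive
#               afterwards (a visit in a strictly later calendar year up to
#               the horizon, or a death date in a later year);
#   excluded  - pets active in Y with no recorded death and no later visit:
#               their status is unknowable (right censoring).

#' Build the deceased/survivor study population for one survey year
#'
#' At least two full calendar years of follow-up after the survey year must
#' exist before the horizon, otherwise an error is raised.
#'
#' @param records cleaned visit-record table.
#' @param survey_year calendar year (integer).
#' @param horizon_end last date of data used to confirm survivors
#'   (Date or ISO string).
#' @param midyear_month_day month-day string ("07-01") at which survivor
#'   ages are taken.
#' @return object of class `study_population`: list with `survey_year`,
#'   `deceased` and `survivors` (data.tables of `pet_id`, `age` in completed
#'   years), and `n_excluded`.
#' @export
build_study_population <- function(records, survey_year,
                                   horizon_end = "2022-07-31",
                                   midyear_month_day = "07-01") {
  horizon_end <- as.Date(horizon_end)
  two_year_mark <- as.Date(sprintf("%d-12-31", survey_year + 2))
  if (two_year_mark > horizon_end)
    stop("survey year ", survey_year, " violates the two-year follow-up rule: ",
         "at least two full calendar years of data after the survey year ",
         "are required before the horizon (", horizon_end, ")")
  dt <- as.data.table(records)
  yr_start <- as.Date(sprintf("%d-01-01", survey_year))
  yr_end   <- as.Date(sprintf("%d-12-31", survey_year))
  midyear  <- as.Date(sprintf("%d-%s", survey_year, midyear_month_day))

  pets <- dt[, .(
    birth_date = birth_date[1],
    death_date = death_date[1],
    visited_in_year = any(visit_date >= yr_start & visit_date <= yr_end),
    later_visit = any(visit_date > yr_end & visit_date <= horizon_end)
  ), by = pet_id]

  died_in_year <- !is.na(pets$death_date) &
    pets$death_date >= yr_start & pets$death_date <= yr_end
  died_later <- !is.na(pets$death_date) & pets$death_date > yr_end

  deceased <- pets[died_in_year]
  deceased <- deceased[, .(pet_id, age = age_in_years(birth_date, death_date))]

  surv <- pets[!died_in_year & visited_in_year & (later_visit | died_later)]
  # pets born after the mid-year point are in their first year of life
  survivors <- surv[, .(pet_id, age = pmax(age_in_years(birth_date, midyear), 0L))]

  n_excluded <- pets[!died_in_year & !died_later & visited_in_year &
                       !later_visit & is.na(death_date), .N]

  structure(list(survey_year = survey_year,
                 deceased = deceased[],
                 survivors = survivors[],
                 n_excluded = n_excluded),
            class = "study_population")
}

#' @export
print.study_population <- function(x, ...) {
  cat(sprintf("Study population %d: %d deceased, %d survivors, %d excluded\n",
              x$survey_year, nrow(x$deceased), nrow(x$survivors), x$n_excluded))
  invisible(x)
}

#' Construct a counts vector
#'
#' Per-interval mid-year population P(x) and deaths d(x) over 1-year
#' intervals 0..(terminal_age-1) plus the open terminal interval.
#'
#' @param P,d non-negative integer vectors, `d <= P` element-wise; length
#'   `terminal_age + 1`.
#' @param terminal_age first age of the open interval (default 17).
#' @return object of class `counts_vector`: data.table with columns
#'   `age_interval`, `P`, `d`, attribute `terminal_age`.
#' @export
counts_vector <- function(P, d, terminal_age = length(P) - 1L) {
  P <- as.numeric(P); d <- as.numeric(d)
  if (length(P) != length(d)) stop("P and d must have equal length")
  if (length(P) != terminal_age + 1L)
    stop("need terminal_age + 1 intervals (ages 0..", terminal_age, ")")
  if (any(P < 0) || any(d < 0)) stop("counts must be non-negative")
  if (any(d > P)) stop("d(x) cannot exceed P(x)")
  ages <- seq_len(length(P)) - 1L
  labels <- c(sprintf("%d-%d", head(ages, -1L), head(ages, -1L) + 1L),
              sprintf("%d+", terminal_age))
  out <- data.table(age_interval = labels, P = P, d = d)
  setattr(out, "terminal_age", as.integer(terminal_age))
  setattr(out, "class", c("counts_vector", class(out)))
  out[]
}

#' Tabulate a study population into age-interval counts
#'
#' Deceased pets are binned by completed age at death; survivors by
#' completed age at the survey-year mid-year point. Ages at or above
#' `terminal_age` pool into the open interval. `P = deceased + survivors`
#' per interval, `d = deceased`.
#'
#' @param pop `study_population`.
#' @param terminal_age first age of the open terminal interval.
#' @return `counts_vector`.
#' @export
tabulate_counts <- function(pop, terminal_age = 17L) {
  ages_d <- pop$deceased$age
  ages_s <- pop$survivors$age
  if (any(c(ages_d, ages_s) < 0))
    stop("negative age encountered; records should have been cleaned")
  bin <- function(a) tabulate(pmin(a, terminal_age) + 1L, nbins = terminal_age + 1L)
  d <- bin(ages_d)
  P <- d + bin(ages_s)
  counts_vector(P, d, terminal_age = terminal_age)
}

#' Pool counts vectors element-wise
#'
#' @param vectors list of `counts_vector`s with identical interval structure.
#' @return `counts_vector` of element-wise sums.
#' @export
pool_counts <- function(vectors) {
  if (!length(vectors)) stop("nothing to pool")
  terms <- vapply(vectors, function(v) attr(v, "terminal_age"), integer(1))
  if (length(unique(terms)) != 1L)
    stop("cannot pool counts with different terminal ages: ",
         paste(unique(terms), collapse = ", "))
  P <- Reduce(`+`, lapply(vectors, `[[`, "P"))
  d <- Reduce(`+`, lapply(vectors, `[[`, "d"))
  counts_vector(P, d, terminal_age = terms[1])
}

#' Read / write counts vectors as CSV
#'
#' The CSV has columns `age_interval` (e.g. "0-1", ..., "17+"), `P`, `d`;
#' this is also the fixture format for the packaged published tables.
#'
#' @param path CSV path.
#' @return `counts_vector`.
#' @export
read_counts_csv <- function(path) {
  dt <- fread(path, select = c("age_interval", "P", "d"))
  terminal_age <- as.integer(sub("\\+$", "", tail(dt$age_interval, 1)))
  counts_vector(dt$P, dt$d, terminal_age = terminal_age)
}

#' @rdname read_counts_csv
#' @param counts `counts_vector` to write.
#' @export
write_counts_csv <- function(counts, path) {
  fwrite(as.data.table(counts)[, .(age_interval, P, d)], path)
  invisible(path)
}

#' Published global counts fixtures
#'
#' Returns the P(x), d(x) columns of the published global life tables for
#' dogs or cats (survey years 2013-2019 pooled) shipped with the package.
#'
#' @param species "dog" or "cat".
#' @return `counts_vector`.
#' @export
published_counts <- function(species = c("dog", "cat")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0(species, "_global_lifetable.csv"),
                      package = "petlifetab", mustWork = TRUE)
  read_counts_csv(path)
}

#' Published global life tables (all columns, as printed)
#'
#' @param species "dog" or "cat".
#' @return data.table of the full published table (display precision).
#' @export
published_lifetable <- function(species = c("dog", "cat")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0(species, "_global_lifetable.csv"),
                      package = "petlifetab", mustWork = TRUE)
  fread(path)
}

#' Filter records to a subpopulation stratum
#'
#' Filters are conjunctive. Breed heritage: dogs are mixed-breed iff the
#' breed label is "mixed breed"; cats iff it is one of the Domestic
#' Short/Medium/Long Hair labels.
#'
#' @param records cleaned visit-record table.
#' @param species optional "dog"/"cat".
#' @param sex optional "male"/"female".
#' @param size_group optional size-group label; requires `size_map`.
#' @param bcs optional median BCS 1..5; requires `bcs_table`.
#' @param heritage optional "purebred"/"mixed breed".
#' @param size_map `size_group_map` from [assign_size_groups()].
#' @param bcs_table per-pet median BCS from [pet_median_bcs()].
#' @return filtered visit-record table (possibly empty, with a warning).
#' @export
stratify <- function(records, species = NULL, sex = NULL, size_group = NULL,
                     bcs = NULL, heritage = NULL,
                     size_map = NULL, bcs_table = NULL) {
  dt <- as.data.table(records)
  sel <- rep(TRUE, nrow(dt))
  if (!is.null(species)) sel <- sel & dt[["species"]] == species
  if (!is.null(sex))     sel <- sel & !is.na(dt[["sex"]]) & dt[["sex"]] == sex
  if (!is.null(heritage)) {
    mixed <- (dt[["species"]] == "dog" & dt[["breed"]] == "mixed breed") |
             (dt[["species"]] == "cat" & dt[["breed"]] %in% CAT_MIXED_BREEDS)
    sel <- sel & if (heritage == "mixed breed") mixed else !mixed
  }
  if (!is.null(size_group)) {
    if (is.null(size_map)) stop("size_group filter requires size_map")
    keep_breeds <- size_map[["breed"]][size_map[["size_group"]] == size_group]
    sel <- sel & dt[["breed"]] %in% keep_breeds
  }
  if (!is.null(bcs)) {
    if (is.null(bcs_table)) stop("bcs filter requires bcs_table")
    keep_ids <- bcs_table[["pet_id"]][bcs_table[["median_bcs"]] == as.integer(bcs)]
    sel <- sel & dt[["pet_id"]] %in% keep_ids
  }
  out <- dt[which(sel)]
  if (!nrow(out)) warning("stratum is empty")
  out[]
}
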