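#' @import data.table
#' @importFrom stats median quantile rbinom rexp rlnorm rnorm runif sd integrate setNames
#' @importFrom utils head tail
NULL

# columns every visit-record table must carry, in canonical order
VISIT_COLUMNS <- c("pet_id", "species", "breed", "sex", "birth_date",
                   "death_date", "visit_date", "bodyweight_kg",
                   "bcs_value", "bcs_scale")

# cat breed labels that denote mixed breed
CAT_MIXED_BREEDS <- c("Domestic Short Hair", "Domestic Long Hair",
                      "Domestic Medium Hair")

#' Assemble and validate a visit-record table
#'
#' One row per clinical visit of one pet. Pet-level attributes (species,
#' breed, sex, birth and death dates) must be constant within a `pet_id`;
#' `visit_date` must be present on every row; a body condition score, when
#' present, must lie within its declared scale (5- or 9-point).
#'
#' @param df data.frame with columns `pet_id`, `species` ("dog"/"cat"),
#'   `breed`, `sex` ("male"/"female" or `NA`), `birth_date`, `death_date`,
#'   `visit_date` (Date or ISO-8601 strings), `bodyweight_kg`, `bcs_value`,
#'   `bcs_scale` (5 or 9).
#' @return a `data.table` with canonical column order and types.
#' @export
visit_records <- function(df) {
  dt <- as.data.table(df)
  missing_cols <- setdiff(VISIT_COLUMNS, names(dt))
  if (length(missing_cols))
    stop("visit records missing columns: ", paste(missing_cols, collapse = ", "))
  dt <- dt[, VISIT_COLUMNS, with = FALSE]
  for (col in c("birth_date", "death_date", "visit_date"))
    if (!inherits(dt[[col]], "Date")) set(dt, j = col, value = as.Date(as.character(dt[[col]])))
  dt[, pet_id := as.character(pet_id)]
  dt[, species := as.character(species)]
  dt[, breed := as.character(breed)]
  dt[, sex := as.character(sex)]
  dt[, bodyweight_kg := as.numeric(bodyweight_kg)]
  dt[, bcs_value := as.integer(bcs_value)]
  dt[, bcs_scale := as.integer(bcs_scale)]
  validate_visit_records(dt)
  dt[]
}

validate_visit_records <- function(dt) {
  if (anyNA(dt$visit_date))
    stop("every record must have a visit_date")
  bad_sp <- setdiff(unique(dt$species), c("dog", "cat"))
  if (length(bad_sp))
    stop("unknown species: ", paste(bad_sp, collapse = ", "))
  has_bcs <- !is.na(dt$bcs_value)
  if (any(has_bcs & is.na(dt$bcs_scale)))
    stop("bcs_value present without bcs_scale")
  if (any(has_bcs & !(dt$bcs_scale %in% c(5L, 9L))))
    stop("bcs_scale must be 5 or 9")
  out_of_range <- has_bcs & (dt$bcs_value < 1L | dt$bcs_value > dt$bcs_scale)
  if (any(out_of_range))
    stop(sum(out_of_range), " BCS values outside their declared scale")
  if (any(!is.na(dt$bodyweight_kg) & dt$bodyweight_kg <= 0))
    stop("bodyweight_kg must be positive when present")
  # pet-level attributes constant within pet
  n_distinct <- dt[, lapply(.SD, function(z) uniqueN(z, na.rm = FALSE)),
                   by = pet_id,
                   .SDcols = c("species", "breed", "sex", "birth_date", "death_date")]
  bad <- n_distinct[species > 1L | breed > 1L | sex > 1L |
                      birth_date > 1L | death_date > 1L]
  if (nrow(bad))
    stop("pet-level attributes differ across visits for pets: ",
         paste(head(bad$pet_id, 5), collapse = ", "))
  invisible(dt)
}

#' Read visit records from CSV
#'
#' Expects the documented header (`pet_id, species, breed, sex, birth_date,
#' death_date, visit_date, bodyweight_kg, bcs_value, bcs_scale`), ISO-8601
#' dates, and the empty string for missing values.
#'
#' @param path CSV file path.
#' @return validated visit-record `data.table`.
#' @export
read_visit_records <- function(path) {
  dt <- fread(path, na.strings = c("", "NA"), colClasses = list(character = "pet_id"))
  visit_records(dt)
}

#' Write visit records to CSV
#'
#' @param records visit-record table.
#' @param path output CSV path; missing values are written as empty strings.
#' @return `path`, invisibly.
#' @export
write_visit_records <- function(records, path) {
  fwrite(as.data.table(records)[, VISIT_COLUMNS, with = FALSE], path, na = "")
  invisible(path)
}

#' Age in completed years
#'
#' Calendar-based completed years: the year difference, minus one if the
#' anniversary has not yet been reached. Leap-safe (a Feb 29 birthday
#' completes on Mar 1 in common years) and exact on anniversaries, unlike
#' day-count division by 365.25.
#'
#' @param from,to Dates (recycled to a common length).
#' @return integer vector of completed years (negative if `to` < `from`).
#' @export
age_in_years <- function(from, to) {
  n <- max(length(from), length(to))
  from <- rep_len(from, n); to <- rep_len(to, n)
  f <- as.POSIXlt(from); t <- as.POSIXlt(to)
  age <- (t$year - f$year) -
    ((t$mon < f$mon) | (t$mon == f$mon & t$mday < f$mday))
  as.integer(age)
}

#' Clean a visit-record table
#'
#' Removes whole pets (all their visits) that violate any of four rules,
#' applied in order; a pet failing several rules is counted under the first:
#' 1. no recorded birth date;
#' 2. anomalous dates (a visit before birth, or after the death date);
#' 3. any visit at an age above `max_age_years` (default 30);
#' 4. incomplete data: missing sex, or no BCS observation at all.
#'
#' Cleaning never fails; an empty result is allowed. The attached report
#' gives per-rule removal counts.
#'
#' @param records visit-record table.
#' @param max_age_years oldest plausible visit age in years.
#' @return list with elements `records` (the cleaned table) and `report`
#'   (a `cleaning_report`).
#' @export
clean_records <- function(records, max_age_years = 30) {
  dt <- as.data.table(records)
  per_pet <- dt[, .(
    no_birth  = anyNA(birth_date),
    anomalous = any(!is.na(birth_date) & visit_date < birth_date) ||
                any(!is.na(death_date) & visit_date > death_date),
    too_old   = any(!is.na(birth_date) &
                      age_in_years(birth_date, visit_date) > max_age_years),
    incomplete = anyNA(sex) || !any(!is.na(bcs_value))
  ), by = pet_id]
  per_pet[, reason := fifelse(no_birth, "no_birth",
                       fifelse(anomalous, "anomalous",
                        fifelse(too_old, "too_old",
                         fifelse(incomplete, "incomplete", "keep"))))]
  keep_ids <- per_pet[reason == "keep", pet_id]
  report <- structure(list(
    n_input_pets            = nrow(per_pet),
    n_removed_no_birth      = per_pet[reason == "no_birth", .N],
    n_removed_anomalous_dates = per_pet[reason == "anomalous", .N],
    n_removed_age_gt_30     = per_pet[reason == "too_old", .N],
    n_removed_incomplete    = per_pet[reason == "incomplete", .N],
    n_output_pets           = length(keep_ids)
  ), class = "cleaning_report")
  list(records = dt[pet_id %in% keep_ids], report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:\n")
  cat(sprintf("  input pets:          %d\n", x$n_input_pets))
  cat(sprintf("  removed, no birth:   %d\n", x$n_removed_no_birth))
  cat(sprintf("  removed, anomalous:  %d\n", x$n_removed_anomalous_dates))
  cat(sprintf("  removed, age > 30:   %d\n", x$n_removed_age_gt_30))
  cat(sprintf("  removed, incomplete: %d\n", x$n_removed_incomplete))
  cat(sprintf("  output pets:         %d\n", x$n_output_pets))
  invisible(x)
}

#' Serialise a cleaning report to JSON
#'
#' @param report a `cleaning_report`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
cleaning_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

# 9-point -> 5-point body condition mapping
BCS_9_TO_5 <- c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L)

#' Convert body condition scores to the 5-point scale
#'
#' The 9-point scale collapses pairwise onto the 5-point scale
#' (1->1; 2,3->2; 4,5->3; 6,7->4; 8,9->5); 5-point input is the identity.
#'
#' @param value integer BCS value(s).
#' @param scale 5 or 9 (scalar or vector matching `value`).
#' @return integer BCS on the 5-point scale.
#' @export
convert_bcs <- function(value, scale) {
  value <- as.integer(value)
  scale <- as.integer(rep(scale, length.out = length(value)))
  if (!all(scale %in% c(5L, 9L), na.rm = TRUE))
    stop("bcs scale must be 5 or 9")
  ok <- is.na(value) | (value >= 1L & value <= scale)
  if (!all(ok))
    stop("BCS value out of range for its scale: ",
         paste(sprintf("%d/%d", value[!ok], scale[!ok]), collapse = ", "))
  out <- value
  nine <- which(!is.na(value) & scale == 9L)
  out[nine] <- BCS_9_TO_5[value[nine]]
  out
}

#' Median life-time body condition score of one pet
#'
#' All BCS observations within the window are converted to the 5-point scale
#' and the median taken; half-integer medians are rounded down.
#'
#' @param records visit records of a single pet.
#' @param window_start,window_end observation window (Dates); defaults span
#'   all records.
#' @return integer in 1..5.
#' @export
median_bcs <- function(records, window_start = NULL, window_end = NULL) {
  dt <- as.data.table(records)
  if (uniqueN(dt$pet_id) > 1L)
    stop("median_bcs expects records of a single pet; see pet_median_bcs()")
  if (!is.null(window_start)) dt <- dt[visit_date >= as.Date(window_start)]
  if (!is.null(window_end))   dt <- dt[visit_date <= as.Date(window_end)]
  vals <- dt[!is.na(bcs_value)]
  if (!nrow(vals))
    stop("no BCS observations in window; pet should have been removed by clean_records()")
  converted <- convert_bcs(vals$bcs_value, vals$bcs_scale)
  as.integer(floor(median(converted)))
}

#' Per-pet median BCS for a whole record table
#'
#' @inheritParams median_bcs
#' @param records visit-record table (many pets).
#' @return `data.table` with columns `pet_id`, `median_bcs`; pets without a
#'   BCS observation in the window are dropped.
#' @export
pet_median_bcs <- function(records, window_start = NULL, window_end = NULL) {
  dt <- as.data.table(records)
  if (!is.null(window_start)) dt <- dt[visit_date >= as.Date(window_start)]
  if (!is.null(window_end))   dt <- dt[visit_date <= as.Date(window_end)]
  dt <- dt[!is.na(bcs_value)]
  dt[, .(median_bcs = as.integer(floor(median(convert_bcs(bcs_value, bcs_scale))))),
     by = pet_id]
}

#' Tukey fences
#'
#' Quartiles use linear interpolation between order statistics
#' (`quantile(type = 7)`); fences are Q1 - 1.5 IQR and Q3 + 1.5 IQR.
#'
#' @param values numeric vector, at least one finite value.
#' @return object of class `tukey_fences` with elements `q1`, `q3`, `iqr`,
#'   `lower_fence`, `upper_fence`.
#' @export
tukey_fences <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("tukey_fences: no non-missing values")
  qs <- unname(quantile(values, c(0.25, 0.75), type = 7))
  iqr <- qs[2] - qs[1]
  structure(list(q1 = qs[1], q3 = qs[2], iqr = iqr,
                 lower_fence = qs[1] - 1.5 * iqr,
                 upper_fence = qs[2] + 1.5 * iqr),
            class = "tukey_fences")
}

#' @export
print.tukey_fences <- function(x, ...) {
  cat(sprintf("Tukey fences: Q1=%g Q3=%g IQR=%g  [%g, %g]\n",
              x$q1, x$q3, x$iqr, x$lower_fence, x$upper_fence))
  invisible(x)
}

# adult bodyweight thresholds (kg), lower bound inclusive
SIZE_GROUP_BREAKS <- c(0, 5.5, 11, 26, 45, Inf)
SIZE_GROUP_LABELS <- c("toy", "small", "medium", "large", "giant")

size_group_from_weight <- function(bw_kg) {
  as.character(cut(bw_kg, breaks = SIZE_GROUP_BREAKS,
                   labels = SIZE_GROUP_LABELS, right = FALSE))
}

#' Assign dog breeds to adult-size groups
#'
#' From purebred dog visit records with bodyweights: (1) drop implausible
#' weights (> 70 kg or < 0.5 kg); (2) remove per-breed bodyweight outliers
#' by Tukey fences; (3) average bodyweight over visits at ages 2-5 completed
#' years per breed; (4) map the breed mean onto the size groups
#' toy < 5.5, small \\[5.5, 11), medium \\[11, 26), large \\[26, 45),
#' giant >= 45 kg. The literal breed "mixed breed" always maps to its own
#' group, whatever the weights.
#'
#' @param records dog visit records with `bodyweight_kg` present.
#' @param adult_age_range completed-year age range defining "adult"
#'   (default `c(2, 5)`).
#' @return object of class `size_group_map`: `data.table` with columns
#'   `breed`, `mean_adult_bw_kg`, `size_group`; breeds with no usable adult
#'   weights are listed in `attr(, "unmapped")`.
#' @export
assign_size_groups <- function(records, adult_age_range = c(2, 5)) {
  dt <- as.data.table(records)[species == "dog" & !is.na(bodyweight_kg)]
  all_breeds <- unique(dt$breed)
  dt <- dt[bodyweight_kg <= 70 & bodyweight_kg >= 0.5]
  # per-breed Tukey-fence outlier removal on bodyweight
  dt <- dt[, {
    tf <- tukey_fences(bodyweight_kg)
    .SD[bodyweight_kg >= tf$lower_fence & bodyweight_kg <= tf$upper_fence]
  }, by = breed]
  dt <- dt[!is.na(birth_date)]
  dt[, age := age_in_years(birth_date, visit_date)]
  adult <- dt[age >= adult_age_range[1] & age <= adult_age_range[2]]
  mapping <- adult[breed != "mixed breed",
                   .(mean_adult_bw_kg = mean(bodyweight_kg)), by = breed]
  mapping[, size_group := size_group_from_weight(mean_adult_bw_kg)]
  if ("mixed breed" %in% all_breeds)
    mapping <- rbind(mapping,
                     data.table(breed = "mixed breed",
                                mean_adult_bw_kg = NA_real_,
                                size_group = "mixed breed"))
  unmapped <- setdiff(all_breeds, mapping$breed)
  if (length(unmapped))
    warning(length(unmapped), " breed(s) had no usable adult weights: ",
            paste(head(unmapped, 5), collapse = ", "))
  setattr(mapping, "unmapped", unmapped)
  setattr(mapping, "class", c("size_group_map", class(mapping)))
  mapping[]
}
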