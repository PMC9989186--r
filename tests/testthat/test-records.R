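test_that("cleaning removes whole pets under the four rules, in order", {
  recs <- make_records(list(
    list(id = "ok",   visits = c("2015-03-01", "2016-03-01"), birth = "2014-01-01"),
    list(id = "nobirth", visits = "2015-03-01", birth = NA),
    list(id = "anom", visits = "2015-01-01", birth = "2016-01-01"),
    list(id = "postmortem", visits = c("2015-01-01", "2015-06-01"),
         birth = "2014-01-01", death = "2015-03-01"),
    list(id = "ancient", visits = "2015-01-01", birth = "1980-01-01"),
    list(id = "nosex", visits = "2015-01-01", birth = "2014-01-01", sex = NA),
    list(id = "nobcs", visits = "2015-01-01", birth = "2014-01-01", bcs = NA)))
  out <- clean_records(recs)
  expect_setequal(unique(out$records$pet_id), "ok")
  rep <- out$report
  expect_equal(rep$n_input_pets, 7)
  expect_equal(rep$n_removed_no_birth, 1)
  expect_equal(rep$n_removed_anomalous_dates, 2)  # birth-after-visit + visit-after-death
  expect_equal(rep$n_removed_age_gt_30, 1)
  expect_equal(rep$n_removed_incomplete, 2)
  expect_equal(rep$n_output_pets,
               rep$n_input_pets - rep$n_removed_no_birth -
                 rep$n_removed_anomalous_dates - rep$n_removed_age_gt_30 -
                 rep$n_removed_incomplete)
  # a pet violating several rules is counted once, under the first rule
  multi <- make_records(list(
    list(id = "multi", visits = "2015-01-01", birth = NA, sex = NA)))
  expect_equal(clean_records(multi)$report$n_removed_no_birth, 1)
  expect_equal(clean_records(multi)$report$n_removed_incomplete, 0)
})

test_that("cleaning is idempotent and tolerates empty output", {
  recs <- make_records(list(
    list(id = "a", visits = "2015-03-01", birth = "2014-01-01"),
    list(id = "b", visits = "2015-03-01", birth = NA)))
  once <- clean_records(recs)
  twice <- clean_records(once$records)
  expect_equal(as.data.frame(twice$records), as.data.frame(once$records))
  expect_equal(twice$report$n_output_pets, twice$report$n_input_pets)
  allbad <- make_records(list(list(id = "b", visits = "2015-03-01", birth = NA)))
  expect_equal(nrow(clean_records(allbad)$records), 0)
})

test_that("cleaning a synthetic cohort removes exactly the seeded defects", {
  sc <- sim_scenario(n_pets = 1500, species = "dog", defect_rate = 0.0174,
                     seed = 101)
  sim <- simulate_population(sc)
  n_pets_in <- length(unique(sim$records$pet_id))
  n_defects <- nrow(sim$truth$defects)
  expect_gt(n_defects, 0)
  out <- clean_records(sim$records)
  expect_equal(out$report$n_output_pets, n_pets_in - n_defects)
  expect_false(any(sim$truth$defects$pet_id %in% out$records$pet_id))
})

test_that("BCS conversion collapses the 9-point scale pairwise onto 5 points", {
  expect_equal(convert_bcs(9L, 9L), 5L)
  expect_equal(convert_bcs(4L, 9L), 3L)
  expect_equal(convert_bcs(3L, 5L), 3L)
  full9 <- convert_bcs(1:9, 9L)
  expect_equal(full9, c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_setequal(full9, 1:5)                 # surjective onto 1..5
  expect_true(all(diff(full9) >= 0))          # order-preserving
  expect_identical(convert_bcs(1:5, 5L), 1:5) # identity on 5-point input
  expect_error(convert_bcs(7L, 5L), "out of range")
  expect_error(convert_bcs(0L, 9L), "out of range")
})

test_that("median BCS converts, windows, and rounds half-integers down", {
  pet <- function(bcs, scale = 5L, dates = NULL) {
    dates <- dates %||% as.character(seq(as.Date("2015-01-01"),
                                         by = "month", length.out = length(bcs)))
    make_records(list(list(id = "p", visits = dates, birth = "2014-01-01",
                           bcs = bcs, scale = scale)))
  }
  expect_equal(median_bcs(pet(c(3L, 3L, 4L))), 3L)
  expect_equal(median_bcs(pet(c(3L, 4L))), 3L)         # 3.5 rounds down
  expect_equal(median_bcs(pet(c(5L, 5L, 5L, 5L))), 5L)
  expect_equal(median_bcs(pet(c(8L, 9L), scale = 9L)), 5L)
  # observation window restricts which visits count
  r <- pet(c(1L, 5L, 5L), dates = c("2013-06-01", "2015-06-01", "2016-06-01"))
  expect_equal(median_bcs(r, window_start = "2015-01-01"), 5L)
  expect_error(median_bcs(pet(NA_integer_)), "no BCS")
  # grouped helper agrees with the single-pet path
  sc <- sim_scenario(n_pets = 300, species = "cat", defect_rate = 0, seed = 5)
  recs <- simulate_population(sc)$records
  tab <- pet_median_bcs(recs)
  one <- tab$pet_id[7]
  expect_equal(tab[tab$pet_id == one, ]$median_bcs,
               median_bcs(recs[recs$pet_id == one, ]))
})

test_that("Tukey fences reproduce printed return-rate fences and a brute-force quartile", {
  # vector whose type-7 quartiles are exactly the printed dog quartiles
  dog_like <- c(0, 21, 70, 169, 400)
  tf <- tukey_fences(dog_like)
  expect_equal(tf$q1, 21)
  expect_equal(tf$q3, 169)
  expect_equal(tf$upper_fence, 391)
  # cat quartiles: exact fence is 443.5, printed truncated to 443
  cat_like <- c(0, 21, 90, 190, 400)
  expect_equal(tukey_fences(cat_like)$upper_fence, 443.5)
  expect_equal(trunc(tukey_fences(cat_like)$upper_fence), 443)
  # constant list degenerates to a point
  tfc <- tukey_fences(c(7, 7, 7))
  expect_equal(tfc$lower_fence, 7)
  expect_equal(tfc$upper_fence, 7)
  expect_error(tukey_fences(numeric(0)), "no non-missing")
  # brute-force equivalence on all random short lists
  set.seed(42)
  for (n in 2:8) {
    x <- round(runif(n, 0, 100), 1)
    tf <- tukey_fences(x)
    q1 <- oracle_quartile(x, 0.25); q3 <- oracle_quartile(x, 0.75)
    expect_equal(tf$q1, q1)
    expect_equal(tf$q3, q3)
    expect_true(tf$lower_fence <= tf$q1 && tf$q1 <= tf$q3 &&
                  tf$q3 <= tf$upper_fence)
  }
})

test_that("size groups follow the adult-bodyweight thresholds with mixed breed apart", {
  mk <- function(breed, bw, age_years = 3) {
    list(id = paste0(breed, bw), visits = as.character(as.Date("2014-01-01") +
                                                         round(age_years * 365.25)),
         birth = "2014-01-01", bw = bw, breed = breed)
  }
  recs <- make_records(c(
    lapply(c(3.8, 4.0, 4.2), function(w) mk("chihuahua", w)),
    lapply(c(25.0, 26.0, 27.0), function(w) mk("boundary", w)),  # mean 26 -> large
    lapply(c(50, 52, 54), function(w) mk("mastiff", w)),
    lapply(c(8, 30, 9), function(w) mk("mixed breed", w)),
    list(mk("puppyonly", 2.0, age_years = 0.5))))  # no adult weights
  expect_warning(map <- assign_size_groups(recs), "no usable adult weights")
  g <- setNames(map$size_group, map$breed)
  expect_equal(g[["chihuahua"]], "toy")
  expect_equal(g[["boundary"]], "large")   # lower bound inclusive at 26 kg
  expect_equal(g[["mastiff"]], "giant")
  expect_equal(g[["mixed breed"]], "mixed breed")
  expect_true("puppyonly" %in% attr(map, "unmapped"))
  # breed assignment invariant to record order; groups partition the breeds
  shuffled <- recs[sample(nrow(recs)), ]
  expect_warning(map2 <- assign_size_groups(shuffled), "no usable adult weights")
  expect_equal(setNames(map2$size_group, map2$breed)[names(g)], g)
  expect_equal(anyDuplicated(map$breed), 0)
})

test_that("implausible and outlier bodyweights are excluded before averaging", {
  mk <- function(bw, i) list(id = paste0("gsd", i),
                             visits = "2017-01-01", birth = "2014-01-01",
                             bw = bw, breed = "gsd")
  # 80 kg is dropped by the plausibility filter, 60 kg by the Tukey fence
  ws <- c(rep(c(30, 31, 32, 33), 5), 80, 60)
  recs <- make_records(Map(mk, ws, seq_along(ws)))
  map <- assign_size_groups(recs)
  expect_equal(map$mean_adult_bw_kg[map$breed == "gsd"], mean(c(30, 31, 32, 33)))
  expect_equal(map$size_group[map$breed == "gsd"], "large")
})

test_that("visit-record CSV round-trips with empty strings as missing", {
  recs <- make_records(list(
    list(id = "a", visits = c("2015-03-01", "2015-09-01"), birth = "2014-01-01"),
    list(id = "b", visits = "2015-04-01", birth = "2013-05-01",
         death = "2015-06-01", sex = NA)))
  path <- tempfile(fileext = ".csv")
  write_visit_records(recs, path)
  back <- read_visit_records(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
  expect_true(is.na(back$sex[back$pet_id == "b"][1]))
  # cleaning report serialises to JSON with all six counts
  js <- jsonlite::fromJSON(cleaning_report_json(clean_records(recs)$report))
  expect_setequal(names(js), c("n_input_pets", "n_removed_no_birth",
                               "n_removed_anomalous_dates", "n_removed_age_gt_30",
                               "n_removed_incomplete", "n_output_pets"))
})
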