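test_that("extreme outliers are masked above normal_high + k * SD only", {
  cat35 <- test_catalog()  # creatinine normal_high 1.5
  mk <- function(vals) {
    complete_labeled(cat35, ages = seq_along(vals) + 4,
                     t0 = max(seq_along(vals) + 4),
                     creatinine = vals)
  }
  sds <- c(creatinine = 0.5, BUN = 10, USG = 0.01, urine_protein = 50)
  out <- mask_outliers(list(mk(c(5.0, 4.4, NA))), cat35, sds,
                       filter_config(outlier_sd_multiple = 6))
  v <- out[[1]]$usable_visits$creatinine
  expect_true(is.na(v[1]))     # 5.0 > 1.5 + 3.0
  expect_equal(v[2], 4.4)      # below the threshold, untouched
  expect_true(is.na(v[3]))
  expect_equal(attr(out, "n_masked"), 1L)  # the NA was not "masked"
})

test_that("masking never alters non-outlier values anywhere", {
  cat35 <- test_catalog()
  sim <- simulate_cohort(cohort_spec(10, 10, 0, seed = 3))
  labeled <- label_cohort(sim$records, cat35)
  labeled <- labeled[vapply(labeled, function(r) {
    r$status %in% c("CKD", "NO_CKD")
  }, logical(1))]
  sds <- population_sds(labeled, cat35)
  masked <- mask_outliers(labeled, cat35, sds)
  for (i in seq_along(labeled)) {
    for (a in analyte_names(cat35)) {
      before <- labeled[[i]]$usable_visits[[a]]
      after <- masked[[i]]$usable_visits[[a]]
      kept <- !is.na(after)
      expect_identical(after[kept], before[kept])
    }
  }
})

test_that("lab-free pre-T0 visits are dropped; anything with labs stays", {
  cat35 <- test_catalog()
  v <- make_visits(cat35, ages = c(6, 7, 8), weight = c(10, 10, 10),
                   creatinine = c(NA, 1.2, 1.3))
  rec <- labeled_record(patient_record("p", "male", "mixed", v),
                        "CKD", 8, v)
  out <- drop_lab_free_visits(rec, cat35)
  expect_equal(out$usable_visits$age_years, c(7, 8))  # weight-only visit gone

  # one blood value is enough to keep a visit
  v2 <- make_visits(cat35, ages = c(6, 8), BUN = c(20, 25))
  rec2 <- labeled_record(patient_record("p", "male", "mixed", v2),
                         "CKD", 8, v2)
  expect_equal(nrow(drop_lab_free_visits(rec2, cat35)$usable_visits), 2)
})

test_that("eligibility arithmetic honours strict fraction inequalities", {
  cat35 <- test_catalog()
  mk <- function(ages, blood_at, urine_at, t0) {
    n <- length(ages)
    v <- make_visits(cat35, ages,
                     creatinine = ifelse(seq_len(n) %in% blood_at, 1.0, NA),
                     USG = ifelse(seq_len(n) %in% urine_at, 1.03, NA))
    labeled_record(patient_record("p", "male", "mixed", v), "CKD", t0, v)
  }
  # 3 in-window visits, blood 2/3 > 0.5, urine 1/3 > 0.25 -> kept
  res <- filter_eligible(list(mk(c(7, 8, 9), 1:2, 3, t0 = 9)), cat35)
  expect_length(res$kept, 1)

  # a single in-window visit fails the visit minimum
  res2 <- filter_eligible(list(mk(c(2, 9), 1:2, 1:2, t0 = 9)), cat35)
  expect_equal(res2$rejected$reasons, "min_visits")

  # urine at exactly 1/4 is not *more than* 25%
  res3 <- filter_eligible(list(mk(c(6, 7, 8, 9), 1:4, 1, t0 = 9)), cat35)
  expect_equal(res3$rejected$reasons, "urine_fraction")
})

test_that("raising filter thresholds never enlarges the kept set", {
  cat35 <- test_catalog()
  sim <- simulate_cohort(cohort_spec(15, 15, 0, seed = 21))
  labeled <- label_cohort(sim$records, cat35)
  labeled <- labeled[vapply(labeled, function(r) {
    r$status %in% c("CKD", "NO_CKD")
  }, logical(1))]
  ids <- function(res) vapply(res$kept, function(r) r$patient$patient_id,
                              character(1))
  loose <- ids(filter_eligible(labeled, cat35,
                               filter_config(min_blood_fraction = 0.01,
                                             min_urine_fraction = 0.01)))
  base <- ids(filter_eligible(labeled, cat35))
  tight <- ids(filter_eligible(labeled, cat35,
                               filter_config(min_visits_in_window = 4,
                                             min_urine_fraction = 0.5)))
  expect_true(all(base %in% loose))
  expect_true(all(tight %in% base))
})

test_that("the split is stratified, exhaustive, disjoint and seeded", {
  cat35 <- test_catalog()
  recs <- c(
    lapply(1:100, function(i) complete_labeled(cat35, c(8, 10), 10, "CKD",
                                               id = paste0("c", i))),
    lapply(1:100, function(i) complete_labeled(cat35, c(8, 10), 10,
                                               "NO_CKD",
                                               id = paste0("n", i)))
  )
  sp <- split_train_test(recs, split_config(0.67, seed = 5))
  st_tr <- table(vapply(sp$train, function(r) r$status, character(1)))
  st_te <- table(vapply(sp$test, function(r) r$status, character(1)))
  expect_equal(as.vector(st_tr[c("CKD", "NO_CKD")]), c(67, 67))
  expect_equal(as.vector(st_te[c("CKD", "NO_CKD")]), c(33, 33))
  id <- function(rs) vapply(rs, function(r) r$patient$patient_id,
                            character(1))
  expect_length(intersect(id(sp$train), id(sp$test)), 0)
  expect_setequal(c(id(sp$train), id(sp$test)), id(recs))

  sp2 <- split_train_test(recs, split_config(0.67, seed = 5))
  expect_identical(id(sp$train), id(sp2$train))

  tiny <- recs[c(1, 101, 102)]
  expect_warning(split_train_test(tiny, split_config(0.67, seed = 1)),
                 "fewer than 2")
})

test_that("truncation augmentation enumerates gap-qualified copies", {
  cat35 <- test_catalog()
  r <- complete_labeled(cat35, ages = c(8.0, 8.6, 9.1, 9.5, 10.0), t0 = 10,
                        status = "CKD")
  out <- augment_truncations(list(r), augment_config(max_gap_years = 2))
  expect_length(out, 5)  # original + 4 copies (gaps 0.5, 0.9, 1.4, 2.0)
  ks <- vapply(out[-1], function(x) x$trunc_k, integer(1))
  expect_equal(sort(ks), 1:4)
  gaps <- vapply(out[-1], function(x) {
    x$t0_years - max(x$usable_visits$age_years)
  }, numeric(1))
  expect_equal(sort(gaps), c(0.5, 0.9, 1.4, 2.0), tolerance = 1e-9)

  single <- complete_labeled(cat35, ages = 10, t0 = 10)
  expect_length(augment_truncations(list(single)), 1)

  wide <- complete_labeled(cat35, ages = c(6.0, 9.9), t0 = 10)
  expect_length(augment_truncations(list(wide)), 1)  # gap 4.0 > 2

  all_tr <- augment_truncations(list(wide),
                                augment_config(drop_gap_filter = TRUE))
  expect_length(all_tr, 2)
})

test_that("augmentation output size follows the counting formula", {
  cat35 <- test_catalog()
  sim <- simulate_cohort(cohort_spec(8, 8, 0, seed = 13))
  labeled <- label_cohort(sim$records, cat35)
  labeled <- labeled[vapply(labeled, function(r) {
    r$status %in% c("CKD", "NO_CKD")
  }, logical(1))]
  cfg <- augment_config()
  out <- augment_truncations(labeled, cfg)
  expected <- sum(vapply(labeled, function(r) {
    n <- nrow(r$usable_visits)
    if (n < 2 || !r$status %in% cfg$apply_to) return(1L)
    ok <- vapply(seq_len(n - 1), function(k) {
      r$t0_years - r$usable_visits$age_years[n - k] <= cfg$max_gap_years
    }, logical(1))
    1L + sum(ok)
  }, integer(1)))
  expect_length(out, expected)
  for (x in out) {
    if (!is.na(x$trunc_k)) {
      origin <- labeled[[which(vapply(labeled, function(r) {
        r$patient$patient_id
      }, character(1)) == x$origin_id)]]
      expect_lt(nrow(x$usable_visits), nrow(origin$usable_visits))
      expect_equal(x$t0_years, origin$t0_years)
      expect_equal(x$status, origin$status)
    }
  }
})
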