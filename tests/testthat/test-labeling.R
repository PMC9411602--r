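test_that("CKD-suggesting points count distinct criteria once each", {
  cat35 <- test_catalog()  # creatinine high 1.5, USG low 1.015
  rules <- labeling_rules()
  r2 <- make_record(cat35, ages = c(5, 6), creatinine = c(3.0, NA),
                    USG = c(NA, 1.010))
  expect_equal(count_ckd_suggesting_points(r2, cat35, rules), 2)

  r1 <- make_record(cat35, ages = 5,
                    notes = list("azotemic"))
  expect_equal(count_ckd_suggesting_points(r1, cat35, rules), 1)

  # two high creatinines are still one criterion under the default mode
  rr <- make_record(cat35, ages = c(5, 6), creatinine = c(3.0, 2.8))
  expect_equal(count_ckd_suggesting_points(rr, cat35, rules), 1)
  alt <- labeling_rules(count_mode = "qualifying_measurements")
  expect_equal(count_ckd_suggesting_points(rr, cat35, alt), 2)

  # token matching is case-insensitive exact match
  tok <- make_record(cat35, ages = 5, notes = list(c("AZOTEMIC", "ckd")))
  expect_equal(count_ckd_suggesting_points(tok, cat35, rules), 1)
})

test_that("diagnosis anchors T0 at the first diagnosed visit with a 30-day tail", {
  cat35 <- test_catalog()
  r <- make_record(cat35, ages = c(8.0, 10.0, 10.4),
                   creatinine = c(1.0, 2.5, 3.0),
                   codes = list(character(0), "CKD", "CKD"))
  lab <- assign_status(r, cat35)
  expect_equal(lab$status, "CKD")
  expect_equal(lab$t0_years, 10.0)
  # 10.4 > 10 + 30/365.25 = 10.082, so the late visit is excluded
  expect_equal(lab$usable_visits$age_years, c(8.0, 10.0))
})

test_that("healthy records get T0 = last age minus two years and lose the tail", {
  cat35 <- test_catalog()
  r <- make_record(cat35, ages = c(5, 6, 7, 8), creatinine = rep(1.0, 4))
  lab <- assign_status(r, cat35)
  expect_equal(lab$status, "NO_CKD")
  expect_equal(lab$t0_years, 6.0)
  expect_true(all(lab$usable_visits$age_years <= 6.0))
})

test_that("short disease-free records are excluded, risk tokens force probable", {
  cat35 <- test_catalog()
  short <- make_record(cat35, ages = c(5.0, 6.2), creatinine = c(1, 1))
  expect_equal(assign_status(short, cat35)$status, "EXCLUDED")

  risky <- make_record(cat35, ages = c(5, 6, 7, 8), creatinine = rep(1, 4),
                       notes = list(character(0), "CKD_RISK",
                                    character(0), character(0)))
  lab <- assign_status(risky, cat35)
  expect_equal(lab$status, "PROBABLE_CKD")
  expect_true(is.na(lab$t0_years))
})

test_that("statuses partition any cohort and usable windows hold", {
  cat35 <- test_catalog()
  withr::with_seed(11, {
    records <- lapply(1:40, function(i) random_record(cat35, paste0("r", i)))
  })
  labeled <- label_cohort(records, cat35)
  expect_length(labeled, length(records))
  st <- vapply(labeled, function(r) r$status, character(1))
  expect_true(all(st %in% c("CKD", "PROBABLE_CKD", "NO_CKD", "EXCLUDED")))
  win <- labeling_rules()$post_diagnosis_window_years
  for (r in labeled) {
    if (r$status == "CKD") {
      expect_true(all(r$usable_visits$age_years <= r$t0_years + win))
      expect_false(is.na(r$t0_years))
    }
    if (r$status == "NO_CKD") {
      expect_true(all(r$usable_visits$age_years <= r$t0_years))
    }
    if (r$status %in% c("PROBABLE_CKD", "EXCLUDED")) {
      expect_true(is.na(r$t0_years))
    }
  }
})

test_that("relabeling the usable visits of a CKD record is idempotent", {
  cat35 <- test_catalog()
  r <- make_record(cat35, ages = c(8.0, 10.0, 10.4),
                   codes = list(character(0), "CKD", "CKD"))
  lab <- assign_status(r, cat35)
  again <- assign_status(
    patient_record(r$patient_id, r$sex, r$breed, lab$usable_visits), cat35)
  expect_equal(again$status, "CKD")
  expect_equal(again$t0_years, lab$t0_years)
})

test_that("generated cohorts label consistently with ground truth", {
  cat35 <- test_catalog()
  sim <- simulate_cohort(cohort_spec(30, 30, 15, seed = 77))
  labeled <- label_cohort(sim$records, cat35)
  st <- vapply(labeled, function(r) r$status, character(1))
  expect_true(all(st[sim$truth$group == "CKD"] == "CKD"))
  expect_true(all(st[sim$truth$group == "PROBABLE"] %in%
                    c("PROBABLE_CKD", "NO_CKD")))
  # diagnosis age is recovered as T0 for every true CKD dog
  idx <- which(sim$truth$group == "CKD")
  t0s <- vapply(labeled[idx], function(r) r$t0_years, numeric(1))
  expect_equal(t0s, sim$truth$diagnosis_age_years[idx])
})
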