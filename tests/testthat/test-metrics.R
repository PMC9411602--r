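test_that("confusion counting follows the >= cutoff rule", {
  cc <- confusion(c(1, 0), c(0.6, 0.4))
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 0, tn = 1, fn = 0))
  # p exactly at the cutoff classifies as CKD
  cc2 <- confusion(0, 0.5)
  expect_equal(cc2$fp, 1)
  cc0 <- confusion(numeric(0), numeric(0))
  expect_equal(cc0$tp + cc0$fp + cc0$tn + cc0$fn, 0)
  expect_error(confusion(c(1, 0), 0.5), "length")
})

test_that("rates reproduce the headline at-diagnosis fractions", {
  cc <- list(tp = 9955, fn = 934, tn = 4142, fp = 121)
  r <- basic_rates(cc)
  expect_equal(round(100 * r[["sensitivity"]], 2), 91.42)  # 9955/10889
  expect_equal(round(100 * r[["specificity"]], 2), 97.16)  # 4142/4263
  expect_equal(round(100 * r[["accuracy"]], 2), 93.04)     # 14097/15152
  # empty denominators give missing rates, not errors
  r2 <- basic_rates(list(tp = 0, fn = 0, tn = 3, fp = 1))
  expect_true(is.na(r2[["sensitivity"]]))
  expect_equal(r2[["specificity"]], 0.75)
})

test_that("predictive values evaluate the prevalence-adjustment formulas", {
  pv <- predictive_values(0.9142, 0.9716, 0.0083)
  expect_equal(round(100 * pv[["ppv"]], 2), 21.22)
  expect_equal(round(100 * pv[["npv"]], 2), 99.93)

  pv35 <- predictive_values(0.2320, 0.9965, 0.0083)
  expect_equal(round(100 * pv35[["npv"]], 2), 99.36)

  expect_equal(unname(predictive_values(1, 1, 0.3)), c(1, 1))
  expect_true(is.na(predictive_values(0.5, 1, 0)[["ppv"]]))
})

test_that("predictive values at sample prevalence equal the confusion-matrix PV", {
  withr::with_seed(20, {
    for (i in 1:200) {
      cc <- list(tp = sample(1:500, 1), fp = sample(1:500, 1),
                 tn = sample(1:500, 1), fn = sample(1:500, 1))
      r <- basic_rates(cc)
      prev <- (cc$tp + cc$fn) / (cc$tp + cc$fn + cc$tn + cc$fp)
      pv <- predictive_values(r[["sensitivity"]], r[["specificity"]], prev)
      expect_equal(pv[["ppv"]], cc$tp / (cc$tp + cc$fp), tolerance = 1e-12)
      expect_equal(pv[["npv"]], cc$tn / (cc$tn + cc$fn), tolerance = 1e-12)
    }
  })
})

test_that("PPV rises and NPV falls with prevalence", {
  withr::with_seed(21, {
    for (i in 1:50) {
      se <- runif(1, 0.05, 0.99)
      sp <- runif(1, 0.05, 0.99)
      prevs <- sort(runif(4, 0.01, 0.99))
      pvs <- vapply(prevs, function(p) {
        predictive_values(se, sp, p)
      }, numeric(2))
      expect_true(all(diff(pvs["ppv", ]) > 0))
      expect_true(all(diff(pvs["npv", ]) < 0))
    }
  })
})

test_that("Wald intervals match the closed form, clip, and shrink with n", {
  ci <- wald_ci(0.5, 100)
  expect_equal(ci[["upper"]] - ci[["lower"]], 2 * qnorm(0.975) * 0.05,
               tolerance = 1e-12)
  expect_equal(round(ci[["upper"]] - 0.5, 3), 0.098)

  expect_equal(unname(wald_ci(1, 50)), c(1, 1))
  expect_equal(round(unname(wald_ci(0.9142, 10889)), 4), c(0.9089, 0.9195))
  expect_true(all(is.na(wald_ci(0.4, 0))))

  widths <- vapply(c(1e2, 1e4, 1e6), function(n) {
    ci <- wald_ci(0.3, n)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], 0.002)

  # rounded-z option reproduces the conventional 1.96 half-width
  expect_equal(wald_ci(0.5, 100, rounded_z = TRUE)[["upper"]], 0.598)
})

test_that("prevalence arithmetic and life stages follow their definitions", {
  expect_equal(round(100 * estimate_prevalence(54098, 6.5e6), 2), 0.83)
  expect_equal(estimate_prevalence(0, 100), 0)
  expect_equal(estimate_prevalence(100, 100), 1)
  expect_error(estimate_prevalence(1, 0), "population")

  expect_equal(as.character(life_stage(5.0)), "adult")
  expect_equal(as.character(life_stage(6.5)), "mature")  # boundary ages up
  expect_equal(as.character(life_stage(9.75)), "senior")
  expect_equal(as.character(life_stage(13.0)), "geriatric")
  expect_equal(as.character(life_stage(14.0)), "geriatric")
  expect_error(life_stage(1.0), "domain")
})

test_that("T0 evaluation applies the visit-window eligibility rule", {
  cat35 <- test_catalog()
  net <- zero_net()  # p = 0.5 for everything: every record predicted CKD
  near <- complete_labeled(cat35, ages = c(8, 9.9), t0 = 10, "CKD",
                           id = "near")
  far <- complete_labeled(cat35, ages = c(8, 9.6), t0 = 10, "CKD",
                          id = "far")  # last visit 0.4 y before T0
  neg <- complete_labeled(cat35, ages = c(8, 9.8), t0 = 10, "NO_CKD",
                          id = "neg")
  s <- evaluate_at_t0(net, list(near, far, neg), t0_window_years = 0.25,
                      prevalence = 0.0083)
  expect_equal(s$n_pos, 1)  # "far" excluded by the window rule
  expect_equal(s$n_neg, 1)
  expect_equal(s$sensitivity, 1)   # zero-net predicts CKD at p = 0.5
  expect_equal(s$specificity, 0)
  expect_false(anyNA(s[c("sens_lower", "sens_upper", "ppv")]))
  expect_error(evaluate_at_t0(net, list(far), prevalence = 0.0083),
               "near T0")
})

test_that("horizon truncation hides late visits and drops emptied records", {
  cat35 <- test_catalog()
  net <- zero_net()
  a <- complete_labeled(cat35, ages = c(8.0, 9.8), t0 = 10, "CKD", id = "a")
  b <- complete_labeled(cat35, ages = 9.8, t0 = 10, "CKD", id = "b")
  neg <- complete_labeled(cat35, ages = c(7, 9.9), t0 = 10, "NO_CKD",
                          id = "n")
  tab <- horizon_evaluation(net, list(a, b, neg), horizons = c(0, 1),
                            prevalence = 0.0083)
  expect_equal(tab$n_pos, c(2, 1))  # at h = 1, only a's 8.0 visit survives
  expect_equal(tab$n_neg, c(1, 1))  # untruncated healthy denominator
  # h = 0 agrees with the at-T0 evaluation on the same eligible set
  s0 <- evaluate_at_t0(net, list(a, b, neg), prevalence = 0.0083)
  expect_equal(tab$sensitivity[1], s0$sensitivity)

  cm <- horizon_evaluation(net, list(a, b, neg), horizons = 1,
                           prevalence = 0.0083, count_as_missed = TRUE)
  expect_equal(cm$n_pos, 2)  # b stays in the denominator as a miss
  expect_equal(cm$sensitivity, 0.5)
})

test_that("stratified reports partition the eligible set and tally by hand", {
  cat35 <- test_catalog()
  net <- zero_net()
  recs <- c(
    lapply(1:3, function(i) complete_labeled(cat35, c(4, 4.9), 5, "CKD",
                                             id = paste0("y", i))),
    lapply(1:2, function(i) complete_labeled(cat35, c(11, 11.9), 12,
                                             "NO_CKD",
                                             id = paste0("o", i)))
  )
  tab <- stratified_report(net, recs, "life-stage", prevalence = 0.0083)
  expect_equal(tab$stratum, c("adult", "senior"))
  expect_equal(tab$n_pos + tab$n_neg, c(3, 2))
  expect_equal(tab$sensitivity[1], 1)   # all predicted CKD by the zero net
  expect_equal(tab$specificity[2], 0)

  vc <- stratified_report(net, recs, "visit-count", prevalence = 0.0083)
  expect_equal(sum(vc$n_pos + vc$n_neg), 5)

  # per-stratum prevalence map drives per-stratum predictive values
  tab2 <- stratified_report(net, recs, "life-stage",
                            prevalence = c(adult = 0.0015, senior = 0.0146))
  expect_equal(tab2$prevalence_used, c(0.0015, 0.0146))
  expect_error(stratified_report(net, recs, "life-stage",
                                 prevalence = c(adult = 0.1)),
               "no prevalence")
})
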