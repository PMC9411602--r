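test_that("an all-zero network outputs p = 0.5 and softmax always sums to 1", {
  net <- zero_net()
  x <- matrix(rnorm(18), 3, 6)
  expect_equal(forward(net, list(x = x)), 0.5)

  withr::with_seed(4, {
    fs <- toy_feature_spec(3)
    rnd <- ckdwatch:::init_net(net_config(hidden_layers = c(4, 2),
                                          seed = 9), fs)
    for (i in 1:5) {
      xr <- matrix(rnorm(12), 4, 3)
      out <- ckdwatch:::rnn_forward(rnd, xr)
      expect_equal(sum(out$p), 1, tolerance = 1e-12)
      expect_true(all(out$p >= 0 & out$p <= 1))
    }
  })
  expect_error(forward(net, list(x = matrix(0, 2, 3))), "features")
})

test_that("a one-unit net over two steps matches the hand-derived value", {
  fs <- toy_feature_spec(1)
  net <- ckdwatch:::init_net(net_config(hidden_layers = 1, seed = 1), fs)
  net$layers[[1]]$W[] <- 0.5
  net$layers[[1]]$U[] <- 0.25
  net$layers[[1]]$b[] <- 0.1
  net$Wout[] <- c(1, -1)   # column-major: 2 x 1
  net$bout[] <- c(0.2, -0.2)
  x <- matrix(c(1, -0.5), 2, 1)
  # recurrence by hand, then the 2-unit softmax
  h1 <- tanh(0.5 * 1 + 0.1)
  h2 <- tanh(0.5 * -0.5 + 0.25 * h1 + 0.1)
  z <- c(h2 + 0.2, -h2 - 0.2)
  expected <- exp(z[1]) / sum(exp(z))
  expect_equal(forward(net, list(x = x)), expected, tolerance = 1e-12)
})

test_that("analytic BPTT gradients match central finite differences", {
  withr::with_seed(12, {
    fs <- toy_feature_spec(2)
    for (widths in list(c(3), c(4, 3), c(5, 3, 3))) {
      net <- ckdwatch:::init_net(net_config(hidden_layers = widths,
                                            seed = 31), fs)
      x <- matrix(rnorm(8), 4, 2)
      for (y in c(1, 0)) {
        analytic <- grad_vector(ckdwatch:::rnn_bptt(net, x, y)$grads)
        numeric <- numeric_gradient(net, x, y)
        rel <- abs(analytic - numeric) / pmax(abs(numeric), 1e-6)
        expect_lt(max(rel), 1e-4)
      }
    }
  })
})

test_that("training is deterministic and separates well-separated classes", {
  withr::with_seed(3, {
    samples <- gaussian_samples(30, mu = 1.5)
  })
  fs <- toy_feature_spec(2)
  cfg <- net_config(hidden_layers = c(4, 3), dropout = 0, epochs = 8,
                    seed = 5)
  net <- train_rnn(samples, cfg, fs)
  acc <- mean((predict_proba(net, samples) >= 0.5) ==
                vapply(samples, `[[`, numeric(1), "y"))
  expect_gt(acc, 0.95)
  expect_length(net$loss_trace, 8)
  expect_lt(net$loss_trace[8], net$loss_trace[1])

  net2 <- train_rnn(samples, cfg, fs)
  expect_identical(net_param_vector(net), net_param_vector(net2))

  one_class <- samples[vapply(samples, `[[`, numeric(1), "y") == 1]
  expect_error(train_rnn(one_class, cfg, fs), "single class")
})

test_that("sequence assembly standardises, carries weight forward, refuses probable", {
  cat35 <- test_catalog()
  fs <- feature_spec(default_features(), data.frame(
    feature = default_features(),
    mean = c(1.2, 20, 1.03, 30, 12, 8),
    sd = c(0.5, 5, 0.01, 40, 4, 3)))
  v <- make_visits(cat35, ages = c(6, 7, 8, 9, 10),
                   weight = c(10, 12, NA, NA, 14),
                   creatinine = c(1.2, 1.3, 1.1, 1.2, 1.4),
                   BUN = rep(20, 5), USG = rep(1.03, 5),
                   urine_protein = rep(30, 5))
  rec <- labeled_record(patient_record("p", "male", "mixed", v),
                        "CKD", 10, v)
  s <- build_sequences(list(rec), fs)[[1]]
  expect_equal(nrow(s$x), 5)
  expect_equal(unname(s$x[1, "creatinine"]), 0)        # equals the scaler mean
  expect_equal(unname(s$x[3, "weight"]) * 4 + 12, 12)  # carried forward from 12
  expect_equal(unname(s$x[4, "weight"]) * 4 + 12, 12)
  expect_equal(unname(s$x[5, "weight"]) * 4 + 12, 14)
  expect_equal(s$y, 1L)

  prob <- labeled_record(rec$patient, "PROBABLE_CKD", NA_real_, v)
  expect_error(build_sequences(list(prob), fs), "PROBABLE")

  expect_error(feature_spec("creatinine",
                            data.frame(feature = "creatinine", mean = 1,
                                       sd = 0)), "unscalable")
})

test_that("the architecture screen scores a grid and breaks ties by size", {
  withr::with_seed(8, {
    samples <- gaussian_samples(15, mu = 1.5, T_range = 3:4)
  })
  fs <- toy_feature_spec(2)
  grid <- list(net_config(hidden_layers = c(3), dropout = 0, epochs = 2,
                          seed = 2),
               net_config(hidden_layers = c(8, 8), dropout = 0, epochs = 2,
                          seed = 2))
  res <- architecture_screen(grid, samples, fs, folds = 3)
  expect_equal(nrow(res$table), 2)
  expect_true(all(res$table$mean_cv_f1 >= 0 & res$table$mean_cv_f1 <= 1))
  best_row <- which(res$table$hidden ==
                      paste(res$best$hidden_layers, collapse = "-"))
  cand <- which(res$table$mean_cv_f1 >=
                  max(res$table$mean_cv_f1) - 1e-12)
  expect_equal(res$table$n_params[best_row],
               min(res$table$n_params[cand]))

  one <- architecture_screen(grid[1], samples, fs, folds = 3)
  expect_equal(one$best$hidden_layers, grid[[1]]$hidden_layers)
})

test_that("forward selection returns nested subsets", {
  cat35 <- test_catalog()
  sim <- simulate_cohort(cohort_spec(12, 12, 0, seed = 61))
  labeled <- label_cohort(sim$records, cat35)
  labeled <- labeled[vapply(labeled, function(r) {
    r$status %in% c("CKD", "NO_CKD")
  }, logical(1))]
  m <- fit_imputer(visit_matrix(labeled, cat35),
                   imputer_config(seed = 5, method = "linear"))
  imputed <- impute_missing(labeled, m, cat35)
  sel <- wrapper_feature_selection(
    c("creatinine", "USG", "age"), imputed,
    base_config = net_config(hidden_layers = c(3), dropout = 0,
                             epochs = 2, seed = 4),
    folds = 2)
  expect_equal(sel$forward$size, 1:3)
  subsets <- strsplit(sel$forward$features, ",")
  expect_true(all(subsets[[1]] %in% subsets[[2]]))
  expect_true(all(subsets[[2]] %in% subsets[[3]]))
  expect_equal(sel$backward$size[1], 3)
})

test_that("a trained net survives a JSON round trip bit-for-bit in behaviour", {
  withr::with_seed(6, {
    samples <- gaussian_samples(10, mu = 1.5, T_range = 3:4)
  })
  fs <- toy_feature_spec(2)
  net <- train_rnn(samples, net_config(hidden_layers = c(3, 2),
                                       dropout = 0, epochs = 2, seed = 7),
                   fs)
  path <- withr::local_tempfile(fileext = ".json")
  save_net(net, path)
  back <- load_net(path)
  expect_equal(predict_proba(back, samples), predict_proba(net, samples),
               tolerance = 1e-12)
  expect_equal(back$config$hidden_layers, net$config$hidden_layers)
})
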