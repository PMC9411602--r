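# Shared builders for hand-made records. All fixtures are constructed in
# code; nothing is read from disk except what a test itself writes.

test_catalog <- function() default_catalog()

# Build a visit frame from per-visit named values, e.g.
# make_visits(cat, ages = c(8, 10), creatinine = c(1.0, 3.0))
make_visits <- function(catalog, ages, weight = NULL, notes = NULL,
                        codes = NULL, ...) {
  v <- new_visit_frame(catalog, length(ages))
  v$age_years <- ages
  if (!is.null(weight)) v$weight_kg <- weight
  vals <- list(...)
  for (a in names(vals)) v[[a]] <- vals[[a]]
  if (!is.null(notes)) v$note_tokens <- notes
  if (!is.null(codes)) v$diagnosis_codes <- codes
  v
}

make_record <- function(catalog, ages, id = "p1", sex = "female",
                        breed = "beagle", ...) {
  patient_record(id, sex, breed, make_visits(catalog, ages, ...))
}

# A random valid patient record for property tests (uses current RNG).
random_record <- function(catalog, id) {
  n <- sample(2:8, 1)
  ages <- sort(1.5 + runif(n) * 15)
  v <- new_visit_frame(catalog, n)
  v$age_years <- ages
  v$weight_kg <- ifelse(runif(n) < 0.9, round(runif(n, 3, 40), 1), NA)
  for (a in sample(analyte_names(catalog), 6)) {
    e <- catalog[a, ]
    vals <- runif(n, e$normal_low, e$normal_high)
    vals[runif(n) < 0.4] <- NA
    v[[a]] <- vals
  }
  if (runif(1) < 0.3) {
    v$note_tokens[[sample.int(n, 1)]] <- c("wellness_exam", "azotemic")
  }
  if (runif(1) < 0.3) {
    v$diagnosis_codes[[sample.int(n, 1)]] <- "CKD"
  }
  patient_record(id, sample(c("male", "female"), 1), "mixed", v)
}

# A labeled record with fully populated model features (no imputation
# needed), for metrics/rnn plumbing tests.
complete_labeled <- function(catalog, ages, t0, status = "CKD",
                             creatinine = NULL, id = "p1") {
  n <- length(ages)
  v <- make_visits(
    catalog, ages, weight = rep(12, n),
    creatinine = if (is.null(creatinine)) rep(1.0, n) else creatinine,
    BUN = rep(18, n), USG = rep(1.03, n), urine_protein = rep(20, n)
  )
  labeled_record(patient_record(id, "female", "mixed", v), status, t0, v)
}

# Zero out every weight of a net: softmax of equal logits, p = 0.5.
zero_net <- function(features = default_features()) {
  fs <- feature_spec(features, data.frame(feature = features,
                                          mean = 0, sd = 1))
  net <- ckdwatch:::init_net(net_config(seed = 1), fs)
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W[] <- 0
    net$layers[[l]]$U[] <- 0
    net$layers[[l]]$b[] <- 0
  }
  net$Wout[] <- 0
  net$bout[] <- 0
  net
}

# Gaussian-class toy sequence samples for training tests.
gaussian_samples <- function(n_per_class, mu, T_range = 3:6, d = 2) {
  mk <- function(n, m, y) lapply(seq_len(n), function(i) {
    T_ <- sample(T_range, 1)
    list(x = matrix(rnorm(T_ * d, m, 1), T_, d), y = y,
         label = if (y == 1) "CKD" else "NO_CKD",
         id = paste0(y, "_", i), trunc_k = NA_integer_)
  })
  c(mk(n_per_class, mu, 1), mk(n_per_class, -mu, 0))
}

toy_feature_spec <- function(d = 2) {
  f <- paste0("f", seq_len(d))
  feature_spec(f, data.frame(feature = f, mean = 0, sd = 1))
}

# Flatten/restore all net parameters; used by finite-difference checks.
net_param_vector <- function(net) {
  unlist(c(lapply(net$layers, function(ly) c(ly$W, ly$U, ly$b)),
           list(net$Wout, net$bout)))
}

net_with_params <- function(net, theta) {
  pos <- 1
  take <- function(k) {
    out <- theta[pos:(pos + k - 1)]
    pos <<- pos + k
    out
  }
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    net$layers[[l]]$W[] <- take(length(ly$W))
    net$layers[[l]]$U[] <- take(length(ly$U))
    net$layers[[l]]$b[] <- take(length(ly$b))
  }
  net$Wout[] <- take(length(net$Wout))
  net$bout[] <- take(length(net$bout))
  net
}

grad_vector <- function(g) {
  unlist(c(lapply(g$layers, function(ly) c(ly$W, ly$U, ly$b)),
           list(g$Wout, g$bout)))
}

# Central finite differences of the sequence loss wrt every parameter.
numeric_gradient <- function(net, x, y, eps = 1e-5) {
  theta <- net_param_vector(net)
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- theta[i] + eps
    tm <- theta; tm[i] <- theta[i] - eps
    (ckdwatch:::rnn_bptt(net_with_params(net, tp), x, y)$loss -
       ckdwatch:::rnn_bptt(net_with_params(net, tm), x, y)$loss) / (2 * eps)
  }, numeric(1))
}
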