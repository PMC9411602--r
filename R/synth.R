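#' Group parameters and cohort specifications for the synthetic generator
#'
#' The generator emulates a two-group canine population ("CKD" vs "no
#' CKD") whose laboratory moments at the evaluation age T0 match the
#' study-population summary the pipeline is calibrated against: creatinine
#' 2.67 (1.86) vs 1.09 (0.29) mg/dL, BUN 56.23 (32.72) vs 17.38 (5.59)
#' mg/dL, USG 1.020 (0.011) vs 1.039 (0.012), urine protein 91.01 (180.81)
#' vs 49.52 (136.21) mg/dL, age at T0 11.56 (3.37) vs 7.19 (2.93) years,
#' weight 13.04 (11.20) vs 15.10 (12.42) kg, with ~15 vs ~12 visits per
#' dog.  CKD dogs follow a progressive trajectory: analyte means move
#' linearly from the healthy-group mean to the CKD-group T0 mean over the
#' progression window before diagnosis; healthy dogs are stationary.
#'
#' @return `default_group_params()`: a named list with entries `CKD`,
#'   `NO_CKD` and `PROBABLE`, each a `group_params` list with fields
#'   `analyte_moments` (named list of `c(mean_t0, sd)`), `age_t0`,
#'   `weight` (each `c(mean, sd)`), `mean_visits` and
#'   `sex_ratio_m_to_f`.
#' @export
default_group_params <- function() {
  ckd <- group_params(
    analyte_moments = list(
      creatinine    = c(mean_t0 = 2.67,   sd = 1.86),
      BUN           = c(mean_t0 = 56.23,  sd = 32.72),
      USG           = c(mean_t0 = 1.020,  sd = 0.011),
      urine_protein = c(mean_t0 = 91.01,  sd = 180.81)
    ),
    age_t0 = c(mean = 11.56, sd = 3.37),
    weight = c(mean = 13.04, sd = 11.20),
    mean_visits = 15.18,
    sex_ratio_m_to_f = 1 / 1.1
  )
  healthy <- group_params(
    analyte_moments = list(
      creatinine    = c(mean_t0 = 1.09,   sd = 0.29),
      BUN           = c(mean_t0 = 17.38,  sd = 5.59),
      USG           = c(mean_t0 = 1.039,  sd = 0.012),
      urine_protein = c(mean_t0 = 49.52,  sd = 136.21)
    ),
    age_t0 = c(mean = 7.19, sd = 2.93),
    weight = c(mean = 15.10, sd = 12.42),
    mean_visits = 11.99,
    sex_ratio_m_to_f = 1 / 0.93
  )
  list(CKD = ckd, NO_CKD = healthy, PROBABLE = healthy)
}

#' @rdname default_group_params
#' @param analyte_moments Named list, per analyte `c(mean_t0, sd)`.
#' @param age_t0,weight Numeric `c(mean, sd)` pairs.
#' @param mean_visits Expected number of visits per dog (>= 2).
#' @param sex_ratio_m_to_f Male-to-female ratio.
#' @export
group_params <- function(analyte_moments, age_t0, weight, mean_visits,
                         sex_ratio_m_to_f = 1) {
  stopifnot(mean_visits >= 2, sex_ratio_m_to_f > 0)
  sds <- c(vapply(analyte_moments, function(m) m[["sd"]], numeric(1)),
           age_t0[["sd"]], weight[["sd"]])
  if (any(sds <= 0)) stop("all SDs in group_params must be > 0")
  structure(list(analyte_moments = analyte_moments, age_t0 = age_t0,
                 weight = weight, mean_visits = mean_visits,
                 sex_ratio_m_to_f = sex_ratio_m_to_f),
            class = "group_params")
}

#' Note tokens that suggest CKD in the absence of a formal diagnosis
#' @export
ckd_note_lexicon <- function() {
  c("CKD", "azotemic", "Royal Canin Veterinary diet Renal",
    "Hill's prescription diet k/d")
}

benign_note_lexicon <- function() {
  c("wellness_exam", "vaccination", "dental_cleaning", "grooming",
    "nail_trim")
}

#' Specify a synthetic cohort
#'
#' @param n_ckd,n_nockd,n_probable Group sizes (>= 0).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the spec including the seed.
#' @param group_params As [default_group_params()].
#' @param catalog Analyte catalog; analytes without explicit group moments
#'   are generated as stationary noise around the middle of their normal
#'   range (SD = range/6) in both groups.
#' @param progression_window_years Years before diagnosis over which CKD
#'   analyte means ramp from healthy to CKD levels.
#' @param missing_rates Named per-analyte missingness probabilities; the
#'   entries `".blood"` and `".urine"` set category-wide defaults.  Urine
#'   analytes go missing as a per-visit block (one Bernoulli per visit),
#'   emulating urinalysis not being run at every visit; blood analytes are
#'   masked independently.
#' @param visit_gap_mean_years Mean of the exponential inter-visit gap.
#' @param note_token_rate Per-visit probability of a benign note token.
#' @param weight_missing_rate Per-visit probability that weight is not
#'   recorded.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_ckd, n_nockd, n_probable = 0, seed,
                        group_params = default_group_params(),
                        catalog = default_catalog(),
                        progression_window_years = 2.0,
                        missing_rates = c(.blood = 0.10, .urine = 0.60),
                        visit_gap_mean_years = 0.5,
                        note_token_rate = 0.3,
                        weight_missing_rate = 0.05) {
  stopifnot(n_ckd >= 0, n_nockd >= 0, n_probable >= 0,
            progression_window_years > 0, visit_gap_mean_years > 0,
            note_token_rate >= 0, note_token_rate <= 1,
            all(missing_rates >= 0), all(missing_rates <= 1))
  if (missing(seed)) stop("cohort_spec requires an explicit seed")
  structure(list(n_ckd = n_ckd, n_nockd = n_nockd, n_probable = n_probable,
                 group_params = group_params, catalog = catalog,
                 progression_window_years = progression_window_years,
                 missing_rates = missing_rates,
                 visit_gap_mean_years = visit_gap_mean_years,
                 note_token_rate = note_token_rate,
                 weight_missing_rate = weight_missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# E[max(N(m,1), 0)] = m*pnorm(m) + dnorm(m); invert on a grid so censored
# draws can be location-shifted to hit a target post-censoring mean.
censored_mean_fn <- function(m) m * stats::pnorm(m) + stats::dnorm(m)

.censor_grid <- new.env(parent = emptyenv())

censor_grid <- function() {
  if (is.null(.censor_grid$grid)) {
    grid <- seq(-8, 8, by = 0.005)
    .censor_grid$grid <- grid
    .censor_grid$values <- censored_mean_fn(grid)
  }
  .censor_grid
}

censor_adjusted_location <- function(target, sd, floor_at) {
  z <- (target - floor_at) / sd
  out <- target
  need <- z < 6 & is.finite(z)
  if (any(need)) {
    g <- censor_grid()
    m <- stats::approx(g$values, g$grid,
                       xout = pmax(z[need], g$values[1]), rule = 2)$y
    out[need] <- floor_at[need] + sd[need] * m
  }
  out
}

# Draw N(target', sd) censored below at floor_at, location-adjusted so the
# post-censoring expectation equals target.
rnorm_censored <- function(n, target, sd, floor_at) {
  loc <- censor_adjusted_location(target, sd, floor_at)
  pmax(stats::rnorm(n, loc, sd), floor_at)
}

usg_bounds <- function() c(1.001, 1.065)

analyte_floor <- function(analyte) {
  if (analyte == "USG") usg_bounds()[1] else 0
}

# Linear ramp weight in [0, 1]: 0 at/before window start, 1 at/after t0.
progression_ramp <- function(age, t0, window) {
  pmin(pmax(1 - (t0 - age) / window, 0), 1)
}

#' Expected analyte value on the CKD trajectory
#'
#' Closed form of the generator's disease trajectory: the expected value of
#' an analyte for a CKD dog at a given age is the linear interpolation
#' between the healthy-group mean (reached `progression_window_years` or
#' more before diagnosis) and the CKD-group T0 mean (reached at
#' diagnosis).  Exposed so tests and users can reason about the generator
#' analytically.
#'
#' @param analyte Analyte name with explicit group moments.
#' @param age,t0 Visit age and diagnosis age in years.
#' @param spec A `cohort_spec`.
#' @return Expected value (before measurement noise).
#' @export
trajectory_mean <- function(analyte, age, t0, spec) {
  gp <- spec$group_params
  h <- gp$NO_CKD$analyte_moments[[analyte]][["mean_t0"]]
  d <- gp$CKD$analyte_moments[[analyte]][["mean_t0"]]
  w <- progression_ramp(age, t0, spec$progression_window_years)
  h + w * (d - h)
}

missing_rate_for <- function(spec, analyte, category) {
  mr <- spec$missing_rates
  if (analyte %in% names(mr)) return(unname(mr[[analyte]]))
  key <- paste0(".", category)
  if (key %in% names(mr)) return(unname(mr[[key]]))
  0
}

#' Simulate one patient
#'
#' Uses the current RNG stream; [simulate_cohort()] wraps it in a seeded
#' context.  CKD dogs get a diagnosis visit at `diagnosis_age` carrying the
#' `"CKD"` diagnosis code (possibly repeated at later visits), increasing
#' creatinine/BUN/urine protein and decreasing USG/weight in expectation
#' across the progression window.  PROBABLE dogs carry no diagnosis code
#' but at least two CKD-suggesting signals (a high creatinine, a low USG,
#' or a lexicon note token).  NO_CKD dogs are stationary with no signals
#' injected.
#'
#' @param group `"CKD"`, `"PROBABLE"` or `"NO_CKD"`.
#' @param spec A `cohort_spec`.
#' @param patient_id Identifier for the new record.
#' @return A list with `record` (a `patient_record`) and
#'   `diagnosis_age_years` (`NA` unless `group == "CKD"`).
#' @export
simulate_patient <- function(group, spec, patient_id = "p1") {
  if (!group %in% c("CKD", "PROBABLE", "NO_CKD")) {
    stop("unknown group label: ", group)
  }
  gp <- spec$group_params[[group]]
  catalog <- spec$catalog

  anchor <- stats::rnorm(1, gp$age_t0[["mean"]], gp$age_t0[["sd"]])
  anchor <- min(max(anchor, 4.0), 19.5)
  # For CKD the anchor is the diagnosis age; for the others it is the age
  # the labeling stage will recover as T0 (last visit age minus the 2-year
  # lookahead), so Table-1-style age moments are comparable across groups.
  last_age <- if (group == "CKD") anchor else min(anchor + 2.0, 21.5)

  n_vis <- max(2L, stats::rpois(1, gp$mean_visits))
  gaps <- stats::rexp(n_vis - 1, rate = 1 / spec$visit_gap_mean_years)
  gaps <- pmax(gaps, 2 / 365.25)  # distinct ages; never two visits same day
  ages <- last_age - rev(c(0, cumsum(gaps)))
  ages <- ages[ages >= 1.5]
  if (length(ages) < 2) ages <- c(max(last_age - 0.5, 1.5), last_age)

  diagnosis_age <- NA_real_
  if (group == "CKD") {
    diagnosis_age <- last_age
    n_post <- stats::rbinom(1, 2, 0.3)
    if (n_post > 0) {
      post <- last_age + cumsum(stats::rexp(n_post, rate = 1 / 0.25) +
                                  2 / 365.25)
      ages <- c(ages, post[post <= 22])
    }
  }
  n <- length(ages)
  vals_by_analyte <- list()

  ramp <- if (group == "CKD") {
    progression_ramp(ages, diagnosis_age, spec$progression_window_years)
  } else {
    rep(0, n)
  }
  healthy <- spec$group_params$NO_CKD
  diseased <- spec$group_params$CKD

  for (a in analyte_names(catalog)) {
    fl <- analyte_floor(a)
    if (a %in% names(healthy$analyte_moments)) {
      h <- healthy$analyte_moments[[a]]
      d <- diseased$analyte_moments[[a]]
      mu <- h[["mean_t0"]] + ramp * (d[["mean_t0"]] - h[["mean_t0"]])
      sdv <- h[["sd"]] + ramp * (d[["sd"]] - h[["sd"]])
    } else {
      entry <- catalog_entry(catalog, a)
      mu <- rep((entry$normal_low + entry$normal_high) / 2, n)
      sdv <- rep((entry$normal_high - entry$normal_low) / 6, n)
    }
    vals <- rnorm_censored(n, mu, sdv, rep(fl, n))
    if (a == "USG") vals <- pmin(vals, usg_bounds()[2])
    vals_by_analyte[[a]] <- vals
  }

  # Weight: dog-level baseline plus a slow disease-linked drift and small
  # per-visit jitter, so cross-sectional spread matches the group SD while
  # within-dog weight stays coherent.
  w_target <- healthy$weight[["mean"]] +
    ramp * (diseased$weight[["mean"]] - healthy$weight[["mean"]])
  baseline <- rnorm_censored(1, healthy$weight[["mean"]],
                             healthy$weight[["sd"]], 0.5)
  drift <- w_target - healthy$weight[["mean"]]
  weight <- pmax(baseline + drift + stats::rnorm(n, 0, 0.02 * baseline),
                 0.5)

  # Missingness: urine analytes drop out as one block per visit; blood
  # analytes independently; weight occasionally unrecorded.
  u_rate <- missing_rate_for(spec, "USG", "urine")
  u_block <- stats::runif(n) < u_rate
  for (a in analyte_names(catalog, "urine")) {
    vals_by_analyte[[a]][u_block] <- NA_real_
  }
  for (a in analyte_names(catalog, "blood")) {
    r <- missing_rate_for(spec, a, "blood")
    if (r > 0) vals_by_analyte[[a]][stats::runif(n) < r] <- NA_real_
  }
  weight[stats::runif(n) < spec$weight_missing_rate] <- NA_real_

  notes <- replicate(n, character(0), simplify = FALSE)
  noted <- which(stats::runif(n) < spec$note_token_rate)
  if (length(noted) > 0) {
    picks <- sample(benign_note_lexicon(), length(noted), replace = TRUE)
    for (i in seq_along(noted)) notes[[noted[i]]] <- picks[i]
  }

  codes <- replicate(n, character(0), simplify = FALSE)
  if (group == "CKD") {
    dx <- which(abs(ages - diagnosis_age) < 1e-9)
    later <- which(ages > diagnosis_age)
    code_at <- c(dx, later[stats::runif(length(later)) < 0.5])
    for (j in code_at) codes[[j]] <- "CKD"
  }

  visits <- structure(
    c(list(age_years = ages, weight_kg = weight),
      vals_by_analyte[analyte_names(catalog)],
      list(note_tokens = notes, diagnosis_codes = codes)),
    class = "data.frame", row.names = c(NA_integer_, -n)
  )

  if (group == "PROBABLE") {
    visits <- inject_probable_signals(visits, catalog)
  }

  sex <- if (stats::runif(1) < gp$sex_ratio_m_to_f /
             (1 + gp$sex_ratio_m_to_f)) "male" else "female"
  breed <- sample(c("mixed", "labrador_retriever", "german_shepherd",
                    "beagle", "dachshund", "boxer"), 1)
  list(record = patient_record(patient_id, sex, breed, visits),
       diagnosis_age_years = diagnosis_age)
}

# Give a probable-CKD dog >= 2 distinct CKD-suggesting signals without a
# diagnosis code: injected after masking so the signals are observable.
inject_probable_signals <- function(visits, catalog) {
  n <- nrow(visits)
  picks <- sample(c("creatinine", "usg", "note"), 2)
  if (stats::runif(1) < 0.3) picks <- c("creatinine", "usg", "note")
  for (p in picks) {
    j <- sample.int(n, 1)
    if (p == "creatinine") {
      hi <- catalog_entry(catalog, "creatinine")$normal_high
      visits$creatinine[j] <- hi * stats::runif(1, 1.2, 2.0)
    } else if (p == "usg") {
      lo <- catalog_entry(catalog, "USG")$normal_low
      visits$USG[j] <- max(lo - stats::runif(1, 0.003, 0.010),
                           usg_bounds()[1])
    } else {
      visits$note_tokens[[j]] <- unique(c(visits$note_tokens[[j]],
                                          sample(ckd_note_lexicon(), 1)))
    }
  }
  visits
}

#' Simulate a synthetic EHR cohort
#'
#' Deterministic given the spec (including its seed): the same spec yields
#' a byte-identical cohort.
#'
#' @param spec A `cohort_spec`.
#' @return A list with `records` (list of `patient_record`) and `truth`, a
#'   data frame with `patient_id`, `group`
#'   (`CKD`/`PROBABLE`/`NO_CKD`) and `diagnosis_age_years` (present iff
#'   `group == "CKD"`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(c("CKD", "NO_CKD", "PROBABLE"),
                c(spec$n_ckd, spec$n_nockd, spec$n_probable))
  withr::with_seed(spec$seed, {
    out <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      out[[i]] <- simulate_patient(groups[i], spec,
                                   patient_id = sprintf("dog%05d", i))
    }
    truth <- data.frame(
      patient_id = vapply(out, function(x) x$record$patient_id, character(1)),
      group = groups,
      diagnosis_age_years = vapply(out, function(x) x$diagnosis_age_years,
                                   numeric(1)),
      stringsAsFactors = FALSE
    )
    list(records = lapply(out, `[[`, "record"), truth = truth)
  })
}

#' Summarize a labeled cohort at T0
#'
#' The synthetic analogue of a study-population demographics table: per
#' status group it reports dog and visit counts, sex ratio, and mean (SD)
#' of age, weight and the headline analytes at the usable visit nearest
#' T0, plus percent missing per analyte over all usable visits.
#'
#' @param labeled A list of `labeled_record`s (see [assign_status()]).
#' @param analytes Analytes to summarize.
#' @return A data frame, one row per status group present.
#' @export
summarize_cohort <- function(labeled,
                             analytes = c("creatinine", "BUN", "USG",
                                          "urine_protein")) {
  statuses <- vapply(labeled, function(r) r$status, character(1))
  rows <- lapply(unique(statuses), function(st) {
    recs <- labeled[statuses == st]
    row <- list(status = st, n = length(recs))
    nv <- vapply(recs, function(r) nrow(r$usable_visits), numeric(1))
    row$mean_visits <- mean(nv)
    sexes <- vapply(recs, function(r) r$patient$sex, character(1))
    nf <- sum(sexes == "female")
    row$m_to_f <- if (nf > 0) sum(sexes == "male") / nf else NA_real_
    at_t0 <- function(r, col) {
      v <- r$usable_visits
      if (nrow(v) == 0) return(NA_real_)
      anchor <- if (is.na(r$t0_years)) max(v$age_years) else r$t0_years
      v[[col]][which.min(abs(v$age_years - anchor))]
    }
    t0s <- vapply(recs, function(r) {
      if (is.na(r$t0_years)) NA_real_ else r$t0_years
    }, numeric(1))
    row$mean_age_t0 <- mean(t0s, na.rm = TRUE)
    row$sd_age_t0 <- stats::sd(t0s, na.rm = TRUE)
    wts <- vapply(recs, at_t0, numeric(1), col = "weight_kg")
    row$mean_weight_t0 <- mean(wts, na.rm = TRUE)
    row$sd_weight_t0 <- stats::sd(wts, na.rm = TRUE)
    for (a in analytes) {
      vals <- vapply(recs, at_t0, numeric(1), col = a)
      row[[paste0("mean_", a, "_t0")]] <- mean(vals, na.rm = TRUE)
      row[[paste0("sd_", a, "_t0")]] <- stats::sd(vals, na.rm = TRUE)
      allv <- unlist(lapply(recs, function(r) r$usable_visits[[a]]))
      row[[paste0("pct_missing_", a)]] <-
        if (length(allv) == 0) NA_real_ else 100 * mean(is.na(allv))
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the ground-truth sidecar produced by [simulate_cohort()]
#' @param truth The `truth` data frame.
#' @param path Output CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(truth, path, na = "")
  invisible(path)
}
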