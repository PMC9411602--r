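#' Confusion counts at a probability cutoff
#'
#' A record is predicted CKD iff `p >= cutoff` (ties classify as CKD).
#'
#' @param labels 0/1 vector (1 = CKD).
#' @param probs Probabilities in `[0, 1]`, same length.
#' @param cutoff Classification threshold (default 0.5).
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, probs, cutoff = 0.5) {
  if (length(labels) != length(probs)) {
    stop("contract error: labels and probs differ in length")
  }
  stopifnot(all(probs >= 0 & probs <= 1))
  pred <- probs >= cutoff
  structure(list(tp = sum(pred & labels == 1),
                 fp = sum(pred & labels == 0),
                 tn = sum(!pred & labels == 0),
                 fn = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' An empty denominator yields `NA` for that rate, never an error.
#'
#' @param c A `confusion_counts` (or any list with tp/fp/tn/fn).
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
basic_rates <- function(c) {
  total <- c$tp + c$fp + c$tn + c$fn
  c(sensitivity = if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else NA_real_,
    specificity = if (c$tn + c$fp > 0) c$tn / (c$tn + c$fp) else NA_real_,
    accuracy = if (total > 0) (c$tp + c$tn) / total else NA_real_)
}

#' Prevalence-adjusted predictive values
#'
#' PPV = (se * prev) / (se * prev + (1 - sp) * (1 - prev));
#' NPV = (sp * (1 - prev)) / (sp * (1 - prev) + (1 - se) * prev).
#' Because PPV and NPV depend on disease prevalence, they are computed at
#' a supplied (population) prevalence rather than at the sample mix.
#'
#' @param sensitivity,specificity,prevalence Proportions in `[0, 1]`.
#' @return Named numeric vector `ppv`, `npv` (`NA` on a degenerate 0/0).
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, prevalence >= 0, prevalence <= 1)
  ppv_den <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  npv_den <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  c(ppv = if (ppv_den > 0) sensitivity * prevalence / ppv_den else NA_real_,
    npv = if (npv_den > 0) {
      specificity * (1 - prevalence) / npv_den
    } else NA_real_)
}

#' Normal-approximation (Wald) confidence interval for a proportion
#'
#' `p +/- z * sqrt(p (1 - p) / n)`, clipped to `[0, 1]`.  The default
#' quantile is the exact `qnorm(0.975)`; set `rounded_z = TRUE` for the
#' conventional 1.96.
#'
#' @param p Proportion.
#' @param n Denominator count.
#' @param level Confidence level.
#' @param rounded_z Use 1.96 instead of the exact quantile at 95%.
#' @return Named numeric vector `lower`, `upper` (`NA` when `n = 0`).
#' @export
wald_ci <- function(p, n, level = 0.95, rounded_z = FALSE) {
  if (is.na(p) || n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- if (rounded_z && level == 0.95) 1.96 else {
    stats::qnorm(1 - (1 - level) / 2)
  }
  hw <- z * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - hw), upper = min(1, p + hw))
}

#' Disease prevalence from case and population counts
#'
#' @param n_cases,n_population Counts, `n_cases <= n_population`,
#'   `n_population > 0`.
#' @return The ratio.
#' @export
estimate_prevalence <- function(n_cases, n_population) {
  if (n_population <= 0) stop("contract error: zero population")
  stopifnot(n_cases >= 0, n_cases <= n_population)
  n_cases / n_population
}

#' Canine life-stage boundaries and assignment
#'
#' Adult `[1.5, 6.5)`, mature `[6.5, 9.75)`, senior `[9.75, 13)`,
#' geriatric `[13, Inf)`; each boundary age belongs to the older stage.
#'
#' @param adult_max,mature_max,senior_max Upper boundaries in years.
#' @export
life_stage_boundaries <- function(adult_max = 6.5, mature_max = 9.75,
                                  senior_max = 13.0) {
  stopifnot(1.5 < adult_max, adult_max < mature_max,
            mature_max < senior_max)
  structure(list(adult_max = adult_max, mature_max = mature_max,
                 senior_max = senior_max),
            class = "life_stage_boundaries")
}

#' @rdname life_stage_boundaries
#' @param age_years Age in years (must be >= 1.5).
#' @param b A `life_stage_boundaries`.
#' @export
life_stage <- function(age_years, b = life_stage_boundaries()) {
  if (any(age_years < 1.5)) stop("domain error: age below 1.5 years")
  cut(age_years, c(1.5, b$adult_max, b$mature_max, b$senior_max, Inf),
      labels = c("adult", "mature", "senior", "geriatric"),
      right = FALSE, include.lowest = TRUE)
}

#' Build a diagnostic summary from scored labels
#'
#' @param labels 0/1 labels; `probs` matching probabilities.
#' @param prevalence Population prevalence used for PPV/NPV.
#' @param cutoff Probability cutoff.
#' @param level CI level.
#' @return A `diagnostic_summary`: one-row data frame with counts, rates,
#'   Wald bounds, PPV/NPV and the prevalence used.
#' @export
diagnostic_summary <- function(labels, probs, prevalence, cutoff = 0.5,
                               level = 0.95) {
  cc <- confusion(labels, probs, cutoff)
  r <- basic_rates(cc)
  n_pos <- cc$tp + cc$fn
  n_neg <- cc$tn + cc$fp
  se_ci <- wald_ci(r[["sensitivity"]], n_pos, level)
  sp_ci <- wald_ci(r[["specificity"]], n_neg, level)
  ac_ci <- wald_ci(r[["accuracy"]], n_pos + n_neg, level)
  pv <- if (is.na(r[["sensitivity"]]) || is.na(r[["specificity"]])) {
    c(ppv = NA_real_, npv = NA_real_)
  } else {
    predictive_values(r[["sensitivity"]], r[["specificity"]], prevalence)
  }
  out <- data.frame(
    n_pos = n_pos, n_neg = n_neg, tp = cc$tp, fp = cc$fp, tn = cc$tn,
    fn = cc$fn,
    sensitivity = r[["sensitivity"]], sens_lower = se_ci[["lower"]],
    sens_upper = se_ci[["upper"]],
    specificity = r[["specificity"]], spec_lower = sp_ci[["lower"]],
    spec_upper = sp_ci[["upper"]],
    accuracy = r[["accuracy"]], acc_lower = ac_ci[["lower"]],
    acc_upper = ac_ci[["upper"]],
    ppv = pv[["ppv"]], npv = pv[["npv"]], prevalence_used = prevalence
  )
  class(out) <- c("diagnostic_summary", "data.frame")
  out
}

empty_summary_row <- function(prevalence) {
  out <- diagnostic_summary(c(0, 1), c(0.1, 0.9), prevalence)
  out[1, ] <- NA
  out$prevalence_used <- prevalence
  out
}

#' Default population prevalence for predictive values
#' @export
default_prevalence <- function() estimate_prevalence(54098, 6.5e6)

eligible_at_t0 <- function(records, t0_window_years) {
  keep <- vapply(records, function(r) {
    v <- r$usable_visits
    nrow(v) > 0 && any(v$age_years >= r$t0_years - t0_window_years)
  }, logical(1))
  records[keep]
}

score_records <- function(net, records) {
  samples <- build_sequences(records, net$feature_spec)
  list(labels = vapply(samples, `[[`, numeric(1), "y"),
       probs = predict_proba(net, samples))
}

#' Evaluate the classifier at the time of diagnosis
#'
#' Restricts the test set to records with a usable visit within
#' `t0_window_years` of T0 (default 3 months) and scores full sequences.
#'
#' @param net A `trained_net`.
#' @param test Test `labeled_record`s (status CKD / NO_CKD), disjoint
#'   from training.
#' @param t0_window_years Eligibility window around T0.
#' @param prevalence Population prevalence for PPV/NPV.
#' @return A `diagnostic_summary`.
#' @export
evaluate_at_t0 <- function(net, test, t0_window_years = 0.25,
                           prevalence = default_prevalence()) {
  elig <- eligible_at_t0(test, t0_window_years)
  if (length(elig) == 0) stop("no records with a visit near T0")
  s <- score_records(net, elig)
  diagnostic_summary(s$labels, s$probs, prevalence)
}

#' Early-detection horizon evaluation
#'
#' For each horizon h, CKD records are truncated to visits at least h
#' years before T0 and their sensitivity recomputed; records left with no
#' visits are dropped from that horizon's denominator.  Specificity comes
#' from untruncated NO_CKD records throughout: for them T0 is an
#' accounting construct (last visit minus the validation window), so a
#' trajectory "towards T0" has no clinical meaning.
#'
#' @param net A `trained_net`.
#' @param test Test `labeled_record`s.
#' @param horizons Years before T0 (default 0, 0.5, ..., 3.5).
#' @param prevalence Population prevalence for PPV/NPV.
#' @param t0_window_years Eligibility window applied once, at horizon 0.
#' @param count_as_missed Score a fully truncated CKD record as a missed
#'   case instead of dropping it.
#' @return A data frame, one `diagnostic_summary` row per horizon.
#' @export
horizon_evaluation <- function(net, test, horizons = seq(0, 3.5, by = 0.5),
                               prevalence = default_prevalence(),
                               t0_window_years = 0.25,
                               count_as_missed = FALSE) {
  stopifnot(all(horizons >= 0))
  elig <- eligible_at_t0(test, t0_window_years)
  statuses <- vapply(elig, function(r) r$status, character(1))
  ckd <- elig[statuses == "CKD"]
  nockd <- elig[statuses == "NO_CKD"]
  s_neg <- if (length(nockd) > 0) score_records(net, nockd) else {
    list(labels = numeric(0), probs = numeric(0))
  }
  rows <- lapply(horizons, function(h) {
    trunc <- lapply(ckd, function(r) {
      r$usable_visits <- r$usable_visits[
        r$usable_visits$age_years <= r$t0_years - h, , drop = FALSE]
      r
    })
    nonempty <- vapply(trunc, function(r) nrow(r$usable_visits) > 0,
                       logical(1))
    s_pos <- if (any(nonempty)) score_records(net, trunc[nonempty]) else {
      list(labels = numeric(0), probs = numeric(0))
    }
    if (count_as_missed && any(!nonempty)) {
      s_pos$labels <- c(s_pos$labels, rep(1, sum(!nonempty)))
      s_pos$probs <- c(s_pos$probs, rep(0, sum(!nonempty)))
    }
    out <- diagnostic_summary(c(s_pos$labels, s_neg$labels),
                              c(s_pos$probs, s_neg$probs), prevalence)
    cbind(data.frame(horizon_years = h), out)
  })
  do.call(rbind, rows)
}

#' Stratified diagnostic report
#'
#' Per-stratum diagnostic summaries, stratifying by integer age at T0,
#' life stage at T0, or the number of usable pre-T0 visits.
#'
#' @param net A `trained_net`.
#' @param test Test `labeled_record`s.
#' @param strata `"age-year"`, `"life-stage"` or `"visit-count"`.
#' @param prevalence Either a single proportion or a named vector mapping
#'   stratum label to prevalence.
#' @param t0_window_years Eligibility window around T0.
#' @param boundaries Life-stage boundaries.
#' @return A data frame with one summary row per stratum.
#' @export
stratified_report <- function(net, test,
                              strata = c("age-year", "life-stage",
                                         "visit-count"),
                              prevalence = default_prevalence(),
                              t0_window_years = 0.25,
                              boundaries = life_stage_boundaries()) {
  strata <- match.arg(strata)
  elig <- eligible_at_t0(test, t0_window_years)
  key <- vapply(elig, function(r) {
    switch(strata,
           "age-year" = as.character(floor(r$t0_years)),
           "life-stage" = as.character(life_stage(r$t0_years, boundaries)),
           "visit-count" = as.character(
             sum(r$usable_visits$age_years <= r$t0_years)))
  }, character(1))
  levels_ <- if (strata == "life-stage") {
    intersect(c("adult", "mature", "senior", "geriatric"), unique(key))
  } else {
    as.character(sort(as.numeric(unique(key))))
  }
  prev_for <- function(lv) {
    if (length(prevalence) == 1 && is.null(names(prevalence))) {
      return(prevalence)
    }
    if (lv %in% names(prevalence)) return(prevalence[[lv]])
    stop("no prevalence supplied for stratum ", lv)
  }
  rows <- lapply(levels_, function(lv) {
    sub <- elig[key == lv]
    out <- if (length(sub) == 0) {
      empty_summary_row(prev_for(lv))
    } else {
      s <- score_records(net, sub)
      diagnostic_summary(s$labels, s$probs, prev_for(lv))
    }
    cbind(data.frame(stratum = lv), out)
  })
  do.call(rbind, rows)
}
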