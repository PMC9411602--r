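#' Cohort filtering, splitting and augmentation configuration
#'
#' @param outlier_sd_multiple Values more than this many population SDs
#'   above the top of the normal range are masked to missing.
#' @param window_years Look-back window before T0 for eligibility.
#' @param min_visits_in_window Minimum visits inside the window.
#' @param min_blood_fraction,min_urine_fraction Required fractions of
#'   in-window visits carrying at least one blood / urine result
#'   (strict `>`).
#' @return A `filter_config` list.
#' @export
filter_config <- function(outlier_sd_multiple = 6, window_years = 4,
                          min_visits_in_window = 2,
                          min_blood_fraction = 0.5,
                          min_urine_fraction = 0.25) {
  stopifnot(outlier_sd_multiple > 0, window_years > 0,
            min_visits_in_window > 0,
            min_blood_fraction > 0, min_blood_fraction < 1,
            min_urine_fraction > 0, min_urine_fraction < 1)
  structure(list(outlier_sd_multiple = outlier_sd_multiple,
                 window_years = window_years,
                 min_visits_in_window = min_visits_in_window,
                 min_blood_fraction = min_blood_fraction,
                 min_urine_fraction = min_urine_fraction),
            class = "filter_config")
}

#' @rdname filter_config
#' @param train_fraction Fraction assigned to the training split.
#' @param seed Integer seed making the split deterministic.
#' @param stratify_by_status Split within each status group.
#' @export
split_config <- function(train_fraction = 0.67, seed,
                         stratify_by_status = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (missing(seed)) stop("split_config requires an explicit seed")
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratify_by_status = stratify_by_status),
            class = "split_config")
}

#' @rdname filter_config
#' @param max_gap_years Maximum gap between the last visit of a truncated
#'   copy and T0 for the copy to be kept.
#' @param apply_to Statuses whose records are augmented.
#' @param drop_gap_filter Generate every truncation regardless of gap.
#' @export
augment_config <- function(max_gap_years = 2.0,
                           apply_to = c("CKD", "NO_CKD"),
                           drop_gap_filter = FALSE) {
  stopifnot(max_gap_years > 0)
  structure(list(max_gap_years = max_gap_years, apply_to = apply_to,
                 drop_gap_filter = drop_gap_filter),
            class = "augment_config")
}

#' Per-analyte population standard deviations
#'
#' Observed-value SD per analyte across all usable visits of a cohort;
#' feeds the extreme-outlier rule.
#'
#' @param records List of `labeled_record`s.
#' @param catalog An `analyte_catalog`.
#' @return Named numeric vector (NA where an analyte was never observed).
#' @export
population_sds <- function(records, catalog) {
  out <- vapply(analyte_names(catalog), function(a) {
    vals <- unlist(lapply(records, function(r) r$usable_visits[[a]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) >= 2) stats::sd(vals) else NA_real_
  }, numeric(1))
  stats::setNames(out, analyte_names(catalog))
}

#' Mask extreme laboratory outliers
#'
#' Any analyte value more than `outlier_sd_multiple` population SDs above
#' the top of its normal range is set to missing; everything else is
#' untouched.  Already-missing cells are not counted as masked.
#'
#' @param records List of `labeled_record`s.
#' @param catalog An `analyte_catalog`.
#' @param population_sd Named SD vector covering every analyte with
#'   observed values (see [population_sds()]).
#' @param cfg A `filter_config`.
#' @return The records with outliers masked; the total number of masked
#'   cells is attached as attribute `"n_masked"`.
#' @export
mask_outliers <- function(records, catalog, population_sd,
                          cfg = filter_config()) {
  n_masked <- 0L
  out <- lapply(records, function(r) {
    v <- r$usable_visits
    for (a in analyte_names(catalog)) {
      vals <- v[[a]]
      if (all(is.na(vals))) next
      if (!a %in% names(population_sd) || is.na(population_sd[[a]])) {
        stop("configuration error: no population SD for analyte ", a)
      }
      thr <- catalog_entry(catalog, a)$normal_high +
        cfg$outlier_sd_multiple * population_sd[[a]]
      bad <- !is.na(vals) & vals > thr
      if (any(bad)) {
        v[[a]][bad] <- NA_real_
        n_masked <<- n_masked + sum(bad)
      }
    }
    r$usable_visits <- v
    r
  })
  attr(out, "n_masked") <- n_masked
  out
}

visit_has_category <- function(visits, catalog, category) {
  cols <- analyte_names(catalog, category)
  if (nrow(visits) == 0) return(logical(0))
  present <- !is.na(as.matrix(visits[cols]))
  rowSums(present) > 0
}

#' Drop pre-T0 visits without any laboratory data
#'
#' Visits strictly before T0 with neither a blood nor a urine result are
#' removed (they carry nothing the laboratory-driven model can use); the
#' T0 visit and anything after it are always retained.
#'
#' @param record A `labeled_record` with T0 present.
#' @param catalog An `analyte_catalog`.
#' @return The trimmed `labeled_record`.
#' @export
drop_lab_free_visits <- function(record, catalog) {
  if (is.na(record$t0_years)) stop("record has no T0")
  v <- record$usable_visits
  has_lab <- visit_has_category(v, catalog, "blood") |
    visit_has_category(v, catalog, "urine")
  keep <- has_lab | v$age_years >= record$t0_years
  record$usable_visits <- v[keep, , drop = FALSE]
  record
}

#' Eligibility filter on pre-T0 data sufficiency
#'
#' A record is kept iff, within the `window_years` before T0 (inclusive),
#' it has (a) at least `min_visits_in_window` visits, (b) a fraction of
#' those visits carrying at least one blood result strictly greater than
#' `min_blood_fraction`, and (c) a urine fraction strictly greater than
#' `min_urine_fraction`.
#'
#' @param records List of `labeled_record`s, each with T0.
#' @param catalog An `analyte_catalog`.
#' @param cfg A `filter_config`.
#' @return A list with `kept` (records) and `rejected` (data frame of
#'   `patient_id` and comma-joined `reasons`).
#' @export
filter_eligible <- function(records, catalog, cfg = filter_config()) {
  kept <- list()
  rej_id <- character(0)
  rej_why <- character(0)
  for (r in records) {
    if (is.na(r$t0_years)) stop("record ", r$patient$patient_id,
                                " has no T0")
    v <- r$usable_visits
    inw <- v$age_years >= r$t0_years - cfg$window_years &
      v$age_years <= r$t0_years
    nw <- sum(inw)
    reasons <- character(0)
    if (nw < cfg$min_visits_in_window) {
      reasons <- c(reasons, "min_visits")
    } else {
      w <- v[inw, , drop = FALSE]
      fb <- mean(visit_has_category(w, catalog, "blood"))
      fu <- mean(visit_has_category(w, catalog, "urine"))
      if (!(fb > cfg$min_blood_fraction)) reasons <- c(reasons,
                                                       "blood_fraction")
      if (!(fu > cfg$min_urine_fraction)) reasons <- c(reasons,
                                                       "urine_fraction")
    }
    if (length(reasons) == 0) {
      kept[[length(kept) + 1]] <- r
    } else {
      rej_id <- c(rej_id, r$patient$patient_id)
      rej_why <- c(rej_why, paste(reasons, collapse = ","))
    }
  }
  list(kept = kept,
       rejected = data.frame(patient_id = rej_id, reasons = rej_why,
                             stringsAsFactors = FALSE))
}

#' Stratified train/test split
#'
#' Within each status group `round(train_fraction * group size)` records
#' go to training; the split is a deterministic function of the seed and
#' of patient order.  A group with fewer than 2 records goes entirely to
#' training with a warning.
#'
#' @param records List of `labeled_record`s.
#' @param cfg A `split_config`.
#' @return A list with `train` and `test`.
#' @export
split_train_test <- function(records, cfg) {
  statuses <- if (cfg$stratify_by_status) {
    vapply(records, function(r) r$status, character(1))
  } else {
    rep("all", length(records))
  }
  train_idx <- integer(0)
  withr::with_seed(cfg$seed, {
    for (st in unique(statuses)) {
      idx <- which(statuses == st)
      if (length(idx) < 2) {
        warning("status group '", st, "' has fewer than 2 records; ",
                "assigning all to training")
        train_idx <- c(train_idx, idx)
      } else {
        n_tr <- round(cfg$train_fraction * length(idx))
        train_idx <- c(train_idx, sample(idx, n_tr))
      }
    }
  })
  list(train = records[sort(train_idx)],
       test = records[setdiff(seq_along(records), train_idx)])
}

#' Truncation augmentation for early-detection training
#'
#' For every training record with n usable visits, adds copies with the
#' last k visits removed (k = 1..n-1), keeping a copy only when the gap
#' between its new last visit and T0 is at most `max_gap_years`.  This
#' enriches training with records that stop well before diagnosis, which
#' is what an early-warning model must score.  Labels and T0 are
#' unchanged on copies; each copy records its origin and k.  Never apply
#' to the test set.
#'
#' @param records Training `labeled_record`s.
#' @param cfg An `augment_config`.
#' @return Originals plus qualifying truncated copies.
#' @export
augment_truncations <- function(records, cfg = augment_config()) {
  out <- list()
  for (r in records) {
    out[[length(out) + 1]] <- r
    if (!r$status %in% cfg$apply_to) next
    v <- r$usable_visits
    n <- nrow(v)
    if (n < 2) next
    for (k in seq_len(n - 1)) {
      vv <- v[seq_len(n - k), , drop = FALSE]
      gap <- r$t0_years - max(vv$age_years)
      if (!cfg$drop_gap_filter && gap > cfg$max_gap_years) next
      out[[length(out) + 1]] <- labeled_record(
        r$patient, r$status, r$t0_years, vv,
        origin_id = r$patient$patient_id, trunc_k = k
      )
    }
  }
  out
}
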