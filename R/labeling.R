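#' Labeling rules for CKD status assignment
#'
#' Records are assigned one of four statuses. A formal diagnosis code
#' anywhere in the record gives status `CKD`, with the evaluation age T0
#' set to the age at the *first* diagnosed visit and data more than
#' `post_diagnosis_window_years` (default 30 days) after T0 excluded.
#' Without a diagnosis, a record is `PROBABLE_CKD` when it carries a
#' structured CKD-risk token or at least `min_suggesting_points` distinct
#' CKD-suggesting criteria (high creatinine, low USG, lexicon note token).
#' Otherwise, a record whose visits span at least `nockd_lookahead_years`
#' is `NO_CKD`: T0 is the last-visit age minus the lookahead and the final
#' lookahead window is removed, so the "healthy" label is validated by the
#' disease-free follow-up. Records supporting none of these are
#' `EXCLUDED`.
#'
#' @param diagnosis_codes_ckd Codes counting as a formal CKD diagnosis.
#' @param probable_note_tokens Note-token lexicon suggesting CKD
#'   (case-insensitive exact token match).
#' @param risk_tokens Structured-risk tokens that directly imply
#'   `PROBABLE_CKD`.
#' @param post_diagnosis_window_years Data window kept after diagnosis.
#' @param nockd_lookahead_years Disease-free follow-up required for
#'   `NO_CKD`, removed from the usable data.
#' @param min_suggesting_points Distinct criteria needed for
#'   `PROBABLE_CKD` (default 2).
#' @param count_mode `"distinct_criteria"` (default) counts each criterion
#'   at most once; `"qualifying_measurements"` counts every qualifying
#'   measurement or token occurrence.
#' @return A `labeling_rules` list.
#' @export
labeling_rules <- function(diagnosis_codes_ckd = "CKD",
                           probable_note_tokens = ckd_note_lexicon(),
                           risk_tokens = "CKD_RISK",
                           post_diagnosis_window_years = 30 / 365.25,
                           nockd_lookahead_years = 2.0,
                           min_suggesting_points = 2,
                           count_mode = c("distinct_criteria",
                                          "qualifying_measurements")) {
  stopifnot(post_diagnosis_window_years > 0, nockd_lookahead_years > 0,
            min_suggesting_points >= 1)
  structure(list(diagnosis_codes_ckd = diagnosis_codes_ckd,
                 probable_note_tokens = probable_note_tokens,
                 risk_tokens = risk_tokens,
                 post_diagnosis_window_years = post_diagnosis_window_years,
                 nockd_lookahead_years = nockd_lookahead_years,
                 min_suggesting_points = min_suggesting_points,
                 count_mode = match.arg(count_mode)),
            class = "labeling_rules")
}

ckd_statuses <- function() c("CKD", "PROBABLE_CKD", "NO_CKD", "EXCLUDED")

#' Construct a labeled record
#'
#' @param patient A `patient_record`.
#' @param status One of `CKD`, `PROBABLE_CKD`, `NO_CKD`, `EXCLUDED`.
#' @param t0_years Evaluation age; present iff status is `CKD` or
#'   `NO_CKD`.
#' @param usable_visits Visit subset usable for modelling.
#' @param origin_id,trunc_k Provenance for truncation-augmented copies.
#' @export
labeled_record <- function(patient, status, t0_years, usable_visits,
                           origin_id = NA_character_, trunc_k = NA_integer_) {
  stopifnot(status %in% ckd_statuses())
  structure(list(patient = patient, status = status,
                 t0_years = t0_years, usable_visits = usable_visits,
                 origin_id = origin_id, trunc_k = trunc_k),
            class = "labeled_record")
}

#' @export
print.labeled_record <- function(x, ...) {
  cat(sprintf("<labeled_record> %s status=%s t0=%s usable_visits=%d\n",
              x$patient$patient_id, x$status,
              ifelse(is.na(x$t0_years), "-", sprintf("%.2f", x$t0_years)),
              nrow(x$usable_visits)))
  invisible(x)
}

tokens_lower <- function(visits) {
  tolower(unlist(visits$note_tokens))
}

#' Count CKD-suggesting data points in a record
#'
#' Three criteria are examined over the whole record: (a) any blood
#' creatinine above the catalog's normal high, (b) any USG below the
#' catalog's normal low, (c) any note token matching the probable-CKD
#' lexicon (case-insensitive exact token match).  Under the default
#' `distinct_criteria` mode each criterion counts at most once, so the
#' maximum is 3.
#'
#' @param record A `patient_record`.
#' @param catalog An `analyte_catalog` (must contain creatinine and USG).
#' @param rules A `labeling_rules`.
#' @return Integer count.
#' @export
count_ckd_suggesting_points <- function(record, catalog,
                                        rules = labeling_rules()) {
  for (a in c("creatinine", "USG")) {
    if (!a %in% catalog$analyte) {
      stop("configuration error: catalog lacks required analyte ", a)
    }
  }
  v <- record$visits
  crea_hi <- catalog_entry(catalog, "creatinine")$normal_high
  usg_lo <- catalog_entry(catalog, "USG")$normal_low
  n_crea <- sum(v$creatinine > crea_hi, na.rm = TRUE)
  n_usg <- sum(v$USG < usg_lo, na.rm = TRUE)
  toks <- tokens_lower(v)
  n_tok <- sum(toks %in% tolower(rules$probable_note_tokens))
  if (rules$count_mode == "distinct_criteria") {
    sum(c(n_crea, n_usg, n_tok) > 0)
  } else {
    n_crea + n_usg + n_tok
  }
}

#' Assign CKD status and evaluation age to one record
#'
#' @inheritParams count_ckd_suggesting_points
#' @return A `labeled_record`; `EXCLUDED` is a value, never an error.
#' @export
assign_status <- function(record, catalog, rules = labeling_rules()) {
  v <- record$visits
  has_dx <- vapply(v$diagnosis_codes, function(codes) {
    any(codes %in% rules$diagnosis_codes_ckd)
  }, logical(1))
  if (any(has_dx)) {
    t0 <- v$age_years[which(has_dx)[1]]
    keep <- v$age_years <= t0 + rules$post_diagnosis_window_years
    return(labeled_record(record, "CKD", t0, v[keep, , drop = FALSE]))
  }
  risk <- any(tokens_lower(v) %in% tolower(rules$risk_tokens))
  if (risk ||
      count_ckd_suggesting_points(record, catalog, rules) >=
        rules$min_suggesting_points) {
    return(labeled_record(record, "PROBABLE_CKD", NA_real_, v))
  }
  span <- max(v$age_years) - min(v$age_years)
  if (span >= rules$nockd_lookahead_years) {
    t0 <- max(v$age_years) - rules$nockd_lookahead_years
    keep <- v$age_years <= t0
    return(labeled_record(record, "NO_CKD", t0, v[keep, , drop = FALSE]))
  }
  labeled_record(record, "EXCLUDED", NA_real_, v[0, , drop = FALSE])
}

#' Label a whole cohort
#'
#' Applies [assign_status()] to each record, preserving order.  The four
#' statuses partition the cohort.
#'
#' @param records List of `patient_record`s.
#' @inheritParams count_ckd_suggesting_points
#' @return List of `labeled_record`s.
#' @export
label_cohort <- function(records, catalog, rules = labeling_rules()) {
  lapply(records, assign_status, catalog = catalog, rules = rules)
}

#' Persist labels
#'
#' @param labeled List of `labeled_record`s.
#' @param path Output CSV path (`patient_id`, `status`, `t0_years`).
#' @export
write_labels <- function(labeled, path) {
  df <- data.frame(
    patient_id = vapply(labeled, function(r) r$patient$patient_id,
                        character(1)),
    status = vapply(labeled, function(r) r$status, character(1)),
    t0_years = vapply(labeled, function(r) r$t0_years, numeric(1)),
    stringsAsFactors = FALSE
  )
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Rebuild labeled records from a trimmed EHR file plus a labels file
#'
#' Inverse of [write_labels()] + [write_ehr_table()] on usable visits:
#' reads the trimmed cohort and reattaches status and T0.
#'
#' @param ehr_path Trimmed EHR long-format file (usable visits only).
#' @param labels_path Labels CSV.
#' @param catalog An `analyte_catalog`.
#' @return List of `labeled_record`s.
#' @export
read_labeled_cohort <- function(ehr_path, labels_path, catalog) {
  records <- read_ehr_table(ehr_path, catalog)
  lab <- readr::read_csv(labels_path, col_types = readr::cols(
    patient_id = readr::col_character(), status = readr::col_character(),
    t0_years = readr::col_double()
  ), progress = FALSE)
  lapply(records, function(r) {
    i <- match(r$patient_id, lab$patient_id)
    if (is.na(i)) stop("no label for patient ", r$patient_id)
    labeled_record(r, lab$status[i], lab$t0_years[i], r$visits)
  })
}
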