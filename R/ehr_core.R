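#' Patient records
#'
#' The in-memory unit of the pipeline is the `patient_record`: one animal's
#' demographics plus its age-ordered visit sequence.  Visits are held in a
#' wide data frame with one numeric column per catalog analyte (`NA` means
#' not measured; 0 is never a missing sentinel), plus `age_years`,
#' `weight_kg`, and list-columns `note_tokens` and `diagnosis_codes`
#' holding character vectors per visit.  Time is fractional age in years;
#' all windows ("4 years preceding", "30 days") are arithmetic on
#' `age_years`, with 30 days = 30/365.25 years.
#'
#' @param patient_id Character scalar identifier.
#' @param sex `"male"` or `"female"`.
#' @param breed Character scalar (free text; never used by the model).
#' @param visits A visit data frame as produced by [new_visit_frame()],
#'   rows in any order (they are sorted by ascending age).
#' @return A `patient_record` object.
#' @export
patient_record <- function(patient_id, sex, breed, visits) {
  ord <- order(visits$age_years)
  visits <- visits[ord, , drop = FALSE]
  rownames(visits) <- NULL
  structure(
    list(patient_id = as.character(patient_id), sex = as.character(sex),
         breed = as.character(breed), visits = visits),
    class = "patient_record"
  )
}

#' @rdname patient_record
#' @param catalog An `analyte_catalog` supplying the analyte columns.
#' @param n Number of visit rows to allocate.
#' @export
new_visit_frame <- function(catalog, n = 0) {
  df <- data.frame(age_years = numeric(n), weight_kg = rep(NA_real_, n))
  for (a in analyte_names(catalog)) df[[a]] <- rep(NA_real_, n)
  df$note_tokens <- replicate(n, character(0), simplify = FALSE)
  df$diagnosis_codes <- replicate(n, character(0), simplify = FALSE)
  df
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s (%s, %s): %d visits, ages %.2f-%.2f y\n",
              x$patient_id, x$sex, x$breed, nrow(x$visits),
              min(x$visits$age_years), max(x$visits$age_years)))
  invisible(x)
}

#' @export
format.patient_record <- function(x, ...) {
  sprintf("<patient_record %s: %d visits>", x$patient_id, nrow(x$visits))
}

#' Validate a patient record against a catalog
#'
#' Structural validation only: visit ordering, duplicate ages, age bounds,
#' and analyte columns unknown to the catalog.  Implausible analyte
#' *values* are deliberately not flagged here — plausibility is handled by
#' outlier masking downstream, not by validation.
#'
#' @param record A `patient_record`.
#' @param catalog An `analyte_catalog`.
#' @param age_range Admissible age range in years.
#' @return A character vector of violation messages; empty when the record
#'   is well formed.  Violations are data, not exceptions.
#' @export
validate_record <- function(record, catalog, age_range = c(1.5, 22)) {
  out <- character(0)
  if (!inherits(record, "patient_record")) {
    return("not a patient_record object")
  }
  v <- record$visits
  if (nrow(v) < 1) out <- c(out, "record has no visits")
  if (is.na(record$patient_id) || !nzchar(record$patient_id)) {
    out <- c(out, "empty patient_id")
  }
  if (!record$sex %in% c("male", "female")) {
    out <- c(out, sprintf("sex '%s' is not male/female", record$sex))
  }
  if (nrow(v) > 0) {
    if (anyNA(v$age_years)) out <- c(out, "missing visit age")
    if (anyDuplicated(v$age_years)) out <- c(out, "duplicate visit ages")
    if (is.unsorted(v$age_years, strictly = FALSE)) {
      out <- c(out, "visits not sorted by ascending age")
    }
    oo <- v$age_years < age_range[1] | v$age_years > age_range[2]
    if (any(oo, na.rm = TRUE)) {
      out <- c(out, sprintf("%d visit(s) outside age range [%g, %g]",
                            sum(oo, na.rm = TRUE), age_range[1], age_range[2]))
    }
  }
  known <- c("age_years", "weight_kg", "note_tokens", "diagnosis_codes",
             analyte_names(catalog))
  unknown <- setdiff(names(v), known)
  if (length(unknown) > 0) {
    out <- c(out, paste0("analyte column(s) not in catalog: ",
                         paste(unknown, collapse = ", ")))
  }
  out
}

split_tokens <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, "|", fixed = TRUE)[[1]]
}

join_tokens <- function(tok) paste(tok, collapse = "|")

#' Read and write the EHR long format
#'
#' The on-disk exchange format is long-form delimited text (UTF-8, comma
#' separated, header row) with columns `patient_id`, `sex`, `breed`,
#' `age_years`, `weight_kg`, `analyte`, `value`, `note_tokens`
#' (`|`-separated), `diagnosis_codes` (`|`-separated): one row per
#' patient-visit-analyte, demographics repeated on every row.  A visit with
#' no measured analytes is carried by a single row with empty `analyte` and
#' `value` fields.  Missing values are empty fields.
#'
#' `read_ehr_table()` and `write_ehr_table()` round-trip: reading a written
#' cohort reproduces it field for field.
#'
#' @param path File path.
#' @param catalog An `analyte_catalog`; rows naming analytes outside the
#'   catalog are rejected with a schema error.
#' @return `read_ehr_table()`: a list of `patient_record`s, one per
#'   distinct `patient_id`, visits sorted by age.  `write_ehr_table()`:
#'   `path`, invisibly.
#' @export
read_ehr_table <- function(path, catalog) {
  spec <- readr::cols(
    patient_id = readr::col_character(), sex = readr::col_character(),
    breed = readr::col_character(), age_years = readr::col_double(),
    weight_kg = readr::col_double(), analyte = readr::col_character(),
    value = readr::col_double(), note_tokens = readr::col_character(),
    diagnosis_codes = readr::col_character()
  )
  df <- readr::read_csv(path, col_types = spec, progress = FALSE,
                        na = c("", "NA"))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed row(s) in %s: line %s (%s)", path,
                 paste(probs$row, collapse = ", "),
                 probs$expected[1]))
  }
  miss <- setdiff(c("patient_id", "age_years", "analyte", "value"), names(df))
  if (length(miss) > 0) stop("EHR file missing column(s): ",
                             paste(miss, collapse = ", "))
  named <- !is.na(df$analyte) & nzchar(df$analyte)
  unknown <- setdiff(unique(df$analyte[named]), analyte_names(catalog))
  if (length(unknown) > 0) {
    stop("schema error: analyte(s) not in catalog: ",
         paste(unknown, collapse = ", "))
  }
  if (anyNA(df$age_years)) {
    stop(sprintf("malformed row(s) in %s: missing age_years at data row %s",
                 path, paste(which(is.na(df$age_years)), collapse = ", ")))
  }
  records <- lapply(split(seq_len(nrow(df)), df$patient_id), function(idx) {
    sub <- df[idx, , drop = FALSE]
    ages <- sort(unique(sub$age_years))
    visits <- new_visit_frame(catalog, length(ages))
    visits$age_years <- ages
    rowvis <- match(sub$age_years, ages)
    for (j in seq_along(ages)) {
      rws <- which(rowvis == j)
      visits$weight_kg[j] <- first_non_na(sub$weight_kg[rws])
      nt <- unique(unlist(lapply(sub$note_tokens[rws], split_tokens)))
      dc <- unique(unlist(lapply(sub$diagnosis_codes[rws], split_tokens)))
      visits$note_tokens[[j]] <- as.character(nt)
      visits$diagnosis_codes[[j]] <- as.character(dc)
      for (k in rws) {
        if (!is.na(sub$analyte[k]) && nzchar(sub$analyte[k])) {
          visits[[sub$analyte[k]]][j] <- sub$value[k]
        }
      }
    }
    patient_record(sub$patient_id[1], sub$sex[1], sub$breed[1], visits)
  })
  unname(records[unique(df$patient_id)])
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else x[1]
}

#' @rdname read_ehr_table
#' @param records A list of `patient_record`s.
#' @export
write_ehr_table <- function(records, path) {
  rows <- lapply(records, function(r) {
    v <- r$visits
    acols <- setdiff(names(v), c("age_years", "weight_kg", "note_tokens",
                                 "diagnosis_codes"))
    per_visit <- lapply(seq_len(nrow(v)), function(j) {
      vals <- vapply(acols, function(a) v[[a]][j], numeric(1))
      present <- acols[!is.na(vals)]
      if (length(present) == 0) {
        an <- NA_character_; va <- NA_real_
      } else {
        an <- present; va <- vals[present]
      }
      data.frame(
        patient_id = r$patient_id, sex = r$sex, breed = r$breed,
        age_years = v$age_years[j], weight_kg = v$weight_kg[j],
        analyte = an, value = unname(va),
        note_tokens = join_tokens(v$note_tokens[[j]]),
        diagnosis_codes = join_tokens(v$diagnosis_codes[[j]]),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_visit)
  })
  out <- if (length(rows) == 0) {
    data.frame(patient_id = character(0), sex = character(0),
               breed = character(0), age_years = numeric(0),
               weight_kg = numeric(0), analyte = character(0),
               value = numeric(0), note_tokens = character(0),
               diagnosis_codes = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}
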