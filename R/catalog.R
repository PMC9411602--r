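#' Analyte catalogs
#'
#' An analyte catalog defines the laboratory panel the pipeline understands:
#' for every analyte its units, a canine normal range, and whether it is
#' measured in blood or urine.  The catalog drives three downstream rules:
#' schema validation of input files, extreme-outlier masking (values far
#' above `normal_high` are set missing), and the CKD-suggesting flags used
#' by probable-CKD labeling (creatinine above `normal_high`, urine specific
#' gravity below `normal_low`).
#'
#' The default catalog ships with the package and covers 35 analytes
#' (hematology, clinical chemistry and urinalysis) with literature-typical
#' canine reference ranges.  It is fully user-overridable: any data frame
#' with columns `analyte`, `units`, `normal_low`, `normal_high`, `category`
#' can be passed to [analyte_catalog()].
#'
#' @param path Path to a catalog CSV.  Defaults to the catalog shipped with
#'   the package.
#' @return An `analyte_catalog`: a data frame with columns `analyte`,
#'   `units`, `normal_low`, `normal_high` and `category`
#'   (`"blood"`/`"urine"`), one row per analyte.
#' @examples
#' cat35 <- default_catalog()
#' nrow(cat35)
#' subset(cat35, analyte == "creatinine")
#' @export
default_catalog <- function(path = system.file("extdata", "analyte_catalog.csv",
                                               package = "ckdwatch")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  analyte_catalog(df)
}

#' @rdname default_catalog
#' @param x A data frame with the catalog columns (see above).
#' @export
analyte_catalog <- function(x) {
  need <- c("analyte", "units", "normal_low", "normal_high", "category")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("catalog is missing columns: ", paste(miss, collapse = ", "))
  }
  x <- as.data.frame(x)[need]
  x$analyte <- as.character(x$analyte)
  x$units <- as.character(x$units)
  x$units[is.na(x$units)] <- ""
  x$normal_low <- as.numeric(x$normal_low)
  x$normal_high <- as.numeric(x$normal_high)
  x$category <- as.character(x$category)
  if (anyDuplicated(x$analyte)) stop("duplicate analyte names in catalog")
  if (!all(x$category %in% c("blood", "urine"))) {
    stop("catalog category must be 'blood' or 'urine'")
  }
  if (!all(x$normal_low < x$normal_high)) {
    bad <- x$analyte[!(x$normal_low < x$normal_high)]
    stop("normal_low must be < normal_high; offending analytes: ",
         paste(bad, collapse = ", "))
  }
  mandatory <- c("creatinine", "BUN", "USG", "urine_protein")
  if (!all(mandatory %in% x$analyte)) {
    stop("catalog must contain the mandatory analytes: ",
         paste(setdiff(mandatory, x$analyte), collapse = ", "))
  }
  rownames(x) <- x$analyte
  class(x) <- c("analyte_catalog", "data.frame")
  x
}

#' @rdname default_catalog
#' @param catalog An `analyte_catalog`.
#' @param category Optional filter, `"blood"` or `"urine"`.
#' @export
analyte_names <- function(catalog, category = NULL) {
  if (is.null(category)) return(catalog$analyte)
  catalog$analyte[catalog$category == category]
}

catalog_entry <- function(catalog, analyte) {
  i <- match(analyte, catalog$analyte)
  if (is.na(i)) stop("analyte '", analyte, "' is not in the catalog")
  catalog[i, ]
}
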