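#' Imputer configuration
#'
#' @param max_iter Maximum chained-update sweeps.
#' @param tol Stop when the normalized change in imputed values between
#'   sweeps falls below this.
#' @param trees Trees per random-forest regressor.
#' @param seed Integer seed (forest fits are seeded per column).
#' @param method `"rf"` (tree-ensemble regressors, the default) or
#'   `"linear"` (chained linear regressions; much faster, used where
#'   imputation quality is not the object of study).
#' @export
imputer_config <- function(max_iter = 10, tol = 1e-3, trees = 50, seed,
                           method = c("rf", "linear")) {
  stopifnot(max_iter >= 1, tol > 0, trees >= 1)
  if (missing(seed)) stop("imputer_config requires an explicit seed")
  structure(list(max_iter = max_iter, tol = tol, trees = trees,
                 seed = as.integer(seed), method = match.arg(method)),
            class = "imputer_config")
}

#' Cross-sectional visit matrix for imputation
#'
#' One row per usable visit, one column per blood/urine analyte with at
#' least one observed value in the cohort.  Status, T0 and diagnosis
#' fields are not part of the matrix, so imputation cannot consult them.
#'
#' @param records List of `labeled_record`s.
#' @param catalog An `analyte_catalog`.
#' @return A numeric matrix with attribute `"index"`: a data frame mapping
#'   each row to (record position, visit row).
#' @export
visit_matrix <- function(records, catalog) {
  cols <- c(analyte_names(catalog, "blood"), analyte_names(catalog, "urine"))
  blocks <- lapply(seq_along(records), function(i) {
    v <- records[[i]]$usable_visits
    if (nrow(v) == 0) return(NULL)
    m <- as.matrix(v[cols])
    attr(m, "rec") <- rep(i, nrow(v))
    m
  })
  blocks <- Filter(Negate(is.null), blocks)
  mat <- do.call(rbind, blocks)
  rec <- unlist(lapply(blocks, attr, "rec"))
  vis <- unlist(lapply(blocks, function(b) seq_len(nrow(b))))
  observed <- colSums(!is.na(mat)) > 0
  mat <- mat[, observed, drop = FALSE]
  attr(mat, "index") <- data.frame(record = rec, visit = vis)
  mat
}

fit_column_regressor <- function(y, x, cfg, col_seed) {
  if (cfg$method == "rf") {
    ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = cfg$trees,
      seed = col_seed, num.threads = 1, respect.unordered.factors = FALSE
    )
  } else {
    dat <- as.data.frame(x)
    dat$.y <- y
    stats::lm(.y ~ ., data = dat)
  }
}

predict_column <- function(model, x, cfg) {
  if (cfg$method == "rf") {
    stats::predict(model, data = as.data.frame(x))$predictions
  } else {
    unname(stats::predict(model, newdata = as.data.frame(x)))
  }
}

#' Fit a chained nonparametric imputer
#'
#' Iterative chained imputation in the spirit of missForest: missing cells
#' start at column means; each sweep regresses every analyte (in order of
#' ascending missingness) on all others using the current completed
#' matrix and updates its missing cells with the regressor's predictions;
#' sweeps stop when the normalized change in imputed values drops below
#' `tol` or after `max_iter` sweeps.  Deterministic given the seed.
#'
#' @param mat A visit matrix (see [visit_matrix()]) with >= 2 columns and
#'   at least one observed value per column.
#' @param cfg An `imputer_config`.
#' @return An `imputer_model`: column means, per-column fitted regressors
#'   from the final sweep, the sweep count reached, and the convergence
#'   trace.
#' @export
fit_imputer <- function(mat, cfg) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  all_missing <- colnames(mat)[colSums(!is.na(mat)) == 0]
  if (length(all_missing) > 0) {
    stop("imputation error: column(s) with no observed values: ",
         paste(all_missing, collapse = ", "))
  }
  mu <- colMeans(mat, na.rm = TRUE)
  miss <- is.na(mat)
  order_cols <- colnames(mat)[order(colSums(miss))]
  filled <- mat
  for (j in colnames(mat)) filled[miss[, j], j] <- mu[[j]]

  models <- stats::setNames(vector("list", ncol(mat)), colnames(mat))
  trace <- numeric(0)
  iters <- 0L
  any_missing <- any(miss)
  max_sweeps <- if (any_missing) cfg$max_iter else 1L
  for (it in seq_len(max_sweeps)) {
    prev <- filled
    for (ci in seq_along(order_cols)) {
      j <- order_cols[ci]
      obs <- !miss[, j]
      others <- setdiff(colnames(mat), j)
      fit <- fit_column_regressor(filled[obs, j],
                                  filled[obs, others, drop = FALSE],
                                  cfg, cfg$seed + ci)
      models[[j]] <- fit
      if (any(miss[, j])) {
        filled[miss[, j], j] <- predict_column(
          fit, filled[miss[, j], others, drop = FALSE], cfg
        )
      }
    }
    if (!any_missing) break
    iters <- it
    delta <- sum((filled[miss] - prev[miss])^2) /
      max(sum(filled[miss]^2), .Machine$double.eps)
    trace <- c(trace, delta)
    # stop on tolerance, or when the update change starts growing again
    # (the usual chained-imputation convention)
    if (delta < cfg$tol) break
    if (it >= 2 && delta > trace[it - 1]) break
  }
  structure(list(columns = colnames(mat), col_means = mu, models = models,
                 col_order = order_cols, iterations = iters,
                 convergence = trace, config = cfg),
            class = "imputer_model")
}

impute_matrix <- function(model, mat) {
  stopifnot(identical(colnames(mat), model$columns))
  miss <- is.na(mat)
  if (!any(miss)) return(mat)
  filled <- mat
  for (j in colnames(mat)) filled[miss[, j], j] <- model$col_means[[j]]
  cfg <- model$config
  for (it in seq_len(cfg$max_iter)) {
    prev <- filled
    for (j in model$col_order) {
      if (!any(miss[, j])) next
      others <- setdiff(model$columns, j)
      filled[miss[, j], j] <- predict_column(
        model$models[[j]], filled[miss[, j], others, drop = FALSE], cfg
      )
    }
    delta <- sum((filled[miss] - prev[miss])^2) /
      max(sum(filled[miss]^2), .Machine$double.eps)
    if (delta < cfg$tol) break
  }
  filled
}

#' Impute missing laboratory values in labeled records
#'
#' Applies a fitted imputer to every usable visit.  Observed cells are
#' preserved exactly; imputed USG is clipped to its physiologic range
#' and other analytes to non-negative values.
#'
#' @param records List of `labeled_record`s.
#' @param model An `imputer_model`.
#' @param catalog An `analyte_catalog` compatible with the model.
#' @return The records with every modeled blood/urine cell populated.
#' @export
impute_missing <- function(records, model, catalog) {
  unknown <- setdiff(model$columns, analyte_names(catalog))
  if (length(unknown) > 0) {
    stop("configuration error: model columns unknown to catalog: ",
         paste(unknown, collapse = ", "))
  }
  mat <- visit_matrix(records, catalog)
  keep <- intersect(model$columns, colnames(mat))
  if (!identical(sort(keep), sort(model$columns))) {
    stop("configuration error: records lack model column(s): ",
         paste(setdiff(model$columns, colnames(mat)), collapse = ", "))
  }
  idx <- attr(mat, "index")
  mat <- mat[, model$columns, drop = FALSE]
  filled <- impute_matrix(model, mat)
  bounds <- usg_bounds()
  for (j in model$columns) {
    v <- filled[, j]
    v <- if (j == "USG") pmin(pmax(v, bounds[1]), bounds[2]) else pmax(v, 0)
    filled[, j] <- v
  }
  for (ri in unique(idx$record)) {
    rows <- which(idx$record == ri)
    v <- records[[ri]]$usable_visits
    sub <- v[model$columns]
    m <- is.na(as.matrix(sub))
    if (any(m)) {
      block <- filled[rows, , drop = FALSE]
      sub[m] <- block[m]
      v[model$columns] <- sub
      records[[ri]]$usable_visits <- v
    }
  }
  records
}
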