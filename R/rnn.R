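#' Feature specification and scaling
#'
#' The classifier consumes one vector per visit.  The default feature set
#' is the six-feature panel the workflow settles on: creatinine, BUN, USG,
#' urine protein, body weight, and the dog's age at the visit.  Features
#' are standardised with a per-feature mean/SD scaler fitted on training
#' data only.  Age is supplied per visit, so truncated training copies
#' naturally look "younger" than their originals.
#'
#' @param features Ordered character vector of feature names.  `"age"`
#'   and `"weight"` map to the visit's `age_years` / `weight_kg`; any
#'   other name must be a catalog analyte column.
#' @param scaler A data frame with columns `feature`, `mean`, `sd`, as
#'   fitted by [fit_feature_scaler()].
#' @export
feature_spec <- function(features = default_features(), scaler) {
  stopifnot(length(features) >= 1)
  if (any(scaler$sd <= 0)) {
    stop("configuration error: unscalable feature(s) (sd <= 0): ",
         paste(scaler$feature[scaler$sd <= 0], collapse = ", "))
  }
  stopifnot(identical(sort(features), sort(scaler$feature)))
  structure(list(features = features, scaler = scaler),
            class = "feature_spec")
}

#' @rdname feature_spec
#' @export
default_features <- function() {
  c("creatinine", "BUN", "USG", "urine_protein", "weight", "age")
}

feature_column <- function(f) {
  switch(f, age = "age_years", weight = "weight_kg", f)
}

#' @rdname feature_spec
#' @param records Training `labeled_record`s the scaler is fitted on.
#' @export
fit_feature_scaler <- function(records, features = default_features()) {
  rows <- lapply(features, function(f) {
    col <- feature_column(f)
    vals <- unlist(lapply(records, function(r) r$usable_visits[[col]]))
    vals <- vals[!is.na(vals)]
    data.frame(feature = f, mean = mean(vals), sd = stats::sd(vals),
               stringsAsFactors = FALSE)
  })
  feature_spec(features, do.call(rbind, rows))
}

#' Assemble per-record visit sequences
#'
#' One `sequence_sample` per record: a T x d matrix of standardised
#' per-visit feature vectors in age order.  Laboratory features must be
#' imputed beforehand; missing weight is carried forward from the most
#' recent prior visit, falling back to the cohort median weight.
#' `PROBABLE_CKD` records are refused — they are never used for training
#' or headline metrics.
#'
#' @param records List of `labeled_record`s with status `CKD` or
#'   `NO_CKD`.
#' @param spec A `feature_spec` (scaler already fitted).
#' @return A list of samples, each with `x` (matrix), `label`, `y`
#'   (1 = CKD), `id` and `trunc_k`.
#' @export
build_sequences <- function(records, spec) {
  statuses <- vapply(records, function(r) r$status, character(1))
  if (any(statuses == "PROBABLE_CKD")) {
    stop("contract error: PROBABLE_CKD records cannot be turned into ",
         "training/evaluation sequences")
  }
  all_w <- unlist(lapply(records, function(r) r$usable_visits$weight_kg))
  median_w <- stats::median(all_w, na.rm = TRUE)
  sc <- spec$scaler[match(spec$features, spec$scaler$feature), ]
  lapply(records, function(r) {
    v <- r$usable_visits
    w <- v$weight_kg
    for (j in seq_along(w)) {
      if (is.na(w[j])) w[j] <- if (j > 1) w[j - 1] else NA_real_
    }
    w[is.na(w)] <- median_w
    raw <- vapply(seq_along(spec$features), function(fi) {
      f <- spec$features[fi]
      if (f == "weight") return(w)
      vals <- v[[feature_column(f)]]
      if (anyNA(vals)) {
        stop("feature '", f, "' has missing values in record ",
             r$patient$patient_id, "; impute first")
      }
      vals
    }, numeric(nrow(v)))
    raw <- matrix(raw, nrow = nrow(v))
    x <- sweep(sweep(raw, 2, sc$mean, "-"), 2, sc$sd, "/")
    colnames(x) <- spec$features
    list(x = x, label = r$status, y = as.integer(r$status == "CKD"),
         id = r$patient$patient_id, trunc_k = r$trunc_k)
  })
}

#' Network configuration
#'
#' Defaults follow the selected production architecture: three hidden
#' layers of 5, 3 and 3 tanh units trained for 8 epochs with 20%
#' inverted dropout, RMSprop updates and a 2-unit softmax head.
#'
#' @param hidden_layers Integer widths of the stacked recurrent layers.
#' @param dropout Dropout probability on hidden activations fed upward
#'   (training only; the recurrent path is not dropped).
#' @param epochs Training epochs.
#' @param learning_rate,rmsprop_decay RMSprop step size and decay.
#' @param batch_size Sequences per gradient update.
#' @param seed Integer seed; training is deterministic given it.
#' @export
net_config <- function(hidden_layers = c(5, 3, 3), dropout = 0.2,
                       epochs = 8, learning_rate = 1e-3,
                       rmsprop_decay = 0.9, batch_size = 1, seed = 1) {
  stopifnot(all(hidden_layers >= 1), dropout >= 0, dropout < 1,
            epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 dropout = dropout, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 rmsprop_decay = rmsprop_decay,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "net_config")
}

n_parameters <- function(config, n_features) {
  widths <- config$hidden_layers
  ins <- c(n_features, widths[-length(widths)])
  sum(widths * ins + widths * widths + widths) + 2 * widths[length(widths)] + 2
}

init_net <- function(config, spec) {
  d <- length(spec$features)
  widths <- config$hidden_layers
  ins <- c(d, widths[-length(widths)])
  layers <- withr::with_seed(config$seed, {
    ls <- lapply(seq_along(widths), function(l) {
      s_w <- 1 / sqrt(ins[l])
      s_u <- 1 / sqrt(widths[l])
      list(W = matrix(stats::runif(widths[l] * ins[l], -s_w, s_w),
                      widths[l], ins[l]),
           U = matrix(stats::runif(widths[l] * widths[l], -s_u, s_u),
                      widths[l], widths[l]),
           b = numeric(widths[l]))
    })
    last <- widths[length(widths)]
    s_o <- 1 / sqrt(last)
    list(layers = ls,
         Wout = matrix(stats::runif(2 * last, -s_o, s_o), 2, last),
         bout = numeric(2))
  })
  structure(list(layers = layers$layers, Wout = layers$Wout,
                 bout = layers$bout, config = config, feature_spec = spec,
                 loss_trace = numeric(0)),
            class = "trained_net")
}

softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Forward pass over one sequence.  x: T x d.  masks: optional list, one
# (width x T) inverted-dropout mask matrix per layer, applied to hidden
# activations fed upward (and into the output head), not to recurrence.
rnn_forward <- function(net, x, masks = NULL) {
  T_ <- nrow(x)
  L <- length(net$layers)
  H <- lapply(net$layers, function(ly) matrix(0, length(ly$b), T_))
  IN <- lapply(seq_len(L), function(l) {
    matrix(0, ncol(net$layers[[l]]$W), T_)
  })
  h_prev <- lapply(net$layers, function(ly) numeric(length(ly$b)))
  for (t in seq_len(T_)) {
    inp <- x[t, ]
    for (l in seq_len(L)) {
      ly <- net$layers[[l]]
      IN[[l]][, t] <- inp
      h <- tanh(drop(ly$W %*% inp + ly$U %*% h_prev[[l]] + ly$b))
      H[[l]][, t] <- h
      h_prev[[l]] <- h
      inp <- if (is.null(masks)) h else h * masks[[l]][, t]
    }
  }
  logits <- drop(net$Wout %*% inp + net$bout)
  p <- softmax2(logits)
  list(p = p, H = H, IN = IN, top_out = inp)
}

#' Score one visit sequence
#'
#' Iterates the stacked tanh recurrence over the sample's time steps and
#' returns the softmax CKD probability (first output unit).  Dropout is
#' inactive at inference.
#'
#' @param net A `trained_net`.
#' @param sample A `sequence_sample` from [build_sequences()] (or any
#'   list with an `x` matrix).
#' @return `p(CKD)` in `[0, 1]`.
#' @export
forward <- function(net, sample) {
  x <- if (is.list(sample)) sample$x else sample
  if (ncol(x) != ncol(net$layers[[1]]$W)) {
    stop("contract error: sample has ", ncol(x), " features, net expects ",
         ncol(net$layers[[1]]$W))
  }
  rnn_forward(net, x)$p[1]
}

#' @rdname forward
#' @param samples A list of samples.
#' @export
predict_proba <- function(net, samples) {
  vapply(samples, function(s) forward(net, s), numeric(1))
}

zero_like_net <- function(net) {
  list(layers = lapply(net$layers, function(ly) {
    list(W = ly$W * 0, U = ly$U * 0, b = ly$b * 0)
  }), Wout = net$Wout * 0, bout = net$bout * 0)
}

# Backpropagation through time for one sequence.  Returns the loss
# (cross-entropy of the final softmax against y) and gradients for every
# weight array.
rnn_bptt <- function(net, x, y, masks = NULL) {
  fw <- rnn_forward(net, x, masks)
  T_ <- nrow(x)
  L <- length(net$layers)
  target <- if (y == 1) c(1, 0) else c(0, 1)
  loss <- -log(max(sum(fw$p * target), .Machine$double.xmin))
  g <- zero_like_net(net)
  dlogits <- fw$p - target
  g$Wout <- dlogits %*% t(fw$top_out)
  g$bout <- dlogits
  d_top <- drop(t(net$Wout) %*% dlogits)
  if (!is.null(masks)) d_top <- d_top * masks[[L]][, T_]
  dh_rec <- lapply(net$layers, function(ly) numeric(length(ly$b)))
  for (t in rev(seq_len(T_))) {
    d_above <- if (t == T_) d_top else numeric(length(net$layers[[L]]$b))
    for (l in rev(seq_len(L))) {
      ly <- net$layers[[l]]
      dh <- dh_rec[[l]] + d_above
      da <- dh * (1 - fw$H[[l]][, t]^2)
      g$layers[[l]]$W <- g$layers[[l]]$W + da %*% t(fw$IN[[l]][, t])
      h_before <- if (t > 1) fw$H[[l]][, t - 1] else numeric(length(ly$b))
      g$layers[[l]]$U <- g$layers[[l]]$U + da %*% t(h_before)
      g$layers[[l]]$b <- g$layers[[l]]$b + da
      dh_rec[[l]] <- drop(t(ly$U) %*% da)
      if (l > 1) {
        d_above <- drop(t(ly$W) %*% da)
        if (!is.null(masks)) d_above <- d_above * masks[[l - 1]][, t]
      }
    }
  }
  list(loss = loss, grads = g)
}

scale_grads <- function(g, s) {
  list(layers = lapply(g$layers, function(ly) {
    list(W = ly$W * s, U = ly$U * s, b = ly$b * s)
  }), Wout = g$Wout * s, bout = g$bout * s)
}

add_grads <- function(a, b) {
  list(layers = lapply(seq_along(a$layers), function(l) {
    list(W = a$layers[[l]]$W + b$layers[[l]]$W,
         U = a$layers[[l]]$U + b$layers[[l]]$U,
         b = a$layers[[l]]$b + b$layers[[l]]$b)
  }), Wout = a$Wout + b$Wout, bout = a$bout + b$bout)
}

sample_masks <- function(net, T_, dropout) {
  lapply(net$layers, function(ly) {
    w <- length(ly$b)
    keep <- matrix(stats::runif(w * T_) >= dropout, w, T_)
    keep / (1 - dropout)
  })
}

#' Train the recurrent classifier
#'
#' Minimises mean cross-entropy of the final-step softmax against the
#' CKD/no-CKD label via backpropagation through time, with per-parameter
#' RMSprop updates and inverted dropout on hidden activations (training
#' only).  Sequences are processed individually (no padding); gradients
#' are averaged over minibatches of sequences.  Deterministic given
#' `config$seed`.
#'
#' @param samples A list of `sequence_sample`s containing both classes.
#' @param config A `net_config`.
#' @param spec The `feature_spec` used to build the samples.
#' @return A `trained_net` with a per-epoch training-loss trace.
#' @export
train_rnn <- function(samples, config, spec) {
  ys <- vapply(samples, `[[`, numeric(1), "y")
  if (length(unique(ys)) < 2) {
    stop("training error: samples contain a single class")
  }
  net <- init_net(config, spec)
  sq <- function(g) lapply(rapply(g, function(m) m * 0, how = "replace"),
                           identity)
  v_state <- zero_like_net(net)
  eps <- 1e-8
  rms_update <- function(net, g) {
    upd <- function(w, gw, vw) {
      vw_new <- config$rmsprop_decay * vw +
        (1 - config$rmsprop_decay) * gw^2
      list(w = w - config$learning_rate * gw / (sqrt(vw_new) + eps),
           v = vw_new)
    }
    for (l in seq_along(net$layers)) {
      for (nm in c("W", "U", "b")) {
        r <- upd(net$layers[[l]][[nm]], g$layers[[l]][[nm]],
                 v_state$layers[[l]][[nm]])
        net$layers[[l]][[nm]] <- r$w
        v_state$layers[[l]][[nm]] <<- r$v
      }
    }
    r <- upd(net$Wout, g$Wout, v_state$Wout)
    net$Wout <- r$w; v_state$Wout <<- r$v
    r <- upd(net$bout, g$bout, v_state$bout)
    net$bout <- r$w; v_state$bout <<- r$v
    net
  }
  trace <- numeric(config$epochs)
  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(seq_along(samples))
      ep_loss <- 0
      b_start <- seq(1, length(ord), by = config$batch_size)
      for (bs in b_start) {
        idx <- ord[bs:min(bs + config$batch_size - 1, length(ord))]
        acc <- NULL
        for (i in idx) {
          s <- samples[[i]]
          masks <- if (config$dropout > 0) {
            sample_masks(net, nrow(s$x), config$dropout)
          } else NULL
          r <- rnn_bptt(net, s$x, s$y, masks)
          ep_loss <- ep_loss + r$loss
          acc <- if (is.null(acc)) r$grads else add_grads(acc, r$grads)
        }
        net <- rms_update(net, scale_grads(acc, 1 / length(idx)))
      }
      trace[ep] <- ep_loss / length(samples)
    }
  })
  net$loss_trace <- trace
  net
}

#' F1 score at a probability cutoff
#'
#' @param labels 0/1 labels (1 = CKD).
#' @param probs Predicted probabilities.
#' @param cutoff Classification threshold; ties classify as CKD.
#' @export
f1_score <- function(labels, probs, cutoff = 0.5) {
  pred <- probs >= cutoff
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

stratified_folds <- function(ys, k, seed) {
  if (k > min(table(ys))) {
    stop("argument error: more folds than members of the smallest class")
  }
  fold <- integer(length(ys))
  withr::with_seed(seed, {
    for (cl in unique(ys)) {
      idx <- sample(which(ys == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

cv_f1 <- function(samples, config, spec, folds, fold_seed) {
  ys <- vapply(samples, `[[`, numeric(1), "y")
  fold <- stratified_folds(ys, folds, fold_seed)
  scores <- vapply(seq_len(folds), function(f) {
    tr <- samples[fold != f]
    te <- samples[fold == f]
    net <- train_rnn(tr, config, spec)
    f1_score(vapply(te, `[[`, numeric(1), "y"), predict_proba(net, te))
  }, numeric(1))
  mean(scores)
}

#' Greedy wrapper feature selection
#'
#' Bottom-up (forward) and top-down (backward) greedy search over feature
#' subsets: every candidate subset is scored by retraining the base
#' recurrent net per fold and averaging the fold F1 at the 0.5 cutoff
#' under stratified cross-validation.  The selection net defaults to two
#' hidden layers of 3 and 7 units.
#'
#' @param candidates Candidate feature names.
#' @param records Imputed training `labeled_record`s used to build
#'   sequences for each subset.
#' @param base_config `net_config` for the selection nets.
#' @param folds Cross-validation folds.
#' @return A list with data frames `forward` and `backward`, one row per
#'   subset size with the best subset (comma-joined) and its CV F1.
#' @export
wrapper_feature_selection <- function(candidates, records,
                                      base_config = net_config(
                                        hidden_layers = c(3, 7)),
                                      folds = 3) {
  stopifnot(length(candidates) >= 1)
  score_subset <- function(feats) {
    spec <- fit_feature_scaler(records, feats)
    samples <- build_sequences(records, spec)
    cv_f1(samples, base_config, spec, folds, base_config$seed + 97L)
  }
  forward_rows <- list()
  sel <- character(0)
  while (length(sel) < length(candidates)) {
    rest <- setdiff(candidates, sel)
    scores <- vapply(rest, function(f) score_subset(c(sel, f)), numeric(1))
    best <- rest[which.max(scores)]
    sel <- c(sel, best)
    forward_rows[[length(sel)]] <- data.frame(
      size = length(sel), features = paste(sel, collapse = ","),
      cv_f1 = max(scores), stringsAsFactors = FALSE)
  }
  backward_rows <- list()
  cur <- candidates
  backward_rows[[1]] <- data.frame(
    size = length(cur), features = paste(cur, collapse = ","),
    cv_f1 = score_subset(cur), stringsAsFactors = FALSE)
  while (length(cur) > 1) {
    scores <- vapply(cur, function(f) score_subset(setdiff(cur, f)),
                     numeric(1))
    cur <- setdiff(cur, cur[which.max(scores)])
    backward_rows[[length(backward_rows) + 1]] <- data.frame(
      size = length(cur), features = paste(cur, collapse = ","),
      cv_f1 = max(scores), stringsAsFactors = FALSE)
  }
  list(forward = do.call(rbind, forward_rows),
       backward = do.call(rbind, backward_rows))
}

#' Architecture screen
#'
#' Scores each candidate configuration by mean cross-validated F1 at the
#' 0.5 cutoff and returns the best, breaking ties toward the
#' configuration with fewer parameters.
#'
#' @param grid List of `net_config`s.
#' @param samples Labeled `sequence_sample`s.
#' @param spec The `feature_spec` behind the samples.
#' @param folds Cross-validation folds (default 10).
#' @return A list with `best` (a `net_config`) and `table` (config label,
#'   parameter count, mean CV F1).
#' @export
architecture_screen <- function(grid, samples, spec, folds = 10) {
  stopifnot(length(grid) >= 1)
  d <- length(spec$features)
  rows <- lapply(grid, function(cfg) {
    data.frame(
      hidden = paste(cfg$hidden_layers, collapse = "-"),
      n_params = n_parameters(cfg, d),
      mean_cv_f1 = cv_f1(samples, cfg, spec, folds, cfg$seed + 193L),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best_f1 <- max(tab$mean_cv_f1)
  cand <- which(tab$mean_cv_f1 >= best_f1 - 1e-12)
  best <- cand[which.min(tab$n_params[cand])]
  list(best = grid[[best]], table = tab)
}

#' Persist / restore a trained network as JSON
#'
#' @param net A `trained_net`.
#' @param path File path.
#' @export
save_net <- function(net, path) {
  obj <- list(
    format_version = 1L,
    layers = lapply(net$layers, function(ly) {
      list(W = ly$W, U = ly$U, b = ly$b)
    }),
    Wout = net$Wout, bout = net$bout,
    config = unclass(net$config),
    feature_spec = list(features = net$feature_spec$features,
                        scaler = net$feature_spec$scaler),
    loss_trace = net$loss_trace
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_net
#' @export
load_net <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(nrow_or_len(obj$layers)), function(l) {
    ly <- if (is.data.frame(obj$layers)) {
      list(W = obj$layers$W[[l]], U = obj$layers$U[[l]],
           b = obj$layers$b[[l]])
    } else obj$layers[[l]]
    list(W = as.matrix(ly$W), U = as.matrix(ly$U), b = as.numeric(ly$b))
  })
  cfg <- do.call(net_config, obj$config[c("hidden_layers", "dropout",
                                          "epochs", "learning_rate",
                                          "rmsprop_decay", "batch_size",
                                          "seed")])
  spec <- feature_spec(obj$feature_spec$features,
                       as.data.frame(obj$feature_spec$scaler))
  structure(list(layers = layers, Wout = as.matrix(obj$Wout),
                 bout = as.numeric(obj$bout), config = cfg,
                 feature_spec = spec,
                 loss_trace = as.numeric(obj$loss_trace)),
            class = "trained_net")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
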