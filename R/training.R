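# Training harness: class weighting, F1-monitored early stopping,
# per-epoch decision-threshold tuning and seed ensembling.

#' Training configuration
#'
#' Defaults mirror the system parameterization: RMSprop with categorical
#' cross-entropy, batch size 128, up to 500 epochs, early-stopping patience
#' 30 monitoring validation micro-F1, validation split 0.3 and a 3-member
#' seed ensemble. Setting `validation_split = 0` switches to no-validation
#' mode: training runs exactly `max_epochs` and keeps the final weights.
#'
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of training epochs.
#' @param patience Epochs without validation improvement tolerated before
#'   stopping (must not exceed `max_epochs`).
#' @param validation_split Fraction of instances held out for monitoring,
#'   in `[0, 1)`.
#' @param n_seeds Ensemble members trained under different random states.
#' @param threshold_grid Candidate decision thresholds.
#' @param learning_rate RMSprop learning rate.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 128L, max_epochs = 500L,
                         patience = 30L, validation_split = 0.3,
                         n_seeds = 3L,
                         threshold_grid = seq(0, 1, by = 0.01),
                         learning_rate = 1e-3) {
  stopifnot(validation_split >= 0, validation_split < 1,
            patience <= max_epochs, batch_size >= 1L, n_seeds >= 1L,
            all(threshold_grid >= 0), all(threshold_grid <= 1))
  structure(list(
    optimizer = "RMSPROP", loss = "categorical cross-entropy",
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), validation_split = validation_split,
    n_seeds = as.integer(n_seeds), threshold_grid = threshold_grid,
    learning_rate = learning_rate
  ), class = "train_config")
}

#' Split instances into training and validation subsets
#'
#' Uniform random split by instance under the given seed; the training set
#' receives `round(n * (1 - fraction))` instances. Different seeds yield
#' different partitions, which is what makes the members of a seed ensemble
#' see distinct training/validation subsets.
#'
#' @param n Number of instances (or an object with that many rows).
#' @param fraction Validation fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_train_validation <- function(n, fraction, seed) {
  if (inherits(n, "encoded_batch")) n <- n_encoded(n)
  n <- as.integer(n)
  if (fraction < 0 || fraction >= 1) {
    stop("validation fraction must lie in [0, 1)", call. = FALSE)
  }
  n_train <- round(n * (1 - fraction))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[setdiff(seq_len(n), seq_len(n_train))]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Class weights inversely proportional to frequency
#'
#' `weight(c) = n_total / (n_classes_present * count(c))`: normalized
#' inverse frequency, so the average weight across the weighted instances
#' is exactly 1 and rarer classes weigh proportionally more.
#'
#' @param labels Character vector of instance labels.
#' @return Named numeric vector of weights over the present classes.
#' @export
compute_class_weights <- function(labels) {
  if (length(labels) == 0L) stop("no labels supplied", call. = FALSE)
  counts <- table(labels)
  n <- sum(counts)
  w <- n / (length(counts) * as.numeric(counts))
  stats::setNames(w, names(counts))
}

# Decision rule: best positive class if its probability reaches theta,
# otherwise the negative class (column 1).
decide_labels <- function(probs, theta, classes = colnames(probs)) {
  pos <- probs[, -1L, drop = FALSE]
  best <- max.col(pos, ties.method = "first")
  pmax_pos <- pos[cbind(seq_len(nrow(pos)), best)]
  ifelse(pmax_pos >= theta, classes[-1L][best], classes[1L])
}

# Instance-level micro P/R/F1 over the positive classes.
instance_micro_f1 <- function(pred_labels, gold_labels) {
  pred_pos <- pred_labels != NEGATIVE_LABEL
  gold_pos <- gold_labels != NEGATIVE_LABEL
  tp <- sum(pred_pos & gold_pos & pred_labels == gold_labels)
  fp <- sum(pred_pos) - tp
  fn <- sum(gold_pos) - tp
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Tune the decision threshold on prediction probabilities
#'
#' The decision rule: let c* be the positive class with the highest
#' probability; predict c* if P(c*) >= theta, otherwise the negative class.
#' The returned theta is the grid value maximizing instance-level micro-F1
#' of the positive classes, with ties resolved towards the smallest theta
#' (favouring recall). Tuning is done on training-portion probabilities to
#' avoid biasing test results.
#'
#' @param probs Probability matrix (rows sum to 1, negative class first).
#' @param gold Character vector of gold labels.
#' @param grid Candidate thresholds.
#' @return The selected threshold.
#' @export
tune_threshold <- function(probs, gold, grid = seq(0, 1, by = 0.01)) {
  stopifnot(nrow(probs) == length(gold))
  if (max(abs(rowSums(probs) - 1)) > 1e-6) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  classes <- colnames(probs)
  pos <- probs[, -1L, drop = FALSE]
  best_col <- max.col(pos, ties.method = "first")
  pmax_pos <- pos[cbind(seq_len(nrow(pos)), best_col)]
  pred_class <- classes[-1L][best_col]
  gold_pos <- gold != NEGATIVE_LABEL
  correct <- gold_pos & pred_class == gold
  n_gold <- sum(gold_pos)
  best_f1 <- -1
  best_theta <- grid[1]
  for (theta in grid) {
    keep <- pmax_pos >= theta
    tp <- sum(keep & correct)
    fp <- sum(keep) - tp
    fn <- n_gold - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    if (f1 > best_f1 + 1e-12) {
      best_f1 <- f1
      best_theta <- theta
    }
  }
  best_theta
}

label_indices <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx)) {
    stop(sprintf("labels outside the class inventory: %s",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  idx
}

fit_epoch <- function(model, batch, order_idx, y_idx, weights, train_cfg) {
  n <- length(order_idx)
  bs <- train_cfg$batch_size
  total_loss <- 0
  for (s in seq(1L, n, by = bs)) {
    idx <- order_idx[s:min(n, s + bs - 1L)]
    sub <- subset_batch(batch, idx)
    fwd <- nn_forward(model, sub, training = TRUE, keep_cache = TRUE)
    ls <- xent_loss(fwd$probs, y_idx[idx], weights[idx])
    grads <- nn_backward(model, fwd, ls$dlogits)
    model <- rmsprop_step(model, grads, lr = train_cfg$learning_rate)
    total_loss <- total_loss + ls$loss * length(idx)
  }
  list(model = model, loss = total_loss / n)
}

#' Train one predictor
#'
#' Per epoch: one weighted pass over the training portion, then the
#' decision threshold is tuned on training-portion probabilities and the
#' validation micro-F1 is computed with that threshold. The weights and
#' threshold of the best validation epoch are kept; training stops once
#' `patience` epochs pass without improvement. In no-validation mode
#' (`validation_split = 0`) training runs exactly `max_epochs` and keeps
#' the final weights, with the threshold tuned on the training data.
#'
#' @param batch An `encoded_batch` with gold labels.
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param tables List with `word`, `pos`, `dep` embedding tables (`word`
#'   usually `vocab_map$table`).
#' @param seed Master random state for this member: it drives the
#'   train/validation split, the weight initialization, the batch shuffling
#'   and the stochastic regularizers together.
#' @return A `trained_predictor` with fields `model`, `theta`, `classes`,
#'   `log` (one row per executed epoch: loss, train F1, validation F1,
#'   theta) and `best_epoch`.
#' @export
train_one <- function(batch, net_cfg, train_cfg, tables, seed = 1L) {
  stopifnot(inherits(batch, "encoded_batch"))
  n <- n_encoded(batch)
  split <- split_train_validation(n, train_cfg$validation_split, seed)
  tr <- split$train
  va <- split$validation
  if (!any(batch$labels[tr] != NEGATIVE_LABEL)) {
    stop("no positive class in the training data", call. = FALSE)
  }
  model <- build_network(net_cfg, tables$word, tables$pos, tables$dep,
                         seed = seed)
  classes <- model$classes
  y_idx <- label_indices(batch$labels, classes)
  cw <- compute_class_weights(batch$labels[tr])
  weights <- rep(1, n)
  weights[tr] <- unname(cw[batch$labels[tr]])
  tr_batch <- subset_batch(batch, tr)
  va_batch <- if (length(va)) subset_batch(batch, va) else NULL
  use_val <- length(va) > 0L

  set.seed(seed)
  log_rows <- vector("list", train_cfg$max_epochs)
  best_val <- -Inf
  best_epoch <- 0L
  best_params <- NULL
  best_theta <- train_cfg$threshold_grid[1]
  wait <- 0L
  executed <- 0L
  for (epoch in seq_len(train_cfg$max_epochs)) {
    order_idx <- tr[sample.int(length(tr))]
    fit <- fit_epoch(model, batch, order_idx, y_idx, weights, train_cfg)
    model <- fit$model
    tr_probs <- predict_proba(model, tr_batch)
    theta <- tune_threshold(tr_probs, batch$labels[tr],
                            train_cfg$threshold_grid)
    train_f1 <- instance_micro_f1(
      decide_labels(tr_probs, theta), batch$labels[tr]
    )[["f1"]]
    val_f1 <- NA_real_
    if (use_val) {
      va_probs <- predict_proba(model, va_batch)
      val_f1 <- instance_micro_f1(
        decide_labels(va_probs, theta), batch$labels[va]
      )[["f1"]]
    }
    executed <- epoch
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = fit$loss, train_f1 = train_f1,
      val_f1 = val_f1, theta = theta
    )
    if (use_val) {
      if (val_f1 > best_val + 1e-12) {
        best_val <- val_f1
        best_epoch <- epoch
        best_params <- model$params
        best_theta <- theta
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > train_cfg$patience) break
      }
    }
  }
  if (use_val && !is.null(best_params)) {
    model$params <- best_params
    theta <- best_theta
  } else {
    best_epoch <- executed
  }
  structure(list(
    model = model, theta = theta, classes = classes,
    log = do.call(rbind, log_rows[seq_len(executed)]),
    best_epoch = best_epoch, seed = seed
  ), class = "trained_predictor")
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat(sprintf(
    "<trained_predictor> core=%s, %d epochs (best %d), theta=%.2f\n",
    x$model$cfg$branch_core, nrow(x$log), x$best_epoch, x$theta
  ))
  invisible(x)
}

#' Train a seed ensemble
#'
#' Trains `train_cfg$n_seeds` predictors whose random states differ in
#' initialization, train/validation split and batch shuffling, all derived
#' from one master seed.
#'
#' @inheritParams train_one
#' @param seed Master seed; member seeds are deterministic offsets of it.
#' @return List of `trained_predictor` objects (class `predictor_ensemble`).
#' @export
train_ensemble <- function(batch, net_cfg, train_cfg, tables, seed = 1L) {
  members <- lapply(seq_len(train_cfg$n_seeds), function(i) {
    train_one(batch, net_cfg, train_cfg, tables,
              seed = as.integer(seed) + 7919L * (i - 1L))
  })
  structure(members, class = "predictor_ensemble")
}

#' Average the predictions of an ensemble
#'
#' Element-wise mean of the members' probability matrices; the ensemble
#' threshold is the mean of the member thresholds unless overridden. Final
#' labels follow the [tune_threshold()] decision rule.
#'
#' @param predictors A `predictor_ensemble`, list of `trained_predictor`s,
#'   or a single `trained_predictor`.
#' @param batch An `encoded_batch`.
#' @param theta Optional threshold override (e.g. re-tuned on training
#'   data).
#' @return List with `probs`, `theta` and `labels`.
#' @export
ensemble_predict <- function(predictors, batch, theta = NULL) {
  if (inherits(predictors, "trained_predictor")) predictors <- list(predictors)
  classes <- predictors[[1]]$classes
  for (p in predictors) {
    if (!identical(p$classes, classes)) {
      stop("ensemble members have mismatched label inventories", call. = FALSE)
    }
  }
  probs <- Reduce(`+`, lapply(predictors, function(p) {
    predict_proba(p$model, batch)
  })) / length(predictors)
  if (is.null(theta)) {
    theta <- mean(vapply(predictors, `[[`, numeric(1), "theta"))
  }
  list(probs = probs, theta = theta,
       labels = decide_labels(probs, theta, classes))
}

#' Predict relation tuples for a corpus batch
#'
#' Applies an ensemble (or single predictor) to an encoded batch and
#' returns the positive predictions as relation tuples ready for
#' [write_predictions()].
#'
#' @inheritParams ensemble_predict
#' @return Data frame with columns `doc_id`, `label`, `arg1`, `arg2`.
#' @export
predict_relations <- function(predictors, batch, theta = NULL) {
  stopifnot(!is.null(batch$meta))
  pred <- ensemble_predict(predictors, batch, theta)
  keep <- pred$labels != NEGATIVE_LABEL
  data.frame(
    doc_id = batch$meta$doc_id[keep],
    label = pred$labels[keep],
    arg1 = batch$meta$chem_id[keep],
    arg2 = batch$meta$prot_id[keep],
    stringsAsFactors = FALSE
  )
}
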