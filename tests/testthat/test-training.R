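# Splits, class weights, threshold tuning, the training protocol and
# ensembling.

test_that("train/validation splits have the prescribed sizes and determinism", {
  s <- split_train_validation(10L, 0.3, seed = 1L)
  expect_length(s$train, 7L)
  expect_length(s$validation, 3L)
  expect_identical(sort(c(s$train, s$validation)), 1:10)

  s0 <- split_train_validation(10L, 0, seed = 1L)
  expect_length(s0$validation, 0L)
  expect_identical(s0$train, 1:10)

  expect_identical(split_train_validation(50L, 0.3, seed = 9L),
                   split_train_validation(50L, 0.3, seed = 9L))
  expect_false(identical(split_train_validation(50L, 0.3, seed = 9L)$train,
                         split_train_validation(50L, 0.3, seed = 10L)$train))
  expect_error(split_train_validation(10L, 1, seed = 1L), "\\[0, 1\\)")
})

test_that("class weights are mean-normalized inverse frequencies", {
  w <- compute_class_weights(c(rep("A", 10), rep("B", 5)))
  expect_equal(unname(w["A"]), 0.75)
  expect_equal(unname(w["B"]), 1.5)
  expect_equal(unname(w["B"] / w["A"]), 2)

  wu <- compute_class_weights(rep(c("A", "B", "C"), each = 4))
  expect_equal(unname(wu), rep(1, 3))

  # training-set counts of the activation and inhibition classes: the rarer
  # class weighs 2254/768 times more
  labels <- c(rep("CPR:3", 768), rep("CPR:4", 2254))
  w2 <- compute_class_weights(labels)
  expect_equal(unname(w2["CPR:3"] / w2["CPR:4"]), 2254 / 768, tolerance = 1e-12)
  expect_equal(unname(w2["CPR:3"] / w2["CPR:4"]), 2.935, tolerance = 1e-3)

  # the mean weight across the weighted instances is always 1
  set.seed(2)
  for (k in 1:20) {
    labs <- sample(LETTERS[1:4], 30, replace = TRUE)
    w <- compute_class_weights(labs)
    expect_equal(mean(w[labs]), 1, tolerance = 1e-9)
  }
  expect_error(compute_class_weights(character(0)), "no labels")
})

test_that("threshold tuning picks the smallest grid value maximizing micro-F1", {
  classes <- cpr_classes()
  probs <- rbind(
    c(0.04, 0.90, 0.02, 0.02, 0.01, 0.01),  # gold CPR:3, confident & right
    c(0.30, 0.60, 0.04, 0.03, 0.02, 0.01)   # gold NEGATIVE, wrongly positive
  )
  colnames(probs) <- classes
  gold <- c("CPR:3", "NEGATIVE")
  # any theta in (0.60, 0.90] yields F1 = 1; smallest grid value is 0.61
  expect_equal(tune_threshold(probs, gold), 0.61)

  # all-negative gold: F1 = 0 everywhere, ties resolve to the smallest theta
  expect_equal(tune_threshold(probs, c("NEGATIVE", "NEGATIVE")), 0)

  # theta = 0 reduces the decision rule to plain argmax-with-negative
  labs <- sdprel:::decide_labels(probs, 0)
  expect_identical(labs, c("CPR:3", "CPR:3"))
})

test_that("threshold tuning agrees with the brute-force oracle", {
  set.seed(33)
  for (k in 1:30) {
    probs <- random_probs(50L)
    gold <- sample(cpr_classes(), 50L, replace = TRUE,
                   prob = c(0.5, rep(0.1, 5)))
    expect_equal(tune_threshold(probs, gold), brute_threshold(probs, gold))
  }
})

test_that("the training protocol logs per epoch and respects early stopping", {
  sh <- shared_synth()
  sub <- sdprel:::subset_batch(sh$enc$batch, 1:80)
  cfg <- network_config("cnn", conv_filters = 8L)
  tc <- train_config(max_epochs = 12L, patience = 2L, n_seeds = 1L)
  pred <- train_one(sub, cfg, tc, sh$tables, seed = 31L)
  log <- pred$log
  expect_identical(names(log), c("epoch", "loss", "train_f1", "val_f1", "theta"))
  expect_identical(log$epoch, seq_len(nrow(log)))
  expect_true(all(pred$theta == round(pred$theta, 2)))  # theta on the grid
  # executed epochs <= best_epoch + patience + 1 in validation mode
  expect_lte(nrow(log), pred$best_epoch + tc$patience + 1L)

  # no-validation mode runs exactly max_epochs
  tc0 <- train_config(max_epochs = 3L, patience = 3L, n_seeds = 1L,
                      validation_split = 0)
  pred0 <- train_one(sub, cfg, tc0, sh$tables, seed = 31L)
  expect_identical(nrow(pred0$log), 3L)
  expect_true(all(is.na(pred0$log$val_f1)))
})

test_that("training is reproducible under a fixed seed", {
  sh <- shared_synth()
  sub <- sdprel:::subset_batch(sh$enc$batch, 1:80)
  cfg <- network_config("bilstm", lstm_units = 8L)
  tc <- train_config(max_epochs = 3L, patience = 3L, n_seeds = 1L)
  a <- train_one(sub, cfg, tc, sh$tables, seed = 77L)
  b <- train_one(sub, cfg, tc, sh$tables, seed = 77L)
  expect_identical(a$log, b$log)
  expect_identical(a$theta, b$theta)
  c_ <- train_one(sub, cfg, tc, sh$tables, seed = 78L)
  expect_false(identical(a$log, c_$log))
})

test_that("training without any positive class is refused", {
  sh <- shared_synth()
  labs <- sh$enc$batch$labels
  neg_idx <- which(labs == "NEGATIVE")[1:30]
  sub <- sdprel:::subset_batch(sh$enc$batch, neg_idx)
  expect_error(
    train_one(sub, network_config("cnn"), train_config(n_seeds = 1L),
              sh$tables, seed = 1L),
    "no positive class"
  )
})

test_that("ensemble predictions are the member mean with the mean threshold", {
  sh <- shared_synth()
  sub <- sdprel:::subset_batch(sh$enc$batch, 1:60)
  cfg <- network_config("cnn", conv_filters = 8L)
  tc <- train_config(max_epochs = 2L, patience = 2L, n_seeds = 1L)
  p1 <- train_one(sub, cfg, tc, sh$tables, seed = 41L)
  p2 <- train_one(sub, cfg, tc, sh$tables, seed = 42L)
  e <- ensemble_predict(list(p1, p2), sub)
  m1 <- predict_proba(p1$model, sub)
  m2 <- predict_proba(p2$model, sub)
  expect_equal(e$probs, (m1 + m2) / 2, tolerance = 1e-12)
  expect_equal(e$theta, mean(c(p1$theta, p2$theta)))
  # identical members degenerate to the single-member prediction
  e1 <- ensemble_predict(list(p1, p1), sub)
  expect_equal(e1$probs, m1, tolerance = 1e-12)
  # mismatched label inventories are refused
  p3 <- p2
  p3$classes <- rev(p3$classes)
  expect_error(ensemble_predict(list(p1, p3), sub), "mismatched label")
})

test_that("relation prediction emits positive tuples only", {
  sh <- shared_synth()
  sub <- sdprel:::subset_batch(sh$enc$batch, 1:60)
  cfg <- network_config("cnn", conv_filters = 8L)
  tc <- train_config(max_epochs = 2L, patience = 2L, n_seeds = 1L)
  p1 <- train_one(sub, cfg, tc, sh$tables, seed = 51L)
  preds <- predict_relations(p1, sub)
  expect_true(all(preds$label != "NEGATIVE"))
  expect_true(all(c("doc_id", "label", "arg1", "arg2") %in% names(preds)))
})
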