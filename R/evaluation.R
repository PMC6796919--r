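# Official-style micro-averaged evaluation over the five evaluated classes.

as_tuples <- function(x, what) {
  req <- c("doc_id", "label", "arg1", "arg2")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    stop(sprintf("%s must be a data frame with columns %s",
                 what, paste(req, collapse = ", ")), call. = FALSE)
  }
  if (nrow(x) > 0L && any(!x$label %in% CPR_POSITIVE)) {
    stop(sprintf("%s contains labels outside the evaluated groups", what),
         call. = FALSE)
  }
  x[, req]
}

#' Micro-averaged precision, recall and F1 over relation tuples
#'
#' A true positive is an exact tuple match (document, label and both
#' arguments); a prediction with the right pair but the wrong label counts
#' simultaneously as one false positive and one false negative. Duplicate
#' predicted tuples are deduplicated before scoring. Zero denominators give
#' zero by convention.
#'
#' @param predicted,gold Data frames with columns `doc_id`, `label`,
#'   `arg1`, `arg2`; labels restricted to the five evaluated groups.
#' @return An `eval_result`: counts `tp`, `fp`, `fn`, the micro `precision`,
#'   `recall`, `f1`, and a 6x6 `confusion` matrix (gold rows, predicted
#'   columns) over the full class inventory including `NEGATIVE`.
#' @export
micro_prf <- function(predicted, gold) {
  predicted <- as_tuples(predicted, "predicted")
  gold <- as_tuples(gold, "gold")
  pk_full <- paste(predicted$doc_id, predicted$label, predicted$arg1, predicted$arg2)
  predicted <- predicted[!duplicated(pk_full), , drop = FALSE]
  # pairs predicted under two labels: keep the first
  pk_pair <- paste(predicted$doc_id, predicted$arg1, predicted$arg2)
  predicted <- predicted[!duplicated(pk_pair), , drop = FALSE]
  pk_pair <- pk_pair[!duplicated(pk_pair)]
  gk_pair <- paste(gold$doc_id, gold$arg1, gold$arg2)

  classes <- cpr_classes()
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(gold = classes, predicted = classes))
  tp <- 0L
  for (i in seq_len(nrow(gold))) {
    hit <- match(gk_pair[i], pk_pair)
    if (is.na(hit)) {
      confusion[gold$label[i], NEGATIVE_LABEL] <-
        confusion[gold$label[i], NEGATIVE_LABEL] + 1L
    } else {
      confusion[gold$label[i], predicted$label[hit]] <-
        confusion[gold$label[i], predicted$label[hit]] + 1L
      if (predicted$label[hit] == gold$label[i]) tp <- tp + 1L
    }
  }
  spurious <- is.na(match(pk_pair, gk_pair))
  for (j in which(spurious)) {
    confusion[NEGATIVE_LABEL, predicted$label[j]] <-
      confusion[NEGATIVE_LABEL, predicted$label[j]] + 1L
  }
  fp <- nrow(predicted) - tp
  fn <- nrow(gold) - tp
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = p, recall = r, f1 = f1_from_pr(p, r),
    confusion = confusion
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Balanced F1 from precision and recall
#'
#' The harmonic mean `2pr / (p + r)`, 0 when both are 0.
#'
#' @param p,r Precision and recall in `[0, 1]`.
#' @return The F1-score.
#' @export
f1_from_pr <- function(p, r) {
  if (any(p < 0 | p > 1 | r < 0 | r > 1)) {
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Precision/recall stratified by sentence entity and relation density
#'
#' Attributes every predicted and gold tuple to the sentence containing its
#' argument pair, and aggregates true/false positives and false negatives
#' per (gold entities in sentence, gold evaluated relations in sentence)
#' cell — the grid underlying precision/recall heatmaps. Tuples whose
#' arguments are not co-sentential are excluded and counted in
#' `attr(, "excluded")`.
#'
#' @param predicted,gold Tuple data frames as in [micro_prf()].
#' @param corpus A parsed `chemprot_corpus` (for entity/sentence alignment).
#' @param cap Axis cap: densities above it are clamped to `cap`.
#' @return Data frame with columns `entities`, `relations`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`; one row per populated cell.
#' @export
stratified_heatmap <- function(predicted, gold, corpus, cap = 10L) {
  predicted <- as_tuples(predicted, "predicted")
  gold <- as_tuples(gold, "gold")
  excluded <- 0L

  sentence_of <- function(doc_id, arg1, arg2) {
    doc <- corpus$documents[[doc_id]]
    if (is.null(doc)) return(NA_integer_)
    s1 <- doc$entities$sentence[doc$entities$term_id == arg1]
    s2 <- doc$entities$sentence[doc$entities$term_id == arg2]
    if (length(s1) != 1L || length(s2) != 1L || is.na(s1) || is.na(s2) ||
        s1 != s2) return(NA_integer_)
    s1
  }
  # per-sentence densities of gold entities and co-sentential gold relations
  density <- function(doc_id, s) {
    doc <- corpus$documents[[doc_id]]
    n_ent <- sum(doc$entities$sentence == s, na.rm = TRUE)
    n_rel <- 0L
    if (nrow(doc$relations)) {
      for (g in seq_len(nrow(doc$relations))) {
        sg <- sentence_of(doc_id, doc$relations$arg1[g], doc$relations$arg2[g])
        if (!is.na(sg) && sg == s) n_rel <- n_rel + 1L
      }
    }
    c(min(n_ent, cap), min(n_rel, cap))
  }

  cells <- new.env(parent = emptyenv())
  bump <- function(key, slot) {
    cur <- get0(key, envir = cells, ifnotfound = c(tp = 0L, fp = 0L, fn = 0L))
    cur[slot] <- cur[slot] + 1L
    assign(key, cur, envir = cells)
  }
  gk <- paste(gold$doc_id, gold$label, gold$arg1, gold$arg2)
  pk <- paste(predicted$doc_id, predicted$label, predicted$arg1, predicted$arg2)
  place <- function(df, i, slot) {
    s <- sentence_of(df$doc_id[i], df$arg1[i], df$arg2[i])
    if (is.na(s)) {
      excluded <<- excluded + 1L
      return()
    }
    dd <- density(df$doc_id[i], s)
    bump(paste(dd[1], dd[2]), slot)
  }
  for (i in seq_len(nrow(predicted))) {
    place(predicted, i, if (pk[i] %in% gk) "tp" else "fp")
  }
  for (i in seq_len(nrow(gold))) {
    if (!gk[i] %in% pk) place(gold, i, "fn")
  }
  keys <- ls(cells)
  out <- do.call(rbind, lapply(keys, function(k) {
    v <- get(k, envir = cells)
    xy <- as.integer(strsplit(k, " ")[[1]])
    data.frame(entities = xy[1], relations = xy[2],
               tp = v[["tp"]], fp = v[["fp"]], fn = v[["fn"]])
  }))
  if (is.null(out)) {
    out <- data.frame(entities = integer(), relations = integer(),
                      tp = integer(), fp = integer(), fn = integer())
  }
  out <- out[order(out$entities, out$relations), , drop = FALSE]
  out$precision <- ifelse(out$tp + out$fp > 0, out$tp / (out$tp + out$fp), 0)
  out$recall <- ifelse(out$tp + out$fn > 0, out$tp / (out$tp + out$fn), 0)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
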