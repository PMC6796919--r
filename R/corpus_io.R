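# Reading and writing CHEMPROT-style corpora.
#
# A corpus is a list of documents; each document holds the raw text
# (title + "\t" + abstract, the offset base used by the entity file),
# entity mentions, gold relations and dependency-parsed sentences.
# Character offsets are 0-based and end-exclusive throughout.

new_document <- function(doc_id, text) {
  list(
    doc_id = doc_id,
    text = text,
    sentences = list(),
    entities = data.frame(
      term_id = character(), etype = character(),
      start = integer(), end = integer(), surface = character(),
      sentence = integer(), stringsAsFactors = FALSE
    ),
    relations = data.frame(
      label = character(), arg1 = character(), arg2 = character(),
      stringsAsFactors = FALSE
    )
  )
}

new_corpus <- function(documents) {
  structure(list(documents = documents, stats = list()), class = "chemprot_corpus")
}

#' @export
print.chemprot_corpus <- function(x, ...) {
  n_ent <- sum(vapply(x$documents, function(d) nrow(d$entities), integer(1)))
  n_rel <- sum(vapply(x$documents, function(d) nrow(d$relations), integer(1)))
  n_sen <- sum(vapply(x$documents, function(d) length(d$sentences), integer(1)))
  cat(sprintf(
    "<chemprot_corpus> %d documents, %d sentences, %d entities, %d relations\n",
    length(x$documents), n_sen, n_ent, n_rel
  ))
  invisible(x)
}

# Split one TSV line into exactly n fields, keeping empty trailing fields.
split_tsv <- function(line, n, path, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  n_tabs <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
  if (n_tabs != n - 1L) {
    stop(sprintf(
      "%s: line %d has %d tab-separated fields, expected %d",
      path, lineno, n_tabs + 1L, n
    ), call. = FALSE)
  }
  length(parts) <- n
  parts[is.na(parts)] <- ""
  parts
}

#' Read a CHEMPROT abstracts file
#'
#' Each line is `pmid \t title \t abstract`. The document text is stored as
#' `title + "\t" + abstract`, the base against which entity character offsets
#' are expressed.
#'
#' @param path Path to a UTF-8 TSV file with three columns.
#' @return A `chemprot_corpus` with empty entity/relation/parse slots.
#' @export
read_abstracts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  docs <- list()
  for (i in seq_along(lines)) {
    f <- split_tsv(lines[i], 3L, path, i)
    if (!is.null(docs[[f[1]]])) {
      stop(sprintf("%s: duplicate document id '%s' at line %d", path, f[1], i),
           call. = FALSE)
    }
    docs[[f[1]]] <- new_document(f[1], paste(f[2], f[3], sep = "\t"))
  }
  new_corpus(docs)
}

# 0-based end-exclusive slice of document text.
text_slice <- function(text, start, end) substr(text, start + 1L, end)

#' Read a CHEMPROT entities file into a corpus
#'
#' Each line is `pmid \t term_id \t type \t start \t end \t text` with 0-based
#' end-exclusive offsets into the document text. Gene subtypes `GENE-Y` and
#' `GENE-N` collapse to `GENE`. Every mention is validated against the
#' document text slice; a mismatch is an error naming the offending mention.
#'
#' @param path Path to the 6-column TSV entity file.
#' @param corpus A `chemprot_corpus` from [read_abstracts()].
#' @return The corpus with entity mentions attached.
#' @export
read_entities <- function(path, corpus) {
  stopifnot(inherits(corpus, "chemprot_corpus"))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  for (i in seq_along(lines)) {
    f <- split_tsv(lines[i], 6L, path, i)
    doc_id <- f[1]; term_id <- f[2]; etype <- f[3]
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    surface <- f[6]
    doc <- corpus$documents[[doc_id]]
    if (is.null(doc)) {
      stop(sprintf("%s: line %d refers to unknown document '%s'", path, i, doc_id),
           call. = FALSE)
    }
    if (etype %in% c("GENE-Y", "GENE-N")) etype <- "GENE"
    if (!etype %in% c("CHEMICAL", "GENE")) {
      stop(sprintf("%s: line %d has unknown entity type '%s'", path, i, f[3]),
           call. = FALSE)
    }
    if (is.na(start) || is.na(end) || start >= end) {
      stop(sprintf(
        "invalid span [%s, %s) for entity %s/%s (offsets must satisfy start < end)",
        f[4], f[5], doc_id, term_id
      ), call. = FALSE)
    }
    if (term_id %in% doc$entities$term_id) {
      stop(sprintf("duplicate term id %s in document %s", term_id, doc_id),
           call. = FALSE)
    }
    slice <- text_slice(doc$text, start, end)
    if (!identical(slice, surface)) {
      stop(sprintf(
        "offset/surface mismatch for entity %s/%s: text slice is '%s', file says '%s'",
        doc_id, term_id, slice, surface
      ), call. = FALSE)
    }
    doc$entities <- rbind(doc$entities, data.frame(
      term_id = term_id, etype = etype, start = start, end = end,
      surface = surface, sentence = NA_integer_, stringsAsFactors = FALSE
    ))
    corpus$documents[[doc_id]] <- doc
  }
  corpus
}

#' Read a CHEMPROT gold-relations file into a corpus
#'
#' Each line is `pmid \t CPR:N \t Arg1:Tx \t Arg2:Ty`. Only the five evaluated
#' groups (CPR:3, 4, 5, 6, 9) are kept; other groups are skipped and counted
#' in `corpus$stats$skipped_nonevaluated` rather than being turned into
#' negatives. A pair listed under several groups keeps its first-seen label
#' with a warning (multi-label pairs are rare and the task is treated as
#' multi-class).
#'
#' @param path Path to the 4-column TSV relations file.
#' @param corpus A `chemprot_corpus` with entities attached.
#' @return The corpus with gold relations attached.
#' @export
read_gold_relations <- function(path, corpus) {
  stopifnot(inherits(corpus, "chemprot_corpus"))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  skipped <- 0L
  collapsed <- 0L
  for (i in seq_along(lines)) {
    f <- split_tsv(lines[i], 4L, path, i)
    doc_id <- f[1]; label <- f[2]
    arg1 <- sub("^Arg1:", "", f[3])
    arg2 <- sub("^Arg2:", "", f[4])
    if (!label %in% CPR_POSITIVE) {
      skipped <- skipped + 1L
      next
    }
    doc <- corpus$documents[[doc_id]]
    if (is.null(doc)) {
      stop(sprintf("%s: line %d refers to unknown document '%s'", path, i, doc_id),
           call. = FALSE)
    }
    ents <- doc$entities
    for (a in c(arg1, arg2)) {
      if (!a %in% ents$term_id) {
        stop(sprintf("relation in document %s refers to unknown term id %s",
                     doc_id, a), call. = FALSE)
      }
    }
    if (ents$etype[ents$term_id == arg1] != "CHEMICAL" ||
        ents$etype[ents$term_id == arg2] != "GENE") {
      stop(sprintf(
        "relation %s(%s, %s) in document %s must pair a CHEMICAL with a GENE",
        label, arg1, arg2, doc_id
      ), call. = FALSE)
    }
    if (any(doc$relations$arg1 == arg1 & doc$relations$arg2 == arg2)) {
      collapsed <- collapsed + 1L
      warning(sprintf(
        "pair (%s, %s) in document %s listed under multiple CPR groups; keeping first label",
        arg1, arg2, doc_id
      ), call. = FALSE)
      next
    }
    doc$relations <- rbind(doc$relations, data.frame(
      label = label, arg1 = arg1, arg2 = arg2, stringsAsFactors = FALSE
    ))
    corpus$documents[[doc_id]] <- doc
  }
  corpus$stats$skipped_nonevaluated <- skipped
  corpus$stats$collapsed_multilabel <- collapsed
  corpus
}

#' Read CoNLL-U dependency parses into a corpus
#'
#' Consumes pre-computed sentence splits, tokenization, PoS tags and
#' dependency parses. The MISC field of every token must carry document
#' character offsets as `start=<int>|end=<int>` (0-based, end-exclusive).
#' `HEAD = 0` means the token has no governor (collapsed-dependency graphs
#' may leave tokens such as absorbed prepositions without an incoming arc);
#' its dependency label is stored as `NA` and later rendered `"#none"`.
#' Sentences are associated to documents through `# doc_id = <id>` comment
#' lines (a sentence without one belongs to the most recent document).
#'
#' After reading, every entity mention is resolved to the tokens overlapping
#' its character span. An entity with no overlapping token, or whose tokens
#' belong to two different sentences, is an error.
#'
#' @param path Path to a CoNLL-U file.
#' @param corpus A `chemprot_corpus` with entities attached.
#' @return The corpus with sentences/tokens attached and entities resolved.
#' @export
read_parses <- function(path, corpus) {
  stopifnot(inherits(corpus, "chemprot_corpus"))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  cur_doc <- NA_character_
  rows <- list()
  flush_sentence <- function(doc_id, rows) {
    if (length(rows) == 0L) return()
    if (is.na(doc_id)) {
      stop(sprintf("%s: sentence without a '# doc_id =' association", path),
           call. = FALSE)
    }
    doc <- corpus$documents[[doc_id]]
    if (is.null(doc)) {
      stop(sprintf("%s: parse refers to unknown document '%s'", path, doc_id),
           call. = FALSE)
    }
    sent <- do.call(rbind, rows)
    sent$index <- seq_len(nrow(sent))
    if (any(!is.na(sent$head) & sent$head == sent$index)) {
      stop(sprintf("self-governed token in document %s", doc_id), call. = FALSE)
    }
    if (any(!is.na(sent$head) & (sent$head < 1L | sent$head > nrow(sent)))) {
      stop(sprintf("head index out of range in document %s", doc_id), call. = FALSE)
    }
    for (k in seq_len(nrow(sent))) {
      slice <- text_slice(doc$text, sent$start[k], sent$end[k])
      if (!identical(slice, sent$surface[k])) {
        stop(sprintf(
          "token/text mismatch in document %s: offsets [%d, %d) give '%s', parse says '%s'",
          doc_id, sent$start[k], sent$end[k], slice, sent$surface[k]
        ), call. = FALSE)
      }
    }
    doc$sentences[[length(doc$sentences) + 1L]] <- sent
    corpus$documents[[doc_id]] <<- doc
  }
  for (line in lines) {
    if (grepl("^#", line)) {
      m <- regmatches(line, regexec("^#\\s*doc_id\\s*=\\s*(\\S+)", line))[[1]]
      if (length(m) == 2L) {
        cur_doc <- m[2]
      }
      next
    }
    if (!nzchar(trimws(line))) {
      flush_sentence(cur_doc, rows)
      rows <- list()
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 10L) {
      stop(sprintf("%s: CoNLL-U token line must have 10 columns, found %d",
                   path, length(f)), call. = FALSE)
    }
    if (grepl("[-.]", f[1])) next  # multi-word / empty nodes are not tokens
    misc <- f[10]
    sm <- regmatches(misc, regexec("start=(\\d+)", misc))[[1]]
    em <- regmatches(misc, regexec("end=(\\d+)", misc))[[1]]
    if (length(sm) != 2L || length(em) != 2L) {
      stop(sprintf("%s: MISC field '%s' lacks start=/end= offsets", path, misc),
           call. = FALSE)
    }
    head <- suppressWarnings(as.integer(f[7]))
    if (is.na(head)) {
      stop(sprintf("%s: non-integer HEAD field '%s'", path, f[7]), call. = FALSE)
    }
    pos <- if (f[4] != "_") f[4] else f[5]
    rows[[length(rows) + 1L]] <- data.frame(
      index = 0L, surface = f[2], pos = pos,
      head = if (head == 0L) NA_integer_ else head,
      dep = if (head == 0L) NA_character_ else f[8],
      start = as.integer(sm[2]), end = as.integer(em[2]),
      stringsAsFactors = FALSE
    )
  }
  flush_sentence(cur_doc, rows)
  resolve_entities(corpus)
}

# Map every entity to the tokens overlapping its span; exactly one sentence.
resolve_entities <- function(corpus) {
  for (doc_id in names(corpus$documents)) {
    doc <- corpus$documents[[doc_id]]
    if (nrow(doc$entities) == 0L) next
    # check sentence spans do not overlap
    if (length(doc$sentences) > 1L) {
      spans <- t(vapply(doc$sentences, function(s) c(min(s$start), max(s$end)),
                        numeric(2)))
      ord <- order(spans[, 1])
      spans <- spans[ord, , drop = FALSE]
      if (any(spans[-1, 1] < spans[-nrow(spans), 2])) {
        stop(sprintf("overlapping sentence spans in document %s", doc_id),
             call. = FALSE)
      }
    }
    tok_list <- vector("list", nrow(doc$entities))
    for (e in seq_len(nrow(doc$entities))) {
      es <- doc$entities$start[e]; ee <- doc$entities$end[e]
      hit_sent <- integer(0); hit_tok <- integer(0)
      for (s in seq_along(doc$sentences)) {
        sent <- doc$sentences[[s]]
        ov <- which(sent$start < ee & sent$end > es)
        if (length(ov) > 0L) {
          hit_sent <- c(hit_sent, s)
          hit_tok <- ov
        }
      }
      if (length(hit_sent) == 0L) {
        stop(sprintf("entity %s/%s does not overlap any token",
                     doc_id, doc$entities$term_id[e]), call. = FALSE)
      }
      if (length(hit_sent) > 1L) {
        stop(sprintf("entity %s/%s spans more than one sentence",
                     doc_id, doc$entities$term_id[e]), call. = FALSE)
      }
      doc$entities$sentence[e] <- hit_sent
      tok_list[[e]] <- hit_tok
    }
    doc$entity_tokens <- tok_list
    corpus$documents[[doc_id]] <- doc
  }
  corpus
}

#' Write corpus parses as CoNLL-U
#'
#' Inverse of [read_parses()]: emits one `# doc_id = <id>` comment per
#' sentence and `start=|end=` offsets in the MISC column, so that a write
#' followed by a read reproduces the sentences exactly.
#'
#' @param corpus A `chemprot_corpus` with sentences attached.
#' @param path Output file path.
#' @export
write_conllu <- function(corpus, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (doc_id in names(corpus$documents)) {
    doc <- corpus$documents[[doc_id]]
    for (sent in doc$sentences) {
      writeLines(sprintf("# doc_id = %s", doc_id), con)
      for (k in seq_len(nrow(sent))) {
        head <- if (is.na(sent$head[k])) 0L else sent$head[k]
        dep <- if (is.na(sent$dep[k])) "_" else sent$dep[k]
        writeLines(paste(
          k, sent$surface[k], "_", sent$pos[k], sent$pos[k], "_",
          head, dep, "_",
          sprintf("start=%d|end=%d", sent$start[k], sent$end[k]),
          sep = "\t"
        ), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Write predictions in the official submission format
#'
#' Emits `doc_id \t CPR:N \t Arg1:Tx \t Arg2:Ty` lines, sorted by
#' (doc_id, arg1, arg2) for deterministic output. Negative pairs are never
#' written; passing a negative label is an error.
#'
#' @param preds Data frame with columns `doc_id`, `label`, `arg1`, `arg2`.
#' @param path Output file path.
#' @export
write_predictions <- function(preds, path) {
  req <- c("doc_id", "label", "arg1", "arg2")
  stopifnot(all(req %in% names(preds)))
  if (nrow(preds) > 0L && any(!preds$label %in% CPR_POSITIVE)) {
    bad <- setdiff(unique(preds$label), CPR_POSITIVE)
    stop(sprintf("predictions must use evaluated CPR labels only; found: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  ord <- order(preds$doc_id, preds$arg1, preds$arg2, method = "radix")
  preds <- preds[ord, , drop = FALSE]
  lines <- if (nrow(preds) == 0L) character(0) else paste(
    preds$doc_id, preds$label,
    paste0("Arg1:", preds$arg1), paste0("Arg2:", preds$arg2),
    sep = "\t"
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a prediction or gold file as relation tuples
#'
#' @param path Path to a 4-column TSV (`doc_id`, `CPR:N`, `Arg1:Tx`, `Arg2:Ty`).
#' @return Data frame with columns `doc_id`, `label`, `arg1`, `arg2`.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(doc_id = character(), label = character(),
                      arg1 = character(), arg2 = character(),
                      stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, lapply(seq_along(lines), function(i) {
    split_tsv(lines[i], 4L, path, i)
  }))
  data.frame(
    doc_id = f[, 1], label = f[, 2],
    arg1 = sub("^Arg1:", "", f[, 3]), arg2 = sub("^Arg2:", "", f[, 4]),
    stringsAsFactors = FALSE
  )
}

#' Read a complete CHEMPROT-style corpus directory
#'
#' Convenience wrapper chaining [read_abstracts()], [read_entities()],
#' [read_gold_relations()] (if a relations file is present) and
#' [read_parses()].
#'
#' @param dir Directory containing `abstracts.tsv`, `entities.tsv`,
#'   optionally `relations.tsv`, and `parses.conllu`.
#' @return A fully populated `chemprot_corpus`.
#' @export
read_chemprot_corpus <- function(dir) {
  corpus <- read_abstracts(file.path(dir, "abstracts.tsv"))
  corpus <- read_entities(file.path(dir, "entities.tsv"), corpus)
  rel <- file.path(dir, "relations.tsv")
  if (file.exists(rel)) corpus <- read_gold_relations(rel, corpus)
  read_parses(file.path(dir, "parses.conllu"), corpus)
}
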