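# Candidate pair generation and the five-sequence instance representation.
#
# Every same-sentence chemical-protein pair becomes one RelationInstance:
# the shortest dependency path (SDP) between the two entity head tokens,
# traversed from the chemical to the protein, plus four linear context
# sequences. The focal mentions are blinded with "#chemical"/"#gene"
# placeholders ("#chemical#gene" when the pair shares a single token), so
# the classifier learns syntactic/lexical patterns rather than names.

#' Find the head token of an entity mention
#'
#' The head is the mention token whose governor lies outside the mention's
#' token span (or which has no governor). If no token or more than one token
#' qualifies, the last mention token is used as a fallback.
#'
#' @param tokens Integer vector of token indices (1-based, within sentence)
#'   covered by the mention.
#' @param sentence Sentence token table (see [read_parses()]).
#' @return A single token index.
#' @export
find_head_token <- function(tokens, sentence) {
  stopifnot(length(tokens) > 0L)
  heads <- sentence$head[tokens]
  external <- is.na(heads) | !(heads %in% tokens)
  cand <- tokens[external]
  if (length(cand) == 1L) cand else max(tokens)
}

#' Shortest path in the undirected dependency graph
#'
#' Breadth-first search over the undirected graph formed by the sentence's
#' dependency arcs, expanding neighbours in ascending token index (the
#' deterministic tie-break). Each path element carries the label of the arc
#' linking it to the next element, regardless of arc direction; the final
#' element's label slot is `NA`.
#'
#' @param sentence Sentence token table.
#' @param from,to Token indices (1-based).
#' @return A list with `indices` (token indices along the path) and `labels`
#'   (arc labels, last `NA`), or `NULL` when no path exists (tokens without
#'   incoming arcs can be disconnected in collapsed-dependency graphs).
#' @export
shortest_dependency_path <- function(sentence, from, to) {
  n <- nrow(sentence)
  stopifnot(from >= 1L, from <= n, to >= 1L, to <= n)
  if (from == to) {
    return(list(indices = from, labels = NA_character_))
  }
  # adjacency: edge child--head labelled with the child's incoming label
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    h <- sentence$head[i]
    if (!is.na(h)) {
      adj[[i]] <- c(adj[[i]], h)
      adj[[h]] <- c(adj[[h]], i)
    }
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  visited[from] <- TRUE
  queue <- from
  while (length(queue) > 0L) {
    u <- queue[1]
    queue <- queue[-1]
    if (u == to) break
    for (v in adj[[u]]) {
      if (!visited[v]) {
        visited[v] <- TRUE
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  if (!visited[to]) return(NULL)
  path <- to
  while (path[1] != from) path <- c(parent[path[1]], path)
  labels <- rep(NA_character_, length(path))
  for (k in seq_len(length(path) - 1L)) {
    u <- path[k]; v <- path[k + 1L]
    h <- sentence$head[v]
    labels[k] <- if (!is.na(h) && h == u) sentence$dep[v] else sentence$dep[u]
  }
  list(indices = path, labels = labels)
}

# Incoming-edge label of a token, "#none" when it has no governor.
incoming_label <- function(sentence, idx) {
  dep <- sentence$dep[idx]
  ifelse(is.na(dep), NONE_LABEL, dep)
}

# Build one context sequence (a data.frame of token/pos/dep triples) from a
# range of token indices, collapsing contiguous runs of focal-entity tokens
# into a single placeholder triple.
context_sequence <- function(sentence, idx, chem_tokens, prot_tokens) {
  if (length(idx) == 0L) {
    return(data.frame(token = character(), pos = character(), dep = character(),
                      stringsAsFactors = FALSE))
  }
  in_chem <- idx %in% chem_tokens
  in_prot <- idx %in% prot_tokens
  kind <- ifelse(in_chem & in_prot, "cg", ifelse(in_chem, "c", ifelse(in_prot, "g", "t")))
  runs <- rle(kind)
  out_tok <- character(0); out_pos <- character(0); out_dep <- character(0)
  pos0 <- 1L
  for (r in seq_along(runs$lengths)) {
    span <- idx[pos0:(pos0 + runs$lengths[r] - 1L)]
    pos0 <- pos0 + runs$lengths[r]
    if (runs$values[r] == "t") {
      out_tok <- c(out_tok, sentence$surface[span])
      out_pos <- c(out_pos, sentence$pos[span])
      out_dep <- c(out_dep, incoming_label(sentence, span))
    } else {
      ph <- switch(runs$values[r], c = CHEM_PLACEHOLDER, g = GENE_PLACEHOLDER,
                   cg = PAIR_PLACEHOLDER)
      rep_tok <- span[length(span)]  # representative: run's last token
      ext <- span[is.na(sentence$head[span]) | !(sentence$head[span] %in% span)]
      if (length(ext) == 1L) rep_tok <- ext
      out_tok <- c(out_tok, ph)
      out_pos <- c(out_pos, sentence$pos[rep_tok])
      out_dep <- c(out_dep, incoming_label(sentence, rep_tok))
    }
  }
  data.frame(token = out_tok, pos = out_pos, dep = out_dep,
             stringsAsFactors = FALSE)
}

#' Build the five-sequence representation of one candidate pair
#'
#' Constructs a `relation_instance` with the SDP between the chemical and
#' protein head tokens (blinded, traversed labels, last label `"#none"`,
#' truncated to the first 10 triples from the chemical side) and the four
#' context sequences. Context sequences are bounded by the other focal
#' entity: the inner sequences cover the tokens strictly between the two
#' mentions (hence chemical-right equals protein-left when the chemical
#' precedes the protein), the outer ones run to the sentence edges. Context
#' tokens carry their incoming dependency label (`"#none"` when headless);
#' left contexts keep their last 20 triples, right contexts their first 20.
#'
#' @param doc A document from a `chemprot_corpus`.
#' @param sentence_index Sentence index within the document.
#' @param chem_id,prot_id Term ids of the chemical and protein mentions.
#' @param label Gold label (`"CPR:N"` or `"NEGATIVE"`).
#' @return A `relation_instance`, or `NULL` when the two head tokens are
#'   disconnected in the dependency graph (the no-path signal).
#' @export
build_instance <- function(doc, sentence_index, chem_id, prot_id,
                           label = NEGATIVE_LABEL) {
  sentence <- doc$sentences[[sentence_index]]
  ei_c <- which(doc$entities$term_id == chem_id)
  ei_p <- which(doc$entities$term_id == prot_id)
  stopifnot(length(ei_c) == 1L, length(ei_p) == 1L)
  chem_tokens <- doc$entity_tokens[[ei_c]]
  prot_tokens <- doc$entity_tokens[[ei_p]]
  chem_head <- find_head_token(chem_tokens, sentence)
  prot_head <- find_head_token(prot_tokens, sentence)

  if (chem_head == prot_head) {
    sdp <- data.frame(token = PAIR_PLACEHOLDER, pos = sentence$pos[chem_head],
                      dep = NONE_LABEL, stringsAsFactors = FALSE)
  } else {
    path <- shortest_dependency_path(sentence, chem_head, prot_head)
    if (is.null(path)) return(NULL)
    tok <- sentence$surface[path$indices]
    tok[path$indices %in% chem_tokens] <- CHEM_PLACEHOLDER
    tok[path$indices %in% prot_tokens] <- GENE_PLACEHOLDER
    tok[1] <- CHEM_PLACEHOLDER
    tok[length(tok)] <- GENE_PLACEHOLDER
    dep <- path$labels
    dep[length(dep)] <- NONE_LABEL
    sdp <- data.frame(token = tok, pos = sentence$pos[path$indices], dep = dep,
                      stringsAsFactors = FALSE)
    if (nrow(sdp) > SDP_MAX_LEN) {
      sdp <- sdp[seq_len(SDP_MAX_LEN), , drop = FALSE]
      sdp$dep[SDP_MAX_LEN] <- NONE_LABEL
    }
  }

  n <- nrow(sentence)
  c_first <- min(chem_tokens); c_last <- max(chem_tokens)
  p_first <- min(prot_tokens); p_last <- max(prot_tokens)
  rng <- function(a, b) if (a > b) integer(0) else seq.int(a, b)
  # each context stops at the other focal entity when that entity lies on
  # the respective side; overlapping spans leave the inner contexts empty
  chem_left <- rng(if (p_last < c_first) p_last + 1L else 1L, c_first - 1L)
  chem_right <- rng(c_last + 1L, if (p_first > c_last) p_first - 1L else n)
  prot_left <- rng(if (c_last < p_first) c_last + 1L else 1L, p_first - 1L)
  prot_right <- rng(p_last + 1L, if (c_first > p_last) c_first - 1L else n)

  take_tail <- function(df) {
    if (nrow(df) > CTX_MAX_LEN) df[(nrow(df) - CTX_MAX_LEN + 1L):nrow(df), , drop = FALSE] else df
  }
  take_head <- function(df) {
    if (nrow(df) > CTX_MAX_LEN) df[seq_len(CTX_MAX_LEN), , drop = FALSE] else df
  }
  ctx <- function(idx) context_sequence(sentence, idx, chem_tokens, prot_tokens)

  structure(list(
    doc_id = doc$doc_id,
    sentence_index = sentence_index,
    chem_id = chem_id,
    prot_id = prot_id,
    label = label,
    sdp = sdp,
    chem_left = take_tail(ctx(chem_left)),
    chem_right = take_head(ctx(chem_right)),
    prot_left = take_tail(ctx(prot_left)),
    prot_right = take_head(ctx(prot_right))
  ), class = "relation_instance")
}

#' @export
print.relation_instance <- function(x, ...) {
  fmt <- function(df) paste(sprintf("%s/%s/%s", df$token, df$pos, df$dep),
                            collapse = " — ")
  cat(sprintf("<relation_instance> %s sent %d (%s, %s) label=%s\n",
              x$doc_id, x$sentence_index, x$chem_id, x$prot_id, x$label))
  cat("  sdp:        ", fmt(x$sdp), "\n")
  cat("  chem_left:  ", fmt(x$chem_left), "\n")
  cat("  chem_right: ", fmt(x$chem_right), "\n")
  cat("  prot_left:  ", fmt(x$prot_left), "\n")
  cat("  prot_right: ", fmt(x$prot_right), "\n")
  invisible(x)
}

#' Generate all candidate relation instances of a corpus
#'
#' One instance per chemical-protein mention pair co-located in a sentence,
#' in deterministic order (document, sentence, chemical term id, protein
#' term id). The label comes from a matching gold relation, otherwise
#' `"NEGATIVE"`. Gold relations whose arguments lie in different sentences
#' are discarded and counted (`attr(, "skipped_cross_sentence")`), as are
#' candidate pairs whose head tokens are disconnected
#' (`attr(, "skipped_no_path")`).
#'
#' @param corpus A parsed, validated `chemprot_corpus`.
#' @return List of `relation_instance` objects with the two counter
#'   attributes attached.
#' @export
generate_candidates <- function(corpus) {
  stopifnot(inherits(corpus, "chemprot_corpus"))
  out <- list()
  skipped_no_path <- 0L
  skipped_cross <- 0L
  for (doc_id in names(corpus$documents)) {
    doc <- corpus$documents[[doc_id]]
    if (length(doc$sentences) == 0L || nrow(doc$entities) == 0L) next
    gold <- doc$relations
    gold_key <- if (nrow(gold)) paste(gold$arg1, gold$arg2) else character(0)
    ent <- doc$entities
    # count gold relations whose arguments are not co-sentential
    if (nrow(gold)) {
      for (g in seq_len(nrow(gold))) {
        s1 <- ent$sentence[ent$term_id == gold$arg1[g]]
        s2 <- ent$sentence[ent$term_id == gold$arg2[g]]
        if (!is.na(s1) && !is.na(s2) && s1 != s2) {
          skipped_cross <- skipped_cross + 1L
        }
      }
    }
    for (s in seq_along(doc$sentences)) {
      chems <- ent$term_id[ent$etype == "CHEMICAL" & ent$sentence == s]
      prots <- ent$term_id[ent$etype == "GENE" & ent$sentence == s]
      chems <- chems[order(chems, method = "radix")]
      prots <- prots[order(prots, method = "radix")]
      for (ci in chems) {
        for (pi in prots) {
          hit <- match(paste(ci, pi), gold_key)
          label <- if (!is.na(hit)) gold$label[hit] else NEGATIVE_LABEL
          inst <- build_instance(doc, s, ci, pi, label)
          if (is.null(inst)) {
            skipped_no_path <- skipped_no_path + 1L
          } else {
            out[[length(out) + 1L]] <- inst
          }
        }
      }
    }
  }
  attr(out, "skipped_no_path") <- skipped_no_path
  attr(out, "skipped_cross_sentence") <- skipped_cross
  out
}

#' Serialize relation instances as JSON lines
#'
#' One JSON object per line with stable field names, for inspection and
#' interoperability.
#'
#' @param instances List of `relation_instance` objects.
#' @param path Output file path.
#' @export
write_instances_jsonl <- function(instances, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (inst in instances) {
    writeLines(jsonlite::toJSON(unclass(inst), dataframe = "rows",
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
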