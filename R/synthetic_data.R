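# Seeded synthetic parsed corpora with the statistical structure the
# method assumes: the class of a positive pair is determined by a trigger
# token placed on the dependency path between the chemical and protein
# heads, negatives carry no trigger on their path, and the generator can
# plant the rare pathological layouts (a chemical/protein mention pair
# sharing a single token, and cross-sentence gold relations that must be
# discarded downstream). Dependency trees are generated directly — the
# classifier consumes parses, so structure matters, grammaticality does
# not.

DEFAULT_TRIGGERS <- c(
  "CPR:3" = "activates", "CPR:4" = "inhibits", "CPR:5" = "agonizes",
  "CPR:6" = "antagonizes", "CPR:9" = "metabolizes"
)
NEUTRAL_VERBS <- c("binds", "contacts", "accompanies", "joins")

#' Synthetic corpus configuration
#'
#' @param n_docs Number of abstracts.
#' @param sentences_per_doc Integer range (min, max) of sentences per
#'   abstract (the title sentence is additional).
#' @param chems_per_sentence,prots_per_sentence Integer ranges of chemical
#'   and protein mentions per entity-bearing sentence.
#' @param class_proportions Named proportions over the sentence classes
#'   (`NEGATIVE` and the five CPR groups); must sum to 1. Every
#'   chemical-protein pair of a trigger-bearing sentence is planted
#'   positive with the sentence label, so negatives only arise in
#'   neutral-verb sentences and the trigger-on-path contract stays exact.
#' @param trigger_lexicon Named label -> trigger token map.
#' @param label_noise Probability of flipping a positive sentence's gold
#'   label to a different class while keeping its trigger (breaks the
#'   trigger/label contract at the stated rate).
#' @param p_overlap_pair Probability that a negative sentence carries a
#'   single-token mention annotated both as CHEMICAL and GENE.
#' @param p_cross_sentence Probability that a multi-sentence document gains
#'   one gold relation whose arguments lie in different sentences.
#' @param distractor_vocab Number of distinct distractor nouns.
#' @param seed Integer seed; generation is fully deterministic under it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_docs = 60L,
                         sentences_per_doc = c(1L, 3L),
                         chems_per_sentence = c(1L, 2L),
                         prots_per_sentence = c(1L, 2L),
                         class_proportions = c(
                           "NEGATIVE" = 0.5, "CPR:3" = 0.1, "CPR:4" = 0.1,
                           "CPR:5" = 0.1, "CPR:6" = 0.1, "CPR:9" = 0.1
                         ),
                         trigger_lexicon = DEFAULT_TRIGGERS,
                         label_noise = 0,
                         p_overlap_pair = 0.05,
                         p_cross_sentence = 0.02,
                         distractor_vocab = 50L,
                         seed = 1L) {
  stopifnot(n_docs >= 0L,
            length(sentences_per_doc) == 2L,
            sentences_per_doc[1] >= 1L,
            sentences_per_doc[1] <= sentences_per_doc[2],
            chems_per_sentence[1] >= 1L,
            chems_per_sentence[1] <= chems_per_sentence[2],
            prots_per_sentence[1] >= 1L,
            prots_per_sentence[1] <= prots_per_sentence[2],
            label_noise >= 0, label_noise <= 1,
            p_overlap_pair >= 0, p_overlap_pair <= 1,
            p_cross_sentence >= 0, p_cross_sentence <= 1,
            distractor_vocab >= 1L)
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  if (!all(names(class_proportions) %in% cpr_classes())) {
    stop("class proportions must be named by NEGATIVE / CPR classes",
         call. = FALSE)
  }
  pos_labels <- setdiff(names(class_proportions)[class_proportions > 0],
                        NEGATIVE_LABEL)
  if (!all(pos_labels %in% names(trigger_lexicon))) {
    stop("every positive class needs a trigger token", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

rint <- function(range) if (range[1] == range[2]) range[1] else
  sample(range[1]:range[2], 1L)

# Build one sentence: token table + entity plan. `offset0` is the document
# character offset where the sentence starts.
synth_sentence <- function(cfg, sclass, overlap, chem_names, prot_names,
                           distractors) {
  n_chem <- rint(cfg$chems_per_sentence)
  n_prot <- rint(cfg$prots_per_sentence)
  verb <- if (sclass == NEGATIVE_LABEL) sample(NEUTRAL_VERBS, 1L) else
    unname(cfg$trigger_lexicon[sclass])
  toks <- character(0); pos <- character(0)
  head <- integer(0); dep <- character(0)
  ent <- list()
  add <- function(tok, p, h, d) {
    toks <<- c(toks, tok); pos <<- c(pos, p)
    head <<- c(head, h); dep <<- c(dep, d)
    length(toks)
  }
  # "the chem1 [chem2] VERB the prot1 [prot2] of distractor ."
  verb_pos <- 2L + n_chem  # filled below once known
  i_det <- add("the", "DT", NA_integer_, NA_character_)  # head fixed later
  chem_idx <- integer(0)
  for (k in seq_len(n_chem)) {
    nm <- sample(chem_names, 1L)
    i <- add(nm, "NN", NA_integer_, NA_character_)
    chem_idx <- c(chem_idx, i)
  }
  i_verb <- add(verb, "VB", 0L, NA_character_)
  i_det2 <- add("the", "DT", NA_integer_, NA_character_)
  prot_idx <- integer(0)
  prot_tok_spans <- list()
  for (k in seq_len(n_prot)) {
    if (overlap && k == n_prot) {
      # single token annotated as both a chemical and a protein mention
      nm <- paste0("dual", sample(99L, 1L))
      i <- add(nm, "NN", NA_integer_, NA_character_)
      prot_idx <- c(prot_idx, i)
      prot_tok_spans[[k]] <- i
      attr(prot_tok_spans, "overlap_at") <- k
    } else if (stats::runif(1) < 0.25) {
      nm <- sample(prot_names, 1L)
      i1 <- add(nm, "NN", NA_integer_, NA_character_)
      i2 <- add("receptor", "NN", NA_integer_, NA_character_)
      prot_idx <- c(prot_idx, i2)  # head token of the two-word mention
      prot_tok_spans[[k]] <- c(i1, i2)
    } else {
      nm <- sample(prot_names, 1L)
      i <- add(nm, "NN", NA_integer_, NA_character_)
      prot_idx <- c(prot_idx, i)
      prot_tok_spans[[k]] <- i
    }
  }
  with_tail <- stats::runif(1) < 0.6
  if (with_tail) {
    add("of", "IN", 0L, NA_character_)  # absorbed preposition: no governor
    i_n <- add(sample(distractors, 1L), "NN", NA_integer_, NA_character_)
    head[i_n] <- i_verb; dep[i_n] <- "prep_of"
  }
  i_dot <- add(".", ".", NA_integer_, NA_character_)
  # wire up the tree: chem1 nsubj-> verb, extra chems nn-> chem1;
  # prot1 dobj-> verb, extra prots nn-> prot1; two-word mentions nn-internal
  head[i_det] <- chem_idx[1]; dep[i_det] <- "det"
  head[chem_idx[1]] <- i_verb; dep[chem_idx[1]] <- "nsubj"
  for (i in chem_idx[-1]) { head[i] <- chem_idx[1]; dep[i] <- "nn" }
  head[i_det2] <- prot_idx[1]; dep[i_det2] <- "det"
  head[prot_idx[1]] <- i_verb; dep[prot_idx[1]] <- "dobj"
  for (i in prot_idx[-1]) { head[i] <- prot_idx[1]; dep[i] <- "nn" }
  for (k in seq_along(prot_tok_spans)) {
    span <- prot_tok_spans[[k]]
    if (length(span) == 2L) { head[span[1]] <- span[2]; dep[span[1]] <- "nn" }
  }
  head[i_dot] <- i_verb; dep[i_dot] <- "amod"
  head[i_verb] <- NA_integer_; dep[i_verb] <- NA_character_

  list(tokens = data.frame(index = seq_along(toks), surface = toks, pos = pos,
                           head = head, dep = dep,
                           start = NA_integer_, end = NA_integer_,
                           stringsAsFactors = FALSE),
       chem_idx = chem_idx, prot_spans = prot_tok_spans,
       overlap_at = attr(prot_tok_spans, "overlap_at"),
       sclass = sclass)
}

#' Generate a synthetic parsed corpus
#'
#' Writes the four standard corpus files (`abstracts.tsv`, `entities.tsv`,
#' `relations.tsv`, `parses.conllu`) to `out_dir` and returns the corpus
#' read back through the package's own readers — so every generated corpus
#' passes the offset/surface validators by construction. Byte-identical
#' output under identical seeds.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if missing); a fresh temporary
#'   directory by default.
#' @return The `chemprot_corpus`, with attributes `planted` (the
#'   recoverable same-sentence gold relations), `planted_cross_sentence`,
#'   and `dir` (where the files were written).
#' @export
generate_corpus <- function(cfg, out_dir = tempfile("synthcorpus")) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  chem_names <- sprintf("chem%02d", 1:20)
  prot_names <- sprintf("prot%02d", 1:20)
  distractors <- sprintf("word%03d", seq_len(cfg$distractor_vocab))
  classes <- names(cfg$class_proportions)
  probs <- as.numeric(cfg$class_proportions)
  pos_labels <- setdiff(classes[probs > 0], NEGATIVE_LABEL)

  abs_lines <- character(0)
  ent_lines <- character(0)
  rel_lines <- character(0)
  conllu <- character(0)
  n_cross <- 0L
  planted <- list()

  for (di in seq_len(cfg$n_docs)) {
    doc_id <- sprintf("S%04d", di)
    n_sent <- rint(cfg$sentences_per_doc)
    title_toks <- c("Synthetic", "abstract", ".")
    title_pos <- c("JJ", "NN", ".")
    title_head <- c(2L, NA_integer_, 2L)
    title_dep <- c("amod", NA_character_, "amod")
    sent_plans <- lapply(seq_len(n_sent), function(s) {
      sclass <- sample(classes, 1L, prob = probs)
      overlap <- sclass == NEGATIVE_LABEL && stats::runif(1) < cfg$p_overlap_pair
      synth_sentence(cfg, sclass, overlap, chem_names, prot_names, distractors)
    })
    # assemble text and offsets: title \t sentences joined by spaces
    title_str <- paste(title_toks, collapse = " ")
    cursor <- 0L
    tok_offsets <- function(toks, cursor) {
      starts <- integer(length(toks)); ends <- integer(length(toks))
      for (i in seq_along(toks)) {
        starts[i] <- cursor
        ends[i] <- cursor + nchar(toks[i])
        cursor <- ends[i] + 1L
      }
      list(starts = starts, ends = ends, cursor = cursor)
    }
    to <- tok_offsets(title_toks, 0L)
    cursor <- to$cursor  # skips the tab separator (1 char like the spaces)
    sent_texts <- vapply(sent_plans, function(sp) {
      paste(sp$tokens$surface, collapse = " ")
    }, character(1))
    text <- paste(title_str, paste(sent_texts, collapse = " "), sep = "\t")
    abs_lines <- c(abs_lines, paste(doc_id, title_str,
                                    paste(sent_texts, collapse = " "),
                                    sep = "\t"))
    # title sentence
    conllu <- c(conllu, sprintf("# doc_id = %s", doc_id))
    for (i in seq_along(title_toks)) {
      conllu <- c(conllu, paste(
        i, title_toks[i], "_", title_pos[i], title_pos[i], "_",
        ifelse(is.na(title_head[i]), 0L, title_head[i]),
        ifelse(is.na(title_dep[i]), "_", title_dep[i]), "_",
        sprintf("start=%d|end=%d", to$starts[i], to$ends[i]), sep = "\t"
      ))
    }
    conllu <- c(conllu, "")
    term_n <- 0L
    doc_entities <- list()  # per sentence: term ids of chems / prots
    for (s in seq_along(sent_plans)) {
      sp <- sent_plans[[s]]
      so <- tok_offsets(sp$tokens$surface, cursor)
      cursor <- so$cursor
      sp$tokens$start <- so$starts
      sp$tokens$end <- so$ends
      conllu <- c(conllu, sprintf("# doc_id = %s", doc_id))
      for (i in seq_len(nrow(sp$tokens))) {
        conllu <- c(conllu, paste(
          i, sp$tokens$surface[i], "_", sp$tokens$pos[i], sp$tokens$pos[i], "_",
          ifelse(is.na(sp$tokens$head[i]), 0L, sp$tokens$head[i]),
          ifelse(is.na(sp$tokens$dep[i]), "_", sp$tokens$dep[i]), "_",
          sprintf("start=%d|end=%d", sp$tokens$start[i], sp$tokens$end[i]),
          sep = "\t"
        ))
      }
      conllu <- c(conllu, "")
      chem_ids <- character(0)
      for (i in sp$chem_idx) {
        term_n <- term_n + 1L
        tid <- paste0("T", term_n)
        chem_ids <- c(chem_ids, tid)
        ent_lines <- c(ent_lines, paste(
          doc_id, tid, "CHEMICAL", sp$tokens$start[i], sp$tokens$end[i],
          sp$tokens$surface[i], sep = "\t"
        ))
      }
      prot_ids <- character(0)
      for (k in seq_along(sp$prot_spans)) {
        span <- sp$prot_spans[[k]]
        term_n <- term_n + 1L
        tid <- paste0("T", term_n)
        prot_ids <- c(prot_ids, tid)
        surface <- paste(sp$tokens$surface[span], collapse = " ")
        etype <- sample(c("GENE-Y", "GENE-N"), 1L)  # collapses to GENE
        ent_lines <- c(ent_lines, paste(
          doc_id, tid, etype, min(sp$tokens$start[span]),
          max(sp$tokens$end[span]), surface, sep = "\t"
        ))
        if (!is.null(sp$overlap_at) && k == sp$overlap_at) {
          # same single token also annotated as a chemical
          term_n <- term_n + 1L
          tid2 <- paste0("T", term_n)
          chem_ids <- c(chem_ids, tid2)
          ent_lines <- c(ent_lines, paste(
            doc_id, tid2, "CHEMICAL", min(sp$tokens$start[span]),
            max(sp$tokens$end[span]), surface, sep = "\t"
          ))
        }
      }
      doc_entities[[s]] <- list(chems = chem_ids, prots = prot_ids)
      if (sp$sclass != NEGATIVE_LABEL) {
        gold_label <- sp$sclass
        if (cfg$label_noise > 0 && stats::runif(1) < cfg$label_noise) {
          gold_label <- sample(setdiff(pos_labels, sp$sclass), 1L)
        }
        # the overlap chemical (if any) only occurs in negative sentences,
        # so every chem x prot pair here is a planted positive
        for (ci in chem_ids) {
          for (pi in prot_ids) {
            rel_lines <- c(rel_lines, paste(
              doc_id, gold_label, paste0("Arg1:", ci), paste0("Arg2:", pi),
              sep = "\t"
            ))
            planted[[length(planted) + 1L]] <- data.frame(
              doc_id = doc_id, label = gold_label, arg1 = ci, arg2 = pi,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    if (n_sent >= 2L && stats::runif(1) < cfg$p_cross_sentence) {
      ss <- sample(n_sent, 2L)
      chems1 <- doc_entities[[ss[1]]]$chems
      prots2 <- doc_entities[[ss[2]]]$prots
      if (length(chems1) && length(prots2)) {
        lab <- sample(pos_labels, 1L)
        c1 <- sample(chems1, 1L); p2 <- sample(prots2, 1L)
        already <- any(vapply(planted, function(x) {
          x$doc_id == doc_id && x$arg1 == c1 && x$arg2 == p2
        }, logical(1)))
        if (!already) {
          rel_lines <- c(rel_lines, paste(
            doc_id, lab, paste0("Arg1:", c1), paste0("Arg2:", p2), sep = "\t"
          ))
          n_cross <- n_cross + 1L
        }
      }
    }
  }
  writeLines(abs_lines, file.path(out_dir, "abstracts.tsv"), useBytes = TRUE)
  writeLines(ent_lines, file.path(out_dir, "entities.tsv"), useBytes = TRUE)
  writeLines(rel_lines, file.path(out_dir, "relations.tsv"), useBytes = TRUE)
  writeLines(conllu, file.path(out_dir, "parses.conllu"), useBytes = TRUE)
  corpus <- read_chemprot_corpus(out_dir)
  attr(corpus, "planted") <- if (length(planted)) do.call(rbind, planted) else
    data.frame(doc_id = character(), label = character(),
               arg1 = character(), arg2 = character(), stringsAsFactors = FALSE)
  attr(corpus, "planted_cross_sentence") <- n_cross
  attr(corpus, "dir") <- out_dir
  corpus
}

#' Seeded fixture word embeddings for a synthetic corpus
#'
#' Random unit vectors for a vocabulary, with the class trigger tokens
#' resampled until all their pairwise cosines fall below 0.3, keeping the
#' classes linearly separable in the embedding space.
#'
#' @param vocab Character vocabulary (typically [corpus_vocabulary()]).
#' @param dim Vector dimension (at least 2).
#' @param seed Integer seed.
#' @param triggers Trigger tokens to spread apart (defaults to the built-in
#'   trigger lexicon).
#' @return An `embedding_table`.
#' @export
make_fixture_embeddings <- function(vocab, dim = 16L, seed = 1L,
                                    triggers = unname(DEFAULT_TRIGGERS)) {
  if (dim < 2L) stop("embedding dimension must be at least 2", call. = FALSE)
  vocab <- unique(vocab)
  set.seed(seed)
  unit <- function(n) {
    v <- matrix(stats::rnorm(n * dim), n, dim)
    v / sqrt(rowSums(v * v))
  }
  mat <- unit(length(vocab))
  tri <- which(vocab %in% triggers)
  if (length(tri) > 1L) {
    repeat {
      tm <- mat[tri, , drop = FALSE]
      cs <- tcrossprod(tm)
      diag(cs) <- 0
      if (max(cs) < 0.3) break
      mat[tri, ] <- unit(length(tri))
    }
  }
  new_embedding_table(vocab, mat)
}

#' Vocabulary of a corpus plus the entity placeholders
#'
#' All distinct token surfaces of the parsed sentences, together with the
#' blinding placeholders, suitable as the vocabulary for
#' [make_fixture_embeddings()].
#'
#' @param corpus A parsed `chemprot_corpus`.
#' @return Character vector.
#' @export
corpus_vocabulary <- function(corpus) {
  toks <- unlist(lapply(corpus$documents, function(d) {
    unlist(lapply(d$sentences, `[[`, "surface"))
  }), use.names = FALSE)
  sort(unique(c(toks, CHEM_PLACEHOLDER, GENE_PLACEHOLDER, PAIR_PLACEHOLDER)))
}
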