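# Shared fixtures and independent oracles for the test suite.

# --- worked-example corpus (reconstructed parse of the meloxicam/COX
# sentence, shipped under inst/extdata) ------------------------------------

example_dir <- function() system.file("extdata", package = "sdprel")

load_example_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- example_dir()
      corpus <- read_abstracts(file.path(d, "example_abstracts.tsv"))
      corpus <- read_entities(file.path(d, "example_entities.tsv"), corpus)
      corpus <- read_gold_relations(file.path(d, "example_relations.tsv"), corpus)
      cache <<- read_parses(file.path(d, "example_parses.conllu"), corpus)
    }
    cache
  }
})

triples <- function(df) sprintf("%s/%s/%s", df$token, df$pos, df$dep)

# --- hand-built documents --------------------------------------------------

# A one-sentence document whose dependency tree is a chain:
# token i is governed by token i+1 (label "nn"), the last token is the root.
# chem_at / prot_at are single-token mentions.
make_chain_doc <- function(n, chem_at = 1L, prot_at = n, doc_id = "D1") {
  surf <- sprintf("w%02d", seq_len(n))
  starts <- cumsum(c(0L, nchar(surf[-n]) + 1L))
  sent <- data.frame(
    index = seq_len(n), surface = surf, pos = rep("NN", n),
    head = c(seq_len(n)[-1], NA_integer_),
    dep = c(rep("nn", n - 1L), NA_character_),
    start = starts, end = starts + nchar(surf),
    stringsAsFactors = FALSE
  )
  doc <- list(
    doc_id = doc_id, text = paste(surf, collapse = " "),
    sentences = list(sent),
    entities = data.frame(
      term_id = c("T1", "T2"), etype = c("CHEMICAL", "GENE"),
      start = c(sent$start[chem_at], sent$start[prot_at]),
      end = c(sent$end[chem_at], sent$end[prot_at]),
      surface = c(surf[chem_at], surf[prot_at]),
      sentence = c(1L, 1L), stringsAsFactors = FALSE
    ),
    relations = data.frame(label = character(), arg1 = character(),
                           arg2 = character(), stringsAsFactors = FALSE),
    entity_tokens = list(chem_at, prot_at)
  )
  doc
}

wrap_corpus <- function(docs) {
  names(docs) <- vapply(docs, `[[`, character(1), "doc_id")
  structure(list(documents = docs, stats = list()), class = "chemprot_corpus")
}

# --- random dependency trees and the exhaustive path oracle ----------------

# Random labelled tree over n tokens with a shuffled node order, returned
# as a sentence token table.
random_tree_sentence <- function(n) {
  parent <- c(NA_integer_, vapply(2:n, function(i) {
    sample.int(i - 1L, 1L)
  }, integer(1)))
  perm <- sample.int(n)  # relabel nodes so heads are not always earlier
  head <- integer(n)
  for (i in seq_len(n)) {
    head[perm[i]] <- if (is.na(parent[i])) NA_integer_ else perm[parent[i]]
  }
  labs <- sample(c("nsubj", "dobj", "prep_of", "amod", "det", "nn"),
                 n, replace = TRUE)
  data.frame(
    index = seq_len(n), surface = sprintf("t%d", seq_len(n)),
    pos = rep("NN", n), head = head,
    dep = ifelse(is.na(head), NA_character_, labs),
    start = (seq_len(n) - 1L) * 3L, end = (seq_len(n) - 1L) * 3L + 2L,
    stringsAsFactors = FALSE
  )
}

# Exhaustive enumeration of all simple paths in the undirected dependency
# graph; returns the minimum hop count (Inf if disconnected).
brute_min_hops <- function(sentence, from, to) {
  n <- nrow(sentence)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    h <- sentence$head[i]
    if (!is.na(h)) {
      adj[[i]] <- c(adj[[i]], h)
      adj[[h]] <- c(adj[[h]], i)
    }
  }
  best <- Inf
  walk <- function(node, visited, depth) {
    if (node == to) {
      best <<- min(best, depth)
      return()
    }
    for (v in adj[[node]]) {
      if (!visited[v]) {
        visited[v] <- TRUE
        walk(v, visited, depth + 1L)
        visited[v] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[from] <- TRUE
  walk(from, visited, 0L)
  best
}

# --- brute-force threshold oracle ------------------------------------------

# Independent re-implementation of the threshold scan with explicit
# per-instance loops.
brute_threshold <- function(probs, gold, grid = seq(0, 1, by = 0.01)) {
  classes <- colnames(probs)
  best_f1 <- -1
  best_theta <- grid[1]
  for (theta in grid) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_len(nrow(probs))) {
      pos <- probs[i, -1]
      cstar <- classes[-1][which.max(pos)]
      pred <- if (max(pos) >= theta) cstar else "NEGATIVE"
      g <- gold[i]
      if (pred != "NEGATIVE" && pred == g) tp <- tp + 1L
      if (pred != "NEGATIVE" && pred != g) fp <- fp + 1L
      if (g != "NEGATIVE" && pred != g) fn <- fn + 1L
    }
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

# Random row-stochastic probability matrix over the class inventory.
random_probs <- function(n, classes = cpr_classes()) {
  m <- matrix(stats::runif(n * length(classes)), n)
  m <- m / rowSums(m)
  colnames(m) <- classes
  m
}

# --- shared synthetic experiment -------------------------------------------

# Small separable corpus shared by several fast tests.
shared_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_docs = 40L, p_cross_sentence = 0, seed = 303L)
      corpus <- generate_corpus(cfg)
      emb <- make_fixture_embeddings(corpus_vocabulary(corpus), dim = 16L,
                                     seed = 303L)
      enc <- encode_corpus(corpus, emb, seed = 303L)
      cache <<- list(corpus = corpus, emb = emb, enc = enc,
                     tables = list(word = enc$vocab_map$table,
                                   pos = enc$pos_table,
                                   dep = enc$dep_table))
    }
    cache
  }
})

# Tiny embedding tables for fast network tests.
tiny_tables <- function(seed = 5L) {
  set.seed(seed)
  list(
    word = sdprel:::new_embedding_table(paste0("w", 1:6),
                                        matrix(stats::rnorm(6 * 4), 6, 4)),
    pos = sdprel:::new_embedding_table(paste0("p", 1:3),
                                       matrix(stats::rnorm(3 * 2), 3, 2)),
    dep = sdprel:::new_embedding_table(paste0("d", 1:3),
                                       matrix(stats::rnorm(3 * 2), 3, 2))
  )
}

# Fabricated encoded batch with post-padded random indices.
tiny_batch <- function(n = 6L, seed = 9L, labels = NULL) {
  set.seed(seed)
  fill <- function(Tn, len_rng, vmax) {
    m <- matrix(0L, n, Tn)
    for (i in seq_len(n)) {
      L <- sample(len_rng[1]:len_rng[2], 1L)
      m[i, seq_len(L)] <- sample.int(vmax, L, replace = TRUE)
    }
    m
  }
  sw <- fill(10L, c(2L, 8L), 6L)
  lw <- fill(80L, c(10L, 60L), 6L)
  structure(list(
    sdp_word = sw, sdp_pos = (sw > 0L) * 2L, sdp_dep = (sw > 0L) * 1L,
    lin_word = lw, lin_pos = (lw > 0L) * 1L, lin_dep = (lw > 0L) * 3L,
    labels = if (is.null(labels))
      sample(cpr_classes(), n, replace = TRUE) else labels,
    meta = data.frame(doc_id = rep("D1", n), sentence_index = 1L,
                      chem_id = paste0("T", seq_len(n)),
                      prot_id = paste0("U", seq_len(n)),
                      stringsAsFactors = FALSE)
  ), class = "encoded_batch")
}
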