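# Embedding tables, vocabulary composition, and instance encoding.
#
# An embedding_table holds an ordered vocabulary with reserved index 0 for
# padding (stored internally as matrix row 1, an all-zero vector). Encoded
# instances store 0-based indices; 0 marks padding and only appears in
# trailing positions of each 10/20-slot segment.

new_embedding_table <- function(vocab, vectors, trainable = FALSE) {
  stopifnot(length(vocab) == nrow(vectors), all(is.finite(vectors)))
  structure(list(vocab = c("<pad>", vocab),
                 vectors = rbind(0, vectors),
                 trainable = trainable),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens (+padding), dim %d\n",
              length(x$vocab) - 1L, ncol(x$vectors)))
  invisible(x)
}

#' Load pre-trained word vectors
#'
#' Reads word2vec text format (`<n> <d>` header, then one `token v1..vd`
#' line per word) or headerless fastText-style `.vec` files. A padding row
#' (index 0, all zeros) is prepended. Duplicate tokens keep their first
#' vector with a warning.
#'
#' @param path Path to the text-format vector file.
#' @return An `embedding_table`.
#' @export
load_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("%s: empty vector file", path), call. = FALSE)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.integer(first))) &&
    all(as.numeric(first) == floor(as.numeric(first)))
  header_n <- NA_integer_
  if (has_header) {
    header_n <- as.integer(first[1])
    lines <- lines[-1]
  }
  if (length(lines) == 0L) stop(sprintf("%s: no vectors after header", path), call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  d <- length(parts[[1]]) - 1L
  if (d < 1L) stop(sprintf("%s: first vector line has no values", path), call. = FALSE)
  toks <- character(length(parts))
  mat <- matrix(0, length(parts), d)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != d + 1L) {
      stop(sprintf("%s: line %d has %d values, expected %d (ragged vector length)",
                   path, i + has_header, length(p) - 1L, d), call. = FALSE)
    }
    toks[i] <- p[1]
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) {
      stop(sprintf("%s: non-numeric vector component at line %d", path,
                   i + has_header), call. = FALSE)
    }
    mat[i, ] <- v
  }
  if (!is.na(header_n) && header_n != length(toks)) {
    stop(sprintf("%s: header announces %d vectors, file has %d",
                 path, header_n, length(toks)), call. = FALSE)
  }
  if (anyDuplicated(toks)) {
    warning(sprintf("%s: duplicate tokens, keeping first occurrence", path),
            call. = FALSE)
    keep <- !duplicated(toks)
    toks <- toks[keep]
    mat <- mat[keep, , drop = FALSE]
  }
  new_embedding_table(toks, mat)
}

#' Save an embedding table in word2vec text format
#'
#' The padding row is not written. Values are printed with 17 significant
#' digits so a save/load round trip reproduces the table exactly.
#'
#' @param table An `embedding_table`.
#' @param path Output file path.
#' @param header Write the `<n> <d>` header line (default `TRUE`).
#' @export
save_word_vectors <- function(table, path, header = TRUE) {
  stopifnot(inherits(table, "embedding_table"))
  vocab <- table$vocab[-1]
  vecs <- table$vectors[-1, , drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (header) writeLines(sprintf("%d %d", length(vocab), ncol(vecs)), con)
  for (i in seq_along(vocab)) {
    writeLines(paste(vocab[i],
                     paste(sprintf("%.17g", vecs[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

# Case-folded token -> row lookup environment (first occurrence wins),
# cached on the table.
table_lookup <- function(table) {
  env <- attr(table, "lookup")
  if (!is.null(env)) return(env)
  env <- new.env(parent = emptyenv(), size = length(table$vocab))
  low <- tolower(table$vocab)
  for (i in rev(seq_along(low))[-length(low)]) {  # skip padding (row 1)
    assign(low[i], i, envir = env)
  }
  env
}

#' Map a corpus word onto the embedding vocabulary
#'
#' An exact (case-folded) hit returns its stored vector unchanged. Otherwise
#' the word is segmented by greedy longest-match over the embedding
#' vocabulary; characters matching no vocabulary entry are skipped. A word
#' with two or more constituents returns the L2-normalized sum of their
#' vectors; a single constituent returns its stored vector (L2-normalized
#' only when `normalize_single = TRUE`). A word with no constituents
#' returns `NULL`: the DROP signal — such tokens, together with their PoS
#' tag and dependency label, are removed from all sequences before padding.
#'
#' @param word Corpus word.
#' @param table An `embedding_table` of pre-trained word vectors.
#' @param normalize_single L2-normalize single-constituent compositions.
#' @return Numeric vector, or `NULL` (DROP).
#' @export
compose_vector <- function(word, table, normalize_single = FALSE,
                           lookup = table_lookup(table)) {
  w <- tolower(word)
  hit <- get0(w, envir = lookup, ifnotfound = NULL)
  if (!is.null(hit)) return(table$vectors[hit, ])
  # greedy longest-match segmentation
  rows <- integer(0)
  pos <- 1L
  n <- nchar(w)
  while (pos <= n) {
    found <- FALSE
    for (len in (n - pos + 1L):1L) {
      sub <- substr(w, pos, pos + len - 1L)
      idx <- get0(sub, envir = lookup, ifnotfound = NULL)
      if (!is.null(idx)) {
        rows <- c(rows, idx)
        pos <- pos + len
        found <- TRUE
        break
      }
    }
    if (!found) pos <- pos + 1L
  }
  if (length(rows) == 0L) return(NULL)
  if (length(rows) == 1L && !normalize_single) return(table$vectors[rows, ])
  v <- colSums(table$vectors[rows, , drop = FALSE])
  nrm <- sqrt(sum(v * v))
  if (nrm == 0) return(NULL)
  v / nrm
}

#' Build the corpus-to-embedding vocabulary map
#'
#' Applies [compose_vector()] to every distinct corpus word, collecting the
#' mapped vectors into a new `embedding_table` over the corpus vocabulary.
#' Words that DROP are recorded with index `NA`.
#'
#' @param words Character vector of corpus words (duplicates allowed).
#' @param table Pre-trained word vector `embedding_table`.
#' @param normalize_single Passed to [compose_vector()].
#' @return A `vocab_map`: list with `table` (corpus-word embedding table)
#'   and `index` (named integer, 0-based row index or `NA` = DROP).
#' @export
build_vocab_map <- function(words, table, normalize_single = FALSE) {
  words <- unique(words)
  kept <- character(0)
  vecs <- list()
  lookup <- table_lookup(table)
  index <- stats::setNames(rep(NA_integer_, length(words)), words)
  for (w in words) {
    v <- compose_vector(w, table, normalize_single, lookup = lookup)
    if (!is.null(v)) {
      kept <- c(kept, w)
      vecs[[length(vecs) + 1L]] <- v
      index[[w]] <- length(kept)  # 0-based index into table incl. padding
    }
  }
  ext <- new_embedding_table(kept, do.call(rbind, c(vecs, list(matrix(0, 0, ncol(table$vectors))))))
  structure(list(table = ext, index = index), class = "vocab_map")
}

#' Train fixed PoS / dependency-label embeddings
#'
#' Builds small embedding tables for the closed tag vocabularies of a
#' corpus. Two deterministic modes are available: `"cooccurrence"` computes
#' windowed co-occurrence counts, PPMI weighting and a truncated SVD (tags
#' that co-occur end up nearby in cosine distance, in the spirit of
#' skip-gram training); `"random"` draws seeded uniform vectors in
#' \[-0.05, 0.05\]. Both kinds of table are kept fixed during network
#' training; randomly initialized fixed tag embeddings perform on par with
#' trained ones for this task.
#'
#' @param sequences List of character vectors (one tag sequence per
#'   sentence).
#' @param dim Embedding dimension.
#' @param window Symmetric co-occurrence window (default 3).
#' @param method `"cooccurrence"` or `"random"`.
#' @param seed Integer seed (sign conventions of the SVD and the random
#'   draws are both deterministic under it).
#' @return An `embedding_table` with one row per tag plus padding.
#' @export
train_feature_embeddings <- function(sequences, dim, window = 3L,
                                     method = c("cooccurrence", "random"),
                                     seed = 1L) {
  method <- match.arg(method)
  if (length(sequences) == 0L || all(lengths(sequences) == 0L)) {
    stop("empty corpus: no tag sequences to train on", call. = FALSE)
  }
  vocab <- sort(unique(unlist(sequences)))
  k <- length(vocab)
  if (method == "random") {
    set.seed(seed)
    mat <- matrix(stats::runif(k * dim, -0.05, 0.05), k, dim)
    rownames(mat) <- NULL
    return(new_embedding_table(vocab, mat))
  }
  C <- matrix(0, k, k, dimnames = list(vocab, vocab))
  for (s in sequences) {
    m <- length(s)
    if (m < 2L) next
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):min(m, i + window)) {
        C[s[i], s[j]] <- C[s[i], s[j]] + 1
        C[s[j], s[i]] <- C[s[j], s[i]] + 1
      }
    }
  }
  total <- sum(C)
  if (total == 0) {
    stop("tag sequences too short: no co-occurrence pairs in window", call. = FALSE)
  }
  rs <- rowSums(C); cs <- colSums(C)
  expected <- outer(rs, cs) / total
  ppmi <- log(pmax(C * total / pmax(expected * total, 1e-12), 1e-12))
  ppmi[ppmi < 0 | C == 0] <- 0
  sv <- svd(ppmi)
  r <- min(dim, k)
  E <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(r)]), r)
  # fix SVD sign ambiguity: largest-magnitude loading positive per component
  for (j in seq_len(r)) {
    i0 <- which.max(abs(E[, j]))
    if (E[i0, j] < 0) E[, j] <- -E[, j]
  }
  if (r < dim) E <- cbind(E, matrix(0, k, dim - r))
  # seeded jitter keeps rows of never-co-occurring tags non-zero
  set.seed(seed)
  E <- E + matrix(stats::runif(k * dim, -5e-4, 5e-4), k, dim)
  rownames(E) <- NULL
  new_embedding_table(vocab, E)
}

# Map tags to 0-based table indices (unseen tags fall back to padding 0).
tag_indices <- function(tags, table) {
  idx <- match(tags, table$vocab) - 1L
  idx[is.na(idx)] <- 0L
  idx
}

encode_sequence <- function(df, vocab_map, pos_table, dep_table, max_len,
                            is_sdp = FALSE) {
  widx <- unname(vocab_map$index[df$token])
  keep <- !is.na(widx)
  widx <- widx[keep]
  pidx <- tag_indices(df$pos[keep], pos_table)
  didx <- tag_indices(df$dep[keep], dep_table)
  if (length(widx) > max_len) {  # re-check caps after dropping
    widx <- widx[seq_len(max_len)]
    pidx <- pidx[seq_len(max_len)]
    didx <- didx[seq_len(max_len)]
  }
  if (is_sdp && length(widx) > 0L) {
    # the final surviving SDP position carries no outgoing arc
    didx[length(didx)] <- tag_indices(NONE_LABEL, dep_table)
  }
  pad <- rep(0L, max_len - length(widx))
  list(word = c(widx, pad), pos = c(pidx, pad), dep = c(didx, pad))
}

#' Encode one relation instance as fixed-length index arrays
#'
#' DROP tokens (words unmappable onto the embedding vocabulary) are removed
#' together with their PoS and dependency entries, truncation caps are
#' re-checked, and every segment is zero-padded at the end: the SDP to 10
#' positions and the four context sequences to 20 positions each,
#' concatenated as chem-left, chem-right, prot-left, prot-right into the
#' 80-position linear input.
#'
#' @param inst A `relation_instance`.
#' @param vocab_map A `vocab_map` from [build_vocab_map()].
#' @param pos_table,dep_table Tag `embedding_table`s.
#' @return An `encoded_instance`: integer vectors `sdp_word`, `sdp_pos`,
#'   `sdp_dep` (length 10), `lin_word`, `lin_pos`, `lin_dep` (length 80),
#'   and the gold `label`.
#' @export
encode_instance <- function(inst, vocab_map, pos_table, dep_table) {
  stopifnot(inherits(inst, "relation_instance"))
  sdp <- encode_sequence(inst$sdp, vocab_map, pos_table, dep_table,
                         SDP_MAX_LEN, is_sdp = TRUE)
  segs <- lapply(list(inst$chem_left, inst$chem_right,
                      inst$prot_left, inst$prot_right),
                 encode_sequence, vocab_map = vocab_map,
                 pos_table = pos_table, dep_table = dep_table,
                 max_len = CTX_MAX_LEN)
  structure(list(
    sdp_word = sdp$word, sdp_pos = sdp$pos, sdp_dep = sdp$dep,
    lin_word = unlist(lapply(segs, `[[`, "word"), use.names = FALSE),
    lin_pos = unlist(lapply(segs, `[[`, "pos"), use.names = FALSE),
    lin_dep = unlist(lapply(segs, `[[`, "dep"), use.names = FALSE),
    label = inst$label
  ), class = "encoded_instance")
}

#' Encode a list of instances as a batch
#'
#' @param instances List of `relation_instance` objects.
#' @inheritParams encode_instance
#' @return An `encoded_batch`: integer index matrices (`sdp_*` of width 10,
#'   `lin_*` of width 80), a `labels` vector and a `meta` data frame
#'   (`doc_id`, `sentence_index`, `chem_id`, `prot_id`).
#' @export
encode_instances <- function(instances, vocab_map, pos_table, dep_table) {
  enc <- lapply(instances, encode_instance, vocab_map = vocab_map,
                pos_table = pos_table, dep_table = dep_table)
  field <- function(nm) do.call(rbind, lapply(enc, `[[`, nm))
  structure(list(
    sdp_word = field("sdp_word"), sdp_pos = field("sdp_pos"),
    sdp_dep = field("sdp_dep"),
    lin_word = field("lin_word"), lin_pos = field("lin_pos"),
    lin_dep = field("lin_dep"),
    labels = vapply(instances, `[[`, character(1), "label"),
    meta = data.frame(
      doc_id = vapply(instances, `[[`, character(1), "doc_id"),
      sentence_index = vapply(instances, `[[`, integer(1), "sentence_index"),
      chem_id = vapply(instances, `[[`, character(1), "chem_id"),
      prot_id = vapply(instances, `[[`, character(1), "prot_id"),
      stringsAsFactors = FALSE
    )
  ), class = "encoded_batch")
}

n_encoded <- function(batch) nrow(batch$sdp_word)

subset_batch <- function(batch, idx) {
  structure(list(
    sdp_word = batch$sdp_word[idx, , drop = FALSE],
    sdp_pos = batch$sdp_pos[idx, , drop = FALSE],
    sdp_dep = batch$sdp_dep[idx, , drop = FALSE],
    lin_word = batch$lin_word[idx, , drop = FALSE],
    lin_pos = batch$lin_pos[idx, , drop = FALSE],
    lin_dep = batch$lin_dep[idx, , drop = FALSE],
    labels = batch$labels[idx],
    meta = if (is.null(batch$meta)) NULL else batch$meta[idx, , drop = FALSE]
  ), class = "encoded_batch")
}
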