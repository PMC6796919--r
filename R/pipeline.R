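# End-to-end glue: corpus -> candidates -> encoded batch, and a text-based
# model archive (JSON weights + word2vec-text embedding tables).

#' Encode a parsed corpus for training or prediction
#'
#' Generates all candidate instances, builds the PoS and dependency-label
#' embedding tables from the corpus sentences (window 3, kept fixed during
#' training), maps the instance vocabulary onto the pre-trained word
#' vectors and encodes everything into an `encoded_batch`.
#'
#' @param corpus A parsed `chemprot_corpus`.
#' @param word_table Pre-trained word vector `embedding_table`.
#' @param pos_dim,dep_dim Tag embedding dimensions.
#' @param feature_method `"random"` (seeded fixed vectors, the default) or
#'   `"cooccurrence"` for [train_feature_embeddings()].
#' @param seed Seed for the tag embeddings.
#' @param vocab_map,pos_table,dep_table Optionally reuse encoders built on
#'   a training corpus (required when encoding a test corpus for an
#'   existing model).
#' @return List with `batch`, `instances`, `vocab_map`, `pos_table`,
#'   `dep_table` and the candidate-generation counters.
#' @export
encode_corpus <- function(corpus, word_table, pos_dim = 8L, dep_dim = 8L,
                          feature_method = "random", seed = 1L,
                          vocab_map = NULL, pos_table = NULL,
                          dep_table = NULL) {
  instances <- generate_candidates(corpus)
  if (length(instances) == 0L) stop("corpus yields no candidate instances",
                                    call. = FALSE)
  if (is.null(pos_table) || is.null(dep_table)) {
    pos_seqs <- list(); dep_seqs <- list()
    for (doc in corpus$documents) {
      for (sent in doc$sentences) {
        pos_seqs[[length(pos_seqs) + 1L]] <- sent$pos
        dep_seqs[[length(dep_seqs) + 1L]] <-
          ifelse(is.na(sent$dep), NONE_LABEL, sent$dep)
      }
    }
    if (is.null(pos_table)) {
      pos_table <- train_feature_embeddings(pos_seqs, pos_dim,
                                            method = feature_method,
                                            seed = seed)
    }
    if (is.null(dep_table)) {
      dep_table <- train_feature_embeddings(dep_seqs, dep_dim,
                                            method = feature_method,
                                            seed = seed + 1L)
    }
  }
  if (is.null(vocab_map)) {
    words <- unique(unlist(lapply(instances, function(i) {
      c(i$sdp$token, i$chem_left$token, i$chem_right$token,
        i$prot_left$token, i$prot_right$token)
    }), use.names = FALSE))
    vocab_map <- build_vocab_map(words, word_table)
  }
  batch <- encode_instances(instances, vocab_map, pos_table, dep_table)
  list(batch = batch, instances = instances, vocab_map = vocab_map,
       pos_table = pos_table, dep_table = dep_table,
       skipped_no_path = attr(instances, "skipped_no_path"),
       skipped_cross_sentence = attr(instances, "skipped_cross_sentence"))
}

mat_to_list <- function(m) list(dim = dim(m), data = as.numeric(m))
list_to_mat <- function(l) {
  m <- matrix(l$data, l$dim[1], l$dim[2])
  m
}

table_to_list <- function(tab) {
  list(vocab = tab$vocab[-1], vectors = mat_to_list(tab$vectors[-1, , drop = FALSE]))
}
list_to_table <- function(l) {
  new_embedding_table(unlist(l$vocab), list_to_mat(l$vectors))
}

#' Save a trained predictor as a JSON archive
#'
#' Self-contained single-file archive: configuration, class inventory,
#' tuned threshold, all weights, the bound embedding tables and the
#' training log, serialized as JSON at full precision.
#'
#' @param predictor A `trained_predictor`.
#' @param path Output file path.
#' @export
save_predictor <- function(predictor, path) {
  stopifnot(inherits(predictor, "trained_predictor"))
  m <- predictor$model
  obj <- list(
    cfg = unclass(m$cfg),
    classes = m$classes,
    dims = as.list(m$dims),
    theta = predictor$theta,
    best_epoch = predictor$best_epoch,
    seed = predictor$seed,
    params = lapply(m$params, mat_to_list),
    emb = lapply(m$emb, mat_to_list),
    log = predictor$log
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a predictor saved by [save_predictor()]
#'
#' @param path Archive path.
#' @return A `trained_predictor`.
#' @export
load_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, obj$cfg[names(obj$cfg) %in%
                                           names(formals(network_config))])
  model <- structure(list(
    cfg = cfg,
    classes = obj$classes,
    dims = unlist(obj$dims),
    emb = lapply(obj$emb, list_to_mat),
    params = lapply(obj$params, list_to_mat),
    opt = NULL,
    seed = obj$seed
  ), class = "sdprel_network")
  structure(list(
    model = model, theta = obj$theta, classes = obj$classes,
    log = as.data.frame(obj$log), best_epoch = obj$best_epoch,
    seed = obj$seed
  ), class = "trained_predictor")
}

#' Save a complete extraction model directory
#'
#' Writes every ensemble member ([save_predictor()] archives), the corpus
#' vocabulary map and tag tables (word2vec text format plus a JSON index)
#' and the network/training configuration, so prediction on new corpora
#' needs only this directory.
#'
#' @param members `predictor_ensemble` or list of `trained_predictor`s.
#' @param encoders List with `vocab_map`, `pos_table`, `dep_table` (as
#'   returned by [encode_corpus()]).
#' @param dir Output directory.
#' @export
save_cpi_model <- function(members, encoders, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(members, "trained_predictor")) members <- list(members)
  for (i in seq_along(members)) {
    save_predictor(members[[i]], file.path(dir, sprintf("member-%d.json", i)))
  }
  save_word_vectors(encoders$vocab_map$table, file.path(dir, "words.vec"))
  save_word_vectors(encoders$pos_table, file.path(dir, "pos.vec"))
  save_word_vectors(encoders$dep_table, file.path(dir, "dep.vec"))
  jsonlite::write_json(list(n_members = length(members),
                            index = as.list(encoders$vocab_map$index)),
                       file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load an extraction model directory
#'
#' @param dir Directory written by [save_cpi_model()].
#' @return List with `members`, `vocab_map`, `pos_table`, `dep_table`.
#' @export
load_cpi_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  members <- lapply(seq_len(meta$n_members), function(i) {
    load_predictor(file.path(dir, sprintf("member-%d.json", i)))
  })
  index <- unlist(meta$index)
  storage.mode(index) <- "integer"
  vocab_map <- structure(list(
    table = load_word_vectors(file.path(dir, "words.vec")),
    index = index
  ), class = "vocab_map")
  list(members = structure(members, class = "predictor_ensemble"),
       vocab_map = vocab_map,
       pos_table = load_word_vectors(file.path(dir, "pos.vec")),
       dep_table = load_word_vectors(file.path(dir, "dep.vec")))
}
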