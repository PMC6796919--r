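# Word-vector IO, vocabulary composition and instance encoding.

test_that("word2vec text files load with a padding row and strict validation", {
  f <- tempfile()
  writeLines(c("2 3", "apple 1 2 3", "banana 4 5 6"), f)
  tab <- load_word_vectors(f)
  expect_length(tab$vocab, 3L)  # padding + 2 tokens
  expect_identical(tab$vectors[1, ], c(0, 0, 0))
  expect_identical(tab$vectors[tab$vocab == "apple", ], c(1, 2, 3))

  writeLines(c("5 3", "apple 1 2 3", "banana 4 5 6"), f)
  expect_error(load_word_vectors(f), "header announces")
  writeLines(c("apple 1 2 3", "banana 4 5"), f)
  expect_error(load_word_vectors(f), "ragged")
  writeLines(c("apple 1 2 3", "apple 7 8 9"), f)
  expect_warning(tab <- load_word_vectors(f), "duplicate")
  expect_identical(tab$vectors[2, ], c(1, 2, 3))
})

test_that("embedding tables survive a save/load round trip exactly", {
  set.seed(3)
  tab <- sdprel:::new_embedding_table(c("alpha", "beta", "gamma"),
                                      matrix(stats::rnorm(9), 3, 3))
  f <- tempfile()
  save_word_vectors(tab, f)
  back <- load_word_vectors(f)
  expect_identical(back$vocab, tab$vocab)
  expect_equal(back$vectors, tab$vectors, tolerance = 0)
  # headerless fastText-style files load too
  save_word_vectors(tab, f, header = FALSE)
  expect_equal(load_word_vectors(f)$vectors, tab$vectors, tolerance = 0)
})

test_that("composition returns exact hits unchanged and L2-normalizes sums", {
  tab <- sdprel:::new_embedding_table(c("alpha", "beta"),
                                      rbind(c(1, 0), c(0, 1)))
  expect_identical(compose_vector("alpha", tab), c(1, 0))
  # "alphabeta" segments into alpha + beta: normalized diagonal
  expect_equal(compose_vector("alphabeta", tab),
               c(0.70710678, 0.70710678), tolerance = 1e-8)
  # unsegmentable word drops
  expect_null(compose_vector("zzz", tab))
  # case folding
  expect_identical(compose_vector("ALPHA", tab), c(1, 0))
})

test_that("multi-constituent compositions always have unit norm", {
  set.seed(8)
  vocab <- c("ab", "cd", "ef", "gh")
  tab <- sdprel:::new_embedding_table(vocab, matrix(stats::rnorm(16), 4, 4))
  words <- c("abcd", "abcdef", "efgh", "ab-gh", "xxabyycd")
  for (w in words) {
    v <- compose_vector(w, tab)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
  }
})

test_that("greedy longest-match prefers the longest vocabulary entry", {
  tab <- sdprel:::new_embedding_table(c("a", "ab", "abc", "d"),
                                      rbind(c(1, 0), c(0, 1), c(2, 2), c(0, 3)))
  # "abcd" must segment as abc + d, not a + b + c + d
  v <- compose_vector("abcd", tab)
  s <- c(2, 2) + c(0, 3)
  expect_equal(v, s / sqrt(sum(s^2)), tolerance = 1e-12)
})

test_that("feature embeddings have the right shape and are seed-deterministic", {
  seqs <- list(c("NN", "VB", "DT"), c("NN", "JJ"), c("VB", "DT", "NN"))
  for (method in c("random", "cooccurrence")) {
    tab <- train_feature_embeddings(seqs, dim = 20L, method = method, seed = 4L)
    expect_length(tab$vocab, 5L)  # 4 tags + padding
    expect_identical(ncol(tab$vectors), 20L)
    norms <- sqrt(rowSums(tab$vectors[-1, , drop = FALSE]^2))
    expect_true(all(norms > 0))
    tab2 <- train_feature_embeddings(seqs, dim = 20L, method = method, seed = 4L)
    expect_identical(tab$vectors, tab2$vectors)
  }
  expect_error(train_feature_embeddings(list(), 8L), "empty corpus")
})

test_that("co-occurring tags end up closer in cosine than non-co-occurring ones", {
  # three isolated clusters of tags that only ever co-occur internally
  set.seed(10)
  seqs <- c(
    replicate(30, sample(c("A1", "A2"), 4, replace = TRUE), simplify = FALSE),
    replicate(30, sample(c("B1", "B2"), 4, replace = TRUE), simplify = FALSE),
    replicate(30, sample(c("C1", "C2"), 4, replace = TRUE), simplify = FALSE)
  )
  tab <- train_feature_embeddings(seqs, dim = 4L, method = "cooccurrence")
  vec <- function(t) tab$vectors[tab$vocab == t, ]
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine(vec("A1"), vec("A2")), cosine(vec("A1"), vec("B1")))
  expect_gt(cosine(vec("B1"), vec("B2")), cosine(vec("B1"), vec("C2")))
  expect_gt(cosine(vec("C1"), vec("C2")), cosine(vec("C2"), vec("A2")))
})

test_that("encoding pads, drops and caps correctly", {
  sh <- shared_synth()
  enc <- sh$enc
  batch <- enc$batch
  expect_identical(ncol(batch$lin_word), 80L)
  expect_identical(ncol(batch$sdp_word), 10L)
  # padding only in trailing positions of each 20/10 segment
  check_trailing <- function(m, seg_len) {
    for (i in seq_len(nrow(m))) {
      for (s in seq(1L, ncol(m), by = seg_len)) {
        seg <- m[i, s:(s + seg_len - 1L)]
        nz <- which(seg > 0L)
        if (length(nz)) expect_identical(max(nz), length(nz))
      }
    }
  }
  check_trailing(batch$sdp_word[1:20, , drop = FALSE], 10L)
  check_trailing(batch$lin_word[1:20, , drop = FALSE], 20L)

  # an instance whose chemical sits at the sentence start: empty left segment
  doc <- make_chain_doc(6L)
  inst <- build_instance(doc, 1L, "T1", "T2")
  vm <- build_vocab_map(c(sprintf("w%02d", 1:6), "#chemical", "#gene"),
                        sdprel:::new_embedding_table(
                          c(sprintf("w%02d", 1:6), "#chemical", "#gene"),
                          matrix(stats::rnorm(16), 8, 2)))
  ei <- encode_instance(inst, vm, sh$enc$pos_table, sh$enc$dep_table)
  expect_identical(ei$lin_word[1:20], rep(0L, 20L))

  # encoding is a pure function
  ei2 <- encode_instance(inst, vm, sh$enc$pos_table, sh$enc$dep_table)
  expect_identical(ei, ei2)
})

test_that("a dropped token removes its PoS and dependency entries too", {
  doc <- make_chain_doc(6L)
  inst <- build_instance(doc, 1L, "T1", "T2")
  # vocabulary missing w03: that token must vanish from the inner contexts
  keep <- c("w01", "w02", "w04", "w05", "w06", "#chemical", "#gene")
  tab <- sdprel:::new_embedding_table(keep, matrix(stats::rnorm(14), 7, 2))
  vm <- build_vocab_map(c(keep, "w03"), tab)
  expect_true(is.na(vm$index[["w03"]]))
  pos_tab <- train_feature_embeddings(list(c("NN", "VB")), 4L, seed = 1L)
  dep_tab <- train_feature_embeddings(list(c("nn", "#none")), 4L, seed = 1L)
  ei <- encode_instance(inst, vm, pos_tab, dep_tab)
  # chem_right contains w02..w05 minus the dropped w03: 3 surviving triples
  seg <- 21:40
  expect_identical(sum(ei$lin_word[seg] > 0L), 3L)
  expect_identical(sum(ei$lin_pos[seg] > 0L), 3L)
  expect_identical(sum(ei$lin_dep[seg] > 0L), 3L)
})
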