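# Head finding, shortest dependency paths and the five-sequence
# representation.

test_that("the worked example yields the expected head tokens and mirrored contexts", {
  corpus <- load_example_corpus()
  doc <- corpus$documents[["10340919"]]
  sent <- doc$sentences[[1]]
  expect_identical(find_head_token(4L, sent), 4L)   # single-token mention
  expect_identical(find_head_token(14L, sent), 14L)
  inst <- build_instance(doc, 1L, "T1", "T2", "CPR:4")
  # the protein-left context equals the chemical-right context here
  expect_identical(inst$prot_left, inst$chem_right)
  expect_identical(nrow(inst$sdp), 7L)
  expect_identical(inst$sdp$token[1], "#chemical")
  expect_identical(inst$sdp$token[7], "#gene")
  expect_identical(inst$sdp$dep[7], "#none")
})

test_that("the head token is the mention token with an external or missing governor", {
  # 5 tokens; mention = {2, 3}; token 2 governed by 3 (internal), 3 by 5
  sent <- data.frame(
    index = 1:5, surface = sprintf("t%d", 1:5), pos = "NN",
    head = c(2L, 3L, 5L, 5L, NA), dep = c("det", "nn", "dobj", "amod", NA),
    stringsAsFactors = FALSE
  )
  expect_identical(find_head_token(c(2L, 3L), sent), 3L)
  # both mention tokens headless: fall back to the last token
  sent2 <- sent
  sent2$head[2:3] <- NA
  expect_identical(find_head_token(c(2L, 3L), sent2), 3L)
  # two external governors (a tie): also the last token
  sent3 <- sent
  sent3$head[2] <- 5L
  expect_identical(find_head_token(c(2L, 3L), sent3), 3L)
})

test_that("a path from a token to itself has one element and zero hops", {
  sent <- random_tree_sentence(5L)
  p <- shortest_dependency_path(sent, 3L, 3L)
  expect_identical(p$indices, 3L)
  expect_true(is.na(p$labels))
})

test_that("BFS path lengths match exhaustive enumeration on random trees", {
  set.seed(41)
  agree <- 0L
  trials <- 200L
  for (k in seq_len(trials)) {
    n <- sample(2:8, 1L)
    sent <- random_tree_sentence(n)
    ab <- sample.int(n, 2L)
    p <- shortest_dependency_path(sent, ab[1], ab[2])
    hops <- length(p$indices) - 1L
    expect_identical(hops, as.integer(brute_min_hops(sent, ab[1], ab[2])))
    # undirected search: same hop count in the reverse direction
    q <- shortest_dependency_path(sent, ab[2], ab[1])
    expect_identical(length(q$indices), length(p$indices))
    agree <- agree + 1L
  }
  expect_identical(agree, trials)
})

test_that("disconnected head tokens give the no-path signal and are skipped", {
  doc <- make_chain_doc(6L)
  # disconnect the chemical's token from the rest of the tree
  doc$sentences[[1]]$head[1] <- NA
  doc$sentences[[1]]$dep[1] <- NA
  expect_null(shortest_dependency_path(doc$sentences[[1]], 1L, 6L))
  expect_null(build_instance(doc, 1L, "T1", "T2"))
  out <- generate_candidates(wrap_corpus(list(doc)))
  expect_length(out, 0L)
  expect_identical(attr(out, "skipped_no_path"), 1L)
})

test_that("long paths truncate to 10 SDP triples with a forced terminal #none", {
  doc <- make_chain_doc(41L)  # 40 hops between the two mentions
  inst <- build_instance(doc, 1L, "T1", "T2")
  expect_identical(nrow(inst$sdp), 10L)
  expect_identical(inst$sdp$token[1], "#chemical")
  expect_identical(inst$sdp$dep[10], "#none")
  expect_false("#gene" %in% inst$sdp$token)  # protein side was discarded
  # contexts keep the 20 entity-proximal tokens
  expect_identical(nrow(inst$chem_right), 20L)
  expect_identical(inst$chem_right$token[1], "w02")
  expect_identical(nrow(inst$prot_left), 20L)
  expect_identical(inst$prot_left$token[20], "w40")
})

test_that("a chemical at the sentence start has an empty left context", {
  doc <- make_chain_doc(6L, chem_at = 1L, prot_at = 4L)
  inst <- build_instance(doc, 1L, "T1", "T2")
  expect_identical(nrow(inst$chem_left), 0L)
  # and the protein-right context runs to the sentence end
  expect_identical(inst$prot_right$token, c("w05", "w06"))
})

test_that("candidate generation is a labelled cartesian product per sentence", {
  # one sentence, 2 chemicals, 2 proteins, 1 gold relation
  surf <- c("c1", "c2", "binds", "p1", "p2")
  sent <- data.frame(
    index = 1:5, surface = surf, pos = c("NN", "NN", "VB", "NN", "NN"),
    head = c(3L, 1L, NA, 3L, 4L), dep = c("nsubj", "nn", NA, "dobj", "nn"),
    start = (0:4) * 3L, end = (0:4) * 3L + 2L, stringsAsFactors = FALSE
  )
  doc <- list(
    doc_id = "D1", text = paste(surf, collapse = " "), sentences = list(sent),
    entities = data.frame(
      term_id = c("T1", "T2", "T3", "T4"),
      etype = c("CHEMICAL", "CHEMICAL", "GENE", "GENE"),
      start = sent$start[c(1, 2, 4, 5)], end = sent$end[c(1, 2, 4, 5)],
      surface = surf[c(1, 2, 4, 5)], sentence = 1L, stringsAsFactors = FALSE
    ),
    relations = data.frame(label = "CPR:4", arg1 = "T1", arg2 = "T3",
                           stringsAsFactors = FALSE),
    entity_tokens = list(1L, 2L, 4L, 5L)
  )
  out <- generate_candidates(wrap_corpus(list(doc)))
  expect_length(out, 4L)
  labels <- vapply(out, `[[`, character(1), "label")
  expect_identical(sum(labels == "CPR:4"), 1L)
  expect_identical(sum(labels == "NEGATIVE"), 3L)
  # deterministic candidate order: (chem term id, prot term id)
  key <- vapply(out, function(i) paste(i$chem_id, i$prot_id), character(1))
  expect_identical(key, c("T1 T3", "T1 T4", "T2 T3", "T2 T4"))
})

test_that("cross-sentence gold relations are discarded and counted", {
  doc1 <- make_chain_doc(4L, doc_id = "D1")
  doc2 <- make_chain_doc(4L, doc_id = "D2")
  # move the protein of D1 into a second sentence
  sent2 <- doc1$sentences[[1]]
  sent2$start <- sent2$start + 100L
  sent2$end <- sent2$end + 100L
  doc1$sentences[[2]] <- sent2
  doc1$entities$sentence[2] <- 2L
  doc1$entities$start[2] <- sent2$start[4]
  doc1$entities$end[2] <- sent2$end[4]
  doc1$relations <- data.frame(label = "CPR:3", arg1 = "T1", arg2 = "T2",
                               stringsAsFactors = FALSE)
  out <- generate_candidates(wrap_corpus(list(doc1, doc2)))
  labels <- vapply(out, `[[`, character(1), "label")
  expect_identical(sum(labels != "NEGATIVE"), 0L)
  expect_identical(attr(out, "skipped_cross_sentence"), 1L)
})

test_that("every emitted instance satisfies the representation invariants", {
  sh <- shared_synth()
  insts <- sh$enc$instances
  expect_gt(length(insts), 50L)
  for (inst in insts) {
    expect_true(inst$sdp$token[1] %in% c("#chemical", "#chemical#gene"))
    last <- nrow(inst$sdp)
    expect_identical(inst$sdp$dep[last], "#none")
    if (last < 10L) {
      expect_true(inst$sdp$token[last] %in% c("#gene", "#chemical#gene"))
    }
    expect_lte(nrow(inst$sdp), 10L)
    for (ctx in list(inst$chem_left, inst$chem_right,
                     inst$prot_left, inst$prot_right)) {
      expect_lte(nrow(ctx), 20L)
      if (nrow(ctx)) expect_true(all(nzchar(ctx$token) & nzchar(ctx$pos) &
                                       nzchar(ctx$dep)))
    }
  }
})

test_that("instances serialize to JSON lines with stable field names", {
  corpus <- load_example_corpus()
  inst <- generate_candidates(corpus)
  f <- tempfile()
  write_instances_jsonl(inst, f)
  obj <- jsonlite::fromJSON(readLines(f)[1])
  expect_setequal(names(obj),
                  c("doc_id", "sentence_index", "chem_id", "prot_id", "label",
                    "sdp", "chem_left", "chem_right", "prot_left", "prot_right"))
  expect_identical(obj$sdp$token[1], "#chemical")
})
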