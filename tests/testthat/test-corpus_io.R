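# Reading/writing the CHEMPROT TSV dialects and CoNLL-U parses.

test_that("abstracts reader joins title and abstract with a tab and validates input", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_length(read_abstracts(f)$documents, 0L)

  writeLines("10340919\tT\tA", f)
  corpus <- read_abstracts(f)
  expect_identical(corpus$documents[["10340919"]]$text, "T\tA")
  expect_identical(sdprel:::text_slice(corpus$documents[["10340919"]]$text, 0L, 1L), "T")
  expect_identical(sdprel:::text_slice(corpus$documents[["10340919"]]$text, 2L, 3L), "A")

  writeLines(c("d1\ta\tb", "d1\tc\td"), f)
  expect_error(read_abstracts(f), "duplicate document id")
  writeLines("d1\tonly-one-field", f)
  expect_error(read_abstracts(f), "expected 3")
})

test_that("entity reader enforces the surface-slice check and normalizes gene subtypes", {
  d <- example_dir()
  corpus <- read_abstracts(file.path(d, "example_abstracts.tsv"))
  corpus <- read_entities(file.path(d, "example_entities.tsv"), corpus)
  ents <- corpus$documents[["10340919"]]$entities
  expect_identical(ents$surface[ents$term_id == "T1"], "meloxicam")
  expect_identical(ents$etype[ents$term_id == "T2"], "GENE")  # GENE-Y collapsed

  base <- read_abstracts(file.path(d, "example_abstracts.tsv"))
  f <- tempfile()
  # offsets shifted by one in either direction must be rejected
  for (shift in c(-1L, 1L)) {
    writeLines(sprintf("10340919\tT1\tCHEMICAL\t%d\t%d\tmeloxicam",
                       23L + shift, 32L + shift), f)
    expect_error(read_entities(f, base), "offset/surface mismatch")
  }
  writeLines("10340919\tT1\tCHEMICAL\t23\t23\t", f)
  expect_error(read_entities(f, base), "start < end")
  writeLines("99999\tT1\tCHEMICAL\t0\t3\tabc", f)
  expect_error(read_entities(f, base), "unknown document")
  writeLines("10340919\tT9\tGENE-N\t88\t91\tCOX", f)
  withN <- read_entities(f, base)
  expect_identical(withN$documents[["10340919"]]$entities$etype, "GENE")
})

test_that("gold-relation reader keeps evaluated groups and collapses multi-label pairs", {
  d <- example_dir()
  corpus <- read_abstracts(file.path(d, "example_abstracts.tsv"))
  corpus <- read_entities(file.path(d, "example_entities.tsv"), corpus)
  f <- tempfile()

  writeLines(character(0), f)
  empty <- read_gold_relations(f, corpus)
  expect_identical(nrow(empty$documents[["10340919"]]$relations), 0L)

  writeLines(c("10340919\tCPR:10\tArg1:T1\tArg2:T2",
               "10340919\tCPR:4\tArg1:T1\tArg2:T2",
               "10340919\tCPR:3\tArg1:T1\tArg2:T2"), f)
  expect_warning(res <- read_gold_relations(f, corpus), "multiple CPR groups")
  rel <- res$documents[["10340919"]]$relations
  expect_identical(nrow(rel), 1L)
  expect_identical(rel$label, "CPR:4")  # first-seen evaluated label wins
  expect_identical(res$stats$skipped_nonevaluated, 1L)
  expect_identical(res$stats$collapsed_multilabel, 1L)

  writeLines("10340919\tCPR:4\tArg1:T77\tArg2:T2", f)
  expect_error(read_gold_relations(f, corpus), "unknown term id")
})

test_that("CoNLL-U parses round-trip and resolve entities to sentence tokens", {
  corpus <- load_example_corpus()
  doc <- corpus$documents[["10340919"]]
  expect_length(doc$sentences, 1L)
  sent <- doc$sentences[[1]]
  expect_identical(nrow(sent), 16L)
  # HEAD=0 tokens have no incoming edge and later render "#none"
  expect_true(is.na(sent$head[3]))
  expect_true(is.na(sent$dep[3]))
  expect_identical(sdprel:::incoming_label(sent, 3L), "#none")
  # entity -> token resolution
  expect_identical(doc$entities$sentence, c(1L, 1L))
  expect_identical(doc$entity_tokens, list(4L, 14L))

  out <- tempfile()
  write_conllu(corpus, out)
  reread <- read_abstracts(file.path(example_dir(), "example_abstracts.tsv"))
  reread <- read_entities(file.path(example_dir(), "example_entities.tsv"), reread)
  reread <- read_parses(out, reread)
  expect_identical(reread$documents[["10340919"]]$sentences,
                   doc$sentences)
})

test_that("an entity partially overlapping a token still claims that token", {
  d <- example_dir()
  corpus <- read_abstracts(file.path(d, "example_abstracts.tsv"))
  f <- tempfile()
  # "melo" = first 4 chars of the meloxicam token
  writeLines("10340919\tT1\tCHEMICAL\t23\t27\tmelo", f)
  corpus <- read_entities(f, corpus)
  corpus <- read_parses(file.path(d, "example_parses.conllu"), corpus)
  expect_identical(corpus$documents[["10340919"]]$entity_tokens[[1]], 4L)
})

test_that("entities outside every token or across sentences raise errors", {
  f_abs <- tempfile(); f_ent <- tempfile(); f_par <- tempfile()
  # text = "ab\tcd ef gh ij": sentence 1 = "cd ef", sentence 2 = "gh ij"
  writeLines("d1\tab\tcd ef gh ij", f_abs)
  writeLines(c(
    "# doc_id = d1",
    "1\tcd\t_\tNN\tNN\t_\t2\tnn\t_\tstart=3|end=5",
    "2\tef\t_\tNN\tNN\t_\t0\t_\t_\tstart=6|end=8",
    "",
    "# doc_id = d1",
    "1\tgh\t_\tNN\tNN\t_\t2\tnn\t_\tstart=9|end=11",
    "2\tij\t_\tNN\tNN\t_\t0\t_\t_\tstart=12|end=14",
    ""
  ), f_par)
  base <- read_abstracts(f_abs)
  # "ef gh" spans the boundary between the two sentences
  writeLines("d1\tT1\tCHEMICAL\t6\t11\tef gh", f_ent)
  corpus <- read_entities(f_ent, base)
  expect_error(read_parses(f_par, corpus), "more than one sentence")
  # the title token "ab" is covered by no parsed token
  writeLines("d1\tT1\tCHEMICAL\t0\t2\tab", f_ent)
  corpus <- read_entities(f_ent, base)
  expect_error(read_parses(f_par, corpus), "does not overlap any token")
})

test_that("prediction files round-trip, sort deterministically and refuse negatives", {
  f <- tempfile()
  empty <- data.frame(doc_id = character(), label = character(),
                      arg1 = character(), arg2 = character())
  write_predictions(empty, f)
  expect_identical(nrow(read_predictions(f)), 0L)

  preds <- data.frame(
    doc_id = c("d2", "d1", "d1"), label = c("CPR:9", "CPR:4", "CPR:3"),
    arg1 = c("T1", "T3", "T1"), arg2 = c("T2", "T4", "T2"),
    stringsAsFactors = FALSE
  )
  write_predictions(preds, f)
  lines <- readLines(f)
  expect_identical(lines, c("d1\tCPR:3\tArg1:T1\tArg2:T2",
                            "d1\tCPR:4\tArg1:T3\tArg2:T4",
                            "d2\tCPR:9\tArg1:T1\tArg2:T2"))
  back <- read_predictions(f)
  key <- function(x) sort(paste(x$doc_id, x$label, x$arg1, x$arg2))
  expect_identical(key(back), key(preds))

  bad <- rbind(preds, data.frame(doc_id = "d3", label = "NEGATIVE",
                                 arg1 = "T1", arg2 = "T2"))
  expect_error(write_predictions(bad, f), "evaluated CPR labels")
})
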