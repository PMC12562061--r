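test_that("clause anchors cover root, subordinate and coordinated clauses", {
  # hand parse of "And he's going to fall because the stool is tilted too much."
  sent <- sentences(toy_sentence(
    forms = c("And", "he", "'s", "going", "to", "fall", "because", "the",
              "stool", "is", "tilted", "too", "much", "."),
    upos = c("CCONJ", "PRON", "AUX", "VERB", "PART", "VERB", "SCONJ", "DET",
             "NOUN", "AUX", "VERB", "ADV", "ADV", "PUNCT"),
    heads = c(4, 4, 4, 0, 6, 4, 11, 9, 11, 11, 6, 13, 11, 4),
    deprels = c("cc", "nsubj", "aux", "root", "mark", "xcomp", "mark", "det",
                "nsubj", "aux", "advcl", "advmod", "advmod", "punct")
  ))[[1]]
  anchors <- clause_anchors(sent)
  expect_setequal(anchors$kind, c("root", "open_complement", "adverbial"))
  expect_true(7L %in% sent$id[sent$deprel == "mark"]) # the subordinator is present
  expect_equal(anchors$position[anchors$kind == "adverbial"], 11L)

  simple <- sentences(toy_sentence(c("The", "boy", "runs", "."),
                                   c("DET", "NOUN", "VERB", "PUNCT"),
                                   c(2, 3, 0, 3),
                                   c("det", "nsubj", "root", "punct")))[[1]]
  expect_equal(nrow(clause_anchors(simple)), 1L)
  expect_equal(clause_anchors(simple)$kind, "root")

  fragment <- sentences(toy_sentence(c("and", "the", "window"),
                                     c("CCONJ", "DET", "NOUN"),
                                     c(3, 3, 0), c("cc", "det", "root")))[[1]]
  expect_equal(clause_anchors(fragment)$kind, "root")
})

test_that("indices follow their operational definitions on planted fixtures", {
  # 10 clauses (root each), 3 subordinators planted -> mark_per_cl = 0.3
  sents <- lapply(1:10, function(s) {
    if (s <= 3) {
      data.frame(doc_id = "d", sent_id = s, id = 1:4,
                 form = c("he", "runs", "because", "tired"),
                 upos = c("PRON", "VERB", "SCONJ", "VERB"),
                 head = c(2L, 0L, 4L, 2L),
                 deprel = c("nsubj", "root", "mark", "advcl"))
    } else {
      data.frame(doc_id = "d", sent_id = s, id = 1:2,
                 form = c("he", "runs"), upos = c("PRON", "VERB"),
                 head = c(2L, 0L), deprel = c("nsubj", "root"))
    }
  })
  tb <- treebank(do.call(rbind, sents))
  # clause count = 10 roots + 3 advcl anchors = 13; marks = 3
  expect_equal(as.numeric(compute_index(tb, "mark_per_cl")), 3 / 13)
  expect_equal(attr(compute_index(tb, "mark_per_cl"), "support"), 13L)

  # adjectival modification: one amod on one non-pronoun nominal
  skirt <- toy_sentence(c("short", "skirt"), c("ADJ", "NOUN"),
                        c(2, 0), c("amod", "root"))
  expect_equal(as.numeric(compute_index(skirt, "amod_all_nominal_deps_NN_struct")), 1)
  # pronouns are excluded from _NN denominators
  mixed <- toy_sentence(c("short", "skirt", "it"), c("ADJ", "NOUN", "PRON"),
                        c(2, 0, 2), c("amod", "root", "nsubj"))
  expect_equal(as.numeric(compute_index(mixed, "amod_all_nominal_deps_NN_struct")), 1)
  expect_equal(as.numeric(compute_index(mixed, "nominal_deps_stdev")),
               sd_pop_ref(c(2, 0))) # nominal incl. pronoun: skirt has 2 deps, it has 0

  # constant clause-dependent counts: cl_av_deps = d, stdev = 0
  const <- lapply(1:4, function(s) data.frame(
    doc_id = "d", sent_id = s, id = 1:3, form = c("a", "b", "v"),
    upos = c("NOUN", "NOUN", "VERB"), head = c(3L, 3L, 0L),
    deprel = c("nsubj", "obj", "root")
  ))
  tbc <- treebank(do.call(rbind, const))
  expect_equal(as.numeric(compute_index(tbc, "cl_av_deps")), 2)
  expect_equal(as.numeric(compute_index(tbc, "cl_ndeps_std_dev")), 0)

  # zero denominator is flagged missing, never silently 0
  no_dobj <- toy_sentence(c("he", "runs"), c("PRON", "VERB"),
                          c(2, 0), c("nsubj", "root"))
  expect_true(is.na(compute_index(no_dobj, "amod_dobj_deps_struct")))
  expect_equal(as.numeric(compute_index(no_dobj, "dobj_per_cl")), 0)
})

test_that("prepositional indices recognise both UD and Stanford attachment", {
  # UD style: nmod with a case child hanging off a nominal
  ud <- toy_sentence(
    c("sight", "through", "the", "window"),
    c("NOUN", "ADP", "DET", "NOUN"),
    c(0, 4, 4, 1),
    c("root", "case", "det", "nmod")
  )
  # Stanford style: prep attaches to the head, pobj to the preposition
  stanford <- toy_sentence(
    c("sight", "through", "the", "window"),
    c("NN", "IN", "DT", "NN"),
    c(0, 1, 4, 2),
    c("root", "prep", "det", "pobj")
  )
  for (tb in list(ud, stanford)) {
    v <- compute_index(tb, "prep_all_nominal_deps_struct")
    expect_equal(as.numeric(v), 1 / 2) # one PP over two nominals
    expect_false(is.na(compute_index(tb, "av_pobj_deps_NN")))
  }
  # the UD pobj ("window") carries its det + case children
  expect_equal(as.numeric(compute_index(ud, "av_pobj_deps_NN")), 2)

  # Stanford relabelings map onto the canonical set
  expect_equal(unname(relation_map()[c("dobj", "rcmod", "vmod", "poss")]),
               c("obj", "acl:relcl", "acl", "nmod:poss"))
})

test_that("the full index vector has the catalogue shape", {
  withr::local_seed(31)
  corpus <- generate_corpus(syntactic_profile(n_transcripts = 4,
                                              sentences_per_transcript_mean = 6),
                            seed = 1)
  idx <- compute_all_indices(corpus$treebank)
  expect_equal(nrow(idx), 4L)
  expect_setequal(setdiff(names(idx), c("doc_id", "ttr")), index_catalogue())
  expect_equal(length(index_catalogue()), 20L)
  # ratio indices are invariant under corpus doubling
  tok <- as.data.frame(corpus$treebank)
  tok2 <- tok
  tok2$doc_id <- paste0(tok2$doc_id, "_copy")
  doubled <- treebank(rbind(tok, tok2))
  one <- compute_all_indices(corpus$treebank, by_transcript = FALSE)
  two <- compute_all_indices(doubled, by_transcript = FALSE)
  for (nm in index_catalogue()) {
    expect_equal(two[[nm]], one[[nm]], tolerance = 1e-12, label = nm)
  }
  expect_lte(two$ttr, one$ttr) # doubling cannot raise lexical diversity
})

test_that("per-clause indices are invariant under sentence reordering", {
  withr::local_seed(17)
  corpus <- generate_corpus(syntactic_profile(n_transcripts = 1,
                                              sentences_per_transcript_mean = 12),
                            seed = 3)
  tok <- as.data.frame(corpus$treebank)
  perm <- sample(unique(tok$sent_id))
  tok$sent_id <- match(tok$sent_id, perm)
  shuffled <- treebank(tok)
  a <- compute_all_indices(corpus$treebank, by_transcript = FALSE)
  b <- compute_all_indices(shuffled, by_transcript = FALSE)
  for (nm in grep("_per_cl$", index_catalogue(), value = TRUE)) {
    expect_equal(a[[nm]], b[[nm]], label = nm)
  }
})

test_that("type-token ratio counts lowercased non-punctuation forms", {
  distinct <- toy_sentence(paste0("w", 1:10), rep("NOUN", 10),
                           c(0, rep(1, 9)), c("root", rep("dep", 9)))
  expect_equal(type_token_ratio(distinct), 1)
  rep3 <- toy_sentence(c("The", "the", "THE"), rep("DET", 3),
                       c(0, 1, 1), c("root", "dep", "dep"))
  expect_equal(type_token_ratio(rep3), 1 / 3)
  # planted 400 tokens over exactly 50 types -> 0.125
  forms <- rep(sprintf("t%02d", 1:50), 8)
  sents <- lapply(1:40, function(s) data.frame(
    doc_id = "d", sent_id = s, id = 1:10, form = forms[(s - 1) * 10 + 1:10],
    upos = "NOUN", head = c(0L, rep(1L, 9)),
    deprel = c("root", rep("dep", 9))
  ))
  expect_equal(type_token_ratio(treebank(do.call(rbind, sents))), 0.125)
})
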