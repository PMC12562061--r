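test_that("network construction aggregates (governor, dependent, relation) arcs", {
  tb <- toy_sentence(c("the", "boy", "runs"), c("DET", "NOUN", "VERB"),
                     c(2, 3, 0), c("det", "nsubj", "root"))
  net <- build_network(tb)
  expect_equal(net$n, 3L)
  expect_equal(net$m, 2L)
  expect_true(all(net$arcs$weight == 1))
  lab <- function(i) net$vertices[i]
  expect_setequal(paste(lab(net$arcs$gov), lab(net$arcs$dep), net$arcs$rel),
                  c("boy the det", "runs boy nsubj"))

  # the same dependency twice collapses to one arc of weight 2
  twice <- treebank(rbind(
    transform(as.data.frame(tb), sent_id = 1L),
    transform(as.data.frame(tb), sent_id = 2L)
  ))
  net2 <- build_network(twice)
  expect_equal(net2$m, 2L)
  expect_true(all(net2$arcs$weight == 2))
})

test_that("network counts equal a brute-force scan on synthetic corpora", {
  withr::local_seed(55)
  corpus <- generate_corpus(syntactic_profile(n_transcripts = 10,
                                              sentences_per_transcript_mean = 10),
                            seed = 21)
  tb <- corpus$treebank
  net <- build_network(tb)
  # brute-force: distinct lowercased non-punct types and (gov, dep, rel) triples
  tok <- as.data.frame(tb)
  types <- unique(tolower(tok$form[!tok$is_punct]))
  triples <- character(0)
  n_links <- 0L
  for (sent in split(tok, paste(tok$doc_id, tok$sent_id))) {
    for (i in seq_len(nrow(sent))) {
      if (sent$head[i] == 0L || sent$is_punct[i]) next
      gov <- tolower(sent$form[sent$id == sent$head[i]])
      triples <- c(triples, paste(gov, tolower(sent$form[i]), sent$deprel[i]))
      n_links <- n_links + 1L
    }
  }
  expect_equal(net$n, length(types))
  expect_equal(net$m, length(unique(triples)))
  # conservation: total arc weight = total non-root, non-punct link count
  expect_equal(sum(net$arcs$weight), n_links)
})

test_that("Pajek-convention summary follows 2m/n and 2m/n^2", {
  tri <- adjacency_to_network(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  s <- pajek_summary(tri)
  expect_equal(s$average_degree, 2)
  expect_equal(s$density_loops_allowed, 2 / 3)
  # self-consistency on arbitrary counts: 2m/n^2 = (2m/n)/n
  for (nm in list(c(9, 14), c(107, 200), c(50, 1))) {
    s2 <- pajek_summary(n = nm[1], m = nm[2])
    expect_equal(s2$density_loops_allowed, s2$average_degree / nm[1])
  }
  expect_error(pajek_summary(n = 0, m = 0), "n must be")
})

test_that("node metrics match closed forms on the path and triangle", {
  path3 <- adjacency_to_network(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
  m <- node_metrics(path3)
  expect_equal(m$betweenness, c(0, 1, 0))
  expect_equal(m$closeness[2], 1)
  expect_equal(m$closeness[c(1, 3)], c(2 / 3, 2 / 3))
  expect_equal(m$clustering, c(0, 0, 0))

  tri <- adjacency_to_network(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  mt <- node_metrics(tri)
  expect_equal(mt$betweenness, c(0, 0, 0))
  expect_equal(mt$clustering, c(1, 1, 1))
  expect_equal(mt$closeness, c(1, 1, 1))
})

test_that("node metrics equal the exhaustive oracle on small graphs", {
  # exhaustive over every labelled graph on 4 vertices (including
  # disconnected ones: closeness must normalise per component)
  n <- 4L
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (code in 0:(2^nrow(pairs) - 1)) {
    bits <- bitwAnd(bitwShiftR(code, seq_len(nrow(pairs)) - 1L), 1L)
    adj <- matrix(0L, n, n)
    for (e in seq_len(nrow(pairs))) {
      if (bits[e] == 1L) {
        adj[pairs[e, 1], pairs[e, 2]] <- adj[pairs[e, 2], pairs[e, 1]] <- 1L
      }
    }
    expect_metrics_match_oracle(adj)
  }
  # random connected graphs up to n = 8
  withr::local_seed(123)
  for (nn in 5:8) {
    for (rep in 1:5) {
      expect_metrics_match_oracle(random_connected_adj(nn))
    }
  }
})

test_that("metric multisets are invariant under vertex relabeling", {
  withr::local_seed(9)
  adj <- random_connected_adj(7)
  net <- adjacency_to_network(adj)
  perm <- sample(7)
  net2 <- dependency_network(
    vertices = paste0("x", sprintf("%02d", seq_len(7))),
    arcs = data.frame(gov = perm[net$arcs$gov], dep = perm[net$arcs$dep],
                      rel = net$arcs$rel, weight = net$arcs$weight)
  )
  m1 <- node_metrics(net)
  m2 <- node_metrics(net2)
  expect_equal(sort(m1$betweenness), sort(m2$betweenness), tolerance = 1e-12)
  expect_equal(sort(m1$closeness), sort(m2$closeness), tolerance = 1e-12)
  expect_equal(sort(m1$clustering), sort(m2$clustering), tolerance = 1e-12)
})

test_that("weighted degrees sum incident weights with deterministic ranking", {
  net <- dependency_network(
    vertices = c("there", "is", "jar", "boy"),
    arcs = data.frame(gov = c(2L, 2L, 3L, 2L), dep = c(1L, 3L, 4L, 2L),
                      rel = c("expl", "nsubj", "nmod", "loop"),
                      weight = c(27, 3, 2, 1), stringsAsFactors = FALSE)
  )
  wd <- weighted_degrees(net, top_k = 4)
  # "is": 27 + 3 out, loop counts twice -> 32; "there": 27; jar 3+2; boy 2
  expect_equal(wd$value[wd$vertex == "is"], 32)
  expect_equal(wd$value[wd$vertex == "there"], 27)
  expect_equal(wd$vertex[1], "is")
  expect_equal(weighted_degrees(net, top_k = 1)$vertex, "is")
  # planted fixture: a vertex with total incident weight 31 ranks first
  planted <- dependency_network(
    vertices = c("there", "in", "jar", "i"),
    arcs = data.frame(gov = c(1L, 1L, 1L), dep = c(2L, 3L, 4L),
                      rel = c("prep", "pobj", "nsubj"),
                      weight = c(14, 9, 8), stringsAsFactors = FALSE)
  )
  top <- weighted_degrees(planted, top_k = 1)
  expect_equal(top$vertex, "there")
  expect_equal(top$value, 31)
  # ties break by label ascending
  tie <- dependency_network(
    vertices = c("b", "a", "c"),
    arcs = data.frame(gov = c(1L, 2L), dep = c(3L, 3L), rel = "dep",
                      weight = c(2, 2), stringsAsFactors = FALSE)
  )
  expect_equal(weighted_degrees(tie, top_k = 3)$vertex, c("c", "a", "b"))
})

test_that("network cross difference is a key-set difference with weight retention", {
  mk <- function(vs, gov, dep, rel, w) dependency_network(
    vs, data.frame(gov = gov, dep = dep, rel = rel, weight = w,
                   stringsAsFactors = FALSE)
  )
  a <- mk(c("x", "y", "z"), c(1L, 1L, 2L), c(2L, 3L, 3L),
          c("det", "nsubj", "obj"), c(5, 4, 2))
  expect_equal(network_difference(a, a)$m, 0L)
  b_disjoint <- mk(c("p", "q"), 1L, 2L, "det", 1)
  expect_equal(network_difference(a, b_disjoint)$m, 3L)
  # overlap: same labels and relation in b removes the arc even though ids differ
  b <- mk(c("y", "x"), 2L, 1L, "det", 99)
  d <- network_difference(a, b)
  keys <- paste(d$vertices[d$arcs$gov], d$vertices[d$arcs$dep], d$arcs$rel)
  expect_setequal(keys, c("x z nsubj", "y z obj"))
  expect_setequal(d$arcs$weight, c(4, 2))
  # top_k keeps the heaviest differing arcs
  d1 <- network_difference(a, b_disjoint, top_k = 1)
  expect_equal(d1$m, 1L)
  expect_equal(d1$arcs$weight, 5)
})
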