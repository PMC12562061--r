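# fixtures and independent oracles, all built in code

# single-sentence treebank from parallel vectors
toy_sentence <- function(forms, upos, heads, deprels, doc_id = "doc1", sent_id = 1L) {
  treebank(data.frame(
    doc_id = doc_id, sent_id = sent_id, id = seq_along(forms),
    form = forms, upos = upos, head = as.integer(heads), deprel = deprels,
    stringsAsFactors = FALSE
  ))
}

# the published worked-example parse, built programmatically
table1_sentence <- function() {
  toy_sentence(
    forms = c("The", "young", "lad", "is", "going", "to", "fall", "from", "the", "stool", "."),
    upos = c("DT", "JJ", "NN", "VBZ", "VBG", "TO", "VB", "IN", "DT", "NN", "PUNCT"),
    heads = c(3, 3, 5, 5, 0, 7, 5, 10, 10, 7, 5),
    deprels = c("det", "amod", "nsubj", "aux", "root", "mark", "xcomp", "case", "det", "obl", "punct")
  )
}

# random valid dependency tree: heads assigned along a random permutation so
# the governor graph is always acyclic with a single root
random_sentence_df <- function(n, doc_id = "doc1", sent_id = 1L, p_punct = 0.15) {
  ord <- sample.int(n)
  head <- integer(n)
  head[ord[1]] <- 0L
  for (k in seq_len(n)[-1]) {
    head[ord[k]] <- ord[sample.int(k - 1L, 1L)]
  }
  is_punct <- stats::runif(n) < p_punct
  is_punct[ord[1]] <- FALSE # root never punctuation
  data.frame(
    doc_id = doc_id, sent_id = sent_id, id = seq_len(n),
    form = ifelse(is_punct, ".", paste0("w", sample.int(50, n, replace = TRUE))),
    upos = ifelse(is_punct, "PUNCT", "NOUN"),
    head = head,
    deprel = ifelse(is_punct, "punct", "dep"),
    stringsAsFactors = FALSE
  )
}

random_treebank <- function(n_sentences, min_tokens = 2L, max_tokens = 12L) {
  sents <- lapply(seq_len(n_sentences), function(s) {
    random_sentence_df(sample(min_tokens:max_tokens, 1L), sent_id = s)
  })
  treebank(do.call(rbind, sents))
}

# independent MDD oracle: direct iteration over tokens
oracle_mdd_text <- function(tb, include_punct, denom_mode = "words_minus_one") {
  tok <- as.data.frame(tb)
  num <- 0
  den <- 0
  n_usable <- 0L
  for (sent in split(tok, paste(tok$doc_id, tok$sent_id))) {
    s_num <- 0
    s_links <- 0L
    for (i in seq_len(nrow(sent))) {
      if (sent$head[i] == 0L) next
      if (!include_punct && sent$is_punct[i]) next
      s_num <- s_num + abs(sent$head[i] - sent$id[i])
      s_links <- s_links + 1L
    }
    s_den <- if (denom_mode == "links_count") s_links else sum(!sent$is_punct) - 1L
    if (s_links > 0L && s_den > 0L) {
      num <- num + s_num
      den <- den + s_den
      n_usable <- n_usable + 1L
    }
  }
  if (n_usable == 0L) return(NA_real_)
  num / den
}

# exhaustive node-metric oracle on a symmetric 0/1 adjacency matrix:
# BFS distances, all-shortest-path enumeration for betweenness, direct
# neighbourhood counting for clustering
oracle_node_metrics <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier) > 0L) {
      d <- d + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] == 1)) {
          if (v != s && is.infinite(D[s, v])) {
            D[s, v] <- d
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      total <- 0
      through <- numeric(n)
      rec <- function(u, interior) {
        if (u == t) {
          total <<- total + 1
          through[interior] <<- through[interior] + 1
          return(invisible())
        }
        for (v in which(adj[u, ] == 1)) {
          if (D[s, v] == D[s, u] + 1 && D[v, t] == D[u, t] - 1) {
            rec(v, if (v == t) interior else c(interior, v))
          }
        }
      }
      rec(s, integer(0))
      if (total > 0) btw <- btw + through / total
    }
  }
  btw <- btw / ((n - 1) * (n - 2) / 2)
  clo <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0L || sum(d) == 0) 0 else (r / (n - 1)) * (r / sum(d))
  }, numeric(1))
  clu <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) 0 else sum(adj[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  list(betweenness = btw, closeness = clo, clustering = clu,
       degree = rowSums(adj))
}

adjacency_to_network <- function(adj) {
  n <- nrow(adj)
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  dependency_network(
    vertices = sprintf("v%02d", seq_len(n)),
    arcs = data.frame(gov = idx[, 1], dep = idx[, 2],
                      rel = rep("dep", nrow(idx)),
                      weight = rep(1, nrow(idx)), stringsAsFactors = FALSE)
  )
}

is_connected_adj <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(adj[u, ] == 1)) {
        if (!seen[v]) {
          seen[v] <- TRUE
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  all(seen)
}

random_connected_adj <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
      }
    }
    if (is_connected_adj(adj)) return(adj)
  }
}

expect_metrics_match_oracle <- function(adj) {
  net <- adjacency_to_network(adj)
  got <- node_metrics(net)
  want <- oracle_node_metrics(adj)
  expect_equal(got$betweenness, want$betweenness, tolerance = 1e-10)
  expect_equal(got$closeness, want$closeness, tolerance = 1e-10)
  expect_equal(got$clustering, want$clustering, tolerance = 1e-10)
  expect_equal(got$degree, as.integer(want$degree))
}

# independent population-SD reference
sd_pop_ref <- function(x) sqrt(mean((x - mean(x))^2))

# definitional VIF reference: 1/(1 - R^2_j) via a direct lm per column
vif_values_ref <- function(X) {
  vapply(names(X), function(j) {
    r2 <- summary(stats::lm(X[[j]] ~ ., data = X[setdiff(names(X), j)]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}
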