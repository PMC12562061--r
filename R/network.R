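#' Weighted directed word-type dependency network
#'
#' Vertices are lowercased surface forms (clitics such as "'s" keep their own
#' type); arcs run governor → dependent, keyed by relation, weighted by
#' occurrence count. Loops (a type governing itself) are permitted.
#'
#' @param vertices character vector of word-type labels, in a fixed order
#'   (1-based vertex ids).
#' @param arcs data frame with columns `gov`, `dep` (1-based vertex ids),
#'   `rel` (relation label) and `weight` (positive count).
#' @return an object of class `dependency_network`.
#' @export
dependency_network <- function(vertices, arcs) {
  stopifnot(is.character(vertices),
            all(c("gov", "dep", "rel", "weight") %in% names(arcs)))
  if (nrow(arcs) > 0L) {
    if (any(arcs$gov < 1L | arcs$gov > length(vertices)) ||
        any(arcs$dep < 1L | arcs$dep > length(vertices))) {
      stop("arc references a vertex id outside 1..", length(vertices))
    }
    if (any(arcs$weight < 1)) stop("arc weights must be >= 1")
    if (anyDuplicated(paste(arcs$gov, arcs$dep, arcs$rel, sep = "\r"))) {
      stop("duplicate (governor, dependent, relation) arc keys")
    }
  }
  arcs <- as.data.frame(arcs)[c("gov", "dep", "rel", "weight")]
  rownames(arcs) <- NULL
  structure(list(vertices = vertices, arcs = arcs,
                 n = length(vertices), m = nrow(arcs)),
            class = "dependency_network")
}

#' @export
print.dependency_network <- function(x, ...) {
  cat(sprintf("<dependency_network: n = %d vertices, m = %d arcs, total weight %s>\n",
              x$n, x$m, format(sum(x$arcs$weight))))
  invisible(x)
}

#' Build the word-type dependency network of a treebank
#'
#' One arc per distinct (governor word type, dependent word type, relation)
#' triple with weight equal to its occurrence count. Root links and links
#' whose dependent is punctuation are excluded; vertices are all distinct
#' lowercased non-punctuation word types, in order of first appearance.
#'
#' @param tb a `treebank`.
#' @return a [dependency_network()].
#' @export
build_network <- function(tb) {
  tok <- as.data.frame(tb)
  tok$lform <- tolower(tok$form)
  vertices <- unique(tok$lform[!tok$is_punct])
  skey <- paste(tok$doc_id, tok$sent_id, sep = "\r")
  hmatch <- match(paste(skey, tok$head, sep = "\r"), paste(skey, tok$id, sep = "\r"))
  keep <- tok$head != 0L & !tok$is_punct
  gov_form <- tok$lform[hmatch[keep]]
  dep_form <- tok$lform[keep]
  rel <- tok$deprel[keep]
  if (length(rel) == 0L) {
    return(dependency_network(vertices, data.frame(
      gov = integer(0), dep = integer(0), rel = character(0), weight = numeric(0),
      stringsAsFactors = FALSE
    )))
  }
  agg <- stats::aggregate(
    list(weight = rep(1L, length(rel))),
    by = list(gov = match(gov_form, vertices), dep = match(dep_form, vertices),
              rel = rel),
    FUN = sum
  )
  agg <- agg[order(agg$gov, agg$dep, agg$rel), , drop = FALSE]
  dependency_network(vertices, agg)
}

#' Pajek-convention network summary
#'
#' Average degree `2m/n` and loops-allowed density `2m/n^2`, where `n` is
#' the vertex count and `m` the number of distinct arcs (lines).
#'
#' @param network a [dependency_network()], or `NULL` if `n`/`m` are given.
#' @param n,m override the vertex and line counts directly (summaries are
#'   often recomputed from printed counts).
#' @return list with `n`, `m`, `average_degree`, `density_loops_allowed`.
#' @export
pajek_summary <- function(network = NULL, n = NULL, m = NULL) {
  if (!is.null(network)) {
    stopifnot(inherits(network, "dependency_network"))
    n <- network$n
    m <- network$m
  }
  if (is.null(n) || is.null(m)) stop("supply a network or both n and m")
  if (n < 1) stop("pajek_summary: n must be >= 1")
  list(n = n, m = m, average_degree = 2 * m / n,
       density_loops_allowed = 2 * m / n^2)
}

as_undirected_skeleton <- function(network) {
  arcs <- network$arcs
  arcs <- arcs[arcs$gov != arcs$dep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(arcs$gov), to = as.character(arcs$dep)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(network$n)))
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Per-vertex topology metrics
#'
#' Computed on the undirected simple skeleton of the network (directions and
#' weights dropped, parallel arcs merged, loops ignored):
#' \describe{
#'   \item{betweenness}{shortest-path betweenness centrality, normalised by
#'     `(n-1)(n-2)/2`}
#'   \item{closeness}{per-component-normalised closeness: with `r` the
#'     number of other reachable vertices and `D` the summed shortest-path
#'     distances to them, `(r/(n-1)) * (r/D)`; isolated vertices score 0}
#'   \item{clustering}{local clustering coefficient
#'     `2 e(N(v)) / (k (k-1))`, 0 when the skeleton degree `k < 2`}
#' }
#' `degree` is the skeleton degree; `weighted_degree` is the sum of the
#' weights of all incident arcs of the original directed network (in + out;
#' a loop counts twice).
#'
#' @param network a [dependency_network()] with at least 2 vertices.
#' @return data frame with columns `vertex`, `degree`, `weighted_degree`,
#'   `betweenness`, `closeness`, `clustering`.
#' @export
node_metrics <- function(network) {
  stopifnot(inherits(network, "dependency_network"))
  if (network$n < 2L) stop("node_metrics: need at least 2 vertices")
  g <- as_undirected_skeleton(network)
  n <- network$n
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  D <- igraph::distances(g)
  closeness <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0L || sum(d) == 0) return(0)
    (r / (n - 1)) * (r / sum(d))
  }, numeric(1))
  clust <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  wdeg <- weighted_degree_values(network)
  data.frame(
    vertex = network$vertices,
    degree = as.integer(igraph::degree(g)),
    weighted_degree = wdeg,
    betweenness = as.numeric(btw),
    closeness = closeness,
    clustering = as.numeric(clust),
    stringsAsFactors = FALSE
  )
}

weighted_degree_values <- function(network) {
  w <- numeric(network$n)
  if (network$m > 0L) {
    out_w <- tapply(network$arcs$weight, factor(network$arcs$gov, levels = seq_len(network$n)), sum)
    in_w <- tapply(network$arcs$weight, factor(network$arcs$dep, levels = seq_len(network$n)), sum)
    out_w[is.na(out_w)] <- 0
    in_w[is.na(in_w)] <- 0
    w <- as.numeric(out_w + in_w)
  }
  w
}

#' Top weighted vertices
#'
#' The weighted degree of a vertex is the sum of the weights of all arcs
#' incident to it (incoming plus outgoing; a loop contributes twice).
#' Ranking is by value descending, ties broken by vertex label ascending.
#'
#' @param network a [dependency_network()].
#' @param top_k number of vertices to return.
#' @return data frame with columns `rank`, `vertex`, `value`.
#' @export
weighted_degrees <- function(network, top_k = network$n) {
  stopifnot(top_k >= 1)
  vals <- weighted_degree_values(network)
  ord <- order(-vals, network$vertices)
  k <- min(top_k, network$n)
  data.frame(rank = seq_len(k), vertex = network$vertices[ord[seq_len(k)]],
             value = vals[ord[seq_len(k)]], stringsAsFactors = FALSE)
}

#' Cross difference of two dependency networks
#'
#' Arcs of `a` whose (governor, dependent, relation) key does not occur in
#' `b`, retaining `a`'s weights; when `top_k` is finite, only the `top_k`
#' heaviest such arcs are kept (weight descending, ties by governor label,
#' dependent label, relation ascending). The result's vertex set is
#' restricted to vertices incident to a retained arc, preserving `a`'s
#' ordering.
#'
#' @param a,b [dependency_network()] objects.
#' @param top_k arc budget; `Inf` keeps every differing arc.
#' @return a [dependency_network()].
#' @export
network_difference <- function(a, b, top_k = Inf) {
  key <- function(net) {
    paste(net$vertices[net$arcs$gov], net$vertices[net$arcs$dep], net$arcs$rel,
          sep = "\r")
  }
  keep <- !(key(a) %in% key(b))
  arcs <- a$arcs[keep, , drop = FALSE]
  if (is.finite(top_k) && nrow(arcs) > top_k) {
    ord <- order(-arcs$weight, a$vertices[arcs$gov], a$vertices[arcs$dep], arcs$rel)
    arcs <- arcs[ord[seq_len(top_k)], , drop = FALSE]
  }
  used <- sort(unique(c(arcs$gov, arcs$dep)))
  vertices <- a$vertices[used]
  arcs$gov <- match(arcs$gov, used)
  arcs$dep <- match(arcs$dep, used)
  dependency_network(vertices, arcs)
}
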