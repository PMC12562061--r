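#' Read a dependency network from a Pajek .net file
#'
#' Accepts the arc-list dialect written by [write_pajek_net()]: a
#' `*Vertices n` section with 1-based ids and quoted labels, then a `*Arcs`
#' section of `gov dep weight l "relation"` lines. Section markers are
#' case-insensitive; any other `*` marker is a parse error.
#'
#' @param path a `.net` file.
#' @return a [dependency_network()].
#' @export
read_pajek_net <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !grepl("^\\*vertices\\s+\\d+", tolower(lines[1]))) {
    stop(path, ": Pajek file must begin with a *Vertices section")
  }
  n <- as.integer(sub("^\\*vertices\\s+(\\d+).*$", "\\1", tolower(lines[1])))
  vertices <- character(n)
  i <- 2L
  while (i <= length(lines) && !startsWith(lines[i], "*")) {
    m <- regmatches(lines[i], regexec('^\\s*(\\d+)\\s+"(.*)"\\s*$', lines[i]))[[1]]
    if (length(m) != 3L) stop(path, ": malformed vertex line: ", lines[i])
    idx <- as.integer(m[2])
    if (idx < 1L || idx > n) stop(path, ": vertex id ", idx, " outside 1..", n)
    vertices[idx] <- m[3]
    i <- i + 1L
  }
  gov <- integer(0); dep <- integer(0); w <- numeric(0); rel <- character(0)
  if (i <= length(lines)) {
    if (tolower(trimws(lines[i])) != "*arcs") {
      stop(path, ": unknown section marker: ", lines[i])
    }
    i <- i + 1L
    while (i <= length(lines)) {
      if (startsWith(lines[i], "*")) stop(path, ": unknown section marker: ", lines[i])
      m <- regmatches(
        lines[i],
        regexec('^\\s*(\\d+)\\s+(\\d+)\\s+([0-9.eE+-]+)(?:\\s+l\\s+"(.*)")?\\s*$', lines[i])
      )[[1]]
      if (length(m) < 4L) stop(path, ": malformed arc line: ", lines[i])
      a <- as.integer(m[2]); b <- as.integer(m[3])
      if (a < 1L || a > n || b < 1L || b > n) {
        stop(path, ": arc references vertex outside 1..", n)
      }
      gov <- c(gov, a); dep <- c(dep, b); w <- c(w, as.numeric(m[4]))
      rel <- c(rel, if (length(m) == 5L && !is.na(m[5])) m[5] else "")
      i <- i + 1L
    }
  }
  dependency_network(
    vertices = vertices,
    arcs = data.frame(gov = gov, dep = dep, rel = rel, weight = w,
                      stringsAsFactors = FALSE)
  )
}

#' Write a dependency network as a Pajek .net file
#'
#' Vertex labels are quoted; vertex ids are 1-based; arcs carry their weight
#' and the relation as a Pajek line label. Arcs are written in a canonical
#' order (governor, dependent, relation), so write → read → write is
#' byte-identical.
#'
#' @param network a [dependency_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pajek_net <- function(network, path) {
  stopifnot(inherits(network, "dependency_network"))
  arcs <- network$arcs
  arcs <- arcs[order(arcs$gov, arcs$dep, arcs$rel), , drop = FALSE]
  lines <- c(
    sprintf("*Vertices %d", length(network$vertices)),
    sprintf('%d "%s"', seq_along(network$vertices), network$vertices),
    "*Arcs",
    if (nrow(arcs) > 0L) {
      sprintf('%d %d %s l "%s"', arcs$gov, arcs$dep,
              format(arcs$weight, trim = TRUE, scientific = FALSE), arcs$rel)
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
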