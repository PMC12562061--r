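#' Token tables for dependency-parsed speech transcripts
#'
#' A `treebank` is a data frame of tokens, one row per token, in the spirit
#' of the token tables used by CoNLL-U tooling. Columns:
#' \describe{
#'   \item{doc_id}{transcript identifier (character); the statistical unit of
#'     the group-level analyses}
#'   \item{sent_id}{utterance index within the transcript (integer)}
#'   \item{id}{1-based linear position of the token within its utterance}
#'   \item{form}{surface form}
#'   \item{upos}{part-of-speech tag (UPOS or PTB-style; both are accepted)}
#'   \item{head}{position of the governor; 0 marks the root}
#'   \item{deprel}{dependency relation label}
#'   \item{is_punct}{`TRUE` for punctuation tokens (`upos == "PUNCT"` or
#'     `deprel == "punct"`)}
#' }
#' plus attributes `group_label` and `source_path`.
#'
#' @param tokens data frame with at least `doc_id`, `sent_id`, `id`, `form`,
#'   `upos`, `head`, `deprel`.
#' @param group_label optional group tag (e.g. `"AD"`, `"HC"`).
#' @param source_path optional provenance string.
#' @param validate if `TRUE` (default), every sentence is checked against the
#'   tree invariants (contiguous positions, single root, acyclicity).
#' @return an object of class `treebank` (a data frame).
#' @export
treebank <- function(tokens, group_label = NA_character_,
                     source_path = NA_character_, validate = TRUE) {
  required <- c("doc_id", "sent_id", "id", "form", "upos", "head", "deprel")
  missing_cols <- setdiff(required, names(tokens))
  if (length(missing_cols) > 0L) {
    stop("treebank tokens lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  tokens$doc_id <- as.character(tokens$doc_id)
  tokens$sent_id <- as.integer(tokens$sent_id)
  tokens$id <- as.integer(tokens$id)
  tokens$head <- as.integer(tokens$head)
  tokens$is_punct <- tokens$upos == "PUNCT" | tokens$deprel == "punct"
  tokens <- tokens[order(tokens$doc_id, tokens$sent_id, tokens$id), , drop = FALSE]
  rownames(tokens) <- NULL
  tb <- structure(tokens,
    class = c("treebank", "data.frame"),
    group_label = group_label,
    source_path = source_path
  )
  if (nrow(tb) == 0L) stop("no sentences: treebank is empty")
  if (validate) validate_treebank(tb)
  tb
}

#' @export
print.treebank <- function(x, ...) {
  lab <- attr(x, "group_label")
  cat(sprintf(
    "<treebank%s: %d transcript(s), %d sentence(s), %d token(s)>\n",
    if (is.na(lab)) "" else paste0(" ", lab),
    length(unique(x$doc_id)), n_sentences(x), nrow(x)
  ))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Number of sentences in a treebank
#' @param tb a `treebank`.
#' @return integer sentence count (the `s` of the text-level mean dependency
#'   distance formula).
#' @export
n_sentences <- function(tb) {
  nrow(unique(as.data.frame(tb)[c("doc_id", "sent_id")]))
}

#' Split a treebank into per-sentence token tables
#' @param tb a `treebank`.
#' @return a list of data frames, one per sentence, in (doc_id, sent_id) order.
#' @export
sentences <- function(tb) {
  key <- paste(tb$doc_id, formatC(tb$sent_id, width = 9, flag = "0"), sep = "\r")
  split(as.data.frame(tb), factor(key, levels = unique(key)))
}

#' Validate the tree invariants of every sentence
#'
#' Checks, per sentence: token positions contiguous `1..n`; exactly one token
#' with `head == 0`; every head resolves to a position within the sentence and
#' never to the token itself; the governor graph is acyclic.
#'
#' @param tb a `treebank`.
#' @return `tb`, invisibly. Signals an error naming the offending sentence.
#' @export
validate_treebank <- function(tb) {
  for (sent in sentences(tb)) {
    tag <- sprintf("sentence %s/%s", sent$doc_id[1], sent$sent_id[1])
    n <- nrow(sent)
    if (!identical(sort(sent$id), seq_len(n))) {
      stop(tag, ": token positions are not contiguous 1..", n)
    }
    n_root <- sum(sent$head == 0L)
    if (n_root != 1L) {
      stop(tag, ": expected exactly one root, found ", n_root)
    }
    if (any(sent$head < 0L | sent$head > n)) {
      stop(tag, ": head reference outside the sentence")
    }
    if (any(sent$head == sent$id)) {
      stop(tag, ": token governs itself")
    }
    # walk to the root from every token; a cycle never reaches head 0
    parent <- sent$head[order(sent$id)]
    for (start in seq_len(n)) {
      cur <- start
      steps <- 0L
      while (cur != 0L) {
        cur <- parent[cur]
        steps <- steps + 1L
        if (steps > n) stop(tag, ": cyclic governor structure")
      }
    }
  }
  invisible(tb)
}

#' Read CoNLL-U treebanks
#'
#' Parses one CoNLL-U file, or every `*.conllu` file in a directory (one
#' transcript per file). Multiword-token ranges (`1-2`) and empty nodes
#' (`1.1`) carry no usable position/head and are skipped with a warning.
#' `# sent_id` and `# newdoc id` comments are honoured when present.
#'
#' @param path a CoNLL-U file or a directory of `*.conllu` files.
#' @param group_label optional group tag stored on the result.
#' @return a `treebank`.
#' @export
read_conllu <- function(path, group_label = NA_character_) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  files <- path
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.conllu$", full.names = TRUE)
    if (length(files) == 0L) stop("no sentences: no .conllu files under ", path)
    files <- sort(files)
  }
  parts <- lapply(files, parse_conllu_file)
  tokens <- do.call(rbind, parts)
  if (is.null(tokens) || nrow(tokens) == 0L) stop("no sentences: ", path)
  treebank(tokens, group_label = group_label, source_path = path)
}

parse_conllu_file <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  default_doc <- sub("\\.conllu$", "", basename(file))
  doc_id <- default_doc
  sent_counter <- 0L
  sent_id <- NA_integer_
  n_skipped <- 0L
  out <- list()
  buf <- NULL
  flush_sentence <- function() {
    if (!is.null(buf) && nrow(buf) > 0L) {
      out[[length(out) + 1L]] <<- buf
    }
    buf <<- NULL
    sent_id <<- NA_integer_
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "") {
      flush_sentence()
      next
    }
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*newdoc(?:\\s+id\\s*=\\s*(.*))?$", line))[[1]]
      if (length(m) > 0L) {
        flush_sentence()
        sent_counter <- 0L
        doc_id <- if (!is.na(m[2]) && nzchar(trimws(m[2]))) trimws(m[2]) else default_doc
        next
      }
      m <- regmatches(line, regexec("^#\\s*sent_id\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 2L) {
        v <- suppressWarnings(as.integer(trimws(m[2])))
        if (!is.na(v)) sent_id <- v
      }
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10L) {
      stop(sprintf("%s:%d: malformed CoNLL-U line (expected 10 tab-separated fields, got %d)",
                   file, i, length(fields)))
    }
    if (grepl("[.-]", fields[1])) { # multiword-token range or empty node
      n_skipped <- n_skipped + 1L
      next
    }
    tok_id <- suppressWarnings(as.integer(fields[1]))
    tok_head <- suppressWarnings(as.integer(fields[7]))
    if (is.na(tok_id) || is.na(tok_head)) {
      stop(sprintf("%s:%d: malformed CoNLL-U line (non-integer ID or HEAD)", file, i))
    }
    if (is.null(buf)) {
      sent_counter <- sent_counter + 1L
      if (is.na(sent_id)) sent_id <- sent_counter
      buf <- data.frame(
        doc_id = character(0), sent_id = integer(0), id = integer(0),
        form = character(0), upos = character(0), head = integer(0),
        deprel = character(0), stringsAsFactors = FALSE
      )
    }
    buf[nrow(buf) + 1L, ] <- list(doc_id, sent_id, tok_id, fields[2],
                                  fields[4], tok_head, fields[8])
    next
  }
  flush_sentence()
  if (n_skipped > 0L) {
    warning(sprintf("%s: skipped %d multiword-token/empty-node line(s)", file, n_skipped))
  }
  if (length(out) == 0L) stop("no sentences: ", file)
  do.call(rbind, out)
}

#' Write a treebank as CoNLL-U
#'
#' Writes all transcripts to one file (with `# newdoc id` boundaries) when
#' `path` ends in `.conllu`, or one file per transcript into a directory
#' otherwise. `read_conllu()` on the output reproduces the treebank
#' token-for-token.
#'
#' @param tb a `treebank`.
#' @param path output file (`*.conllu`) or directory.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(tb, path) {
  fmt_doc <- function(doc, with_newdoc) {
    lines <- character(0)
    if (with_newdoc) lines <- c(lines, paste0("# newdoc id = ", doc$doc_id[1]))
    for (sent in split(doc, doc$sent_id)) {
      sent <- sent[order(sent$id), , drop = FALSE]
      lines <- c(
        lines,
        paste0("# sent_id = ", sent$sent_id[1]),
        sprintf("%d\t%s\t_\t%s\t_\t_\t%d\t%s\t_\t_",
                sent$id, sent$form, sent$upos, sent$head, sent$deprel),
        ""
      )
    }
    lines
  }
  docs <- split(as.data.frame(tb), tb$doc_id)
  docs <- docs[order(names(docs))]
  if (grepl("\\.conllu$", path)) {
    writeLines(unlist(lapply(docs, fmt_doc, with_newdoc = TRUE)), path, useBytes = TRUE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (doc in docs) {
      writeLines(fmt_doc(doc, with_newdoc = FALSE),
                 file.path(path, paste0(doc$doc_id[1], ".conllu")), useBytes = TRUE)
    }
  }
  invisible(path)
}
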