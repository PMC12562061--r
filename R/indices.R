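#' Canonical dependency-relation mapping
#'
#' Treebanks arrive in two label dialects: Universal Dependencies v2 and
#' Stanford-style labels (the dialect used by older complexity tools). The
#' index definitions operate on a canonical UD-flavoured label set; this
#' table renames the Stanford labels that have a direct UD counterpart.
#' Structural differences that a rename cannot express (prepositions head
#' their object in the Stanford style, while UD attaches the adposition to
#' the nominal via `case`) are handled inside the index predicates, which
#' recognise both attachment patterns.
#'
#' @return named character vector: `names()` are source labels, values are
#'   canonical labels.
#' @export
relation_map <- function() {
  c(
    dobj = "obj", rcmod = "acl:relcl", vmod = "acl", poss = "nmod:poss",
    nsubjpass = "nsubj:pass", auxpass = "aux:pass", num = "nummod",
    nn = "compound", possessive = "case", attr = "ncomp", acomp = "xcomp"
  )
}

canonical_deprel <- function(deprel, map = relation_map()) {
  hit <- match(deprel, names(map))
  out <- deprel
  out[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  out
}

NOMINAL_POS <- c("NOUN", "PROPN", "NN", "NNS", "NNP", "NNPS")
PRONOUN_POS <- c("PRON", "PRP", "PRP$", "WP", "WP$")
VERBAL_POS <- c("VERB", "AUX", "VB", "VBD", "VBG", "VBN", "VBP", "VBZ", "MD")

# Per-token derived features shared by the index predicates. Returns the
# token table with canonical relations plus, per token: number of dependents,
# counts of specific child relations, and unit-membership flags.
token_features <- function(tb) {
  tok <- as.data.frame(tb)
  tok$crel <- canonical_deprel(tok$deprel)
  skey <- paste(tok$doc_id, tok$sent_id, sep = "\r")
  tok$tkey <- paste(skey, tok$id, sep = "\r")
  hkey <- ifelse(tok$head == 0L, NA_character_, paste(skey, tok$head, sep = "\r"))

  count_children <- function(mask) {
    tab <- table(hkey[mask & !is.na(hkey)])
    out <- as.integer(tab[tok$tkey])
    out[is.na(out)] <- 0L
    out
  }
  tok$ndeps <- count_children(rep(TRUE, nrow(tok)))
  tok$n_amod <- count_children(tok$crel == "amod")
  tok$n_case <- count_children(tok$crel == "case")
  tok$n_poss <- count_children(tok$crel == "nmod:poss")
  tok$n_relcl <- count_children(tok$crel == "acl:relcl")
  tok$n_vmod <- count_children(tok$crel == "acl")
  tok$n_cop <- count_children(tok$crel == "cop")
  # prepositional-phrase dependents: a `prep` child (Stanford) or a
  # nominal-modifier child that itself carries a `case` marker (UD)
  has_case_child <- tok$n_case > 0L
  pp_mask <- tok$crel == "prep" |
    (tok$crel %in% c("nmod", "obl") & has_case_child)
  tok$n_pp <- count_children(pp_mask)
  tok$is_pp <- pp_mask

  tok$is_nominal <- tok$upos %in% c(NOMINAL_POS, PRONOUN_POS) & !tok$is_punct
  tok$is_nominal_nn <- tok$upos %in% NOMINAL_POS & !tok$is_punct
  tok$is_verbal <- tok$upos %in% VERBAL_POS
  # object of a preposition: Stanford pobj, or a nominal bearing a case child
  tok$is_pobj <- tok$crel == "pobj" | (tok$is_nominal & has_case_child)
  tok$is_nsubj <- tok$crel %in% c("nsubj", "nsubj:pass")
  tok$is_dobj <- tok$crel == "obj"
  # nominal complement: predicate nominal (copular head) or Stanford attr
  tok$is_ncomp <- tok$is_nominal & (tok$n_cop > 0L | tok$crel == "ncomp")
  tok
}

#' Clause anchors of a sentence
#'
#' A clause anchor is the token heading a clause: the sentence root plus
#' every token bearing a clausal relation (clausal complement, open clausal
#' complement, adverbial clause, relative/adnominal-finite clause) and every
#' verb-headed conjunct (clause-level coordination). A verbless fragment
#' contributes its root as a single anchor, so per-clause denominators are
#' defined for phrase-only utterances.
#'
#' @param sentence a one-sentence token data frame.
#' @return data frame with columns `position` and `kind` (`root`,
#'   `complement`, `open_complement`, `adverbial`, `relative`,
#'   `coordinated`).
#' @export
clause_anchors <- function(sentence) {
  crel <- canonical_deprel(sentence$deprel)
  verbal <- sentence$upos %in% VERBAL_POS
  kind <- rep(NA_character_, nrow(sentence))
  kind[sentence$head == 0L] <- "root"
  kind[crel == "ccomp"] <- "complement"
  kind[crel == "xcomp"] <- "open_complement"
  kind[crel == "advcl"] <- "adverbial"
  kind[crel == "acl:relcl"] <- "relative"
  kind[crel == "conj" & verbal] <- "coordinated"
  keep <- !is.na(kind)
  data.frame(position = sentence$id[keep], kind = kind[keep],
             stringsAsFactors = FALSE)
}

clause_anchor_flags <- function(tok) {
  verbal <- tok$upos %in% VERBAL_POS
  tok$head == 0L | tok$crel %in% c("ccomp", "xcomp", "advcl", "acl:relcl") |
    (tok$crel == "conj" & verbal)
}

#' The fine-grained syntactic index catalogue
#'
#' @return character vector of the 20 index names: 11 phrase-complexity
#'   indices (nominal elaboration) and 9 clause-complexity indices.
#' @export
index_catalogue <- function() {
  c(
    # phrase complexity
    "av_pobj_deps_NN", "amod_all_nominal_deps_NN_struct",
    "amod_dobj_deps_struct", "av_ncomp_deps_NN", "nominal_deps_stdev",
    "pobj_NN_stdev", "poss_nsubj_deps_NN_struct",
    "prep_all_nominal_deps_struct", "prep_nsubj_deps_NN_struct",
    "rcmod_nsubj_deps_NN_struct", "vmod_all_nominal_deps_NN_struct",
    # clause complexity
    "cc_per_cl", "ccomp_per_cl", "cl_av_deps", "cl_ndeps_std_dev",
    "conj_per_cl", "dobj_per_cl", "mark_per_cl", "prep_per_cl",
    "xcomp_per_cl"
  )
}

# population (divide-by-N) standard deviation: a descriptive statistic over
# the observed units
sd_pop <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

ratio_index <- function(numerator, denominator) {
  if (denominator == 0L) {
    structure(NA_real_, support = 0L)
  } else {
    structure(numerator / denominator, support = as.integer(denominator))
  }
}

compute_index_from_features <- function(tok, name) {
  anchors <- clause_anchor_flags(tok)
  n_cl <- sum(anchors)
  cc_tok <- tok$crel == "cc" & !tok$is_punct
  # clausal coordinating conjunction: a cc attached to a verbal head or to a
  # clause anchor (clause-level coordination, as opposed to NP-level)
  skey <- paste(tok$doc_id, tok$sent_id, sep = "\r")
  hkey <- ifelse(tok$head == 0L, NA_character_, paste(skey, tok$head, sep = "\r"))
  anchor_or_verb_keys <- tok$tkey[anchors | tok$is_verbal]
  cc_clausal <- cc_tok & !is.na(hkey) & hkey %in% anchor_or_verb_keys

  nom <- tok$is_nominal
  nom_nn <- tok$is_nominal_nn
  nsubj_nn <- tok$is_nsubj & nom_nn
  pobj_nn <- tok$is_pobj & nom_nn
  dobj <- tok$is_dobj
  ncomp_nn <- tok$is_ncomp & nom_nn

  switch(name,
    av_pobj_deps_NN = ratio_index(sum(tok$ndeps[pobj_nn]), sum(pobj_nn)),
    amod_all_nominal_deps_NN_struct = ratio_index(sum(tok$n_amod[nom_nn]), sum(nom_nn)),
    amod_dobj_deps_struct = ratio_index(sum(tok$n_amod[dobj]), sum(dobj)),
    av_ncomp_deps_NN = ratio_index(sum(tok$ndeps[ncomp_nn]), sum(ncomp_nn)),
    nominal_deps_stdev = structure(sd_pop(tok$ndeps[nom]), support = sum(nom)),
    pobj_NN_stdev = structure(sd_pop(tok$ndeps[pobj_nn]), support = sum(pobj_nn)),
    poss_nsubj_deps_NN_struct = ratio_index(sum(tok$n_poss[nsubj_nn]), sum(nsubj_nn)),
    prep_all_nominal_deps_struct = ratio_index(sum(tok$n_pp[nom]), sum(nom)),
    prep_nsubj_deps_NN_struct = ratio_index(sum(tok$n_pp[nsubj_nn]), sum(nsubj_nn)),
    rcmod_nsubj_deps_NN_struct = ratio_index(sum(tok$n_relcl[nsubj_nn]), sum(nsubj_nn)),
    vmod_all_nominal_deps_NN_struct = ratio_index(sum(tok$n_vmod[nom_nn]), sum(nom_nn)),
    cc_per_cl = ratio_index(sum(cc_clausal), n_cl),
    ccomp_per_cl = ratio_index(sum(tok$crel == "ccomp"), n_cl),
    cl_av_deps = ratio_index(sum(tok$ndeps[anchors]), n_cl),
    cl_ndeps_std_dev = structure(sd_pop(tok$ndeps[anchors]), support = n_cl),
    conj_per_cl = ratio_index(sum(cc_tok), n_cl),
    dobj_per_cl = ratio_index(sum(dobj), n_cl),
    mark_per_cl = ratio_index(sum(tok$crel == "mark"), n_cl),
    prep_per_cl = ratio_index(sum(tok$is_pp), n_cl),
    xcomp_per_cl = ratio_index(sum(tok$crel == "xcomp"), n_cl),
    stop("unknown index: ", name)
  )
}

#' Compute one fine-grained syntactic index
#'
#' Each index is a ratio of a (relation, part-of-speech) count over a unit
#' count: `*_per_cl` indices divide by the clause count; `*_deps_*` indices
#' divide by the count of the named target unit (nominals, nominal subjects,
#' prepositional objects, direct objects); `*stdev`/`*std_dev` indices are
#' the population standard deviation of per-unit dependent counts. Variants
#' marked `_NN` / "no pronouns" restrict the unit to non-pronoun nominals.
#' A zero denominator yields `NA` (flagged missing, never silently 0).
#'
#' @param tb a `treebank`.
#' @param name an index name from [index_catalogue()].
#' @return a numeric value with attribute `support` (the denominator size).
#' @export
compute_index <- function(tb, name) {
  if (!name %in% index_catalogue()) stop("unknown index: ", name)
  compute_index_from_features(token_features(tb), name)
}

#' Compute the full index catalogue for each transcript
#'
#' One row per transcript (`doc_id`): the 20 catalogue indices plus `ttr`.
#' Support counts (per-index denominators) are returned alongside as
#' `<name>_support` columns when `support = TRUE`.
#'
#' @param tb a `treebank`.
#' @param by_transcript if `FALSE`, the whole treebank is treated as one
#'   unit and a single row is returned.
#' @param support include per-index support-count columns.
#' @return data frame with `doc_id` plus 20 index columns and `ttr`.
#' @export
compute_all_indices <- function(tb, by_transcript = TRUE, support = FALSE) {
  tok_all <- token_features(tb)
  groups <- if (by_transcript) split(tok_all, tok_all$doc_id) else
    list(corpus = tok_all)
  cat_names <- index_catalogue()
  rows <- lapply(groups, function(tok) {
    vals <- lapply(cat_names, function(nm) compute_index_from_features(tok, nm))
    row <- as.data.frame(setNames(lapply(vals, as.numeric), cat_names))
    row$ttr <- ttr_from_tokens(tok)
    if (support) {
      sup <- setNames(lapply(vals, function(v) attr(v, "support")),
                      paste0(cat_names, "_support"))
      row <- cbind(row, as.data.frame(sup))
    }
    cbind(data.frame(doc_id = tok$doc_id[1], stringsAsFactors = FALSE), row)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ttr_from_tokens <- function(tok) {
  forms <- tolower(tok$form[!tok$is_punct])
  if (length(forms) == 0L) return(NA_real_)
  length(unique(forms)) / length(forms)
}

#' Type-token ratio
#'
#' Distinct lowercased surface forms divided by total tokens, punctuation
#' excluded. Disfluent repetitions count as tokens, so heavily fragmented
#' speech with short utterances inflates TTR.
#'
#' @param tb a `treebank`.
#' @return a value in (0, 1].
#' @export
type_token_ratio <- function(tb) {
  forms <- tolower(tb$form[!tb$is_punct])
  if (length(forms) == 0L) stop("type_token_ratio: no non-punctuation tokens")
  length(unique(forms)) / length(forms)
}
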