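#' Fixed function-word inventory of the generator
#'
#' The closed-class vocabulary used by [generate_corpus()]: determiners,
#' pronouns, auxiliaries/copulas, adpositions, conjunctions, the expletive
#' and the relativiser. Content words are drawn from an indexed vocabulary
#' (`n###`, `v###`, `j##`) and never collide with this set, so the inventory
#' doubles as the function-word vertex set for network analyses of
#' generated corpora.
#'
#' @return character vector of function-word forms.
#' @export
function_words <- function() {
  unique(c(
    "the", "a", "her", "his", "their", "she", "he", "it", "they", "i", "you",
    "there", "that", "is", "'s", "was", "are", "and", "or", "but",
    "in", "on", "of", "with", "under", "from", "to",
    "because", "when", "while", "if"
  ))
}

# token builder: grows parallel vectors; heads are local indices patched as
# the structure is assembled (0 = sentence root)
new_sentence_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$form <- character(0)
  env$upos <- character(0)
  env$head <- integer(0)
  env$deprel <- character(0)
  env
}

add_token <- function(b, form, upos, head, deprel) {
  i <- length(b$form) + 1L
  b$form[i] <- form
  b$upos[i] <- upos
  b$head[i] <- head
  b$deprel[i] <- deprel
  i
}

make_lexicon <- function(profile) {
  v <- profile$vocab_size
  n_nouns <- max(4L, round(0.60 * v))
  n_verbs <- max(3L, round(0.25 * v))
  n_adjs <- max(3L, v - n_nouns - n_verbs)
  zipf <- function(k) {
    p <- seq_len(k)^(-profile$zipf_exponent)
    p / sum(p)
  }
  list(
    nouns = sprintf("n%03d", seq_len(n_nouns)), p_nouns = zipf(n_nouns),
    verbs = sprintf("v%03d", seq_len(n_verbs)), p_verbs = zipf(n_verbs),
    adjs = sprintf("j%02d", seq_len(n_adjs)), p_adjs = zipf(n_adjs)
  )
}

draw <- function(x, p = NULL) sample(x, 1L, prob = p)
bern <- function(p) stats::runif(1) < p

# noun phrase: [poss|det] adj* noun pp* relcl* [cc conj]; returns the index
# of the head noun, whose head/deprel the caller must set
gen_np <- function(b, profile, lex, depth = 0L) {
  det_i <- NA_integer_
  if (bern(0.15)) {
    det_i <- add_token(b, draw(c("her", "his", "their")), "PRON", NA, "nmod:poss")
  } else if (bern(0.85)) {
    det_i <- add_token(b, draw(c("the", "a")), "DET", NA, "det")
  }
  n_adj <- min(stats::rpois(1, profile$adjective_rate), 2L)
  adj_i <- integer(0)
  for (k in seq_len(n_adj)) {
    adj_i <- c(adj_i, add_token(b, draw(lex$adjs, lex$p_adjs), "ADJ", NA, "amod"))
  }
  noun_i <- add_token(b, draw(lex$nouns, lex$p_nouns), "NOUN", NA, "dep")
  if (!is.na(det_i)) b$head[det_i] <- noun_i
  for (i in adj_i) b$head[i] <- noun_i
  if (depth < 2L) {
    n_pp <- min(stats::rpois(1, profile$pp_postmod_rate), 2L)
    for (k in seq_len(n_pp)) {
      pp_head <- gen_pp(b, profile, lex, depth + 1L)
      b$head[pp_head] <- noun_i
      b$deprel[pp_head] <- "nmod"
    }
    if (bern(profile$p_relative_clause)) {
      rel_i <- add_token(b, "that", "PRON", NA, "nsubj")
      rv_i <- add_token(b, draw(lex$verbs, lex$p_verbs), "VERB", noun_i, "acl:relcl")
      b$head[rel_i] <- rv_i
      if (bern(0.5)) {
        obj_i <- gen_np(b, profile, lex, depth + 1L)
        b$head[obj_i] <- rv_i
        b$deprel[obj_i] <- "obj"
      }
    }
    if (bern(profile$p_phrasal_coordination)) {
      cc_i <- add_token(b, draw(c("and", "or")), "CCONJ", NA, "cc")
      det2_i <- if (bern(0.6)) {
        add_token(b, draw(c("the", "a")), "DET", NA, "det")
      } else NA_integer_
      conj_i <- add_token(b, draw(lex$nouns, lex$p_nouns), "NOUN", noun_i, "conj")
      b$head[cc_i] <- conj_i
      if (!is.na(det2_i)) b$head[det2_i] <- conj_i
    }
  }
  noun_i
}

# adpositional phrase: adp + NP; returns the index of the object nominal,
# whose head/deprel the caller must set (case marking is already attached)
gen_pp <- function(b, profile, lex, depth) {
  adp_i <- add_token(b, draw(c("in", "on", "of", "with", "under", "from")),
                     "ADP", NA, "case")
  obj_i <- gen_np(b, profile, lex, depth)
  b$head[adp_i] <- obj_i
  obj_i
}

# clause core (subject + verb + arguments); returns the index of the clause
# head, whose head/deprel the caller must set
gen_clause <- function(b, profile, lex, depth = 0L, p_pron_subj = 0.35) {
  if (bern(p_pron_subj)) {
    subj_i <- add_token(b, draw(c("she", "he", "it", "they", "i", "you")),
                        "PRON", NA, "nsubj")
  } else {
    subj_i <- gen_np(b, profile, lex, depth)
    b$deprel[subj_i] <- "nsubj"
  }
  aux_i <- if (bern(0.35)) add_token(b, draw(c("is", "was")), "AUX", NA, "aux") else NA_integer_
  verb_i <- add_token(b, draw(lex$verbs, lex$p_verbs), "VERB", NA, "dep")
  b$head[subj_i] <- verb_i
  if (!is.na(aux_i)) b$head[aux_i] <- verb_i
  # open or closed complement clause (rates tied to the subordination rate),
  # else an optional direct object
  if (depth < 2L && bern(0.5 * profile$p_subordination)) {
    to_i <- add_token(b, "to", "PART", NA, "mark")
    xv_i <- add_token(b, draw(lex$verbs, lex$p_verbs), "VERB", verb_i, "xcomp")
    b$head[to_i] <- xv_i
    if (bern(0.6)) {
      obj_i <- gen_np(b, profile, lex, depth + 1L)
      b$head[obj_i] <- xv_i
      b$deprel[obj_i] <- "obj"
    }
  } else if (depth < 2L && bern(0.3 * profile$p_subordination)) {
    that_i <- add_token(b, "that", "SCONJ", NA, "mark")
    cv_i <- gen_clause(b, profile, lex, depth + 1L, p_pron_subj = 0.6)
    b$head[cv_i] <- verb_i
    b$deprel[cv_i] <- "ccomp"
    b$head[that_i] <- cv_i
  } else if (bern(0.6)) {
    obj_i <- gen_np(b, profile, lex, depth)
    b$head[obj_i] <- verb_i
    b$deprel[obj_i] <- "obj"
  }
  p_adjunct <- min(0.9, max(0.05, (profile$sentence_length_mean - 7) / 6))
  if (depth < 2L && bern(p_adjunct)) {
    pp_head <- gen_pp(b, profile, lex, depth + 1L)
    b$head[pp_head] <- verb_i
    b$deprel[pp_head] <- "obl"
  }
  verb_i
}

gen_sentence <- function(profile, lex) {
  b <- new_sentence_builder()
  if (bern(profile$fragment_rate)) {
    # verbless fragment: bare NP or stray adpositional phrase
    lead_cc <- if (bern(0.3)) add_token(b, "and", "CCONJ", NA, "cc") else NA_integer_
    if (bern(0.3)) {
      head_i <- gen_pp(b, profile, lex, depth = 1L)
    } else {
      head_i <- gen_np(b, profile, lex, depth = 1L)
    }
    b$head[head_i] <- 0L
    b$deprel[head_i] <- "root"
    if (!is.na(lead_cc)) b$head[lead_cc] <- head_i
  } else {
    rep_slot <- bern(profile$repetition_rate)
    rep_start <- length(b$form) + 1L
    if (rep_slot) {
      # duplicated-chunk disfluency, resolved to the upcoming clause subject
      rd_i <- add_token(b, draw(c("the", "a")), "DET", NA, "det")
      rn_i <- add_token(b, draw(lex$nouns, lex$p_nouns), "NOUN", NA, "reparandum")
      b$head[rd_i] <- rn_i
    }
    if (bern(profile$p_existential)) {
      expl_i <- add_token(b, "there", "PRON", NA, "expl")
      be_i <- add_token(b, draw(c("is", "'s", "was", "are")), "VERB", 0L, "root")
      b$head[expl_i] <- be_i
      piv_i <- gen_np(b, profile, lex, depth = 0L)
      b$head[piv_i] <- be_i
      b$deprel[piv_i] <- "nsubj"
      if (bern(0.6)) {
        pp_head <- gen_pp(b, profile, lex, depth = 1L)
        b$head[pp_head] <- be_i
        b$deprel[pp_head] <- "obl"
      }
      root_i <- be_i
    } else if (bern(0.2)) {
      # copular predication: subject + copula + predicate nominal root
      if (bern(0.4)) {
        subj_i <- add_token(b, draw(c("she", "he", "it", "they")), "PRON", NA, "nsubj")
      } else {
        subj_i <- gen_np(b, profile, lex, depth = 1L)
        b$deprel[subj_i] <- "nsubj"
      }
      cop_i <- add_token(b, draw(c("is", "was")), "AUX", NA, "cop")
      pred_i <- gen_np(b, profile, lex, depth = 0L)
      b$head[pred_i] <- 0L
      b$deprel[pred_i] <- "root"
      b$head[subj_i] <- pred_i
      b$head[cop_i] <- pred_i
      root_i <- pred_i
    } else {
      root_i <- gen_clause(b, profile, lex, depth = 0L)
      b$head[root_i] <- 0L
      b$deprel[root_i] <- "root"
    }
    if (rep_slot) {
      # attach the reparandum to the first following noun (or the root)
      after <- which(seq_along(b$form) > rep_start + 1L & b$upos == "NOUN")
      b$head[rep_start + 1L] <- if (length(after) > 0L) after[1] else root_i
    }
    if (bern(profile$p_subordination)) {
      mark_i <- add_token(b, draw(c("because", "when", "while", "if")),
                          "SCONJ", NA, "mark")
      adv_i <- gen_clause(b, profile, lex, depth = 1L, p_pron_subj = 0.5)
      b$head[adv_i] <- root_i
      b$deprel[adv_i] <- "advcl"
      b$head[mark_i] <- adv_i
    }
    if (bern(profile$p_clausal_coordination)) {
      cc_i <- add_token(b, draw(c("and", "but", "or")), "CCONJ", NA, "cc")
      conj_i <- gen_clause(b, profile, lex, depth = 1L, p_pron_subj = 0.6)
      b$head[conj_i] <- root_i
      b$deprel[conj_i] <- "conj"
      b$head[cc_i] <- conj_i
    }
  }
  if (bern(0.85)) {
    root_pos <- which(b$head == 0L)
    add_token(b, ".", "PUNCT", root_pos, "punct")
  }
  data.frame(id = seq_along(b$form), form = b$form, upos = b$upos,
             head = b$head, deprel = b$deprel, stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic CoNLL-U-style corpus
#'
#' Assembles dependency trees from a template grammar (SVO cores with
#' optional auxiliaries, copular and existential *there* frames, determiner
#' / adjective / possessive pre-modifiers, adpositional post-modifiers,
#' marker-introduced adverbial and complement clauses, relative clauses,
#' phrase- and clause-level coordination, verbless fragments, duplicated-
#' chunk disfluencies). Content words are drawn Zipf-wise from an indexed
#' vocabulary over a fixed function-word inventory. Every generated
#' sentence satisfies the treebank invariants; regeneration with the same
#' (profile, seed) is identical.
#'
#' @param profile a [syntactic_profile()].
#' @param seed integer seed for the generator's random stream.
#' @param group_label group tag stored on the treebank (default from the
#'   profile's provenance; pass e.g. `"AD"` / `"HC"`).
#' @return a `generated_corpus` list: `treebank`, `profile` (the truth),
#'   `seed`.
#' @export
generate_corpus <- function(profile, seed, group_label = NA_character_) {
  stopifnot(inherits(profile, "syntactic_profile"))
  lex <- make_lexicon(profile)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  docs <- vector("list", profile$n_transcripts)
  for (d in seq_len(profile$n_transcripts)) {
    n_sent <- 1L + stats::rpois(1, max(0, profile$sentences_per_transcript_mean - 1))
    sents <- vector("list", n_sent)
    for (s in seq_len(n_sent)) {
      sent <- gen_sentence(profile, lex)
      sent$doc_id <- sprintf("t%04d", d)
      sent$sent_id <- s
      sents[[s]] <- sent
    }
    docs[[d]] <- do.call(rbind, sents)
  }
  tokens <- do.call(rbind, docs)
  tb <- treebank(tokens, group_label = group_label,
                 source_path = sprintf("synthetic(seed=%d)", as.integer(seed)))
  structure(list(treebank = tb, profile = profile, seed = as.integer(seed)),
            class = "generated_corpus")
}

#' @export
print.generated_corpus <- function(x, ...) {
  cat(sprintf("<generated_corpus: seed %d, %d transcript(s)>\n",
              x$seed, x$profile$n_transcripts))
  print(x$treebank)
  invisible(x)
}
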