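#' Syntactic profile for the treebank generator
#'
#' Parameters of the template grammar behind [generate_corpus()]. Each rate
#' steers at least one measurable property of the generated corpus:
#' subordination and complementation steer `mark_per_cl` and clause counts,
#' relative clauses steer `rcmod_nsubj_deps_NN_struct`, adpositional
#' post-modifiers steer the prepositions-per-nominal indices and stretch
#' subject–verb dependencies, and so on.
#'
#' @param p_subordination probability of an adverbial clause per sentence
#'   (complement and open-complement clauses are generated at fixed
#'   fractions of this rate).
#' @param p_relative_clause probability of a relative clause per nominal.
#' @param p_clausal_coordination probability of clause-level conjunction per
#'   sentence.
#' @param p_phrasal_coordination probability of NP-level conjunction per
#'   nominal.
#' @param p_existential probability that a non-fragment utterance is an
#'   existential *there* frame.
#' @param adjective_rate expected adjectival pre-modifiers per nominal.
#' @param pp_postmod_rate expected adpositional post-modifiers per nominal.
#' @param fragment_rate probability that an utterance is a verbless
#'   fragment (a bare noun, adpositional or coordinated phrase).
#' @param repetition_rate probability of a duplicated-chunk disfluency per
#'   sentence.
#' @param sentence_length_mean soft target for tokens per utterance; scales
#'   the rate of verb-attached adjuncts.
#' @param vocab_size number of content word types (nouns, verbs,
#'   adjectives) in the indexed vocabulary.
#' @param zipf_exponent exponent of the Zipf rank distribution over content
#'   words.
#' @param n_transcripts number of transcripts per generated corpus.
#' @param sentences_per_transcript_mean mean utterances per transcript.
#' @return a `syntactic_profile` list.
#' @export
syntactic_profile <- function(p_subordination = 0.2,
                              p_relative_clause = 0.1,
                              p_clausal_coordination = 0.2,
                              p_phrasal_coordination = 0.2,
                              p_existential = 0.2,
                              adjective_rate = 0.25,
                              pp_postmod_rate = 0.25,
                              fragment_rate = 0.1,
                              repetition_rate = 0.05,
                              sentence_length_mean = 10,
                              vocab_size = 300,
                              zipf_exponent = 1.1,
                              n_transcripts = 150,
                              sentences_per_transcript_mean = 8) {
  prof <- list(
    p_subordination = p_subordination,
    p_relative_clause = p_relative_clause,
    p_clausal_coordination = p_clausal_coordination,
    p_phrasal_coordination = p_phrasal_coordination,
    p_existential = p_existential,
    adjective_rate = adjective_rate,
    pp_postmod_rate = pp_postmod_rate,
    fragment_rate = fragment_rate,
    repetition_rate = repetition_rate,
    sentence_length_mean = sentence_length_mean,
    vocab_size = as.integer(vocab_size),
    zipf_exponent = zipf_exponent,
    n_transcripts = as.integer(n_transcripts),
    sentences_per_transcript_mean = sentences_per_transcript_mean
  )
  probs <- c("p_subordination", "p_relative_clause", "p_clausal_coordination",
             "p_phrasal_coordination", "p_existential", "fragment_rate",
             "repetition_rate")
  for (p in probs) {
    if (prof[[p]] < 0 || prof[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (prof$vocab_size < 10L) stop("vocab_size must be >= 10")
  if (prof$n_transcripts < 1L) stop("n_transcripts must be >= 1")
  structure(prof, class = "syntactic_profile")
}

#' AD-like and HC-like generator presets
#'
#' Two calibrated profiles emulating the group contrasts reported for
#' picture-description speech: the AD-like profile leans on existential
#' *there* frames, verbless fragments, repetition and phrase-internal
#' elaboration (adjectives, adpositional post-modifiers) with little
#' subordination; the HC-like profile embeds more clauses (adverbial,
#' complement, relative, clause-level coordination) in longer utterances
#' over a larger vocabulary. Under the default sizes (150 transcripts per
#' group) the AD-like corpus yields a lower text-level mean dependency
#' distance and a more function-word-centralised dependency network than
#' the HC-like corpus.
#'
#' @return a [syntactic_profile()].
#' @export
ad_profile <- function() {
  syntactic_profile(
    p_subordination = 0.10,
    p_relative_clause = 0.05,
    p_clausal_coordination = 0.16,
    p_phrasal_coordination = 0.30,
    p_existential = 0.42,
    adjective_rate = 0.32,
    pp_postmod_rate = 0.42,
    fragment_rate = 0.18,
    repetition_rate = 0.12,
    sentence_length_mean = 8.5,
    vocab_size = 400,
    zipf_exponent = 1.1,
    n_transcripts = 150,
    sentences_per_transcript_mean = 10
  )
}

#' @rdname ad_profile
#' @export
hc_profile <- function() {
  syntactic_profile(
    p_subordination = 0.38,
    p_relative_clause = 0.18,
    p_clausal_coordination = 0.30,
    p_phrasal_coordination = 0.18,
    p_existential = 0.12,
    adjective_rate = 0.22,
    pp_postmod_rate = 0.20,
    fragment_rate = 0.06,
    repetition_rate = 0.02,
    sentence_length_mean = 11,
    vocab_size = 420,
    zipf_exponent = 1.05,
    n_transcripts = 150,
    sentences_per_transcript_mean = 10
  )
}
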