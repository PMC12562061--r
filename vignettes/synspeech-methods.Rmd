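---
title: "Methods: models, conventions and design choices in synspeech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in synspeech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synspeech)
```

`synspeech` measures syntactic complexity in dependency-parsed speech
transcripts at three levels — mean dependency distance, fine-grained
phrase/clause indices, and dependency-network topology — and wraps them in
the two-group statistical workflow used in clinical speech research. This
vignette is the package's account of the science: what is computed, under
which conventions, why the open design decisions were resolved the way they
were, and what the synthetic test corpora do and do not establish.

## The substrate: dependency treebanks

Every analysis consumes a `treebank`: a token table parsed from CoNLL-U, one
row per token with a 1-based position, surface form, part-of-speech tag,
governor position (0 = root) and dependency relation. Per sentence the
package enforces the tree invariants — contiguous positions, exactly one
root, in-sentence heads, acyclicity — at construction time, so downstream
code never defends against malformed trees. Multiword-token ranges and empty
nodes carry no usable position or head and are skipped with a warning.

Both Universal Dependencies v2 and Stanford-style label dialects load. Pure
renames (`dobj`→`obj`, `rcmod`→`acl:relcl`, `vmod`→`acl`, `poss`→`nmod:poss`,
…) are handled by an editable mapping table (`relation_map()`); the one
structural divergence — Stanford attaches a preposition to the modified head
and its object to the preposition, while UD attaches the adposition to the
object nominal via `case` — is absorbed inside the index predicates, which
recognise both attachment patterns. POS tests likewise accept UPOS and
PTB-style tags.

Transcript cleaning removes a configurable set of filler interjections
(word-boundary anchored and case-insensitive, so "um" never damages
"summer") and transcription symbols. Utterance segmentation splits on
terminal punctuation and newlines; prosodic boundary cues are not available
in text, so a newline is treated as a dialogue boundary, and verbless
fragments (isolated noun phrases, stray prepositional phrases) are retained
as independent units rather than merged — in this population they are
analytically meaningful, not noise.

## Mean dependency distance

Each non-root token contributes a distance `|governor − dependent|`; the
sentence value divides the summed distances by a denominator, and the text
value is the pooled ratio over sentences (sum of distances over summed
per-sentence denominators), **not** the mean of per-sentence values.

The literature this package serves is not internally consistent about two
details, so both are reified as named conventions rather than silently
chosen:

* `published_example` — punctuation links are summed; the denominator is
  (non-punctuation words − 1) per sentence. This reproduces the canonical
  worked derivation, where a 10-word sentence sums all ten link distances
  (including the 6 of the final period) and divides by 9, giving 2.33.
* `stated_rule` — punctuation links are excluded, denominator as above
  (pooling to words − sentences at text level). This follows the stated
  rule that punctuation and root tags do not enter the calculation.

A third denominator mode, `links_count`, divides by the number of links
actually used; it matches per-sentence values quoted in the clinical
literature for sentences where the two denominators differ (e.g. 1.67 for a
7-token sentence with 6 links, punctuation included). The two presets imply
slightly different arithmetic and neither is declared "intended";
reproduction work should use `published_example`, new analyses
`stated_rule`.

Degenerate sentences — one token, or no usable link under the active
convention — have no defined MDD. They are excluded from both numerator and
denominator of the text value and counted in `n_sentences_excluded`;
silently propagating `NaN` would poison the text statistic, and silently
scoring 0 would bias it downward.

## The index catalogue

The 20 indices are ratios of (relation, POS)-filtered counts over unit
counts. The original tooling that popularised these names does not publish
formulas, so each index is defined operationally here and tested against
planted-count fixtures:

* **Units.** "Nominal" = noun/proper-noun tokens, plus pronouns except where
  an index is marked `_NN` / "no pronouns". "Prepositional object" = a
  Stanford `pobj` token or a nominal bearing a `case` child. "Direct
  object" = `obj`. "Nominal complement" (the ambiguous `av_ncomp` family) is
  interpreted as a nominal serving as a copular predicate (a nominal with a
  `cop` child, or Stanford `attr`); this is a documented interpretation, not
  the only defensible one.
* **Clauses.** A clause anchor is the sentence root plus every token bearing
  a clausal relation (`ccomp`, `xcomp`, `advcl`, `acl:relcl`) and every
  verb-headed conjunct. Verbless fragments count as one clause: fragments
  are first-class discourse units here, and per-clause denominators must be
  defined for them.
* **Conjunctions.** `conj_per_cl` counts all coordinating-conjunction
  tokens per clause; `cc_per_cl` counts the clausal subset (a `cc` attached
  to a verbal head or clause anchor). The two therefore nest.
* **Dispersion indices.** `*stdev` indices are population (divide-by-N)
  standard deviations of per-unit dependent counts — a descriptive statistic
  over the observed units, not an inferential estimate.
* **Missingness.** A zero denominator yields `NA` with a support count of 0,
  never a silent 0; the regression layer drops incomplete transcripts
  listwise and reports how many.

The type–token ratio is distinct lowercased non-punctuation forms over total
such tokens. Disfluent repetitions count as tokens deliberately: in heavily
fragmented speech, short utterances inflate TTR, and that inflation is
itself the phenomenon of interest.

## Dependency networks

`build_network()` maps a treebank to a weighted directed word-type graph:
vertices are lowercased surface forms in order of first appearance (clitics
such as `'s` remain their own type), arcs run governor → dependent keyed by
relation, weights are occurrence counts, root and punctuation links are
excluded, loops are allowed.

Conventions fixed as the package contract:

* **Summary statistics** follow the Pajek conventions recoverable from
  published tables: average degree `2m/n` and loops-allowed density
  `2m/n²`, with `m` the number of distinct arcs ("lines").
* **Node metrics** are computed on the undirected simple skeleton
  (directions and weights dropped, parallel arcs merged, loops ignored):
  normalised shortest-path betweenness (divided by `(n−1)(n−2)/2`);
  per-component-normalised closeness `(r/(n−1)) · (r/Σd)` with `r` the
  reachable count, so disconnected networks are well-defined; local
  clustering `2·e(N(v))/(k(k−1))`, 0 for degree < 2. The choice of the
  undirected skeleton is consistent with published tables in which
  low-degree function words attain clustering 1. igraph supplies
  betweenness, clustering and the distance matrix; the closeness form is
  assembled from distances because this normalisation is not an igraph
  option. All three are verified against an exhaustive brute-force
  shortest-path oracle on small graphs.
* **Weighted degree** of a vertex sums the weights of all incident arcs,
  in plus out, loops counting twice.
* **Rankings** break ties by weight descending, then label ascending —
  determinism over elegance.
* **Cross difference** (the under-documented network-comparison operation)
  is implemented as a key-set difference: arcs of A whose (governor,
  dependent, relation) key is absent from B, retaining A's weights,
  optionally truncated to the `top_k` heaviest.

Published per-vertex metric values for 30 function words are shipped as data
(`function_word_metrics()`) and used as inputs to the group-comparison
workflow; they are not recomputation targets, because the underlying corpus
is access-restricted. Faithfulness of the metric implementations is instead
established by oracle equivalence.

## Group statistics

`compare_groups()` mirrors the SPSS independent-samples workflow: Shapiro–Wilk per
group; Levene's test on mean-centred absolute deviations (the SPSS form —
R's default is median-centred); pooled-variance t when Levene's p > 0.05,
Welch's form otherwise; Cohen's d from the pooled standard deviation,
reported as a magnitude. Treating network vertices as independent sampling
units in such t-tests is statistically questionable; the package reproduces
the workflow as practised and leaves the caveat here.

Screening retains indices whose Pearson correlation with MDD has p < 0.05
and |r| ≥ 0.100, then iteratively removes the highest-VIF index while any
VIF ≥ 5 (perfect collinearity is handled by removal, never failure).
Stepwise regression uses forward selection with backward elimination at the
SPSS defaults (enter p < 0.05, remove p > 0.10) — the canonical defaults of
the named tool, since the literature rarely states thresholds. Standardised
betas come from the coefficient times `sd(x)/sd(y)`; per-predictor VIFs are
reported for the final model.

## The synthetic treebank generator

Clinical speech corpora are access-restricted, so the package carries its
own study conditions: a template grammar that emits well-formed dependency
trees under a parameterised `syntactic_profile`. Sentences are assembled
from an SVO core with optional auxiliary, copular and existential *there*
frames, determiner/adjective/possessive pre-modifiers, adpositional
post-modifiers, marker-introduced adverbial/complement/open-complement
clauses, relative clauses, phrase- and clause-level coordination, verbless
fragments, and duplicated-chunk disfluencies. Content words are drawn
Zipf-wise from an indexed vocabulary (`n###`, `v###`, `j##`) over a fixed
closed-class inventory (`function_words()`); structure choices are
independent Bernoulli/Poisson draws — the simplest mechanism under which
every catalogue index is steerable by at least one parameter. Complement
and open-complement rates are tied to the subordination rate (0.3× and
0.5×) so a single knob controls clausal embedding depth. A single seeded
stream drives everything; identical (profile, seed) regenerate identical
corpora, and the caller's RNG state is restored afterwards.

The presets encode the two group profiles: `ad_profile()` leans on
existential frames (0.42), fragments (0.18), repetition (0.12) and
phrase-internal elaboration (adjective rate 0.32, adpositional post-modifier
rate 0.42) with little subordination (0.10); `hc_profile()` inverts this
(subordination 0.38, relative clauses 0.18, clausal coordination 0.30,
longer utterances). Default magnitudes were calibrated once, before the
acceptance tests were written, so that 150-transcript groups land near the
2.5–2.7 text-MDD band reported for real picture-description corpora
(measured ≈2.49 vs ≈2.64 across probe seeds); they are calibration choices,
not empirical claims. One calibration lesson is recorded as a design
constraint: the two profiles' vocabulary sizes are kept comparable (400 vs
420, mirroring the near-equal vertex counts of published networks), because
vocabulary-size asymmetry lets type diversity — not structure — dominate
function-word centrality and can invert the group contrast.

What the generator does **not** emulate: lexical semantics, topic coherence,
prosody and timing, severity gradients, or annotation noise from a real
parser. Passing direction-recovery tests therefore shows that the pipeline
detects the intended structural contrasts at realistic sizes — not that the
profiles are a faithful generative model of clinical speech.

## Numerical choices and problem sizes

* Reported reproduction values are rounded to the precision the source
  prints (2 d.p. for MDD, 4 d.p. for metric means, 8 d.p. for network
  summaries); full precision is kept internally.
* Oracle-equivalence tests run exhaustively over all labelled connected
  graphs on 3–5 vertices and seeded random connected graphs on 6–8
  vertices; MDD is checked against brute-force summation on 1,000 random
  sentences; stepwise recovery uses 50 seeded replicates at n = 200 with 10
  noise predictors; direction recovery uses 20 seeded replicates of 150 +
  150 transcripts. These sizes were chosen as the smallest that exercise
  the asymptotics convincingly.
* Ties, degenerate inputs and missingness are resolved as described above;
  no analysis silently imputes.

## Known limitations

* The index definitions are operational reconstructions; other tools'
  implementations of the same names may differ in detail (pronoun handling,
  clause inventories), so absolute index values are comparable within this
  package, not across tools.
* The per-vertex network t-tests inherit the independence caveat above.
* The parser itself is out of scope: the package consumes CoNLL-U produced
  elsewhere, and a parser adapter is the documented extension point.
* Regression coefficients reported for real clinical corpora are not
  reproducible here by design; the package reproduces what is
  self-contained (worked examples, printed-table statistics, convention
  arithmetic) and establishes the rest by oracle equivalence and synthetic
  direction recovery.
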