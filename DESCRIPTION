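Package: synspeech
Title: Syntactic Complexity Analysis of Dependency-Parsed Speech Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies syntactic complexity in dependency-parsed speech
    transcripts for two-group clinical comparisons. Provides transcript
    cleaning and utterance segmentation, CoNLL-U and Pajek network file
    input/output, sentence- and text-level mean dependency distance under
    explicit punctuation and denominator conventions, a catalogue of
    fine-grained phrase- and clause-complexity indices with type-token
    ratio, weighted directed word-type dependency networks with
    betweenness, closeness and clustering metrics, a correlation and
    variance-inflation screening plus stepwise regression workflow, and a
    seeded synthetic treebank generator emulating clinical and control
    speech profiles for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
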