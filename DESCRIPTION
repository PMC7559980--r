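Package: violframe
Title: Violence Detection and Frame-Based Explanation for Emergency Room Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking violence-related injuries in noisy emergency
    room narrative text. Cleans abbreviation- and typo-laden reports with a
    curated rewrite dictionary, categorizes each record as violence-related
    (V) or not (NV) with a convolutional-recurrent neural classifier
    initialized from skip-gram word vectors trained on the corpus, and
    explains every V categorization by filling a six-slot violence frame
    (agent, mode/instrument, time, location, body part, lesion type) through
    a hybrid of part-of-speech filtering, supersense filtering and
    embedding-prototype ranking. Includes a synthetic corpus generator with
    gold frame annotations and ranked-retrieval evaluation (MAP, S@k, R@k),
    so the whole pipeline is testable without access to restricted clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
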