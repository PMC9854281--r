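Package: srtecho
Title: Instance-Based Memory Simulation of Serial Response Time Tasks
    with Two Uncorrelated Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a serial response time task (SRTT) in which a
    stimulus stream and a response stream each follow an independent
    probabilistic sequence, using a MINERVA-2-style global-matching
    instance memory with a single, non-modular store.  Each trial is
    encoded as one memory trace holding current and previous stimulus
    and response features; retrieval returns an echo whose intensity
    and response-segment content drive the drift rate of a two-boundary
    Wiener diffusion decision stage.  Includes a probabilistic sequence
    generator with exact regularity labelling, an exact first-passage
    sampler for the Wiener diffusion, block-by-trial-type aggregation of
    response times and error rates with within-subject confidence
    intervals, and plotting of the resulting learning curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
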