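Package: hofstee
Title: Hofstee Compromise Cut-Off Scores for Pass/Fail Standard Setting
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes pass/fail cut-off scores for examinations with the
    Hofstee compromise method. Aggregates several judges' bounds on the
    acceptable cut-off score (c_min, c_max) and on the acceptable failure
    rate (f_min, f_max), builds the cumulative percentage curve of a score
    distribution, and locates the cut-off algebraically as the intersection
    of the judges' compromise line with the cumulative polyline, instead of
    reading it off a hand-drawn chart. Also reports the largest score gaps
    near the cut-off, renders full and detailed Hofstee charts, and ships a
    small command-line interface with JSON output.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
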