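Package: afasScreen
Title: Antisense Transcript Discovery Screens with Artificial Antisense
    Tiling Probes
Version: 0.1.0
Authors@R:
    person("afasScreen", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering natural antisense transcripts with
    artificial antisense (AFAS) tiling microarray probes and for screening
    sense-antisense expression-balance reversals between paired cancer and
    normal tissue. Includes antisense probe tiling along spliced gene
    models with exon-junction ("truncated") flagging, global mean scaling
    normalization, detection-fraction summaries contrasting oligo-dT and
    random priming, fold-change and balance-reversal screens with a
    random-shuffling permutation null, hierarchical clustering of
    sense/antisense log expression ratios with saturating heat-map export,
    and a synthetic-data generator that emulates the paired-patient,
    two-tissue, two-priming-method design with planted reversal pairs for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    grDevices,
    graphics,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
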