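Package: poolcnv
Title: Copy Number Variant Discovery from Pooled SNP-Array Intensity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering copy number variant (CNV) regions from
    DNA-pooling SNP-array experiments, where equal amounts of DNA from many
    subjects are hybridised as one sample and the Log R ratio reflects the
    mean copy number of the pool. Provides a synthetic pooled-signal
    simulator with embedded truth events, marker-level quality control,
    a three-state hidden Markov model segmenter for pool-level Log R ratio,
    region filtering, gap-ratio merging and cross-pool union, classification
    of informative regions against a population reference CNV map,
    case-control CNV burden and pooled-signal association tests with exact
    rank-sum p-values, gene annotation of candidate regions, and a
    config-driven end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
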