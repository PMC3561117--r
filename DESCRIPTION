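Package: primertile
Title: Minimal-Cost Reusable Degenerate PCR Primer Sets by Metropolis-Hastings Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs minimal-cost sets of reusable, optionally degenerate (W/S)
    PCR primers that tile a collection of target gene sequences with amplicons.
    Candidate primers are enumerated per integer melting temperature under GC,
    hairpin, self-dimer and background-redundancy constraints, generalized into
    W/S-degenerate primers around collated SNPs, and a per-gene amplicon tiling
    is optimized by Metropolis-Hastings Markov chain Monte Carlo sampling with
    three greedy proposal generators. The objective is the total nucleotide
    count over the distinct primers in the design; primer reuse across loci is
    paid for once. Includes a synthetic fixture generator with planted repeated
    priming sites and injected SNPs, a brute-force optimum oracle for small
    instances, and plain-text reporting of per-temperature designs.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
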