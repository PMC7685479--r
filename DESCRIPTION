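Package: driverscan
Title: Pan-Cancer Driver Gene Discovery from Mutation-Expression Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate cancer driver genes by integrating per-sample
    somatic mutation status (MAF) with gene expression matrices across multiple
    cohorts. Each mutated gene is tested for its transcriptome-wide effect with
    a from-scratch two-class SAM permutation procedure (moderated d-statistic
    with fudge factor, expected order statistics from label permutations, delta
    cutpoints, pi0 and FDR estimation); genes that perturb expression in every
    cohort are selected as candidate drivers and characterized with the 20/20
    rule, gene/protein length comparisons and hypergeometric gene-set
    over-representation. Includes a synthetic multi-cohort generator with
    planted drivers so every stage is verifiable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
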