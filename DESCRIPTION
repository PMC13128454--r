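Package: p53trap
Title: Intracellular Trapping Kinetics and Target Nomination for
    Bifunctional Cytotoxins Exploiting Mutant p53 Overabundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing how an overabundant, slowly degraded
    intracellular protein (such as missense-mutant p53) traps freely
    diffusing bifunctional small molecules inside cells. Provides a
    stiff ODE model of compound accumulation with a closed-form
    steady-state solution and half-life by dose sweeps; differential
    screening of CRISPR dependency and z-scored proteomic abundance
    matrices between TP53-mutant and wild-type samples; ranking of
    candidate cytotoxic payload targets by joint essentiality and low
    protein abundance; read-pair based cis/trans phasing of two coding
    variants on one transcript; four-parameter logistic dose-response
    quantification with competition and NanoBiT Emax conventions and
    2^-ddCt relative expression; and seeded synthetic-data generators
    emulating the statistical structure of each input so the full
    pipeline runs and is tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
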