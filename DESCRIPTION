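Package: opsinshift
Title: Ancestral Reconstruction and Spectral Tuning of Green-Sensitive Visual Pigments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood ancestral amino-acid sequence reconstruction
    under the empirical JTT, WAG and Dayhoff substitution models on a fixed
    rooted topology, together with the downstream analyses used to study the
    spectral tuning of green-sensitive (RH2) cone opsins: per-branch shifts in
    the wavelength of maximal absorption (lambda-max) with significance and
    mutation-explanation classification, tracing of substitutions at the
    tuning-critical sites 122, 207 and 292 (bovine-RH1 numbering),
    lineage-specific amino-acid substitution rates with bootstrap standard
    errors and Z comparisons, and seeded simulators that evolve sequences along
    a tree with recorded ancestral truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
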