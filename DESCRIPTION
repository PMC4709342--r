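Package: cysanchor
Title: Barcode-Anchored Alignment of Cysteine-Rich Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Aligns highly divergent cysteine-rich protein families by
    replacing structurally homologous cysteine columns with distinctive
    10-residue peptide barcodes, re-aligning the free inter-cysteine loops
    with any standard aligner, and restoring the original columns so that
    homologous cysteines are guaranteed to share a column. Includes the
    barcode-set design procedure (composition-entropy filter, minimum
    edit-distance constraint, chance-match probability model, collision
    checking), a deterministic built-in progressive aligner, homologous
    cysteine column suggestion from structure-based alignments, per-loop
    biophysical profiling (length, Kyte-Doolittle hydropathy, net charge),
    and a synthetic family generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
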