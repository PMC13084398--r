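Package: pepnexus
Title: De Novo Protein Sequence Assembly from Peptide-Spectrum Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs contiguous protein sequences from tables of de novo
    peptide-spectrum matches (PSMs), as produced by multiprotease shotgun
    proteomics of antibodies, nanobodies and other proteins absent from
    reference databases. Provides confidence/FDR-based PSM filtering, two
    complementary assemblers (greedy longest-overlap-first merging and a
    weighted de Bruijn graph with unitig extraction and overlap-layout-
    consensus refinement), scaffold scoring and ranking, identity-based
    clustering with PSSM-derived consensus sequences, reference-based
    evaluation metrics (coverage, N50, precision, mean identity, a weighted
    composite score and an assembly quality score), an exhaustive
    hyperparameter grid search, and an in-silico multiprotease digestion
    simulator with a configurable noise model for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    parallel,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
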