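Package: allosite
Title: Evolution-Guided Engineering of Enzyme Allosteric Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for deregulating enzyme allosteric inhibition
    by exploiting the contrasting evolutionary signatures of catalytic and
    allosteric ligand-binding sites. Provides per-residue conservation
    scoring from multiple sequence alignments (Jensen-Shannon divergence
    against a BLOSUM62 background, percentile-normalized), structure-based
    residue classification via a 6 Angstrom ligand-proximity rule and
    relative solvent accessibility (Shrake-Rupley), amino-acid composition
    enrichment statistics, a three-rule mutation-candidate designer for
    allosteric sites, and Hill / noncompetitive-inhibition kinetic fitting
    with inhibition-constant fold-change estimation. Includes synthetic-data
    generators (alignments, toy structures, velocity tables) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
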