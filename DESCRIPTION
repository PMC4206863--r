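Package: scrmap
Title: Structural Mapping of Disease-Associated Mutations in Complement Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates registries of disease-associated genetic alterations in the
    complement alternative-pathway proteins factor H (CFH), factor I (CFI),
    membrane cofactor protein (MCP/CD46) and C3, and maps them onto protein
    structure. Provides HGVS-style protein-change parsing, domain assignment
    against curated domain architectures, consequence and per-domain tallies with
    non-intronic mutational frequencies per 100 residues, projection of missense
    mutations from short complement regulator (SCR/sushi) domains onto a consensus
    SCR numbering with hypervariable-loop and cysteine-anchor region statistics,
    anchor-based rigid-body superposition of domain coordinate sets,
    Shrake-Rupley solvent-accessible surface area with decile binning and
    buried/exposed classification, per-domain mutational hotspot ranking, and a
    heuristic Type I/II phenotype prediction. Seeded synthetic generators emit
    mutation tables, decoy coordinate sets and SCR-like alignments with exact
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
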