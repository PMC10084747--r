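Package: gpxlike
Title: Classification of Gpx-Like Proteins as Thioredoxin-Dependent Peroxiredoxins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-analysis toolkit for deciding whether glutathione
    peroxidase (Gpx)-like protein sequences are thioredoxin-dependent,
    Gpx-like peroxiredoxins or canonical glutathione-dependent peroxidases.
    Implements a three-criterion classifier based on the peroxidatic
    cysteine, the resolving cysteine in the "Cys block", and the absence of
    dimer/oligomerization interface loops, together with the supporting
    machinery: greedy identity clustering of redundant sequence sets,
    global pairwise alignment with affine gaps and a progressive multiple
    aligner, reference-anchored alignment-column mapping,
    consensus-proportion conservation profiling with conserved-domain
    segmentation, neighbor-joining phylogenies with column-resampling
    bootstrap and star-likeness/phylum-mixing statistics, and structural
    readouts (Kabsch superposition RMSD, residue-pair distances,
    Shrake-Rupley solvent accessibility). A synthetic-family generator with
    planted diagnostic features provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    bio3d,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
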