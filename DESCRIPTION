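Package: aatcensus
Title: Census and Comparative Analysis of Insect Amino Acid Transporter
    Repertoires
Version: 0.1.0
Authors@R: person("R.", "Delahaye", email = "rdelahaye@example.org",
    role = c("aut", "cre"))
Description: Tools for counting amino acid transporter (AAT) gene loci in
    the APC and AAAP families from de novo insect transcriptome assemblies
    and for comparing counts across life histories.  Candidate transcripts
    are selected from profile-HMM domain hits and best-BLAST-hit
    annotations, then collapsed into putative loci using assembly component
    identifiers, pairwise synonymous substitution rates (Nei-Gojobori
    counting with a Jukes-Cantor correction), a short-overlap rule, or
    shared genome mapping locations.  Per-taxon locus counts are summarised
    by life-history group and tested with phylogenetic generalized least
    squares under a Brownian-motion tree covariance.  A synthetic-data
    module generates transcriptomes with isoform, fragment, allele,
    paralog, contaminant and background structure, matching mock hit
    tables, pure-birth trees and truth tables, so the whole pipeline can be
    validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
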