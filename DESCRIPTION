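Package: tepair
Title: Homotypic Transposable-Element Pairing at Focal Chromatin Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls focal chromatin-contact hotspots on sparse 600 bp binned
    Micro-C/Hi-C contact maps, matches each hotspot to a contact-depleted
    coldfield by diagonal TMC minimisation, and measures homotypic versus
    heterotypic transposable-element (TE) pairing at the two contact anchors
    with sliding-window profiles, hot/cold ratios, specificity indices,
    pairwise specificity matrices, strand-orientation ratios and
    evolutionary-age correlations. Includes cross-dataset reproducibility
    utilities (Pearson correlation, average-linkage clustering), an
    off-lattice misbinning negative control, and a synthetic-data generator
    that plants known hotspots and known TE coupling for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
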