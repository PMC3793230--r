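Package: ecaudit
Title: Enzyme Nomenclature Ambiguity Scanning, Annotation Auditing and
    Coupled-Assay Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control of enzyme function annotation. Parses
    and writes ENZYME-style flat files (the enzyme.dat dialect), scans a
    database for enzyme names assigned to more than one EC number and
    classifies each collision by the depth at which the EC numbers diverge,
    audits tabular protein annotation records for ambiguous-name usage,
    name/EC conflicts and interpolation-style misassignments, and simulates
    the urease/glutamate-dehydrogenase-coupled continuous assay that
    discriminates ammonia-releasing (EC 3.5.3.19) from urea-releasing
    (EC 4.3.2.3) activity on ureidoglycolate. Includes synthetic-data
    generators with exact planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
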