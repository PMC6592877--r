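Package: eegbids
Title: Organize, Read, Write and Validate EEG Datasets in the Brain
    Imaging Data Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for working with electroencephalography (EEG)
    datasets organized under the Brain Imaging Data Structure (BIDS).
    Provides the entity-based filename grammar and dataset indexing,
    readers and writers for the two official EEG data formats (European
    Data Format and the BrainVision Core Data Format triplet), tab- and
    JSON-sidecar metadata handling with the Inheritance Principle, a
    rule-based dataset validator that reports machine-readable issues,
    a converter that turns raw recordings into validator-clean BIDS
    subtrees, and a deterministic synthetic-data generator so the whole
    stack can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
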