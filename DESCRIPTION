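Package: fiaprep
Title: Pre-Processing of Flow-Injection High-Resolution Mass Spectrometry
    Metabolomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scriptable pre-processing for flow-injection analysis
    high-resolution mass spectrometry (FIA-HRMS) untargeted metabolomics.
    Reads per-acquisition centroided peak lists (m/z, intensity CSV), removes
    the carrier-solvent contribution by paired blank subtraction at a ppm
    tolerance, aligns peaks across samples into a feature-by-sample intensity
    matrix by progressive-mean greedy matching, optionally regroups rows into
    [M+H]+/[M+Na]+/[M+K]+ adduct groups in positive mode, and annotates
    features against an adduct-mass table built from HMDB-style metabolite
    XML. Includes a synthetic acquisition-batch generator with full ground
    truth so every stage is testable offline, and a command-line wrapper.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    writexl,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
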