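Package: inchiaudit
Title: Structure-Identifier Consistency Auditing for Small-Molecule Databases
Version: 0.1.0
Authors@R: person("inchiaudit", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Audits the internal consistency of small-molecule database
    entries by comparing identifiers derived from deposited 3D structures
    against the identifiers and formulas archived alongside them. Reads
    multi-record SDF V2000 files (optionally gzip-compressed), generates
    standard InChI strings and unique, reproducible atom labels from the
    InChI canonical numbering, decomposes InChI strings into semantic
    layers (formula, /c, /h, /q, /p, /b, /t, /m, /s, /i), reconciles
    Hill-notation formulas against the core-parent/charged-species
    arithmetic of the /q and /p layers, and classifies every mismatch
    into atom-connectivity, charge, and stereochemistry discrepancy
    categories. Includes a batch workflow for sharded archives and a
    seeded synthetic-corpus generator with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the RDKit package, used as the
    InChI generation delegate (an implementation of the IUPAC standard
    InChI algorithm); located via the PATH or the inchiaudit.python option.
Config/testthat/edition: 3
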