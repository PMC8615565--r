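Package: gclogic
Title: Patient-Specific Logical Modeling of Germinal-Center B-Cell Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-valued (Boolean/ternary) logical modeling of germinal-center
    B-cell signaling and marker-gene regulation, with exhaustive fixpoint
    enumeration, genotype-driven per-patient perturbation of the network from
    Oncoprint-style lesion tables, stage-resolved attractor profiling,
    oncogenicity and NF-kB-dependency classification, and in-silico simulation
    of single and combined pathway inhibitors for diffuse large B-cell
    lymphoma (DLBCL). Includes a synthetic-cohort generator emulating the
    statistical shape of published DLBCL genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
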