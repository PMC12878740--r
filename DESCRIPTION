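Package: mgpbpk
Title: Physiologically Based Pharmacokinetic Model of Magnesium Implant
    Ion Release
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the systemic distribution of Mg(II) ions released by
    biodegradable magnesium implants with a four-compartment (serum, bone,
    tissue, implant-zone) linear physiologically based pharmacokinetic
    model. Provides an exact matrix-exponential solution and a stiff-capable
    numeric integrator, closed-form approximations for the local and
    systemic buildup time scales, the critical release rate and onset time
    for hypermagnesemia, renal-function and dietary-intake intervention
    scenarios, and a command-line interface for running named scenarios and
    derived-quantity reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
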