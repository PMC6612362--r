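Package: omeconvert
Title: Equianalgesic Opioid Dose Conversion with Audit Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinician decision-support core for equianalgesic opioid dose
    conversion in palliative care. Converts doses between opioids and routes
    through an oral morphine equivalent (OME) hub driven by a data-file
    formulary, selects transdermal patch strengths from dose-band tables with
    a safety round-down tie rule, computes breakthrough (rescue) doses,
    attaches renal-impairment cautions, and refuses to fabricate a dose when
    the guideline tables carry no equivalence. An append-only audit layer
    records every conversion and reproduces prescribing-audit summaries:
    per-opioid index/target usage tallies, exclusion filtering, gold-standard
    match rates, and a Cochran-Armitage trend test with a permutation-null
    cross-check. Ships a deterministic fixture formulary, seeded request
    generators and two independent test oracles, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
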