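Package: pbpkddi
Title: Whole-Body Physiologically Based Pharmacokinetic Simulation of
    Apatinib Drug-Drug and Drug-Disease Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained whole-body physiologically based
    pharmacokinetic (PBPK) simulator for the tyrosine kinase inhibitor
    apatinib. Couples a nine-compartment gastrointestinal
    dissolution-absorption-transit model to a perfusion-limited
    thirteen-organ circulation with saturable CYP3A4/3A5/2D6 metabolism,
    glomerular-filtration renal clearance, and tissue partitioning by the
    Poulin-Theil tissue-composition method. Simulates drug-drug
    interactions through competitive inhibition, mechanism-based
    inactivation and induction acting on dynamic enzyme turnover, and
    drug-disease interactions through virtual hepatic-impairment
    (Child-Pugh A/B/C) and renal-impairment populations with seeded
    between-subject variability. Reports noncompartmental exposure
    metrics (Cmax, Tmax, AUC), fold errors against observed data, and
    exposure ratios for interaction scenarios.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
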