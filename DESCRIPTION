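Package: mplgluc
Title: Receptor-Mediated Meta-Model of Methylprednisolone Effects on Glucose Regulation in Rats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and maximum-likelihood estimation for a mechanistic
    pharmacokinetic/pharmacodynamic systems model of methylprednisolone effects
    on glucose regulation in rats. Implements two-compartment pharmacokinetics
    for intravenous, intramuscular and infusion dosing; fifth-generation
    glucocorticoid receptor dynamics in liver, skeletal muscle and white
    adipose tissue; adipose leptin transcription and leptin-driven suppression
    of food intake; hepatic cAMP/PEPCK gluconeogenic signaling; muscle
    IL6R1/IRS-1 insulin-signaling transit cascades; and the coupled plasma
    glucose-insulin-free-fatty-acid turnover system. Includes a synthetic
    destructive-sampling data generator with a power-of-the-mean variance
    model, naive-pooled maximum-likelihood fitting, and a staged (piecewise)
    estimation workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
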