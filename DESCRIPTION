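Package: jiawithdraw
Title: Decision Support for Withdrawing Biologic Therapy in Juvenile
    Idiopathic Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multicriteria decision-support model for the
    withdrawal of biologic therapy in children with nonsystemic juvenile
    idiopathic arthritis (JIA) in clinically inactive disease (CID). A
    stated-preference logit utility combines nine patient, disease, and
    treatment criteria; a log-time baseline converts time in CID into a
    baseline withdrawal probability; their product is the predicted
    likelihood that pediatric rheumatologists would withdraw therapy.
    The package derives the relative importance of the criteria from the
    model coefficients, lets users adjust importance on a 0-100 rating
    scale and recompute predictions, reads and scores patient profiles
    from JSON and CSV, and validates the whole model by simulating
    vignette-study choice data and recovering the coefficients by
    maximum likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
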