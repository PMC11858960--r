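Package: venbupddi
Title: Whole-Body PBPK Simulation of the Venlafaxine-Bupropion CYP2D6
    Drug-Drug Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and integrates a whole-body physiologically based
    pharmacokinetic (PBPK) model of venlafaxine, bupropion and their active
    metabolites, with competitive CYP2D6 inhibition by bupropion,
    hydroxybupropion, threohydrobupropion and erythrohydrobupropion.
    Provides extended-release oral absorption via a Weibull dissolution
    model, virtual age-stratified populations, enzyme-abundance calibration
    against exposure statistics, non-compartmental and active-moiety
    exposure metrics (prediction error, metabolic ratio, fold-error and
    percentile coverage), EMA/FDA inhibition-strength classification,
    encoded drug-drug interaction study protocols, and a synthetic
    therapeutic-drug-monitoring data generator with exclusion filters for
    end-to-end evaluation of the interaction model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
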