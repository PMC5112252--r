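Package: revlearn
Title: Serial Reversal Learning in Recurrent Rate Networks with Gated
    Expert Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates reinforcement learning of auditory categorization
    under serial contingency reversals in a recurrent shunting rate
    network.  A shared sensory basis network feeds several expert modules
    (association layer plus two motor units each); learning is driven by
    a reward-prediction-error-gated three-factor plasticity rule whose
    credit-assignment signal is computed from the adjoint of the network
    dynamics linearized at the activity fixed point.  A dynamic control
    network (tonic bias unit, winner-take-all field, suppression units)
    releases exactly one expert per trial from inhibition and relearns
    its bias weights from the reward prediction error, which lets a
    previously acquired stimulus-response strategy be re-instated quickly
    after a second contingency reversal.  Includes the serial reversal
    task (population-coded binary stimulus dimensions, scheduled
    reversals), behavioural analyses (learner classification, interpolated
    time to criterion over trial blocks, paired group statistics,
    sensitivity index d'), and representation-similarity analysis of the
    basis network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
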