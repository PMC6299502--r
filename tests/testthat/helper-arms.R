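# Random but internally consistent arms for property-style tests.
random_arm <- function(label = "A", n = sample(50:400, 1)) {
  sr <- as.vector(stats::rmultinom(1, n, c(0.25, 0.55, 0.2)))
  ur <- as.vector(stats::rmultinom(1, sr[1], c(0.55, 0.15, 0.3)))
  arm_counts(label, n, sr[1], sr[2], sr[3], ur[1], ur[2], ur[3])
}

# A two-arm trial with nothing missing at either stage.
no_missing_trial <- function() {
  arms <- rbind(arm_counts("A", 100, 30, 70, 0, 20, 10, 0),
                arm_counts("B", 120, 50, 70, 0, 35, 15, 0))
  trial_counts(arms, list(ab = list(exposed = "B", control = "A")))
}
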