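# shared fixtures: the default ABC/3TC scaling setup
abc_model <- function() scaling_model(adult_value = 600,
                                      reference_weight_kg = 70,
                                      exponent = 0.75)

tiny_cohort <- function(weights, ages = NULL) {
  n <- length(weights)
  if (is.null(ages)) ages <- rep(8L, n)
  data.frame(id = sprintf("T%02d", seq_len(n)),
             age_years = as.integer(ages),
             weight_kg = weights,
             sex = rep("F", n),
             stringsAsFactors = FALSE)
}
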