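# shared fixtures, built in code

study_ref <- function() {
  study_data(arm_summary(30, 10, 10), arm_summary(40, 10, 10),
             sham = arm_summary(70, 4, 5))
}

# a random meta-analysis dataset with independent effects and SEs
random_meta <- function(k, measure = "RMD", mu = 1) {
  se <- runif(k, 0.3, 1.5)
  meta_dataset(rnorm(k, mu, se), se,
               sample(5:16, k, TRUE), sample(7:14, k, TRUE), measure)
}

# exactly left-censored dataset: symmetric grid with the lowest m removed
censored_meta <- function(k = 30, m = 3, mu = 1) {
  se <- rep(seq(0.3, 1.2, length.out = k), length.out = k)
  y <- mu + qnorm(seq(0.05, 0.95, length.out = k)) * se
  keep <- order(y)[-(seq_len(m))]
  meta_dataset(y[keep], se[keep], rep(10, k - m), rep(10, k - m), "RMD")
}
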