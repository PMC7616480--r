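# Shared fixtures and independent oracles used across the suite.

# forward-simulated spectrum in the column layout fit_cole() expects
make_spectrum <- function(r0 = 786, rinf = 597, fc_khz = 40, alpha = 0.1,
                          n = 64, fmin = 3, fmax = 1000) {
  f <- exp(seq(log(fmin), log(fmax), length.out = n))
  sp <- cole_impedance(f, r0, rinf, fc_khz, alpha)
  names(sp)[1] <- "frequency_khz"
  sp
}

# rescales a vector to an exact mean and (n-1)-denominator SD
with_exact_moments <- function(x, mean, sd) {
  z <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * z
}

# brute-force Passing-Bablok slope: enumerate every pairwise slope, drop
# undefined and -1 slopes, take the K-shifted median
pb_slope_bruteforce <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] == x[i]) next
      s <- (y[j] - y[i]) / (x[j] - x[i])
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  nn <- length(slopes)
  k <- sum(slopes < -1)
  if (nn %% 2 == 1) slopes[(nn + 1) / 2 + k] else
    mean(slopes[nn / 2 + k + c(0, 1)])
}

# joint cohort table most tests operate on
cohort_table <- function(seed, config = synth_config(), spectra = FALSE) {
  co <- generate_cohort(config, seed = seed, spectra = spectra)
  add_model_terms(dplyr::left_join(co$records, co$references, by = "child_id"))
}
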