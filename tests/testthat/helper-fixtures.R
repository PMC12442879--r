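# Shared fixtures and small independent oracles used across test files.

# Noise-free optimum-curve observations on a fixed CO2 ladder.
curve_points <- function(x, y, s, n = 12, cmax = 100) {
  co2 <- seq(0.5, cmax, length.out = n)
  data.frame(co2 = co2, rate = mm_rate(co2, x, y, s))
}

# Frozen outputs of the independent reference speciation solver
# (standalone Python bisection implementation of the same published
# constant formulations, computed once and stored as plain text).
oracle_sweep <- function() {
  read.csv(test_path("oracle-carb-sweep.csv"))
}

oracle_spot <- function() {
  jsonlite::read_json(test_path("oracle-carb-spot.json"),
                      simplifyVector = TRUE)
}

# Small literature-style corpus built from known profiles; co2 reported
# directly for `direct`, as TA/DIC pairs for `pairs` studies.
make_literature <- function(profiles, n_levels = 6, sigma = 0.04,
                            seed = 1) {
  set.seed(seed)
  out <- NULL
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    co2 <- exp(seq(log(0.5), log(120), length.out = n_levels))
    rate <- pmax(mm_rate(co2, p$x, p$y, p$s) +
                   rnorm(n_levels, 0, sigma), 0.01)
    out <- rbind(out, data.frame(
      study_id = paste0("study", i), species = paste0("sp", i),
      growth_rate = rate,
      param1_name = "co2", param1_value = co2,
      param2_name = "ta", param2_value = 2300,
      ph_scale = NA_character_, temperature = 15, salinity = 33,
      manipulation = "NaOH/HCl"))
  }
  out
}
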