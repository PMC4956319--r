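# published point estimates for the C. barnesi polyp tolerance surface,
# used throughout as a realistic truth for simulations
published_params <- function(k = 5) {
  response_params(a = 11.48, t_opt = 22.91,
                  sigma_t_low = 3.47, sigma_t_high = 5.01,
                  s_opt = 26.04, sigma_s_low = 5.19, sigma_s_high = 31.07,
                  dispersion_k = k)
}

# published 95% profile confidence limits, by parameter
published_limits <- list(
  a = c(9.00, 14.95),
  sigma_t_low = c(2.91, 4.02),
  sigma_t_high = c(4.39, 5.72),
  t_opt = c(21.92, 23.86),
  sigma_s_low = c(4.39, 6.22),
  sigma_s_high = c(21.70, 89.95),
  s_opt = c(24.54, 27.85))

# small crossed count table written to a temp CSV in the thermal-osmotic
# column order, with unit-suffixed headers
write_thermal_csv <- function(path, rows) {
  header <- c("Sample identification number", "Well number",
              "Treatment number", "Temperature (°C)",
              "Salinity (‰)", "Time (weeks)", "Total", "Proportion")
  df <- as.data.frame(rows)
  names(df) <- header[seq_along(df)]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  path
}

# a valid 2-treatment, 2-well toy in long form (times 0 and 6)
toy_thermal_rows <- function() {
  list(
    sample = 1:8,
    well = c(1, 1, 2, 2, 1, 1, 2, 2),
    treatment = c(1, 1, 1, 1, 2, 2, 2, 2),
    temperature = c(rep(21, 4), rep(25, 4)),
    salinity = c(rep(26, 4), rep(33, 4)),
    time = rep(c(0, 6), 4),
    total = c(10, 25, 12, 30, 20, 10, 15, 6),
    proportion = c(NA, 2.5, NA, 2.5, NA, 0.5, NA, 0.4))
}

# small but identifiable paired dataset for fitting tests
small_paired <- function(seed = 7, k = 3) {
  truth <- response_params(a = 4, t_opt = 22, sigma_t_low = 4,
                           sigma_t_high = 6, s_opt = 28, sigma_s_low = 6,
                           sigma_s_high = 12, dispersion_k = k)
  cfg <- synthetic_config(truth,
                          temperatures = c(14, 18, 22, 26, 30),
                          salinities = c(18, 24, 30, 36, 42),
                          replicates = 4, seed = seed)
  list(truth = truth,
       paired = pair_initial_final(simulate_experiment(cfg), 6))
}
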