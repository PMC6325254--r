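# Printed harmonized values of the bundled time-discounting effect table, in
# fixture row order: sign-aligned Fisher z, its standard error, and the
# tolerance implied by each entry's printed precision (two of the z values
# are printed at 2 decimals, the rest at 3).
printed_table1 <- function() {
  data.frame(
    z  = c(-0.867, -0.010, -1.420, 0.151, 0.758, -0.356, -0.181,
           -0.775, -0.711, 0.633, -0.050, -0.567, 0.599, 0.027),
    se = c(0.333, 0.333, 0.333, 0.333, 0.267, 0.204, 0.204,
           0.378, 0.354, 0.224, 0.250, 0.277, 0.218, 0.097),
    tol_z = c(0.001, 0.005, 0.005, 0.001, 0.001, 0.001, 0.001,
              0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001))
}

# Writes a data frame to a temporary CSV and returns the path.
write_fixture_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# A small valid effect data frame for loader edge-case tests.
minimal_effects <- function(n = 6) {
  data.frame(study_id = paste0("s", seq_len(n)),
             group = rep(c("healthy", "addiction", "other_psychopathology"),
                         length.out = n),
             tracer_target = "d2_receptor", region = "whole_striatum",
             index = "k", r = seq(-0.5, 0.5, length.out = n),
             t = NA, df = NA, n = 20, exclude = FALSE, note = "",
             stringsAsFactors = FALSE)
}
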