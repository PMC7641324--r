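# Shared fixtures: canonical kinetic constants (from the two-condition IC50
# solve), condition shorthands, and noiseless enzyme variants.

std_km <- 3750 / 9
std_ki <- 9.4339623

std_kin <- function() motor_kinetics(v_max = 1, km_atp = std_km,
                                     ki_inh = std_ki)

kinetic_cond <- function(atp_uM, inhibitor_uM = 0) {
  reaction_conditions(atp_uM = atp_uM, inhibitor_uM = inhibitor_uM,
                      mode = "kinetic")
}

table_cond <- function(inhibitor_uM = 0) {
  reaction_conditions(inhibitor_uM = inhibitor_uM, mode = "table")
}

# default enzyme with deterministic swing (cv = 0), optionally a custom table
enzyme_cv0 <- function(calibration = default_calibration(), ...) {
  enzyme_params(swing = swing_model(cv = 0), calibration = calibration, ...)
}

# independent numeric oracle: IC50 as the bisection root of half activity
numeric_ic50 <- function(kin, atp_uM, upper = 1e6) {
  f <- function(I) {
    relative_activity(kin, kinetic_cond(atp_uM, I)) - 0.5
  }
  stats::uniroot(f, c(1e-9, upper), tol = 1e-12)$root
}

# one-row substrate helpers
chi_plus_sub <- function(length_nt, chi_from_label = 970) {
  substrate_spec(sprintf("chi_plus_%d", length_nt), length_nt, "right",
                 chi_cut_from_label = chi_from_label)
}
chi_zero_sub <- function(length_nt) {
  substrate_spec(sprintf("chi_zero_%d", length_nt), length_nt, "right")
}
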