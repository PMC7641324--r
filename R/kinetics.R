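# Competitive-inhibition rate laws for the RecB and RecD motors, the
# Cheng-Prusoff closed form, and the two-condition Ki/Km solver.

#' Kinetic constants of one helicase motor
#'
#' Bundles the Michaelis-Menten and competitive-inhibition constants of a
#' single translocating motor (RecB or RecD). The inhibitor is assumed to
#' compete with ATP at the motor's ATP-binding site, so inhibition raises the
#' apparent Km without touching v_max.
#'
#' @param v_max Maximal translocation velocity, nt/ms.
#' @param km_atp Michaelis constant for ATP, uM.
#' @param ki_inh Competitive inhibition constant of the small molecule, uM.
#' @return An object of class `motor_kinetics`.
#' @examples
#' motor_kinetics(v_max = 1, km_atp = 416.7, ki_inh = 9.434)
#' @export
motor_kinetics <- function(v_max, km_atp, ki_inh) {
  for (nm in c("v_max", "km_atp", "ki_inh")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      rlang::abort(
        sprintf("`%s` must be a single strictly positive number, got %s.",
                nm, format(x)[1]),
        class = "chirace_invalid_parameter"
      )
    }
  }
  structure(
    list(v_max = as.numeric(v_max), km_atp = as.numeric(km_atp),
         ki_inh = as.numeric(ki_inh)),
    class = "motor_kinetics"
  )
}

#' Reaction conditions for one incubation
#'
#' @param atp_uM ATP concentration, uM.
#' @param inhibitor_uM Inhibitor (NSAC1003) concentration, uM.
#' @param duration_s Reaction time, s.
#' @param mode `"kinetic"` (velocities from the rate laws) or `"table"`
#'   (velocity ratio and swing advance looked up in a per-concentration
#'   calibration table).
#' @return An object of class `reaction_conditions`.
#' @export
reaction_conditions <- function(atp_uM = 5000, inhibitor_uM = 0,
                                duration_s = 60,
                                mode = c("table", "kinetic")) {
  mode <- match.arg(mode)
  if (!is.numeric(atp_uM) || atp_uM < 0 || !is.numeric(inhibitor_uM) ||
      inhibitor_uM < 0) {
    rlang::abort("Concentrations must be non-negative.",
                 class = "chirace_invalid_parameter")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    rlang::abort("`duration_s` must be positive.",
                 class = "chirace_invalid_parameter")
  }
  structure(
    list(atp_uM = as.numeric(atp_uM), inhibitor_uM = as.numeric(inhibitor_uM),
         duration_s = as.numeric(duration_s), mode = mode),
    class = "reaction_conditions"
  )
}

#' Motor translocation velocity under competitive inhibition
#'
#' Evaluates the single-substrate competitive-inhibition rate law
#' \deqn{v = v_{max} [ATP] / (K_m (1 + [I]/K_i) + [ATP])}
#' The form is the signature of ATP-competitive inhibition: the IC50 shifts
#' linearly with ATP concentration (see [cheng_prusoff_ic50()]).
#'
#' @param kin A [motor_kinetics()] object.
#' @param cond A [reaction_conditions()] object with `mode = "kinetic"`.
#' @return Velocity in nt/ms (a single number).
#' @examples
#' kin <- motor_kinetics(1, 416.7, 9.434)
#' motor_velocity(kin, reaction_conditions(atp_uM = 416.7, mode = "kinetic"))
#' @export
motor_velocity <- function(kin, cond) {
  stopifnot(inherits(kin, "motor_kinetics"),
            inherits(cond, "reaction_conditions"))
  if (cond$mode != "kinetic") {
    rlang::abort("`motor_velocity()` needs conditions with mode = \"kinetic\".",
                 class = "chirace_invalid_parameter")
  }
  kin$v_max * cond$atp_uM /
    (kin$km_atp * (1 + cond$inhibitor_uM / kin$ki_inh) + cond$atp_uM)
}

#' Closed-form IC50 of a competitive inhibitor
#'
#' For the rate law in [motor_velocity()] the half-inhibitory concentration
#' is the Cheng-Prusoff relation \eqn{IC_{50} = K_i (1 + [ATP]/K_m)}: the
#' apparent potency of an ATP-competitive inhibitor falls as ATP rises.
#'
#' @param kin A [motor_kinetics()] object.
#' @param atp_uM ATP concentration, uM (>= 0).
#' @return IC50 in uM.
#' @examples
#' kin <- motor_kinetics(1, km_atp = 3750 / 9, ki_inh = 9.434)
#' cheng_prusoff_ic50(kin, 25)    # ~10 uM
#' cheng_prusoff_ic50(kin, 4000)  # ~100 uM
#' @export
cheng_prusoff_ic50 <- function(kin, atp_uM) {
  stopifnot(inherits(kin, "motor_kinetics"))
  if (!is.numeric(atp_uM) || any(atp_uM < 0)) {
    rlang::abort("`atp_uM` must be >= 0.", class = "chirace_invalid_parameter")
  }
  kin$ki_inh * (1 + atp_uM / kin$km_atp)
}

#' Solve Ki and Km from IC50s at two ATP concentrations
#'
#' Under the Cheng-Prusoff relation, IC50 is linear in ATP:
#' \eqn{IC_{50}(A) = K_i + (K_i/K_m) A}. Two observations at distinct ATP
#' concentrations therefore determine \eqn{(K_i, K_m)} uniquely.
#'
#' @param obs A data frame with columns `atp_uM` and `ic50_uM` (two rows,
#'   distinct `atp_uM`, all values positive).
#' @return A tibble with one row: `ki_uM`, `km_uM`.
#' @examples
#' solve_ki_km(tibble::tibble(atp_uM = c(25, 4000), ic50_uM = c(10, 100)))
#' @export
solve_ki_km <- function(obs) {
  obs <- tibble::as_tibble(obs)
  if (!all(c("atp_uM", "ic50_uM") %in% names(obs)) || nrow(obs) != 2L) {
    rlang::abort("`obs` must have two rows with columns atp_uM, ic50_uM.",
                 class = "chirace_invalid_parameter")
  }
  if (any(obs$atp_uM < 0) || any(obs$ic50_uM <= 0)) {
    rlang::abort("ATP must be >= 0 and IC50 > 0.",
                 class = "chirace_invalid_parameter")
  }
  a <- obs$atp_uM; i <- obs$ic50_uM
  if (a[1] == a[2]) {
    rlang::abort("The two ATP concentrations must differ.",
                 class = "chirace_no_solution")
  }
  slope <- (i[2] - i[1]) / (a[2] - a[1])   # = Ki/Km
  ki <- i[1] - slope * a[1]
  if (slope <= 0 || ki <= 0) {
    rlang::abort(
      "Observations imply non-positive Ki or Km; no competitive-inhibition solution.",
      class = "chirace_no_solution"
    )
  }
  tibble::tibble(ki_uM = ki, km_uM = ki / slope)
}

#' Nuclease swing-time model
#'
#' Time for the tethered RecB nuclease domain to swing to its cutting
#' position: fast (~1 ms) when triggered by a Chi hotspot, slow (~200-300 ms)
#' when triggered by RecD stopping at the DNA end. The slow swing lets RecB
#' advance 200-300 nt past the naive cut point and smears the product band.
#'
#' @param tau_chi_ms Mean swing time after a Chi encounter, ms.
#' @param tau_stop_ms Mean swing time after RecD stops at the end, ms.
#' @param cv Coefficient of variation of the swing time (gamma-distributed).
#' @param chi_offset_nt Nominal cut offset 3' of the Chi 8-mer, nt (0-6).
#' @return An object of class `swing_model`.
#' @export
swing_model <- function(tau_chi_ms = 1, tau_stop_ms = 250, cv = 0.2,
                        chi_offset_nt = 5) {
  if (tau_chi_ms <= 0 || tau_stop_ms <= 0 || cv < 0 ||
      chi_offset_nt < 0 || chi_offset_nt > 6) {
    rlang::abort("Invalid swing parameters: times > 0, cv >= 0, offset in [0, 6].",
                 class = "chirace_invalid_parameter")
  }
  structure(
    list(tau_chi_ms = tau_chi_ms, tau_stop_ms = tau_stop_ms, cv = cv,
         chi_offset_nt = chi_offset_nt),
    class = "swing_model"
  )
}

#' Full enzyme parameter set
#'
#' RecB and RecD motor kinetics, the nuclease swing model, the probability
#' that a traversed Chi site triggers cutting, the half-saturation of
#' inhibitor-induced end-stop sensitization, and the per-concentration
#' calibration table used in table mode.
#'
#' Defaults: RecD at 1 nt/ms so nucleotides and milliseconds interchange
#' numerically; RecB at 0.8 nt/ms uninhibited; shared Km for ATP solved from
#' the two-condition IC50 system; RecD's Ki 7.3-fold weaker than RecB's (the
#' docking affinity ratio), so inhibitor slows RecB relative to RecD.
#'
#' @param recB,recD [motor_kinetics()] for the two motors.
#' @param swing A [swing_model()].
#' @param p_chi_recognition Probability a traversed, correctly oriented Chi
#'   triggers cutting.
#' @param k_sens_uM Half-saturation (uM) of the inhibitor's sensitization of
#'   RecB to cut when RecD stops at the DNA end.
#' @param calibration Table-mode calibration: data frame with columns
#'   `inhibitor_uM`, `ratio`, `advance_nt` (see [default_calibration()]).
#' @return An object of class `enzyme_params`.
#' @export
enzyme_params <- function(recB = motor_kinetics(0.8, 3750 / 9, 9.434),
                          recD = motor_kinetics(1.0, 3750 / 9, 9.434 * 7.3),
                          swing = swing_model(),
                          p_chi_recognition = 1,
                          k_sens_uM = 75,
                          calibration = default_calibration()) {
  stopifnot(inherits(recB, "motor_kinetics"), inherits(recD, "motor_kinetics"),
            inherits(swing, "swing_model"))
  if (p_chi_recognition < 0 || p_chi_recognition > 1) {
    rlang::abort("`p_chi_recognition` must lie in [0, 1].",
                 class = "chirace_invalid_parameter")
  }
  if (k_sens_uM <= 0) {
    rlang::abort("`k_sens_uM` must be > 0.",
                 class = "chirace_invalid_parameter")
  }
  calibration <- tibble::as_tibble(calibration)
  need <- c("inhibitor_uM", "ratio", "advance_nt")
  if (!all(need %in% names(calibration))) {
    rlang::abort("Calibration table needs columns inhibitor_uM, ratio, advance_nt.",
                 class = "chirace_config_error")
  }
  structure(
    list(recB = recB, recD = recD, swing = swing,
         p_chi_recognition = p_chi_recognition, k_sens_uM = k_sens_uM,
         calibration = calibration),
    class = "enzyme_params"
  )
}

#' Default enzyme parameter set
#'
#' @return An [enzyme_params()] object with package defaults.
#' @export
default_enzyme <- function() enzyme_params()

#' Packaged per-concentration calibration table
#'
#' Velocity ratio (RecB/RecD) and mean swing advance at each inhibitor
#' concentration of the standard titration. The 25 and 400 uM ratios are the
#' observed ~70% and ~30% cut positions; the 50-400 uM advances are the
#' magnitudes of the negative intercepts of the product-length versus
#' substrate-length fits; intermediate ratios are linearly interpolated and
#' the 0 uM ratio is the uninhibited RecB:RecD ratio by back-extrapolation.
#'
#' @return A tibble with columns `inhibitor_uM`, `ratio`, `advance_nt`.
#' @export
default_calibration <- function() {
  tibble::tibble(
    inhibitor_uM = c(0, 25, 50, 100, 200, 400),
    ratio        = c(0.80, 0.70, 0.60, 0.50, 0.40, 0.30),
    advance_nt   = c(250, 250, 250, 370, 290, 200)
  )
}

# Internal: (ratio, advance) for given conditions, honouring the mode.
lookup_race_params <- function(enz, cond) {
  if (cond$mode == "table") {
    idx <- which(abs(enz$calibration$inhibitor_uM - cond$inhibitor_uM) < 1e-9)
    if (length(idx) != 1L) {
      rlang::abort(
        sprintf("Inhibitor concentration %g uM is not in the calibration table.",
                cond$inhibitor_uM),
        class = "chirace_config_error"
      )
    }
    v_d <- enz$recD$v_max
    list(ratio = enz$calibration$ratio[idx],
         advance_nt = enz$calibration$advance_nt[idx],
         v_b = enz$calibration$ratio[idx] * v_d, v_d = v_d)
  } else {
    v_b <- motor_velocity(enz$recB, cond)
    v_d <- motor_velocity(enz$recD, cond)
    list(ratio = v_b / v_d, advance_nt = v_b * enz$swing$tau_stop_ms,
         v_b = v_b, v_d = v_d)
  }
}

#' RecB:RecD velocity ratio
#'
#' The ratio x/y of the slower RecB to the faster RecD translocation rate.
#' It sets the end-stop cut position as a fraction of substrate length. In
#' kinetic mode it is computed from the two rate laws; in table mode it is
#' looked up in the packaged calibration.
#'
#' @inheritParams motor_velocity
#' @param enz An [enzyme_params()] object.
#' @param cond A [reaction_conditions()] object.
#' @return The dimensionless ratio in (0, 1].
#' @export
velocity_ratio <- function(enz, cond) {
  stopifnot(inherits(enz, "enzyme_params"),
            inherits(cond, "reaction_conditions"))
  r <- lookup_race_params(enz, cond)$ratio
  if (r > 1 || r <= 0) {
    rlang::abort(
      sprintf("Velocity ratio %.3f outside (0, 1]: RecB may not outrun RecD.", r),
      class = "chirace_invalid_parameter"
    )
  }
  r
}

#' Relative nuclease activity under inhibition
#'
#' Scalar activity for the DNA-solubilization assay: the RecB velocity under
#' the given conditions divided by its uninhibited velocity at the same ATP.
#' Equals 1 with no inhibitor, 1/2 at the IC50, and falls hyperbolically.
#'
#' @param enz An [enzyme_params()] or [motor_kinetics()] object (for an
#'   enzyme, the RecB motor is used).
#' @param cond A [reaction_conditions()] object; the mode is ignored (the
#'   rate law is always used here).
#' @return Activity fraction in (0, 1].
#' @export
relative_activity <- function(enz, cond) {
  kin <- if (inherits(enz, "enzyme_params")) enz$recB else enz
  stopifnot(inherits(kin, "motor_kinetics"),
            inherits(cond, "reaction_conditions"))
  kcond <- reaction_conditions(atp_uM = cond$atp_uM,
                               inhibitor_uM = cond$inhibitor_uM,
                               duration_s = cond$duration_s, mode = "kinetic")
  k0 <- reaction_conditions(atp_uM = cond$atp_uM, inhibitor_uM = 0,
                            duration_s = cond$duration_s, mode = "kinetic")
  motor_velocity(kin, kcond) / motor_velocity(kin, k0)
}

#' @export
print.motor_kinetics <- function(x, ...) {
  cat(sprintf("<motor_kinetics> v_max = %g nt/ms, Km(ATP) = %g uM, Ki = %g uM\n",
              x$v_max, x$km_atp, x$ki_inh))
  invisible(x)
}

#' @export
print.enzyme_params <- function(x, ...) {
  cat("<enzyme_params>\n")
  cat(sprintf("  RecB: v_max %g nt/ms, Km %g uM, Ki %g uM\n",
              x$recB$v_max, x$recB$km_atp, x$recB$ki_inh))
  cat(sprintf("  RecD: v_max %g nt/ms, Km %g uM, Ki %g uM\n",
              x$recD$v_max, x$recD$km_atp, x$recD$ki_inh))
  cat(sprintf("  swing: tau_chi %g ms, tau_stop %g ms, cv %g, chi offset %d nt\n",
              x$swing$tau_chi_ms, x$swing$tau_stop_ms, x$swing$cv,
              x$swing$chi_offset_nt))
  cat(sprintf("  p(Chi recognition) %g, k_sens %g uM, calibration: %d concentrations\n",
              x$p_chi_recognition, x$k_sens_uM, nrow(x$calibration)))
  invisible(x)
}
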