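# Seeded generators of complete in-silico experiments: the three-substrate
# cutting assay across the inhibitor titration, and the T7-solubilization
# nuclease dose-response.

#' Generate a full in-silico cutting experiment
#'
#' One gel lane per (substrate x inhibitor concentration): each lane is a
#' simulated molecule population rendered through the gel forward model with
#' the packaged marker ladder. Deterministic for a fixed seed.
#'
#' @param substrates A `substrate_spec` tibble (default: the six packaged
#'   substrates).
#' @param concentrations_uM Inhibitor concentrations; each must appear in
#'   the enzyme's calibration table when `mode = "table"`.
#' @param enz An [enzyme_params()] object.
#' @param n_molecules Molecules simulated per lane.
#' @param mode `"table"` (default) or `"kinetic"`.
#' @param atp_uM ATP concentration (used in kinetic mode).
#' @param gel A [gel_params()] object.
#' @param markers Marker ladder (default: packaged ladder on this gel).
#' @param band_jitter_mm Per-band measurement noise, mm (0 = noiseless).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `cutting_experiment`: list with `lanes` (named list of
#'   `gel_lane`), `index` (tibble of lane metadata), `truth` (tibble of the
#'   generating ratio/advance per concentration), `gel`, `markers`, `seed`.
#' @examples
#' ex <- generate_cutting_experiment(n_molecules = 200, seed = 1)
#' ex$index
#' @export
generate_cutting_experiment <- function(substrates = make_default_substrates(),
                                        concentrations_uM = c(0, 25, 50, 100,
                                                              200, 400),
                                        enz = default_enzyme(),
                                        n_molecules = 2000,
                                        mode = c("table", "kinetic"),
                                        atp_uM = 5000,
                                        gel = gel_params(),
                                        markers = default_marker_ladder(gel),
                                        band_jitter_mm = 0,
                                        seed = NULL) {
  mode <- match.arg(mode)
  if (n_molecules < 1) rlang::abort("`n_molecules` must be >= 1.",
                                    class = "chirace_invalid_parameter")
  if (mode == "table") {
    missing <- setdiff(concentrations_uM, enz$calibration$inhibitor_uM)
    if (length(missing) > 0) {
      rlang::abort(
        sprintf("Concentration(s) %s uM missing from the calibration table.",
                paste(missing, collapse = ", ")),
        class = "chirace_config_error"
      )
    }
  }
  build <- function() {
    lanes <- list()
    index <- list()
    for (i in seq_len(nrow(substrates))) {
      sub <- substrates[i, ]
      for (conc in concentrations_uM) {
        cond <- reaction_conditions(atp_uM = atp_uM, inhibitor_uM = conc,
                                    mode = mode)
        frags <- simulate_population(n_molecules, sub, enz, cond)
        lane <- render_lane(frags, gel, markers,
                            band_jitter_mm = band_jitter_mm)
        key <- sprintf("%s_I%g", sub$name, conc)
        lanes[[key]] <- lane
        index[[key]] <- tibble::tibble(
          lane = key, substrate = sub$name, length_nt = sub$length_nt,
          chi_status = sub$chi_status, inhibitor_uM = conc,
          n_molecules = n_molecules
        )
      }
    }
    list(lanes = lanes, index = dplyr::bind_rows(index))
  }
  res <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  truth <- if (mode == "table") {
    dplyr::filter(enz$calibration,
                  .data$inhibitor_uM %in% concentrations_uM)
  } else {
    purrr::map_dfr(concentrations_uM, function(conc) {
      cond <- reaction_conditions(atp_uM = atp_uM, inhibitor_uM = conc,
                                  mode = "kinetic")
      rp <- lookup_race_params(enz, cond)
      tibble::tibble(inhibitor_uM = conc, ratio = rp$ratio,
                     advance_nt = rp$advance_nt)
    })
  }
  structure(
    list(lanes = res$lanes, index = res$index, truth = truth,
         gel = gel, markers = tibble::as_tibble(markers), seed = seed),
    class = "cutting_experiment"
  )
}

#' @export
print.cutting_experiment <- function(x, ...) {
  cat(sprintf("<cutting_experiment> %d lanes (%d substrates x %d concentrations)\n",
              length(x$lanes), length(unique(x$index$substrate)),
              length(unique(x$index$inhibitor_uM))))
  invisible(x)
}

#' Generate a synthetic nuclease-solubilization dose-response
#'
#' Emulates the radiolabeled-T7-DNA solubilization assay: relative nuclease
#' activity from the competitive-inhibition rate law, multiplied by
#' `1 + N(0, noise_cv)` per replicate and clamped at zero.
#'
#' @param ki_uM,km_uM Inhibition and Michaelis constants, uM.
#' @param atp_uM ATP concentration of the assay, uM.
#' @param concentrations_uM Inhibitor concentrations assayed.
#' @param replicates Replicates per concentration.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return A tibble with columns `inhibitor_uM`, `atp_uM`,
#'   `activity_fraction`, `replicate`.
#' @examples
#' generate_nuclease_assay(atp_uM = 25,
#'                         concentrations_uM = c(0, 5, 10, 20, 40),
#'                         replicates = 2, noise_cv = 0, seed = 1)
#' @export
generate_nuclease_assay <- function(ki_uM = fig2b_settings()$ki_uM,
                                    km_uM = fig2b_settings()$km_uM,
                                    atp_uM = 25,
                                    concentrations_uM = c(0, 1.25, 2.5, 5, 10,
                                                          20, 40, 80),
                                    replicates = 3, noise_cv = 0,
                                    seed = NULL) {
  kin <- motor_kinetics(v_max = 1, km_atp = km_uM, ki_inh = ki_uM)
  grid <- tidyr_expand(concentrations_uM, seq_len(replicates))
  act <- purrr::map_dbl(grid$conc, function(I) {
    relative_activity(kin, reaction_conditions(atp_uM = atp_uM,
                                               inhibitor_uM = I,
                                               mode = "kinetic"))
  })
  noisy <- function() {
    eps <- if (noise_cv > 0) stats::rnorm(length(act), 0, noise_cv) else 0
    pmax(0, act * (1 + eps))
  }
  vals <- if (is.null(seed)) noisy() else withr::with_seed(seed, noisy())
  tibble::tibble(inhibitor_uM = grid$conc, atp_uM = atp_uM,
                 activity_fraction = vals, replicate = grid$rep)
}

# minimal expand.grid in deterministic order (concentration-major)
tidyr_expand <- function(conc, reps) {
  cc <- rep(conc, each = length(reps))
  rr <- rep(reps, times = length(conc))
  tibble::tibble(conc = cc, rep = rr)
}

#' Packaged settings of the standard-assay inhibition curve
#'
#' The nuclease-assay generator settings reproducing the observed standard
#' (25 uM ATP) inhibition: `ki_uM` is chosen so that the Cheng-Prusoff IC50
#' at 25 uM ATP equals the measured 6.3 uM, with Km from the two-condition
#' solve ([default_ic50_observations()]).
#'
#' @return A list with `ki_uM`, `km_uM`, `atp_uM`.
#' @export
fig2b_settings <- function() {
  km <- 3750 / 9
  list(ki_uM = 6.3 / (1 + 25 / km), km_uM = km, atp_uM = 25)
}

#' Packaged two-condition IC50 observations
#'
#' The measured half-inhibitory concentrations of the side-by-side assays at
#' two ATP levels: ~10 uM at 25 uM ATP and ~100 uM at 4 mM ATP. These two
#' points determine Ki and Km of the competitive model via [solve_ki_km()].
#'
#' @return A tibble with columns `atp_uM`, `ic50_uM`.
#' @export
default_ic50_observations <- function() {
  tibble::tibble(atp_uM = c(25, 4000), ic50_uM = c(10, 100))
}
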