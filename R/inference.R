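# Inference: band lengths per lane, product-length vs substrate-length OLS,
# recovery of the velocity ratio and swing delay, and 4PL dose-response fits.

#' Estimate band lengths in a lane
#'
#' Runs [detect_bands()] and converts each band center to a length by
#' [interpolate_length()] against the lane's markers. Bands falling outside
#' the marker span are kept but flagged (`in_span = FALSE`, length `NA`)
#' with a warning, never silently dropped. The full-length (uncut substrate)
#' band is flagged as any band within `full_length_tol` of the substrate
#' length.
#'
#' @param lane A `gel_lane`.
#' @param min_rel_intensity Band detection threshold (see [detect_bands()]).
#' @param full_length_tol Relative tolerance for calling a band full-length.
#' @return A tibble with columns `distance_mm`, `intensity`, `width_mm`,
#'   `in_span`, `length_nt`, `is_full_length`.
#' @export
estimate_band_lengths <- function(lane, min_rel_intensity = 0.05,
                                  full_length_tol = 0.02) {
  stopifnot(inherits(lane, "gel_lane"))
  bands <- detect_bands(lane, min_rel_intensity)
  if (nrow(bands) == 0) {
    return(tibble::tibble(distance_mm = numeric(0), intensity = numeric(0),
                          width_mm = numeric(0), in_span = logical(0),
                          length_nt = numeric(0), is_full_length = logical(0)))
  }
  mk <- lane$markers
  span <- range(mk$distance_mm)
  # a band centered on the outermost marker can land epsilon outside the
  # span through profile discretization; snap such centers to the edge
  eps <- 0.05
  near_edge <- bands$distance_mm < span[1] & bands$distance_mm >= span[1] - eps
  bands$distance_mm[near_edge] <- span[1]
  near_edge <- bands$distance_mm > span[2] & bands$distance_mm <= span[2] + eps
  bands$distance_mm[near_edge] <- span[2]
  bands$in_span <- bands$distance_mm >= span[1] & bands$distance_mm <= span[2]
  if (any(!bands$in_span)) {
    rlang::warn(sprintf(
      "%d band(s) outside the marker span were flagged (length NA).",
      sum(!bands$in_span)))
  }
  bands$length_nt <- NA_real_
  bands$length_nt[bands$in_span] <-
    interpolate_length(bands$distance_mm[bands$in_span], mk)
  S <- lane$metadata$length_nt
  bands$is_full_length <- !is.na(bands$length_nt) &
    abs(bands$length_nt - S) <= full_length_tol * S
  bands
}

#' Fit labeled product length against substrate length
#'
#' Ordinary least squares of product length on substrate length across
#' substrates at one inhibitor concentration. Under the race model the
#' end-stop product length is `S (1 - x/y) - advance`, so the slope is
#' `1 - x/y` and the intercept is minus the swing advance.
#'
#' @param points Data frame with columns `substrate_length_nt` and
#'   `product_length_nt`; at least two distinct substrate lengths.
#' @return An object of class `product_fit` with fields `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `n_points`, `r_squared` and
#'   the underlying `lm` fit. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' pts <- tibble::tibble(substrate_length_nt = c(1340, 2270, 4350),
#'                       product_length_nt = c(152, 431, 1055))
#' fit_product_vs_substrate(pts)
#' @export
fit_product_vs_substrate <- function(points) {
  points <- tibble::as_tibble(points)
  need <- c("substrate_length_nt", "product_length_nt")
  if (!all(need %in% names(points))) {
    rlang::abort("`points` needs columns substrate_length_nt, product_length_nt.",
                 class = "chirace_fit_error")
  }
  points <- stats::na.omit(points[need])
  if (length(unique(points$substrate_length_nt)) < 2L) {
    rlang::abort("Need at least two distinct substrate lengths.",
                 class = "chirace_fit_error")
  }
  fit <- stats::lm(product_length_nt ~ substrate_length_nt, data = points)
  sm <- summary(fit)
  co <- sm$coefficients
  se <- if (nrow(points) > 2L) co[, "Std. Error"] else c(NA_real_, NA_real_)
  structure(
    list(slope = unname(co["substrate_length_nt", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         se_slope = unname(se[2]), se_intercept = unname(se[1]),
         n_points = nrow(points), r_squared = sm$r.squared, fit = fit),
    class = "product_fit"
  )
}

#' @export
print.product_fit <- function(x, ...) {
  cat(sprintf(
    "<product_fit> product = %.4f * S %+.1f nt  (n = %d, R^2 = %.4f)\n",
    x$slope, x$intercept, x$n_points, x$r_squared))
  invisible(x)
}

#' @export
tidy.product_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(x$se_intercept, x$se_slope))
}

#' @export
glance.product_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, nobs = x$n_points)
}

#' Recover the velocity ratio and nuclease swing delay from a fit
#'
#' Inverts the end-stop product model: ratio `x/y = 1 - slope`, swing
#' advance `= -intercept` (nt), and swing time `= advance / v_B` (ms).
#'
#' @param fit A `product_fit`.
#' @param v_b_nt_per_ms RecB velocity used to convert the advance to a
#'   time; at the canonical ~1 nt/ms, nucleotides and ms interchange.
#' @return A one-row tibble: `ratio`, `advance_nt`, `tau_ms`,
#'   `advance_clamped` (TRUE when a positive intercept was clamped to zero
#'   advance, with a warning).
#' @examples
#' pts <- tibble::tibble(substrate_length_nt = c(1340, 2270, 4350),
#'                       product_length_nt = c(152, 431, 1055))
#' recover_ratio_and_delay(fit_product_vs_substrate(pts))
#' @export
recover_ratio_and_delay <- function(fit, v_b_nt_per_ms = 1) {
  stopifnot(inherits(fit, "product_fit"), v_b_nt_per_ms > 0)
  if (fit$slope <= 0 || fit$slope >= 1) {
    rlang::abort(
      sprintf("Slope %.3f outside (0, 1); not interpretable as 1 - x/y.",
              fit$slope),
      class = "chirace_fit_error"
    )
  }
  clamped <- FALSE
  adv <- -fit$intercept
  if (adv < 0) {
    rlang::warn(sprintf(
      "Positive intercept (%.1f nt): swing advance clamped to 0.",
      fit$intercept))
    adv <- 0
    clamped <- TRUE
  }
  tibble::tibble(ratio = 1 - fit$slope, advance_nt = adv,
                 tau_ms = adv / v_b_nt_per_ms, advance_clamped = clamped)
}

#' Four-parameter logistic dose-response fit
#'
#' Fits `activity = bottom + (top - bottom) / (1 + ([I]/ic50)^hill)` by
#' nonlinear least squares ([minpack.lm::nlsLM()]). The IC50 is the
#' inflection concentration. Initial values: `top`/`bottom` from the data
#' extremes, `hill = 1`, `ic50` the concentration whose mean activity is
#' nearest half-maximal.
#'
#' @param points Data frame with columns `inhibitor_uM` and
#'   `activity_fraction`; at least four distinct concentrations including
#'   one near zero.
#' @param weighting `"none"` for ordinary nonlinear least squares, or
#'   `"relative"` for inverse-squared-activity weights, the appropriate
#'   variance model when assay noise is proportional to the signal (as in
#'   scintillation-counting readouts).
#' @return An object of class `dose_response_fit` with fields `ic50_uM`,
#'   `hill`, `top`, `bottom`, `se_ic50` and the `nls` fit. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_dose_response <- function(points, weighting = c("none", "relative")) {
  weighting <- match.arg(weighting)
  points <- tibble::as_tibble(points)
  need <- c("inhibitor_uM", "activity_fraction")
  if (!all(need %in% names(points))) {
    rlang::abort("`points` needs columns inhibitor_uM, activity_fraction.",
                 class = "chirace_fit_error")
  }
  points <- stats::na.omit(points[need])
  concs <- sort(unique(points$inhibitor_uM))
  if (length(concs) < 4L) {
    rlang::abort("Need at least four distinct inhibitor concentrations.",
                 class = "chirace_fit_error")
  }
  if (min(concs) > 0.05 * max(concs)) {
    rlang::warn("No near-zero concentration: the top plateau is poorly anchored.")
  }
  top0 <- max(points$activity_fraction)
  bot0 <- min(points$activity_fraction)
  mid <- (top0 + bot0) / 2
  means <- points |>
    dplyr::group_by(.data$inhibitor_uM) |>
    dplyr::summarise(m = mean(.data$activity_fraction), .groups = "drop") |>
    dplyr::filter(.data$inhibitor_uM > 0)
  ic0 <- means$inhibitor_uM[which.min(abs(means$m - mid))]
  start <- list(top = top0, bottom = bot0, ic50 = ic0, hill = 1)
  w <- if (weighting == "relative") {
    1 / pmax(points$activity_fraction, 0.05)^2
  } else rep(1, nrow(points))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      activity_fraction ~ bottom + (top - bottom) /
        (1 + (inhibitor_uM / ic50)^hill),
      data = points, start = start, weights = w,
      lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-9, hill = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) rlang::abort(
      sprintf(
        "Dose-response fit failed to converge (start: top=%.3g bottom=%.3g ic50=%.3g hill=1): %s",
        top0, bot0, ic0, conditionMessage(e)),
      class = "chirace_fit_error")
  )
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]
  if (est["top"] <= est["bottom"]) {
    rlang::warn("Fitted top <= bottom: dose-response is not decreasing.")
  }
  structure(
    list(ic50_uM = unname(est["ic50"]), hill = unname(est["hill"]),
         top = unname(est["top"]), bottom = unname(est["bottom"]),
         se_ic50 = unname(co["ic50", "Std. Error"]), fit = fit,
         data = points),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> IC50 = %.3g uM (se %.2g), hill = %.3g, top = %.3g, bottom = %.3g\n",
    x$ic50_uM, x$se_ic50, x$hill, x$top, x$bottom))
  invisible(x)
}

#' @export
tidy.dose_response_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, "Estimate"],
                 std.error = co[, "Std. Error"])
}

#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(ic50_uM = x$ic50_uM, hill = x$hill, top = x$top,
                 bottom = x$bottom, se_ic50 = x$se_ic50,
                 nobs = length(stats::residuals(x$fit)))
}

#' Infer race parameters from a cutting experiment
#'
#' The analysis stage of the pipeline: for each inhibitor concentration,
#' takes the Chi-independent product band from each Chi-free lane (the most
#' intense non-full-length band inside the marker span), fits product length
#' against substrate length by OLS, and inverts the fit into the velocity
#' ratio and swing advance/delay. Concentrations with fewer than two usable
#' lanes (e.g. no inhibitor, hence no end-stop product) are skipped.
#'
#' @param experiment A `cutting_experiment` from
#'   [generate_cutting_experiment()], or a plain list of `gel_lane` objects.
#' @param v_b_nt_per_ms RecB velocity for the time conversion.
#' @param min_rel_intensity Band detection threshold.
#' @return A tibble with one row per concentration: `inhibitor_uM`, `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `r_squared`, `n_points`,
#'   `ratio`, `advance_nt`, `tau_ms`.
#' @export
infer_cutting_experiment <- function(experiment, v_b_nt_per_ms = 1,
                                     min_rel_intensity = 0.05) {
  lanes <- if (inherits(experiment, "cutting_experiment")) {
    experiment$lanes
  } else experiment
  stopifnot(length(lanes) > 0, all(purrr::map_lgl(lanes, inherits, "gel_lane")))
  pts <- purrr::map_dfr(lanes, function(ln) {
    md <- ln$metadata
    if (!identical(md$chi_status, "chi_zero")) return(tibble::tibble())
    bands <- estimate_band_lengths(ln, min_rel_intensity)
    prod <- dplyr::filter(bands, .data$in_span, !.data$is_full_length)
    if (nrow(prod) == 0) return(tibble::tibble())
    best <- prod[which.max(prod$intensity), ]
    tibble::tibble(inhibitor_uM = md$inhibitor_uM,
                   substrate_length_nt = md$length_nt,
                   product_length_nt = best$length_nt)
  })
  if (nrow(pts) == 0) {
    rlang::abort("No Chi-free product bands found in any lane.",
                 class = "chirace_fit_error")
  }
  pts |>
    dplyr::group_by(.data$inhibitor_uM) |>
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$substrate_length_nt)) < 2L) return(tibble::tibble())
      f <- fit_product_vs_substrate(df)
      rec <- recover_ratio_and_delay(f, v_b_nt_per_ms)
      tibble::tibble(slope = f$slope, intercept = f$intercept,
                     se_slope = f$se_slope, se_intercept = f$se_intercept,
                     r_squared = f$r_squared, n_points = f$n_points,
                     ratio = rec$ratio, advance_nt = rec$advance_nt,
                     tau_ms = rec$tau_ms)
    }) |>
    dplyr::ungroup()
}
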