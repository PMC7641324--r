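# Forward model of the denaturing agarose-gel readout and its inverse:
# log-linear migration, marker ladders, lane densitometry, band detection,
# and length interpolation against the ladder.

#' Gel migration and band-spread parameters
#'
#' Migration is log-linear in fragment length,
#' `d = a_mm - b_mm * log10(length)`, adequate for denatured single-stranded
#' DNA of 100-6000 nt on agarose. Each molecular species renders as a
#' Gaussian band of point-spread `sigma_mm`.
#'
#' @param a_mm Migration offset, mm.
#' @param b_mm Migration slope, mm per decade of length.
#' @param sigma_mm Band point-spread (Gaussian sd), mm.
#' @param min_length_nt,max_length_nt Validity range of the migration model.
#' @return An object of class `gel_params`.
#' @export
gel_params <- function(a_mm = 120, b_mm = 30, sigma_mm = 0.8,
                       min_length_nt = 100, max_length_nt = 6000) {
  if (b_mm <= 0 || sigma_mm <= 0 || min_length_nt <= 0 ||
      max_length_nt <= min_length_nt) {
    rlang::abort("Invalid gel parameters.", class = "chirace_invalid_parameter")
  }
  structure(
    list(a_mm = a_mm, b_mm = b_mm, sigma_mm = sigma_mm,
         min_length_nt = min_length_nt, max_length_nt = max_length_nt),
    class = "gel_params"
  )
}

#' Migration distance of a fragment
#'
#' @param length_nt Fragment length(s), nt, within the gel's validity range.
#' @param gel A [gel_params()] object.
#' @return Migration distance(s) in mm; strictly decreasing in length.
#' @examples
#' migration_distance(1000, gel_params(a_mm = 100, b_mm = 30))  # 10 mm
#' @export
migration_distance <- function(length_nt, gel = gel_params()) {
  stopifnot(inherits(gel, "gel_params"))
  if (any(length_nt < gel$min_length_nt | length_nt > gel$max_length_nt)) {
    rlang::abort(
      sprintf("Fragment length outside the gel validity range [%g, %g] nt.",
              gel$min_length_nt, gel$max_length_nt),
      class = "chirace_range_error"
    )
  }
  gel$a_mm - gel$b_mm * log10(length_nt)
}

#' Default single-strand marker ladder
#'
#' A generic ladder spanning the packaged substrates: the three boiled
#' substrates plus shorter standards down to 100 nt, placed on the gel by
#' the same migration model used for the samples.
#'
#' @param gel A [gel_params()] object.
#' @param lengths_nt Ladder lengths, nt.
#' @return A tibble with columns `length_nt`, `distance_mm`, sorted by
#'   decreasing length (increasing distance).
#' @export
default_marker_ladder <- function(gel = gel_params(),
                                  lengths_nt = c(4350, 2270, 1340, 1000,
                                                 500, 250, 100)) {
  lengths_nt <- sort(unique(lengths_nt), decreasing = TRUE)
  tibble::tibble(length_nt = lengths_nt,
                 distance_mm = migration_distance(lengths_nt, gel))
}

#' Interpolate fragment length from migration distance
#'
#' Piecewise-linear interpolation in (distance, log10 length) against a
#' marker ladder, exact at the marker points. Distances outside the marker
#' span are refused: no silent extrapolation.
#'
#' @param distance_mm Band distance(s), mm.
#' @param markers Marker tibble with columns `length_nt`, `distance_mm`.
#' @return Interpolated length(s), nt.
#' @examples
#' g <- gel_params()
#' mk <- default_marker_ladder(g)
#' interpolate_length(migration_distance(970, g), mk)
#' @export
interpolate_length <- function(distance_mm, markers) {
  markers <- tibble::as_tibble(markers)
  if (nrow(markers) < 2L) {
    rlang::abort("Need at least two markers.",
                 class = "chirace_invalid_parameter")
  }
  if (any(distance_mm < min(markers$distance_mm) |
          distance_mm > max(markers$distance_mm))) {
    rlang::abort("Distance outside the marker span; refusing to extrapolate.",
                 class = "chirace_extrapolation_error")
  }
  markers <- markers[order(markers$distance_mm), ]
  fit <- stats::approx(markers$distance_mm, log10(markers$length_nt),
                       xout = distance_mm, ties = "ordered")
  10^fit$y
}

#' Render a fragment set as a densitometry lane
#'
#' Forward model of one gel lane: each fragment species becomes a Gaussian
#' band centered at its migration distance with area proportional to its
#' molecule count (end-labeling means molar, not mass, weighting). The
#' full-length (uncut) band is included.
#'
#' @param frags A `fragment_set` from [simulate_population()].
#' @param gel A [gel_params()] object.
#' @param markers Marker ladder tibble (defaults to the packaged ladder on
#'   this gel).
#' @param band_jitter_mm Gaussian sd of a random per-species band-position
#'   shift (measurement noise); 0 for a noiseless lane.
#' @param grid_step_mm Profile grid resolution, mm.
#' @param off_gel How to treat fragments shorter than the gel's validity
#'   floor: `"drop"` (default; they electrophorese off the gel and are
#'   excluded from the profile, counted in `metadata$n_off_gel`) or
#'   `"error"`.
#' @param seed Optional seed for the band jitter.
#' @return An object of class `gel_lane`: list with `profile` (tibble
#'   `distance_mm`, `intensity`), `markers`, and `metadata` (substrate name,
#'   length, chi status, inhibitor concentration, n_molecules).
#' @export
render_lane <- function(frags, gel = gel_params(),
                        markers = default_marker_ladder(gel),
                        band_jitter_mm = 0, grid_step_mm = 0.02,
                        off_gel = c("drop", "error"), seed = NULL) {
  off_gel <- match.arg(off_gel)
  stopifnot(inherits(frags, "fragment_set"), inherits(gel, "gel_params"))
  sub <- attr(frags, "substrate")
  too_long <- frags$fragment_length_nt > gel$max_length_nt
  too_short <- frags$fragment_length_nt < gel$min_length_nt
  if (any(too_long) || (off_gel == "error" && any(too_short))) {
    rlang::abort("Fragment length outside the gel validity range.",
                 class = "chirace_range_error")
  }
  n_off_gel <- sum(frags$count[too_short])
  frags <- frags[!too_short, , drop = FALSE]
  lens <- frags$fragment_length_nt
  centers <- if (length(lens) > 0) migration_distance(lens, gel) else numeric(0)
  if (band_jitter_mm > 0 && length(centers) > 0) {
    jit <- function() stats::rnorm(length(centers), 0, band_jitter_mm)
    centers <- centers +
      (if (is.null(seed)) jit() else withr::with_seed(seed, jit()))
  }
  lo <- gel$a_mm - gel$b_mm * log10(gel$max_length_nt) - 4 * gel$sigma_mm
  hi <- gel$a_mm - gel$b_mm * log10(gel$min_length_nt) + 4 * gel$sigma_mm
  grid <- seq(lo, hi, by = grid_step_mm)
  intensity <- numeric(length(grid))
  if (length(centers) > 0) {
    for (i in seq_along(centers)) {
      intensity <- intensity +
        frags$count[i] * stats::dnorm(grid, centers[i], gel$sigma_mm)
    }
  }
  structure(
    list(
      profile = tibble::tibble(distance_mm = grid, intensity = intensity),
      markers = tibble::as_tibble(markers),
      gel = gel,
      metadata = list(
        substrate = sub$name, length_nt = sub$length_nt,
        chi_status = sub$chi_status,
        inhibitor_uM = attr(frags, "inhibitor_uM"),
        n_molecules = attr(frags, "n_molecules"),
        n_off_gel = n_off_gel
      )
    ),
    class = "gel_lane"
  )
}

#' @export
print.gel_lane <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<gel_lane> %s (%g nt, %s) at %g uM inhibitor; %d profile points\n",
              md$substrate, md$length_nt, md$chi_status, md$inhibitor_uM,
              nrow(x$profile)))
  invisible(x)
}

#' Detect bands in a lane profile
#'
#' Finds local maxima above `min_rel_intensity` of the profile maximum.
#' Each peak's extent runs to the flanking local minima (or profile edges);
#' the band center is the intensity-weighted centroid over that extent (the
#' "middle of the band" convention) and the width is the full width at half
#' maximum. Overlapping species closer than about one point-spread merge
#' into a single band.
#'
#' @param lane A `gel_lane`.
#' @param min_rel_intensity Detection threshold relative to the profile
#'   maximum.
#' @return A tibble with columns `distance_mm`, `intensity`, `width_mm`,
#'   sorted by distance; zero rows for a flat or empty profile.
#' @export
detect_bands <- function(lane, min_rel_intensity = 0.05) {
  stopifnot(inherits(lane, "gel_lane"))
  d <- lane$profile$distance_mm
  y <- lane$profile$intensity
  n <- length(y)
  empty <- tibble::tibble(distance_mm = numeric(0), intensity = numeric(0),
                          width_mm = numeric(0))
  if (n < 3 || max(y) <= 0) return(empty)
  thr <- min_rel_intensity * max(y)
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                   y[2:(n - 1)] >= y[3:n] &
                   y[2:(n - 1)] >= thr) + 1L
  if (length(is_peak) == 0) return(empty)
  # valley boundaries: local minima (or edges) between consecutive peaks
  bands <- purrr::map_dfr(is_peak, function(p) {
    l <- p
    while (l > 1 && y[l - 1] <= y[l]) l <- l - 1
    r <- p
    while (r < n && y[r + 1] <= y[r]) r <- r + 1
    idx <- l:r
    centroid <- sum(d[idx] * y[idx]) / sum(y[idx])
    half <- y[p] / 2
    li <- p; while (li > l && y[li - 1] > half) li <- li - 1
    ri <- p; while (ri < r && y[ri + 1] > half) ri <- ri + 1
    tibble::tibble(distance_mm = centroid, intensity = y[p],
                   width_mm = d[ri] - d[li])
  })
  # plateaus can yield duplicate peak points; keep distinct centroids
  bands <- dplyr::distinct(bands,
                           .keep_all = TRUE,
                           dplyr::across("distance_mm"))
  bands <- dplyr::arrange(bands, .data$distance_mm)
  # maxima closer than one point-spread belong to one physical band
  merge_close <- function(b) {
    repeat {
      if (nrow(b) < 2) return(b)
      gap <- diff(b$distance_mm)
      i <- which(gap < lane_sigma)[1]
      if (is.na(i)) return(b)
      w <- b$intensity[i:(i + 1)]
      merged <- tibble::tibble(
        distance_mm = sum(b$distance_mm[i:(i + 1)] * w) / sum(w),
        intensity = max(w),
        width_mm = max(b$width_mm[i:(i + 1)])
      )
      b <- dplyr::bind_rows(
        if (i > 1) b[seq_len(i - 1), ], merged,
        if (i + 1 < nrow(b)) b[(i + 2):nrow(b), ]
      )
    }
  }
  lane_sigma <- if (!is.null(lane$gel)) lane$gel$sigma_mm else 0.8
  merge_close(bands)
}
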