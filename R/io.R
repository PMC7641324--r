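# Plain-text readers and writers: lane profiles as TSV with a JSON sidecar
# of markers and metadata, fragment sets and dose-response tables as TSV.

#' Write a cutting experiment to a directory
#'
#' Layout: `lanes/<lane>.tsv` (columns `distance_mm`, `intensity`),
#' `markers.json`, `index.tsv`, `truth.json` (generating parameters, for
#' recovery tests) and `manifest.json` (seed, gel parameters, lane count).
#'
#' @param experiment A `cutting_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cutting_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "cutting_experiment"))
  lane_dir <- file.path(dir, "lanes")
  dir.create(lane_dir, recursive = TRUE, showWarnings = FALSE)
  purrr::iwalk(experiment$lanes, function(lane, key) {
    readr::write_tsv(lane$profile, file.path(lane_dir, paste0(key, ".tsv")),
                     progress = FALSE)
  })
  readr::write_tsv(experiment$index, file.path(dir, "index.tsv"),
                   progress = FALSE)
  jsonlite::write_json(experiment$markers, file.path(dir, "markers.json"),
                       digits = NA)
  jsonlite::write_json(experiment$truth, file.path(dir, "truth.json"),
                       digits = NA)
  g <- experiment$gel
  jsonlite::write_json(
    list(seed = experiment$seed, n_lanes = length(experiment$lanes),
         gel = g[c("a_mm", "b_mm", "sigma_mm", "min_length_nt",
                   "max_length_nt")]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' Read a cutting experiment written by [write_cutting_experiment()]
#'
#' @param dir Directory containing `lanes/`, `index.tsv`, `markers.json`.
#' @return A `cutting_experiment` (without truth if `truth.json` is absent).
#' @export
read_cutting_experiment <- function(dir) {
  idx_path <- file.path(dir, "index.tsv")
  mk_path <- file.path(dir, "markers.json")
  if (!file.exists(idx_path) || !file.exists(mk_path)) {
    rlang::abort(
      sprintf("'%s' does not contain index.tsv and markers.json.", dir),
      class = "chirace_parse_error"
    )
  }
  index <- readr::read_tsv(idx_path, show_col_types = FALSE, progress = FALSE)
  markers <- tibble::as_tibble(jsonlite::fromJSON(mk_path))
  manifest <- if (file.exists(file.path(dir, "manifest.json"))) {
    jsonlite::fromJSON(file.path(dir, "manifest.json"))
  } else NULL
  gel <- if (!is.null(manifest$gel)) {
    do.call(gel_params, as.list(manifest$gel))
  } else gel_params()
  lanes <- purrr::map(index$lane, function(key) {
    prof <- readr::read_tsv(file.path(dir, "lanes", paste0(key, ".tsv")),
                            show_col_types = FALSE, progress = FALSE)
    row <- index[index$lane == key, ]
    structure(
      list(profile = prof, markers = markers, gel = gel,
           metadata = list(substrate = row$substrate,
                           length_nt = row$length_nt,
                           chi_status = row$chi_status,
                           inhibitor_uM = row$inhibitor_uM,
                           n_molecules = row$n_molecules)),
      class = "gel_lane"
    )
  })
  names(lanes) <- index$lane
  truth <- if (file.exists(file.path(dir, "truth.json"))) {
    tibble::as_tibble(jsonlite::fromJSON(file.path(dir, "truth.json")))
  } else NULL
  structure(
    list(lanes = lanes, index = index, truth = truth, gel = gel,
         markers = markers, seed = manifest$seed),
    class = "cutting_experiment"
  )
}

#' Write a fragment set as TSV
#'
#' Columns: `substrate`, `chi_status`, `inhibitor_uM`, `trigger`,
#' `fragment_length_nt`, `count`.
#'
#' @param frags A `fragment_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  stopifnot(inherits(frags, "fragment_set"))
  sub <- attr(frags, "substrate")
  out <- tibble::tibble(
    substrate = sub$name, chi_status = sub$chi_status,
    inhibitor_uM = attr(frags, "inhibitor_uM"),
    trigger = frags$trigger,
    fragment_length_nt = frags$fragment_length_nt, count = frags$count
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write dose-response tables
#'
#' Tab-separated with columns `inhibitor_uM`, `atp_uM`, `activity_fraction`,
#' `replicate`.
#'
#' @param x A dose-response tibble (for writing).
#' @param path TSV path.
#' @return The tibble (reading) or `path` invisibly (writing).
#' @export
write_dose_response <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
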