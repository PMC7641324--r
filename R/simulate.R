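# Event-driven race between the RecB and RecD motors on one substrate:
# Chi-triggered cut vs inhibitor-sensitized end-stop cut.

#' Deterministic end-stop cut position
#'
#' When RecD reaches the far end of a substrate of length `S`, RecB sits at
#' `S * r` (r = RecB:RecD velocity ratio) and, after the slow nuclease swing,
#' cuts `advance_nt` further along. If that position reaches the end of the
#' substrate there is no internal cut.
#'
#' @param S Substrate length, nt.
#' @param r Velocity ratio in (0, 1].
#' @param advance_nt Mean advance during the nuclease swing, nt.
#' @return Cut distance from entry in nt, or `NA` when the cut would fall at
#'   or beyond the substrate end.
#' @examples
#' predicted_cut_position(4350, 0.30, 200)  # 1505
#' predicted_cut_position(1000, 0.95, 200)  # NA: runs off the end
#' @export
predicted_cut_position <- function(S, r, advance_nt) {
  if (S <= 0 || advance_nt < 0) {
    rlang::abort("Need S > 0 and advance_nt >= 0.",
                 class = "chirace_invalid_parameter")
  }
  if (r <= 0 || r > 1) {
    rlang::abort("`r` must lie in (0, 1].",
                 class = "chirace_invalid_parameter")
  }
  pos <- S * r + advance_nt
  if (pos < S) pos else NA_real_
}

#' Single-stranded loop size between the two motors
#'
#' RecD outruns RecB, so single-stranded DNA accumulates between them at
#' rate `v_D - v_B`; the loop at time `t` (before RecD reaches the end) is
#' `(v_D - v_B) * t`.
#'
#' @param enz An [enzyme_params()] object.
#' @param cond A [reaction_conditions()] object.
#' @param t_ms Time since initiation, ms.
#' @return Loop size in nt (0 when the motors run at equal speed).
#' @export
loop_size <- function(enz, cond, t_ms) {
  stopifnot(t_ms >= 0)
  rp <- lookup_race_params(enz, cond)
  out <- (rp$v_d - rp$v_b) * t_ms
  if (any(out < 0)) {
    rlang::abort("RecB faster than RecD: loop geometry violated.",
                 class = "chirace_invalid_parameter")
  }
  out
}

# Internal vectorized engine: one row per molecule.
simulate_cuts <- function(n, sub, enz, cond) {
  stopifnot(nrow(sub) == 1L)
  S <- sub$length_nt
  rp <- lookup_race_params(enz, cond)
  r <- rp$ratio
  if (r <= 0 || r > 1) {
    rlang::abort("Velocity ratio outside (0, 1].",
                 class = "chirace_invalid_parameter")
  }
  if (rp$v_d <= 0) {
    rlang::abort("RecD velocity must be positive.",
                 class = "chirace_invalid_parameter")
  }
  cv <- enz$swing$cv
  chi_dist <- chi_cut_from_entry(sub)
  t_end <- S / rp$v_d

  # race: Chi fires only if RecB reaches it before RecD reaches the end
  chi_in_race <- !is.na(chi_dist) && chi_dist < r * S
  chi_hit <- if (chi_in_race) {
    stats::runif(n) < enz$p_chi_recognition
  } else rep(FALSE, n)

  p_sens <- cond$inhibitor_uM / (cond$inhibitor_uM + enz$k_sens_uM)
  sens <- !chi_hit & stats::runif(n) < p_sens

  trigger <- rep("none", n)
  position <- rep(NA_real_, n)
  time_ms <- rep(NA_real_, n)

  if (any(chi_hit)) {
    k <- sum(chi_hit)
    # Chi cuts are pinned near the Chi-directed position: +/-1 nt jitter
    jitter <- sample(c(-1, 0, 1), k, replace = TRUE)
    position[chi_hit] <- pmin(S, pmax(0, chi_dist + jitter))
    delay <- if (cv > 0) {
      stats::rgamma(k, shape = 1 / cv^2, rate = 1 / (cv^2 * enz$swing$tau_chi_ms))
    } else rep(enz$swing$tau_chi_ms, k)
    time_ms[chi_hit] <- chi_dist / rp$v_b + delay
    trigger[chi_hit] <- "chi"
  }
  if (any(sens)) {
    k <- sum(sens)
    g <- if (cv > 0) {
      stats::rgamma(k, shape = 1 / cv^2, rate = 1 / cv^2)  # mean 1, cv = cv
    } else rep(1, k)
    adv <- rp$advance_nt * g
    position[sens] <- pmin(S, S * r + adv)
    time_ms[sens] <- t_end + adv / rp$v_b
    trigger[sens] <- "end_stop"
  }
  tibble::tibble(trigger = trigger, position_nt = position, time_ms = time_ms)
}

#' Simulate one unwinding trajectory
#'
#' Runs the race for a single molecule: RecB heads for the Chi site (if one
#' is present and correctly oriented) at velocity `v_B` while RecD heads for
#' the far end at `v_D`. If RecB reaches Chi first and recognizes it, the
#' nuclease swings quickly (~1 ms) and cuts at the Chi-directed position. If
#' instead RecD reaches the end first, the inhibitor-sensitized enzyme cuts
#' with probability `[I]/([I] + k_sens)` at RecB's position after the slow
#' swing; otherwise the molecule is unwound full length without a cut.
#'
#' @param sub A one-row [substrate_spec()].
#' @param enz An [enzyme_params()] object.
#' @param cond A [reaction_conditions()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return A one-row tibble: `trigger` (`"chi"`, `"end_stop"` or `"none"`),
#'   `position_nt` (cut distance from entry; `NA` when uncut), `time_ms`.
#' @export
simulate_molecule <- function(sub, enz, cond, seed = NULL) {
  run <- function() simulate_cuts(1L, sub, enz, cond)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a population of molecules into a fragment set
#'
#' Repeats the race for `n` molecules and aggregates the 5'-labeled fragment
#' lengths. A cut at distance `p` from entry leaves a labeled fragment of
#' `S - p` nt (the label sits at the end distal to entry); uncut molecules
#' contribute a full-length band.
#'
#' @inheritParams simulate_molecule
#' @param n Number of molecules (>= 1).
#' @return A `fragment_set`: a tibble with columns `trigger`,
#'   `fragment_length_nt`, `count`, plus attributes `n_molecules`,
#'   `full_length_count`, `substrate` (the substrate_spec row) and `inhibitor_uM`.
#' @examples
#' sub <- make_default_substrates()[1, ]
#' fs <- simulate_population(200, sub, default_enzyme(),
#'                           reaction_conditions(inhibitor_uM = 0), seed = 1)
#' head(fs)
#' @export
simulate_population <- function(n, sub, enz, cond, seed = NULL) {
  if (n < 1) rlang::abort("`n` must be >= 1.",
                          class = "chirace_invalid_parameter")
  run <- function() simulate_cuts(as.integer(n), sub, enz, cond)
  sim <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  S <- sub$length_nt
  frag <- dplyr::mutate(
    sim,
    fragment_length_nt = ifelse(is.na(.data$position_nt), S,
                                S - .data$position_nt)
  )
  out <- frag |>
    dplyr::count(.data$trigger, .data$fragment_length_nt, name = "count") |>
    dplyr::arrange(.data$fragment_length_nt)
  # a cut exactly at the substrate end leaves no labeled fragment
  dropped <- out$fragment_length_nt <= 0
  if (any(dropped)) out <- out[!dropped, , drop = FALSE]
  structure(
    out,
    n_molecules = as.integer(n),
    full_length_count = sum(sim$trigger == "none"),
    substrate = sub,
    inhibitor_uM = cond$inhibitor_uM,
    class = c("fragment_set", class(out))
  )
}
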