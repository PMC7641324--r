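test_that("deterministic end-stop position follows the race formula", {
  expect_equal(predicted_cut_position(4350, 0.30, 200), 1505)
  expect_true(is.na(predicted_cut_position(1000, 0.95, 200)))
  expect_equal(predicted_cut_position(4350, 0.70, 0), 3045)
  expect_error(predicted_cut_position(4350, 1.2, 0),
               class = "chirace_invalid_parameter")
  expect_error(predicted_cut_position(-1, 0.5, 0),
               class = "chirace_invalid_parameter")
})

test_that("single-molecule race matches the closed forms when noiseless", {
  # S = 2270 with Chi 1300 nt from entry: Chi wins iff r > 1300/2270
  sub <- chi_plus_sub(2270)          # chi 970 from label = 1300 from entry
  enz <- enzyme_cv0()
  m <- simulate_molecule(sub, enz, table_cond(25), seed = 1)   # r = 0.70
  expect_equal(m$trigger, "chi")
  expect_true(abs(m$position_nt - 1300) <= 1)

  # same race with RecB slowed to r = 0.5 flips the outcome; a huge
  # inhibitor concentration makes the end-stop sensitization near-certain
  cal <- tibble::tibble(inhibitor_uM = 1e6, ratio = 0.5, advance_nt = 200)
  enz_slow <- enzyme_cv0(calibration = cal)
  m2 <- simulate_molecule(sub, enz_slow, table_cond(1e6), seed = 1)
  expect_equal(m2$trigger, "end_stop")
  expect_equal(m2$position_nt, 2270 * 0.5 + 200)

  # no inhibitor, no Chi: nothing triggers a cut
  m3 <- simulate_molecule(chi_zero_sub(2270), enz, table_cond(0), seed = 1)
  expect_equal(m3$trigger, "none")
  expect_true(is.na(m3$position_nt))
})

test_that("noiseless simulation agrees with the closed-form oracle", {
  # randomized small cases: cv = 0, p_chi = 1, sensitization forced on
  set.seed(101)
  for (i in 1:25) {
    S <- round(runif(1, 500, 5000))
    r <- runif(1, 0.2, 0.95)
    adv <- runif(1, 0, 300)
    chi_entry <- round(runif(1, 50, S - 50))
    cal <- tibble::tibble(inhibitor_uM = 1e6, ratio = r, advance_nt = adv)
    enz <- enzyme_cv0(calibration = cal)     # p_sens ~ 1 at I = 1e6
    sub <- chi_plus_sub(S, chi_from_label = S - chi_entry)
    m <- simulate_molecule(sub, enz, table_cond(1e6), seed = i)
    if (chi_entry < r * S) {
      expect_equal(m$trigger, "chi")
      expect_true(abs(m$position_nt - chi_entry) <= 1)
    } else {
      oracle <- predicted_cut_position(S, r, adv)
      expect_equal(m$trigger, "end_stop")
      expect_equal(m$position_nt, min(S, S * r + adv))
      if (!is.na(oracle)) expect_equal(m$position_nt, oracle)
    }
  }
})

test_that("labeled fragment length and cut distance always sum to S", {
  sub <- chi_plus_sub(4350)
  enz <- default_enzyme()
  for (I in c(0, 50, 400)) {
    fs <- simulate_population(400, sub, enz, table_cond(I), seed = I + 9)
    sim_total <- attr(fs, "n_molecules")
    expect_equal(sum(fs$count), sim_total)
    cut <- fs[fs$trigger != "none", ]
    expect_true(all(cut$fragment_length_nt > 0 &
                    cut$fragment_length_nt <= sub$length_nt))
    full <- fs[fs$trigger == "none", ]
    if (nrow(full) > 0) {
      expect_true(all(full$fragment_length_nt == sub$length_nt))
      expect_equal(sum(full$count), attr(fs, "full_length_count"))
    }
  }
})

test_that("population means converge to the law-of-large-numbers limits", {
  # end-stop mean fragment length -> S(1 - r) - advance
  sub <- chi_zero_sub(4350)
  enz <- default_enzyme()                     # cv = 0.2
  fs <- simulate_population(10000, sub, enz, table_cond(400), seed = 5)
  es <- fs[fs$trigger == "end_stop", ]
  m <- sum(es$fragment_length_nt * es$count) / sum(es$count)
  sdev <- sqrt(sum(es$count * (es$fragment_length_nt - m)^2) / sum(es$count))
  se <- sdev / sqrt(sum(es$count))
  expect_lt(abs(m - (4350 * 0.7 - 200)), 3 * se)
})

test_that("simulation is reproducible under a fixed seed", {
  sub <- chi_plus_sub(2270)
  enz <- default_enzyme()
  a <- simulate_population(500, sub, enz, table_cond(100), seed = 42)
  b <- simulate_population(500, sub, enz, table_cond(100), seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_population(500, sub, enz, table_cond(100), seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("Chi-triggered cuts stay within a 3-nucleotide window", {
  fs <- simulate_population(10000, chi_plus_sub(4350), default_enzyme(),
                            table_cond(0), seed = 8)
  chi <- fs[fs$trigger == "chi", ]
  expect_gt(sum(chi$count), 0)
  span <- diff(range(chi$fragment_length_nt))
  expect_lte(span, 3)
})

test_that("end-stop fragment length grows with inhibitor concentration", {
  sub <- chi_zero_sub(4350)
  enz <- default_enzyme()
  means <- vapply(c(25, 50, 100, 200, 400), function(I) {
    fs <- simulate_population(3000, sub, enz, table_cond(I), seed = I)
    es <- fs[fs$trigger == "end_stop", ]
    sum(es$fragment_length_nt * es$count) / sum(es$count)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("loop between the motors grows at the velocity difference", {
  enz <- enzyme_params(recB = motor_kinetics(0.7, 400, 10),
                       recD = motor_kinetics(1.0, 400, 73))
  cond <- kinetic_cond(1e9)  # saturating: v_D ~ 1, v_B ~ 0.7
  expect_equal(loop_size(enz, cond, 1000), 300, tolerance = 1e-3)
  expect_equal(loop_size(enz, cond, 0), 0)
  t <- seq(0, 2000, by = 250)
  expect_true(all(diff(loop_size(enz, cond, t)) >= 0))
  # equal motors: zero loop at all times
  enz_eq <- enzyme_params(recB = motor_kinetics(1, 400, 10),
                          recD = motor_kinetics(1, 400, 10))
  expect_equal(loop_size(enz_eq, cond, 500), 0)
})
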