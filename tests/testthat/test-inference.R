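test_that("band lengths are estimated by interpolation against the ladder", {
  g <- gel_params()
  sub <- chi_plus_sub(4350)
  enz <- enzyme_cv0()
  fs <- simulate_population(1000, sub, enz, table_cond(0), seed = 3)
  lane <- render_lane(fs, g)
  bands <- estimate_band_lengths(lane)
  main <- bands[which.max(bands$intensity), ]
  expect_lt(abs(main$length_nt - 970) / 970, 0.01)
  expect_false(main$is_full_length)

  # a Chi-free, uninhibited lane has only the full-length band
  fs0 <- simulate_population(500, chi_zero_sub(2270), enz, table_cond(0),
                             seed = 4)
  b0 <- estimate_band_lengths(render_lane(fs0, g))
  expect_equal(nrow(b0), 1)
  expect_true(b0$is_full_length)
  expect_equal(b0$length_nt, 2270, tolerance = 0.01)
})

test_that("bands outside the marker span are flagged, not dropped", {
  g <- gel_params()
  sub <- chi_zero_sub(2270)
  mk <- default_marker_ladder(g, lengths_nt = c(2270, 1000, 500))
  fs <- structure(
    tibble::tibble(trigger = "end_stop", fragment_length_nt = 300,
                   count = 100L),
    n_molecules = 100L, full_length_count = 0L, substrate = sub,
    inhibitor_uM = 100, class = c("fragment_set", class(tibble::tibble()))
  )
  lane <- render_lane(fs, g, markers = mk)
  expect_warning(bands <- estimate_band_lengths(lane), "marker span")
  expect_equal(nrow(bands), 1)
  expect_false(bands$in_span)
  expect_true(is.na(bands$length_nt))
})

test_that("product-vs-substrate OLS recovers collinear points exactly", {
  pts <- tibble::tibble(substrate_length_nt = c(1340, 2270, 4350),
                        product_length_nt = c(152, 431, 1055))
  fit <- suppressWarnings(fit_product_vs_substrate(pts))
  expect_equal(fit$slope, 0.300, tolerance = 1e-12)
  expect_equal(fit$intercept, -250, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  td <- tidy(fit)
  expect_equal(td$estimate, c(-250, 0.3), tolerance = 1e-9)

  # two points: exact line, standard errors flagged undefined
  two <- pts[1:2, ]
  f2 <- fit_product_vs_substrate(two)
  expect_equal(f2$slope, (431 - 152) / (2270 - 1340))
  expect_true(is.na(f2$se_slope))

  expect_error(fit_product_vs_substrate(pts[c(1, 1), ]),
               class = "chirace_fit_error")
})

test_that("OLS slope estimator is unbiased on noisy synthetic triples", {
  set.seed(55)
  S <- c(1340, 2270, 4350)
  slopes <- replicate(100, {
    y <- 0.3 * S - 250 + rnorm(3, 0, 30)
    fit_product_vs_substrate(
      tibble::tibble(substrate_length_nt = S, product_length_nt = y))$slope
  })
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.3), 2 * se_mean)
})

test_that("ratio and delay recovery inverts the product-length model", {
  mkfit <- function(slope, intercept) {
    pts <- tibble::tibble(substrate_length_nt = c(1000, 2000, 4000))
    pts$product_length_nt <- slope * pts$substrate_length_nt + intercept
    suppressWarnings(fit_product_vs_substrate(pts))
  }
  rec <- recover_ratio_and_delay(mkfit(0.3, -250), v_b_nt_per_ms = 1)
  expect_equal(rec$ratio, 0.7)
  expect_equal(rec$advance_nt, 250)
  expect_equal(rec$tau_ms, 250)
  # the -200 nt intercept at the highest dose maps to a ~200 ms swing
  expect_equal(recover_ratio_and_delay(mkfit(0.7, -200), 1)$tau_ms, 200)
  expect_equal(recover_ratio_and_delay(mkfit(0.5, 0), 1)$advance_nt, 0)
  expect_warning(rec2 <- recover_ratio_and_delay(mkfit(0.5, 40), 1),
                 "clamped")
  expect_equal(rec2$advance_nt, 0)
  expect_true(rec2$advance_clamped)
  expect_error(recover_ratio_and_delay(mkfit(1.2, -100), 1),
               class = "chirace_fit_error")
})

test_that("4PL dose-response fit recovers the rate-law IC50", {
  # noiseless data generated by the competitive model are an exact 4PL
  # with hill 1; the fitted IC50 must match the closed form within 2%
  kin <- std_kin()
  dr <- generate_nuclease_assay(ki_uM = std_ki, km_uM = std_km, atp_uM = 25,
                                concentrations_uM = c(0, 1.25, 2.5, 5, 10,
                                                      20, 40, 80),
                                replicates = 1, noise_cv = 0)
  fit <- fit_dose_response(dr)
  expect_equal(fit$ic50_uM, cheng_prusoff_ic50(kin, 25), tolerance = 0.02)
  expect_equal(fit$hill, 1, tolerance = 0.01)

  # constant background shifts bottom, not the IC50
  dr2 <- dr
  dr2$activity_fraction <- 0.1 + dr2$activity_fraction
  fit2 <- fit_dose_response(dr2)
  expect_equal(fit2$bottom, 0.1, tolerance = 0.02)
  expect_equal(fit2$ic50_uM, fit$ic50_uM, tolerance = 0.02)

  expect_error(
    fit_dose_response(tibble::tibble(inhibitor_uM = c(0, 5, 10),
                                     activity_fraction = c(1, 0.5, 0.3))),
    class = "chirace_fit_error")
})

test_that("noisy recovery falls inside classical 95% CIs at nominal rate", {
  # measurement noise sigma = 30 nt on the product lengths; the OLS CI for
  # the slope and intercept should cover the truth in >= 90% of replicates
  set.seed(77)
  S <- c(1340, 2270, 4350)
  n_rep <- 200
  cover <- replicate(n_rep, {
    y <- 0.4 * S - 250 + rnorm(3, 0, 30)
    f <- fit_product_vs_substrate(
      tibble::tibble(substrate_length_nt = S, product_length_nt = y))
    tcrit <- qt(0.975, df = 1)
    c(abs(f$slope - 0.4) <= tcrit * f$se_slope,
      abs(f$intercept + 250) <= tcrit * f$se_intercept)
  })
  expect_gte(mean(cover[1, ]), 0.90)
  expect_gte(mean(cover[2, ]), 0.90)
})

test_that("experiment-level inference recovers the calibration table", {
  enz <- enzyme_cv0()
  ex <- generate_cutting_experiment(
    substrates = make_default_substrates()[
      make_default_substrates()$chi_status == "chi_zero", ],
    concentrations_uM = c(50, 400), enz = enz, n_molecules = 800, seed = 19
  )
  fits <- suppressWarnings(infer_cutting_experiment(ex))
  truth <- ex$truth
  for (conc in c(50, 400)) {
    got <- fits[fits$inhibitor_uM == conc, ]
    want <- truth[truth$inhibitor_uM == conc, ]
    expect_equal(got$ratio, want$ratio, tolerance = 0.01)
    expect_equal(got$advance_nt, want$advance_nt, tolerance = 0.01)
  }
})
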