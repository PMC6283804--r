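# TIA integration, TIACs, S-factors, doses, uncertainty combination,
# prescription, and dose-table summaries.

test_that("piecewise TIA matches the adaptive-quadrature oracle", {
  res <- integrate_tia(100, 12.6, 3, 48)
  oracle <- tia_quadrature(100, 12.6, 3, 48, 17)
  expect_lt(abs(res$tia_MBq_h - oracle) / oracle, 1e-3)
  expect_equal(res$tia_MBq_h, 2021, tolerance = 1e-3)
  expect_equal(res$rise_MBq_h, 150)
  expect_equal(res$body_MBq_h, 1665.0, tolerance = 1e-4)
  expect_equal(res$tail_MBq_h, 206.3, tolerance = 1e-3)
  # segments sum to the total
  expect_equal(res$rise_MBq_h + res$body_MBq_h + res$tail_MBq_h,
               res$tia_MBq_h)
})

test_that("TIA limit cases behave analytically", {
  # t1 -> 0, t3 -> infinity: pure exponential, A * T_eff / ln 2
  res <- integrate_tia(100, 12.6, 0, 1e4)
  expect_equal(res$tia_MBq_h, 100 * 12.6 / log(2), tolerance = 1e-9)

  # T_eff = T_phys: the tail is continuous with the body, t3 drops out
  r1 <- integrate_tia(100, 17, 3, 24)
  r2 <- integrate_tia(100, 17, 3, 48)
  expect_equal(r1$tia_MBq_h, r2$tia_MBq_h, tolerance = 1e-12)
  expect_equal(r1$tia_MBq_h, 100 * (1.5 + 17 / log(2)), tolerance = 1e-12)

  expect_error(integrate_tia(100, -1, 3, 48), "positive")
  expect_error(integrate_tia(Inf, 12.6, 3, 48), "finite")
})

test_that("TIA property grid: quadrature agreement, additivity, monotonicity, bound", {
  lam_p <- log(2) / 17
  grid <- expand.grid(t1 = c(1, 3, 5, 8), t3 = c(24, 48, 72),
                      T_eff = c(4, 8, 12.6, 15, 17), A = c(40, 100))
  grid <- grid[seq_len(nrow(grid)) %% 1 == 0, ][1:100, ]
  prev_by_teff <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- integrate_tia(g$A, g$T_eff, g$t1, g$t3)
    oracle <- tia_quadrature(g$A, g$T_eff, g$t1, g$t3, 17)
    expect_lt(abs(res$tia_MBq_h - oracle) / oracle, 1e-3)
    expect_equal(res$rise_MBq_h + res$body_MBq_h + res$tail_MBq_h,
                 res$tia_MBq_h, tolerance = 1e-12)
    # physical upper bound with full retention at injection
    A0 <- g$A
    A_t1_max <- A0 * exp(-lam_p * g$t1)
    res_max <- integrate_tia(A_t1_max, g$T_eff, g$t1, g$t3)
    expect_lte(tiac(res_max$tia_MBq_h, A0), 17 / log(2) + 1e-9)
  }
  # strictly increasing in T_eff and in A(t1)
  tias <- vapply(c(6, 10, 14, 17),
                 function(Te) integrate_tia(100, Te, 3, 48)$tia_MBq_h, 0)
  expect_true(all(diff(tias) > 0))
  tias_A <- vapply(c(50, 100, 150),
                   function(A) integrate_tia(A, 12.6, 3, 48)$tia_MBq_h, 0)
  expect_true(all(diff(tias_A) > 0))
})

test_that("single-point TIA uses the assumed half-life from t1 to infinity", {
  res <- integrate_tia(100, 12.6, 3, last_scan_h = NULL)
  expect_equal(res$tia_MBq_h, 100 * (1.5 + 12.6 / log(2)), tolerance = 1e-12)
  expect_equal(res$body_MBq_h, 0)
  res_p <- integrate_tia(100, 17, 3, last_scan_h = NULL)
  expect_equal(res_p$tia_MBq_h, 100 * (1.5 + 17 / log(2)), tolerance = 1e-12)
})

test_that("TIAC is the TIA per injected activity", {
  expect_equal(tiac(2021.3, 6000), 0.33688, tolerance = 1e-4)
  expect_equal(tiac(0, 1000), 0)
  expect_equal(tiac(1234, 1234), 1)
  expect_error(tiac(100, 0), "positive")
})

test_that("local-deposition S-factor converts beta energy per unit mass", {
  expect_equal(sfactor_local_beta(0.1), 4.40, tolerance = 1e-3)
  expect_equal(sfactor_local_beta(0.2), sfactor_local_beta(0.1) / 2)
  expect_error(sfactor_local_beta(0), "positive")
})

test_that("organ dose chains TIAC, S-factor and injected activity", {
  d <- organ_dose(0.3369, A0_MBq = 2000, mass_kg = 0.1)
  expect_equal(d$normalized_mGy_per_MBq, 1.482, tolerance = 1e-3)
  expect_equal(d$absolute_Gy, 2.96, tolerance = 2e-3)

  # doubling the mass halves the default normalized dose
  d2 <- organ_dose(0.3369, 2000, 0.2)
  expect_equal(d2$normalized_mGy_per_MBq, d$normalized_mGy_per_MBq / 2)

  # doubling A0 doubles absolute, leaves normalized unchanged
  d3 <- organ_dose(0.3369, 4000, 0.1)
  expect_equal(d3$absolute_Gy, 2 * d$absolute_Gy)
  expect_equal(d3$normalized_mGy_per_MBq, d$normalized_mGy_per_MBq)

  # reference-table route with mass scaling
  tab <- tibble::tibble(region = "liver", ref_mass_kg = 1.8,
                        S_mGy_per_MBq_h = 2.4)
  dt <- organ_dose(0.5, 2000, 1.2, region = "liver", s_table = tab)
  expect_equal(dt$S_mGy_per_MBq_h, 2.4 * 1.8 / 1.2)
  expect_error(organ_dose(0.5, 2000, 1.2, region = "lungs", s_table = tab),
               "missing")
})

test_that("sphere S interpolation is exact at nodes and along a 1/m law", {
  tab <- sphere_s_table()
  # node: volume such that mass hits a node exactly
  node_mass <- tab$mass_g[7]
  d <- tumor_dose_sphere(1, 1000, node_mass / 1.03, s_table = tab,
                         small_volume_warn_mL = 0)
  expect_equal(d$S_mGy_per_MBq_h, tab$S_mGy_per_MBq_h[7], tolerance = 1e-12)

  # halfway in log-mass between nodes, an S ~ 1/m series interpolates exactly
  m_half <- exp(mean(log(tab$mass_g[7:8])))
  d2 <- tumor_dose_sphere(1, 1000, m_half / 1.03, s_table = tab,
                          small_volume_warn_mL = 0)
  expect_equal(d2$S_mGy_per_MBq_h, sfactor_local_beta(m_half / 1000),
               tolerance = 1e-6)

  # very small tumors are flagged but still dosed
  expect_warning(d3 <- tumor_dose_sphere(0.3369, 1637, 2.3),
                 "partial-volume")
  expect_true(is.finite(d3$absolute_Gy) && d3$absolute_Gy > 0)
  expect_error(tumor_dose_sphere(1, 1000, -5), "positive")
})

test_that("administered-activity uncertainty adds in quadrature", {
  expect_equal(round(administered_activity_uncertainty(c(0.5, 3, 10)), 1), 10.5)
  expect_equal(administered_activity_uncertainty(7), 7)
  expect_equal(administered_activity_uncertainty(c(3, 4)), 5)
  expect_error(administered_activity_uncertainty(c(-1, 2)), ">= 0")
})

test_that("activity prescription clamps the per-volume rate", {
  expect_equal(prescribe_activity(100, 37), 3700)
  expect_equal(prescribe_activity(10, 120), 10 * 92.5)
  expect_equal(prescribe_activity(500, 10), 500 * 14.8)
  expect_error(prescribe_activity(0), "positive")
})

test_that("dose-table summaries are recomputed from body rows", {
  dt <- lipiodol_dose_summary()
  s <- dt$summary
  tum <- s[s$region == "tumor", ]
  expect_equal(tum$n, 14)
  expect_equal(round(tum$norm_mean, 1), 23.5)
  expect_equal(round(tum$norm_min, 2), 2.32)
  expect_equal(round(tum$norm_max, 2), 162.49)
  lun <- s[s$region == "lungs", ]
  expect_equal(lun$n, 13) # one missing entry excluded
  # absolute doses recompute from normalized x A0
  expect_equal(round(tum$abs_max_Gy, 0), 266)

  # single-row table: mean = min = max, SD 0 by convention
  one <- suppressMessages(summarize_dose_table(
    tibble::tibble(patient_id = "a", region = "liver",
                   normalized_mGy_per_MBq = 2.5),
    tibble::tibble(patient_id = "a", A0_MBq = 2000)
  ))
  expect_equal(one$summary$norm_mean, 2.5)
  expect_equal(one$summary$norm_sd, 0)
  expect_equal(one$summary$abs_mean_Gy, 5)

  expect_error(summarize_dose_table(
    tibble::tibble(patient_id = "a", region = "liver",
                   normalized_mGy_per_MBq = NA_real_),
    tibble::tibble(patient_id = "a", A0_MBq = 2000)
  ), "no valid entries")
})
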