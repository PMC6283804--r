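# Synthetic cohort generator: sampling distributions, projection physics,
# counting model, and dataset assembly.

test_that("cohort sampling is reproducible and respects its invariants", {
  a <- sample_cohort(3, seed = 7)
  b <- sample_cohort(3, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$T_eff_h > 2 & a$T_eff_h <= 17))
  expect_true(all(a$uptake_fraction > 0 & a$uptake_fraction < 1))
  sums <- tapply(a$uptake_fraction, a$patient_id, sum)
  expect_true(all(sums <= 1))
  expect_true(all(a$T_eff_h <= a$T_phys_h))
  c <- sample_cohort(3, seed = 8)
  expect_false(identical(a$T_eff_h, c$T_eff_h))
})

test_that("truncated-normal draws match the quadrature mean of the truncated density", {
  set.seed(1)
  x <- rtrunc_norm(10000, 12.6, 1.7, 2, 17)
  oracle <- truncnorm_mean_quadrature(12.6, 1.7, 2, 17)
  expect_lt(abs(mean(x) - oracle), 0.1)
  expect_true(all(x > 2 & x <= 17))
})

test_that("degenerate SD gives the mean exactly; bad truncation errors", {
  params <- cohort_population()
  params$teff_sd_h <- 0
  coh <- sample_cohort(1, params = params, seed = 1)
  expect_equal(coh$T_eff_h, params$teff_mean_h[match(coh$region, params$region)])
  expect_error(rtrunc_norm(5, 10, 0, 12, 17), "outside the truncation")
  expect_error(rtrunc_norm(5, 100, 1, 2, 17), "probability mass")
  expect_error(sample_cohort(0), ">= 1")
})

test_that("projection without attenuation conserves counts and is view-symmetric", {
  geom <- slab_geometry()
  act <- array(0, geom$shape)
  act[5, 8, 5] <- 3.7 # point source
  ant <- project_planar(act, geom, "anterior", attenuation = FALSE,
                        cal_cps_per_MBq = 6)
  post <- project_planar(act, geom, "posterior", attenuation = FALSE,
                         cal_cps_per_MBq = 6)
  expect_equal(ant, mirror_lr(post))
  expect_equal(sum(ant), 3.7 * 6)

  # uniform slab: each in-slab pixel integrates thickness x voxel activity
  act2 <- array(0, geom$shape)
  act2[3:7, 4:9, 3:7] <- 0.25
  img <- project_planar(act2, geom, "anterior", attenuation = FALSE,
                        cal_cps_per_MBq = 2)
  expect_equal(img[5, 5], 6 * 0.25 * 2) # 6 voxels deep
  expect_equal(img[1, 1], 0)
})

test_that("conjugate-view geometric mean of a point source is depth-invariant", {
  geom <- slab_geometry(mu_cm = 0.15)
  labels <- voxelize(geom)
  mu <- 0.15
  thickness_cm <- geom$shape[2] * geom$voxel_mm / 10
  expected <- exp(-mu * thickness_cm / 2)
  for (depth in c(3L, 8L, 12L)) {
    act <- array(0, geom$shape)
    act[5, depth, 5] <- 1
    ant <- project_planar(act, geom, "anterior", TRUE, labels)
    post <- project_planar(act, geom, "posterior", TRUE, labels)
    gm <- sqrt(ant[5, 5] * mirror_lr(post)[5, 5])
    expect_equal(gm, expected, tolerance = 1e-6)
  }
})

test_that("counting model applies the paralyzable loss factor before Poisson draws", {
  rates <- matrix(c(30000, 20000), 1, 2) # total 50 kcps
  lam <- apply_counting_model(rates, tau_s = 1e-6, duration_s = 2,
                              poisson = FALSE)
  expect_equal(lam, rates * exp(-0.05) * 2, tolerance = 1e-12)

  # tau = 0: observed mean over repeated draws matches duration x rate
  r <- matrix(c(50, 80), 1, 2)
  draws <- replicate(200, sum(apply_counting_model(r, 0, 1)))
  se <- sqrt(sum(r)) / sqrt(200)
  expect_lt(abs(mean(draws) - sum(r)), 3 * se)

  expect_identical(apply_counting_model(matrix(0, 2, 2), 1e-6, 10),
                   matrix(0L, 2, 2) * 1L)
  expect_error(apply_counting_model(matrix(-1, 1, 1), 0, 1), "non-negative")
  expect_error(apply_counting_model(matrix(1, 1, 1), -1, 1), ">= 0")
})

test_that("phantom labels are exclusive, tumor sits inside the liver, volumes are consistent", {
  geom <- phantom_geometry()
  labels <- voxelize(geom)
  expect_true(all(labels %in% region_codes()))
  vols <- region_volumes(labels, geom$voxel_mm)
  for (rn in c("tumor", "liver", "lungs", "stomach", "spleen", "kidneys")) {
    row <- geom$regions[geom$regions$region == rn, ]
    analytic <- 4 / 3 * pi * row$a_mm * row$b_mm * row$c_mm / 1000
    vox_vol <- vols$volume_mL[vols$region == rn]
    if (rn == "liver") {
      vox_vol <- vox_vol + vols$volume_mL[vols$region == "tumor"]
    }
    # voxelized volume within one voxel-shell of the analytic ellipsoid
    shell <- surface_shell_mL(row, geom$voxel_mm)
    expect_lt(abs(vox_vol - analytic), shell)
  }
  # moving the tumor outside the liver is rejected
  bad <- phantom_regions()
  bad$cx_mm[bad$region == "tumor"] <- 100
  expect_error(phantom_geometry(regions = bad), "not fully contained")
})

test_that("noiseless datasets conserve activity exactly and decay by construction", {
  kin <- exact_kinetics()
  pat <- noiseless_patient(kin)
  expect_equal(sum(pat$spect$activity),
               sum(kin$uptake_fraction) * kin$A0_MBq[1],
               tolerance = 1e-9)
  # planar-derived rate ratios equal the ground-truth decay factors
  tacs <- extract_relative_tacs(pat)
  for (rn in unique(tacs$region)) {
    g <- tacs[tacs$region == rn, ]
    T_true <- kin$T_eff_h[kin$region == rn]
    expect_equal(g$rate[2] / g$rate[1], 2^(-(21) / T_true), tolerance = 1e-9)
    expect_equal(g$rate[3] / g$rate[1], 2^(-(45) / T_true), tolerance = 1e-9)
  }
})

test_that("two-scan patients carry two planar pairs and remain analysable", {
  kin <- exact_kinetics(scan_times = c(3, 24))
  pat <- noiseless_patient(kin)
  expect_length(pat$scans, 2L)
  expect_true(is.na(pat$record$t3_h))
  tacs <- extract_relative_tacs(pat)
  expect_equal(nrow(tacs[tacs$region == "liver", ]), 2L)
  fits <- fit_tacs(tacs)
  expect_equal(fits$T_eff_h[fits$region == "liver"], 12.6, tolerance = 1e-9)
})

test_that("identical seeds give bit-identical noisy datasets", {
  kin <- patient_kinetics(uptake_fractions = 0.4, T_eff_h = 12.6,
                          regions = "liver", tau_s = 1e-6)
  p1 <- build_patient(kin, noise = TRUE, seed = 11)
  p2 <- build_patient(kin, noise = TRUE, seed = 11)
  expect_identical(p1$scans[[2]]$anterior, p2$scans[[2]]$anterior)
  expect_identical(p1$spect$activity, p2$spect$activity)
})
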