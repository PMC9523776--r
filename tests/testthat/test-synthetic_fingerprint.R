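test_that("the default sebum profile is TG-dominated and seed-reproducible", {
  p1 <- default_sebum_profile(3)
  p2 <- default_sebum_profile(3)
  expect_identical(p1, p2)
  totals <- tapply(p1$species$abundance, p1$species$class, sum)
  expect_identical(names(which.max(totals)), "TG")
  # medium-chain FAs start absent
  fa <- p1$species[p1$species$class == "FA", ]
  expect_true(all(fa$species_c >= 13))
  expect_equal(sum(p1$omega_weights), 1)
})

test_that("aging kinetics respect boundaries and conserve every species pool", {
  prof <- default_sebum_profile(1)
  expect_error(age_profile(prof, -1), ">= 0")
  # day 0: substrates untouched except the epoxide cap; no ozonolysis pools
  p0 <- age_profile(prof, 0)
  expect_false(any(p0$pool %in% c("OZ1", "OZ2", "E_OZ", "OZBOND", "LOST")))
  sub0 <- p0[p0$pool == "substrate", ]
  m <- merge(sub0, prof$species, by = c("class", "species_c", "db"))
  cap <- aging_params()$epoxide_cap
  expected <- ifelse(m$db > 0, (1 - cap) * m$abundance.y, m$abundance.y)
  expect_equal(m$abundance.x, expected)
  # k = 0: no ozonolysis products at any day
  pk0 <- age_profile(prof, 7, aging_params(k_ozonolysis = 0))
  expect_false(any(pk0$pool %in% c("OZ1", "OZ2", "E_OZ", "OZBOND")))
  # mass balance at every sampled day
  for (d in c(0, 1, 3, 7)) {
    p <- age_profile(prof, d)
    p <- p[p$pool %in% c("substrate", "E", "OZ1", "OZ2", "E_OZ", "LOST"), ]
    agg <- stats::aggregate(abundance ~ class + species_c + db, p, sum)
    m <- merge(agg, prof$species, by = c("class", "species_c", "db"))
    expect_identical(nrow(m), nrow(prof$species))
    expect_lt(max(abs(m$abundance.x - m$abundance.y)), 1e-9)
  }
})

test_that("substrates decay and cleaved-bond pools accumulate monotonically", {
  prof <- default_sebum_profile(1)
  days <- c(0, 1, 2, 3, 5, 7)
  sub_tot <- ozbond_tot <- numeric(length(days))
  for (i in seq_along(days)) {
    p <- age_profile(prof, days[i])
    unsat <- p$pool == "substrate" & p$db > 0
    sub_tot[i] <- sum(p$abundance[unsat])
    ozbond_tot[i] <- sum(p$abundance[p$pool == "OZBOND"])
  }
  expect_true(all(diff(sub_tot) <= 1e-12))
  expect_true(all(diff(ozbond_tot) >= -1e-12))
})

test_that("noise-free rendering hits theoretical m/z and isotope ratios", {
  prof <- default_sebum_profile(1)
  params <- aging_params(mz_jitter_ppm = 0, noise_peaks = 0,
                         intensity_noise_sdlog = 0)
  rs <- render_spectrum(age_profile(prof, 7, params), params, seed = 2)
  tr <- rs$truth
  expect_true(all(tr$source == "signal"))
  expect_equal(tr$mz_observed, tr$mz, tolerance = 1e-12)
  # binomial 13C statistics of a specific large ion: TG 50:0 sodiated, C53
  f0 <- "C53H102O6Na"
  f1 <- "C52[13C]H102O6Na"
  r01 <- tr$intensity[tr$formula == f1] / tr$intensity[tr$formula == f0]
  expect_equal(r01, 53 * 0.0107 / (1 - 0.0107), tolerance = 1e-9)
  expect_equal(r01, 0.57, tolerance = 0.01)
  # the aged fingerprint must exhibit the FA 10:0 ion at m/z 217.117
  fa10_mz <- ion_mz(parse_formula("C10H19O2Na2"))
  expect_equal(round(fa10_mz, 3), 217.117)
  d <- abs(tr$mz_observed - fa10_mz) / fa10_mz * 1e6
  expect_true(any(d < 2 & tr$intensity > 0.1))
})

test_that("time-course generation is deterministic in its seed", {
  a <- generate_timecourse(ages = c(0, 3), replicates = 2, seed = 9)
  b <- generate_timecourse(ages = c(0, 3), replicates = 2, seed = 9)
  for (i in seq_along(a$samples)) {
    expect_identical(a$samples[[i]]$peaks$peaks, b$samples[[i]]$peaks$peaks)
    expect_identical(a$samples[[i]]$truth$intensity,
                     b$samples[[i]]$truth$intensity)
  }
  d <- generate_timecourse(ages = c(0, 3), replicates = 2, seed = 10)
  expect_false(identical(a$samples[[1]]$peaks$peaks,
                         d$samples[[1]]$peaks$peaks))
  # replicates of one age share kinetics, differ by deposition and noise
  expect_identical(a$samples[[1]]$age_days, a$samples[[2]]$age_days)
  expect_false(identical(a$samples[[1]]$deposition_factor,
                         a$samples[[2]]$deposition_factor))
})

test_that("sparse-ozone preset favors epoxides over Criegee acids; ambient does not", {
  prof <- default_sebum_profile(1)
  ratio_ec <- function(params) {
    rs <- render_spectrum(age_profile(prof, 3, params), params, seed = 11)
    tr <- rs$truth
    tg <- !is.na(tr$substrate) & grepl("TG", tr$substrate) &
      tr$isotopologue == 0
    e <- sum(tr$intensity[tg & grepl("(^|\\|)E($|\\|)", tr$product_tag)])
    cc <- sum(tr$intensity[tg & grepl("B/C|(^|\\|)C($|\\|)",
                                      tr$product_tag)])
    e / cc
  }
  expect_gt(ratio_ec(sparse_ozone_params()), 1)
  expect_lt(ratio_ec(aging_params()), 1)
})
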