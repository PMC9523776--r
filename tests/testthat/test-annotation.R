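test_that("peaks are assigned within 2 ppm and left unassigned outside", {
  tl <- shared_targets()
  mz0 <- tl$mz[which(tl$formula == "C30H50Na")]
  shifted <- peaklist(c(mz0 * (1 + 1e-6), mz0 * (1 + 3e-6)), c(10, 10))
  ann <- annotate_peaks(shifted, tl)
  expect_identical(ann$formula[1], "C30H50Na")
  expect_equal(ann$ppm_error[1], 1, tolerance = 0.01)
  expect_true(is.na(ann$label[2]))
})

test_that("annotation is deterministic and order-independent", {
  pl <- shared_day7()$peaks
  tl <- shared_targets()
  ann <- annotate_peaks(pl, tl)
  set.seed(51)
  shuffled <- pl$peaks[sample.int(nrow(pl$peaks)), ]
  ann2 <- annotate_peaks(shuffled, tl)
  ann2 <- ann2[order(ann2$mz), ]
  expect_equal(ann2$formula, ann$formula[order(ann$mz)])
  expect_equal(ann2$ppm_error, ann$ppm_error[order(ann$mz)])
})

test_that("sodium assignments win ties against potassium adducts", {
  # two isobaric alternatives at identical m/z: the Na entry must win
  fake <- data.frame(
    label = c("X(K) 1:0", "Y(Na) 1:0"), formula = c("C10H20O2K", "C10H20O2Na"),
    mz = c(500.0, 500.0), c = c(10L, 10L), species_c = c(10L, 10L),
    DBE = c(1L, 1L), O = c(2L, 2L), Na = c(0L, 1L), K = c(1L, 0L),
    product_tag = c("substrate", "substrate"), substrate = c("FA", "FA"),
    adduct = c("[M+K]+", "[M+Na]+"), class_id = c("k", "na"),
    stringsAsFactors = FALSE)
  ann <- annotate_peaks(data.frame(mz = 500.0, intensity = 1), fake)
  expect_identical(ann$adduct, "[M+Na]+")
  expect_true(ann$multi_class_ambiguous)
  expect_match(ann$alternates, "X\\(K\\)")
})

test_that("simulated interference-free peaks are fully recovered", {
  s7 <- shared_day7()
  tl <- shared_targets()
  ann <- annotate_peaks(s7$peaks, tl)
  tr <- s7$truth
  sig <- tr[tr$source == "signal" & tr$isotopologue == 0 &
              tr$formula %in% tl$formula &
              tr$intensity > 30 * 0.002, ]
  # interference-free: no other target within 3 ppm of the true target
  tmz <- tl$mz[match(sig$formula, tl$formula)]
  clear <- vapply(tmz, function(m) {
    d <- abs(tl$mz - m) / m * 1e6
    sum(d < 3) == 1L
  }, logical(1))
  sig <- sig[clear, ]
  idx <- vapply(sig$mz_observed, function(m)
    which.min(abs(ann$mz - m)), integer(1))
  recovered <- ann$formula[idx] == sig$formula
  expect_gt(length(recovered), 100)  # guard: the fixture is not vacuous
  expect_true(all(recovered, na.rm = FALSE))
})

test_that("Type-II isotopic interference is flagged from the M+2 overlap", {
  # closed form: second 13C isotopologue vs one more saturation
  am <- atomic_masses()
  gap <- 2 * am[["H"]] - 2 * (am[["C13"]] - am[["C"]])
  expect_equal(round(gap, 4), 0.0089)
  tl <- shared_targets()
  na1 <- elemental_composition(Na = 1)
  mz_501 <- ion_mz(compose_lipid("TG", 50, 1) + na1)
  # lone monoisotopic peak: no flag
  lone <- peaklist(mz_501, 10)
  ann <- flag_type2_interference(annotate_peaks(lone, tl), lone)
  expect_false(any(ann$type2_isotope_risk))
  # a 10x-intense more-unsaturated homolog 2.0067 Da below: its M+2 lands
  # 0.0089 Da under the assigned peak and the flag must fire
  delta2 <- 2 * (am[["C13"]] - am[["C"]])
  both <- peaklist(c(mz_501 - delta2, mz_501), c(100, 10))
  ann2 <- flag_type2_interference(annotate_peaks(both, tl), both)
  i <- which.min(abs(ann2$mz - mz_501))
  expect_true(ann2$type2_isotope_risk[i])
})

test_that("class profiles expose the bimodal aldehyde/epoxide structure", {
  tl <- shared_targets()
  ann7 <- annotate_peaks(shared_day7()$peaks, tl)
  expect_error(class_intensity_profile(ann7, n_O = 19, dbe_value = 40),
               "unknown")
  # known class with no assigned peaks: empty profile
  none <- annotate_peaks(peaklist(numeric(0), numeric(0)), tl)
  expect_identical(nrow(class_intensity_profile(none, 7, 4)), 0L)
  # aged O7 / DBE 4 profile: aldehyde mode low, epoxide mode at TG masses
  prof7 <- class_intensity_profile(ann7, n_O = 7, dbe_value = 4)
  split7 <- split_bimodal_profile(prof7)
  expect_identical(split7$n_modes, 2L)
  wmean_mz <- function(p) {
    p <- p[!is.na(p$mz) & p$intensity > 0, ]
    sum(p$mz * p$intensity) / sum(p$intensity)
  }
  expect_gt(wmean_mz(split7$low), 650)
  expect_lt(wmean_mz(split7$low), 730)
  expect_gt(wmean_mz(split7$high), 780)
  expect_lt(wmean_mz(split7$high), 870)
  expect_identical(split7$mode_labels, c(low = "A", high = "E"))
  # fresh O6 / DBE 4 (monounsaturated TG) profile is unimodal
  ann0 <- annotate_peaks(shared_day0()$peaks, tl)
  prof0 <- class_intensity_profile(ann0, n_O = 6, dbe_value = 4)
  expect_identical(split_bimodal_profile(prof0)$n_modes, 1L)
})

test_that("bimodal splitting finds a constructed valley", {
  cs <- 30:60
  y <- 10 * exp(-(cs - 37)^2 / 8) + 8 * exp(-(cs - 52)^2 / 10)
  prof <- data.frame(c = cs, intensity = y, mz = NA_real_)
  sp <- split_bimodal_profile(prof)
  expect_identical(sp$n_modes, 2L)
  expect_lte(abs(sp$valley_c - 44), 1)   # analytic valley near c = 44
  # strictly unimodal: single mode
  uni <- data.frame(c = cs, intensity = exp(-(cs - 45)^2 / 30),
                    mz = NA_real_)
  expect_identical(split_bimodal_profile(uni)$n_modes, 1L)
  # too few members: no split attempted
  tiny <- data.frame(c = 1:4, intensity = c(5, 1, 6, 1), mz = NA_real_)
  expect_identical(split_bimodal_profile(tiny)$n_modes, 1L)
})
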