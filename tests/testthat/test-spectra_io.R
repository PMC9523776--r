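test_that("peak lists round-trip through TSV bit-exactly at 6 decimals", {
  pl <- peaklist(c(217.117495, 433.380472, 829.725562), c(1.5, 20, 3.25),
                 sample_id = "fp01", age_days = 3, replicate = 2,
                 noise_level = 0.002)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peaklist(pl, path)
  back <- read_peaklist(path)
  expect_equal(back$peaks$mz, round(pl$peaks$mz, 6))
  expect_equal(back$peaks$intensity, round(pl$peaks$intensity, 6))
  expect_identical(back$meta$sample_id, "fp01")
  expect_identical(back$meta$age_days, 3)
  expect_identical(back$meta$replicate, 2L)
  expect_identical(back$meta$noise_level, 0.002)
})

test_that("degenerate peak-list inputs behave as specified", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("mz\tintensity", path)
  empty <- read_peaklist(path)
  expect_identical(nrow(empty$peaks), 0L)
  # duplicate m/z merge by intensity sum, with a warning
  expect_warning(pl <- peaklist(c(500.1, 500.1, 600.2), c(1, 2, 5)),
                 "merged")
  expect_equal(pl$peaks$intensity, c(3, 5))
  # malformed rows are reported with their line number
  writeLines(c("mz\tintensity", "500.1\t2.0", "oops"), path)
  expect_error(read_peaklist(path), "line 3")
  expect_error(peaklist(c(-5, 10), c(1, 1)), "0, 10000")
})

test_that("saturated-TG normalization rescales to unit saturated-TG sum", {
  tl <- shared_targets()
  na1 <- elemental_composition(Na = 1)
  mz_tg <- vapply(c(48, 50), function(cn)
    ion_mz(compose_lipid("TG", cn, 0) + na1), numeric(1))
  pl <- peaklist(mz_tg, c(3, 1))
  ann <- annotate_peaks(pl, tl)
  norm <- normalize_to_saturated_tg(pl, ann)
  expect_equal(norm$peaks$intensity, c(0.75, 0.25))
  expect_true(norm$meta$normalized)
  # scale invariance
  pl10 <- peaklist(mz_tg, 10 * c(3, 1))
  norm10 <- normalize_to_saturated_tg(pl10, annotate_peaks(pl10, tl))
  expect_equal(norm10$peaks$intensity, norm$peaks$intensity)
  # idempotence
  twice <- normalize_to_saturated_tg(norm, annotate_peaks(norm, tl))
  expect_equal(twice$peaks$intensity, norm$peaks$intensity)
  # no saturated TG signal -> undefined
  sq_only <- peaklist(433.3805, 5)
  expect_error(normalize_to_saturated_tg(sq_only,
                                         annotate_peaks(sq_only, tl)),
               "undefined")
})

test_that("spectrum subtraction is zero on self and antisymmetric", {
  tl <- shared_targets()
  na1 <- elemental_composition(Na = 1)
  mz_tg <- ion_mz(compose_lipid("TG", 50, 0) + na1)
  fresh <- peaklist(c(433.380472, mz_tg), c(4, 8), sample_id = "fresh")
  aged <- peaklist(c(mz_tg, 700.123), c(8, 2), sample_id = "aged")
  fresh <- normalize_to_saturated_tg(fresh, annotate_peaks(fresh, tl))
  aged <- normalize_to_saturated_tg(aged, annotate_peaks(aged, tl))
  self <- subtract_spectra(fresh, fresh)
  expect_true(all(self$delta == 0))
  ab <- subtract_spectra(fresh, aged)
  ba <- subtract_spectra(aged, fresh)
  expect_equal(ab$delta, -ba$delta)
  # squalene present only in fresh: negative delta at 433.3805
  i <- which.min(abs(ab$mz - 433.3805))
  expect_lt(ab$delta[i], 0)
  # peak only in aged: positive delta equal to its intensity
  j <- which.min(abs(ab$mz - 700.123))
  expect_equal(ab$delta[j], ab$intensity_aged[j])
  expect_gt(ab$delta[j], 0)
  # unnormalized inputs are rejected
  raw <- peaklist(mz_tg, 1)
  expect_error(subtract_spectra(raw, aged), "normalized")
})
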