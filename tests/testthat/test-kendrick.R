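test_that("Kendrick mass rescales the CH2 unit to exactly 14", {
  ch2 <- sum(atomic_masses()[c("C", "H", "H")])
  expect_equal(kendrick_mass(ch2), 14, tolerance = 1e-12)
  expect_equal(round(kendrick_mass(433.3805), 4), 432.8966)
  expect_equal(kendrick_mass(500 + ch2) - kendrick_mass(500), 14,
               tolerance = 1e-12)
  expect_equal(kendrick_mass_defect(ch2), 0, tolerance = 1e-12)
  expect_error(kendrick_mass(-1), "positive")
})

test_that("KMD is invariant under CH2 homologation", {
  ch2 <- sum(atomic_masses()[c("C", "H", "H")])
  set.seed(41)
  mz <- runif(1e4, 100, 1200)
  km <- kendrick_mass(mz)
  # exclude the measure-zero rounding boundary
  ok <- abs(abs(km - floor(km)) - 0.5) > 1e-4
  mz <- mz[ok]
  kmd0 <- kendrick_mass_defect(mz)
  for (k in 1:20)
    expect_lt(max(abs(kendrick_mass_defect(mz + k * ch2) - kmd0)), 1e-9)
})

test_that("one degree of unsaturation offsets KMD by 0.0134", {
  for (cn in c(46, 50, 54)) {
    mz0 <- ion_mz(compose_lipid("TG", cn, 0) + elemental_composition(Na = 1))
    mz1 <- ion_mz(compose_lipid("TG", cn, 1) + elemental_composition(Na = 1))
    dk <- abs(kendrick_mass_defect(mz0) - kendrick_mass_defect(mz1))
    expect_equal(dk, 0.013399362, tolerance = 1e-7)
    expect_equal(round(dk, 4), 0.0134)
  }
})

test_that("homologous-series grouping collects CH2 ladders and splits on unsaturation", {
  na1 <- elemental_composition(Na = 1)
  mz_sat <- vapply(44:54, function(cn)
    ion_mz(compose_lipid("TG", cn, 0) + na1), numeric(1))
  g <- group_homologous_series(data.frame(mz = mz_sat))
  expect_identical(length(unique(g$series)), 1L)
  expect_identical(unique(g$series_size), 11L)
  # adding a mono-unsaturated ion opens a second series (dKMD 0.0134 > tol)
  mz_all <- c(mz_sat, ion_mz(compose_lipid("TG", 50, 1) + na1))
  g2 <- group_homologous_series(data.frame(mz = mz_all))
  expect_identical(length(unique(g2$series)), 2L)
  # a lone point is a singleton series
  g3 <- group_homologous_series(data.frame(mz = 433.3805))
  expect_identical(g3$series, 1L)
  expect_identical(g3$series_size, 1L)
})

test_that("series grouping agrees with brute-force transitive clustering", {
  ch2 <- sum(atomic_masses()[c("C", "H", "H")])
  set.seed(42)
  base <- runif(6, 300, 700)
  mz <- c(unlist(lapply(base, function(b) b + sample(0:12, 5) * ch2)),
          runif(20, 100, 1200))
  mz <- unique(mz)
  pts <- data.frame(mz = mz)
  g <- group_homologous_series(pts)
  # oracle: explicit pairwise adjacency + connected components by BFS
  kmd <- kendrick_mass_defect(mz)
  n <- length(mz)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- abs(mz[j] - mz[i])
    k <- round(d / ch2)
    adj[i, j] <- adj[j, i] <-
      abs(kmd[i] - kmd[j]) <= 5e-4 &&
      abs(d - k * ch2) <= 2e-6 * max(mz[i], mz[j])
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in 1:n) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  oracle <- comp[match(g$mz, mz)]
  # identical partitions (ids may differ)
  expect_identical(length(unique(g$series)), length(unique(oracle)))
  expect_true(all(tapply(g$series, oracle,
                         function(v) length(unique(v))) == 1L))
})

test_that("KMD plot data applies the S/N and window filters", {
  expect_identical(nrow(kmd_plot_data(data.frame(mz = numeric(0),
                                                 intensity = numeric(0)))),
                   0L)
  pl <- peaklist(c(433.3805, 829.7256), c(100, 5000), noise_level = 1)
  tab <- kmd_plot_data(pl, sn_threshold = 30)
  expect_identical(nrow(tab), 2L)
  tab2 <- kmd_plot_data(pl, sn_threshold = 300)
  expect_identical(nrow(tab2), 1L)
  expect_error(kmd_plot_data(pl, kmd_range = c(0.35, 0.05)), "increasing")
})

test_that("the aged TG ozonolysis cluster sits in the 675-775 band", {
  tr <- shared_day7()$truth
  heads <- tr$source == "signal" & tr$isotopologue == 0 &
    !is.na(tr$substrate) & grepl("TG", tr$substrate) &
    grepl("(^|\\|)(A|B/C)($|\\|)", tr$product_tag)
  med <- weighted_median(tr$mz[heads], tr$intensity[heads])
  expect_gt(med, 675)
  expect_lt(med, 775)
  # and those features survive the default KMD plot filters
  tab <- kmd_plot_data(shared_day7()$peaks)
  in_band <- tab$mz >= 675 & tab$mz <= 775
  expect_gt(sum(in_band), 10)
})
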