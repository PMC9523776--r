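test_that("lipid stoichiometry composes the expected neutral formulas", {
  expect_identical(format_formula(compose_lipid("TG", 48, 0)), "C51H98O6")
  expect_identical(format_formula(compose_lipid("TG", 47, 1)), "C50H94O6")
  expect_identical(format_formula(compose_lipid("FA", 16, 1)), "C16H30O2")
  expect_identical(format_formula(compose_lipid("SQ")), "C30H50")
  # DBE = double bonds + ester count for every class
  esters <- c(FA = 1L, WE = 1L, DG = 2L, TG = 3L)
  for (cl in names(esters)) for (d in 0:3)
    expect_identical(dbe(compose_lipid(cl, 30, d)), d + esters[[cl]])
  expect_identical(dbe(compose_lipid("SQ")), 6L)
})

test_that("ozonolysis cleavage yields the omega-split products", {
  p <- ozonolysis_products(lipid_species("TG", 47, 1), omega = 10)
  expect_identical(format_formula(p$head_aldehyde_A), "C40H74O7")
  expect_identical(format_formula(p$tail_acid_C), "C10H20O2")
  p2 <- ozonolysis_products(lipid_species("FA", 16, 1,
                                          db_positions = 10), omega = 10)
  expect_identical(format_formula(p2$tail_acid_C), "C10H20O2")  # FA 10:0
  expect_error(ozonolysis_products(lipid_species("TG", 48, 0), 10),
               "at least one")
  expect_error(ozonolysis_products(lipid_species("TG", 47, 1), 46), "omega")
})

test_that("ozonolysis conserves atoms: head + tail = substrate + added O", {
  set.seed(21)
  o2 <- elemental_composition(O = 2)
  o3 <- elemental_composition(O = 3)
  for (i in 1:40) {
    cl <- sample(c("TG", "DG", "WE", "FA"), 1)
    n <- sample(20:50, 1)
    d <- sample(1:3, 1)
    w <- sample(2:(n - 10), 1)
    s <- lipid_species(cl, n, d)
    p <- ozonolysis_products(s, w)
    sub <- compose_lipid(s)
    expect_true(p$head_aldehyde_A + p$tail_aldehyde == sub + o2)
    expect_true(p$head_criegee_BC + p$tail_aldehyde == sub + o3)
    expect_true(p$head_aldehyde_A + p$tail_acid_C == sub + o3)
  }
})

test_that("double ozonolysis applies the aldehyde delta twice", {
  aa <- double_ozonolysis_products(lipid_species("TG", 48, 2), c(10, 10))
  expect_identical(format_formula(aa), "C31H54O8")
  expect_error(double_ozonolysis_products(lipid_species("FA", 18, 2),
                                          c(9, 9)), "DG, WE and TG")
  expect_error(double_ozonolysis_products(lipid_species("TG", 48, 1),
                                          c(10, 10)), "at least two")
  # conservation: AA + two tail aldehydes = substrate + 4 O
  s <- lipid_species("TG", 50, 2)
  tails <- elemental_composition(C = 19, H = 38, O = 2)  # omega 9 + 10
  expect_true(double_ozonolysis_products(s, c(9, 10)) + tails ==
                compose_lipid(s) + elemental_composition(O = 4))
})

test_that("epoxidation adds exactly one oxygen and conserves DBE", {
  e <- epoxidation_product(lipid_species("TG", 50, 1))
  expect_identical(format_formula(e), "C53H100O7")
  expect_identical(dbe(e), dbe(compose_lipid("TG", 50, 1)))
  e2 <- epoxidation_product(lipid_species("FA", 16, 1))
  expect_identical(format_formula(e2), "C16H30O3")
  expect_equal(monoisotopic_mass(e) -
                 monoisotopic_mass(compose_lipid("TG", 50, 1)),
               atomic_masses()[["O"]], tolerance = 1e-12)
  expect_error(epoxidation_product(lipid_species("TG", 48, 0)),
               "at least one")
})

test_that("default target list contains the published marker ions", {
  tl <- shared_targets()
  fa10 <- tl[tl$formula == "C10H19O2Na2", ]
  expect_identical(nrow(fa10), 1L)
  expect_equal(round(fa10$mz, 3), 217.117)
  expect_match(fa10$label, "FA 10:0")
  tga <- tl[tl$formula == "C40H74O7Na", ]
  expect_identical(nrow(tga), 1L)
  expect_match(tga$label, "TG(A) 37:0", fixed = TRUE)
  expect_identical(tga$DBE, 4L)
  sq <- tl[tl$formula == "C30H50Na", ]
  expect_equal(round(sq$mz, 4), 433.3805)
})

test_that("one-K substitution duplicates entries one K-minus-Na heavier", {
  am <- atomic_masses()
  dm <- am[["K"]] - am[["Na"]]
  expect_equal(round(dm, 3), 15.974)
  tl <- shared_targets()
  na_rows <- tl[tl$Na == 1 & tl$K == 0 & tl$adduct == "[M+Na]+", ]
  set.seed(31)
  na_rows <- na_rows[sample.int(nrow(na_rows), 25), ]
  for (i in seq_len(nrow(na_rows))) {
    comp <- parse_formula(na_rows$formula[i]) -
      elemental_composition(Na = 1) + elemental_composition(K = 1)
    twin <- tl[tl$formula == format_formula(comp), ]
    expect_identical(nrow(twin), 1L)
    expect_equal(twin$mz - na_rows$mz[i], dm, tolerance = 1e-9)
  }
})

test_that("epoxide entries share the heteroatom class of the aldehyde series", {
  tl <- shared_targets()
  e_rows <- grepl("(^|\\|)E($|\\|)", tl$product_tag) & tl$substrate == "TG"
  a_rows <- grepl("(^|\\|)A($|\\|)", tl$product_tag) &
    grepl("TG", tl$substrate)
  expect_true(any(e_rows))
  expect_true(all(tl$class_id[e_rows] %in% tl$class_id[a_rows]))
  # one more O, same Z as the substrate entries of the same residual db
  tg_sub <- tl[tl$product_tag == "substrate" & tl$substrate == "TG" &
                 tl$DBE == 4 & tl$adduct == "[M+Na]+", ]
  tg_e <- tl[e_rows & tl$DBE == 4 & tl$adduct == "[M+Na]+", ]
  expect_identical(unique(tg_e$O), unique(tg_sub$O) + 1L)
  expect_identical(unique(tg_e$Z), unique(tg_sub$Z))
})

test_that("no two target entries in one class share a carbon number", {
  tl <- shared_targets()
  expect_false(anyDuplicated(paste(tl$class_id, tl$c, tl$adduct)) > 0)
  expect_false(is.unsorted(tl$mz))
})

test_that("degenerate configurations are rejected", {
  expect_error(target_list_config(tg_c = c(60, 40)), "range")
  expect_error(target_list_config(mz_range = c(50, 1300)), "mz_range")
})
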