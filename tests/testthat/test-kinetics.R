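test_that("stoichiometric matrix has one -1/+1 pair per reaction column", {
  chain <- tiny_net(edge_df(c("M9x", "M8x"), c("M8x", "M7x")))
  sm <- build_stoichiometry(chain, "E1")
  expect_equal(dim(sm$S), c(3, 2))
  expect_equal(unname(sm$S[, 1]), c(-1, 1, 0))
  expect_equal(unname(sm$S[, 2]), c(0, -1, 1))
  expect_true(all(colSums(sm$S) == 0))

  # two entities: block-diagonal by entity
  one <- tiny_net(edge_df("A", "B"))
  sm2 <- build_stoichiometry(one, c("P1", "P2"))
  expect_equal(ncol(sm2$S), 2)
  expect_true(all(sm2$S[sm2$species$entity == "P1", 2] == 0))
  expect_true(all(sm2$S[sm2$species$entity == "P2", 1] == 0))

  # toy network: every column conserves glycan count
  sm3 <- build_stoichiometry(make_toy_grn(), c("IgG", "HCP"))
  expect_true(all(colSums(sm3$S) == 0))
  expect_true(all(colSums(sm3$S != 0) == 2))
})

test_that("Michaelis-Menten rate matches hand substitution and limits", {
  kf <- 60; E <- 1.5; km <- 100
  expect_equal(rate_mm(0, E, kf, km), 0)
  # half saturation at [OS] = Km
  expect_equal(rate_mm(km, E, kf, km), kf * E / 2, tolerance = 1e-12)
  # saturation limit
  expect_equal(rate_mm(1e6 * km, E, kf, km), kf * E, tolerance = 1e-4)
  expect_error(rate_mm(1, E, kf, -1), "Km")
})

test_that("sequential Bi-Bi rate matches hand substitution and limits", {
  kf <- 60; E <- 1.5; km <- 100; kmd <- 50
  expect_equal(rate_bibi(km, E, kf, km, nsd = 0, kmd = kmd), 0)
  # [OS] = Km and [NSD] = Kmd gives kf E / 3
  expect_equal(rate_bibi(km, E, kf, km, nsd = kmd, kmd = kmd),
               kf * E / 3, tolerance = 1e-12)
  # double saturation
  expect_equal(rate_bibi(1e6 * km, E, kf, km, nsd = 1e6 * kmd, kmd = kmd),
               kf * E, tolerance = 1e-4)
  # NSD excess reduces to the Michaelis-Menten form
  expect_equal(rate_bibi(37, E, kf, km, nsd = 1e8 * kmd, kmd = kmd),
               rate_mm(37, E, kf, km), tolerance = 1e-6)
  expect_error(rate_bibi(1, E, kf, km, nsd = 1, kmd = 0), "Kmd")
})

test_that("rate laws are monotone, bounded and competition-consistent", {
  set.seed(5)
  for (i in 1:50) {
    kf <- runif(1, 10, 1000); E <- runif(1, 0.01, 5)
    km <- runif(1, 10, 500); kmd <- runif(1, 10, 500)
    os <- runif(1, 0, 400); nsd <- runif(1, 0, 2000)
    comp_c <- c(os, runif(2, 0, 400)); comp_k <- c(km, runif(2, 10, 500))
    r1 <- rate_mm(os, E, kf, km, comp_c, comp_k)
    r2 <- rate_bibi(os, E, kf, km, nsd, kmd, comp_c, comp_k)
    expect_gte(r1, 0); expect_gte(r2, 0)
    expect_lte(r1, kf * E + 1e-12); expect_lte(r2, kf * E + 1e-12)
    # increasing in own substrate
    up_c <- comp_c; up_c[1] <- os * 1.1
    expect_gte(rate_mm(os * 1.1, E, kf, km, up_c, comp_k), r1)
    # decreasing in a competitor's concentration
    comp_hi <- comp_c; comp_hi[2] <- comp_c[2] + 100
    expect_lte(rate_mm(os, E, kf, km, comp_hi, comp_k), r1)
    expect_lte(rate_bibi(os, E, kf, km, nsd, kmd, comp_hi, comp_k), r2)
  }
})

test_that("enzyme specs carry law, donor and normalised localisation", {
  specs <- enzyme_specs()
  expect_equal(specs$ManI$law, "MM")
  expect_true(is.na(specs$ManII$nsd))
  expect_equal(specs$GnTI$law, "BiBi")
  expect_equal(specs$GnTI$nsd, "UDP-GlcNAc")
  expect_equal(specs$b4GalT$nsd, "UDP-Gal")
  expect_equal(specs$a3SiaT$nsd, "CMP-Neu5Ac")
  expect_equal(specs$a6FucT$nsd, "GDP-Fuc")
  for (s in specs)
    expect_equal(sum(s$compartment_fractions), 1, tolerance = 1e-9)
  expect_error(enzyme_specs("ManI", fractions = list(ManI = c(1, 1, 0, 0))),
               "sum to 1")
})

test_that("parameter containers validate their invariants", {
  expect_error(kinetic_parameters(m9_prop = c(IgG = 1.2)), "m9_prop")
  expect_error(kinetic_parameters(kf = c(ManI = -5)), "positive")
  p <- kinetic_parameters(entities = "IgG",
                          km_override = list(IgG = list(ManI = list(M9 = 42))))
  expect_equal(glykin:::.get_km(p, "M9", "ManI", "IgG"), 42)
  expect_equal(glykin:::.get_km(p, "M8", "ManI", "IgG"), 200)
  expect_error(protein_entity("x", molecular_weight = -1))
})
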