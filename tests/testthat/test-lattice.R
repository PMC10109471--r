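test_that("bmc_hexamer recentres bookkeeping and orients the normal", {
  h <- make_toy_hexamer()
  expect_equal(as.numeric(h$com), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(length(h$chains), 6)
  expect_equal(as.numeric(h$normal), c(0, 0, -1), tolerance = 1e-9)
})

test_that("expand_layer on P1 regenerates the neighbour ring", {
  cry <- toy_crystal()
  layer <- expand_layer(cry, radius = 100)
  n_ch <- length(unique(as_atoms(layer)$chain))
  expect_gte(n_ch, 18)
  det <- detect_hexamers(layer)
  expect_gte(length(det$hexamers), 3)
  expect_equal(length(det$ungrouped), 0)
})

test_that("expand_layer on P6 builds hexamers from a single chain", {
  h <- make_toy_hexamer()
  a1 <- dplyr::filter(h$atoms, chain == "A")
  cry <- crystal_structure(a1,
                           cell = c(a = 68.5, b = 68.5, c = 200,
                                    alpha = 90, beta = 90, gamma = 120),
                           sym_ops = bmchex:::spacegroup_ops("P 6"),
                           spacegroup = "P 6")
  det <- detect_hexamers(expand_layer(cry, radius = 80))
  expect_gte(length(det$hexamers), 3)
  expect_equal(length(det$hexamers[[1]]$chains), 6)
})

test_that("expand_layer requires symmetry information", {
  h <- make_toy_hexamer()
  cry <- crystal_structure(h$atoms)
  expect_error(expand_layer(cry), "no symmetry")
})

test_that("find_pairs reports touching hexamers only", {
  lat <- make_lattice(toy_lattice_spec(spacing = 68.5), n_hex = 3)
  pr <- find_pairs(lat$hexamers)
  expect_equal(nrow(pr), 3)
  expect_equal(pr$separation, rep(68.5, 3), tolerance = 1e-9)
  far <- make_lattice(toy_lattice_spec(spacing = 200), n_hex = 3)
  expect_equal(nrow(find_pairs(far$hexamers)), 0)
})

test_that("build_trihexamer extracts a mutually contacting triangle", {
  th <- build_trihexamer(toy_crystal())
  expect_s3_class(th, "bmc_trihexamer")
  expect_equal(length(th$hexamers), 3)
  seps <- as.numeric(dist(do.call(rbind,
                                  lapply(th$hexamers, function(h) h$com))))
  expect_equal(seps, rep(68.5, 3), tolerance = 1e-6)
})

test_that("detect_hexamers rejects non-C6 chain groups", {
  h <- make_toy_hexamer()
  five <- dplyr::filter(h$atoms, chain != "F")
  det <- detect_hexamers(five)
  expect_equal(length(det$hexamers), 0)
  expect_setequal(det$ungrouped, c("A", "B", "C", "D", "E"))
})
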