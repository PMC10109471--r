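canon <- canonical_specs()

test_that("interface metrics recover constructed distances exactly", {
  lat <- make_lattice(canon[["Arr-A"]], n_hex = 2)
  im <- interface_metrics(lat$hexamers[[1]], lat$hexamers[[2]])
  expect_equal(im$d_lys, 8, tolerance = 1e-9)
  expect_equal(im$spacing, 68.5, tolerance = 1e-9)
  expect_equal(im$lateral_offset, 0, tolerance = 1e-9)
  expect_true(im$arg_inserted)
  expect_false(im$saltbridge)
  # symmetric under swapping the hexamers
  im2 <- interface_metrics(lat$hexamers[[2]], lat$hexamers[[1]])
  expect_equal(im2$d_lys, im$d_lys, tolerance = 1e-12)
  expect_equal(im2$lateral_offset, im$lateral_offset, tolerance = 1e-9)
})

test_that("canonical Arr-B carries offset and salt bridge", {
  lat <- make_lattice(canon[["Arr-B"]], n_hex = 2)
  im <- interface_metrics(lat$hexamers[[1]], lat$hexamers[[2]])
  expect_equal(im$d_lys, 17, tolerance = 1e-9)
  expect_equal(im$lateral_offset, 9, tolerance = 1e-6)
  expect_true(im$saltbridge)
  expect_false(im$arg_inserted)
  expect_equal(classify(im)$label, "Arr-B")
})

test_that("decision rule reproduces the documented examples", {
  expect_equal(classify_dlys(8, 68.5, 0), "Arr-A")
  expect_equal(classify_dlys(16, 70.5, 9), "Arr-B")
  expect_equal(classify_dlys(10.2, 70.7, 0), "Arr-C")
  expect_equal(classify_dlys(20, 71.5, 18), "Arr-D")
  expect_equal(classify_dlys(30, 95, 0), "unclassified")
  expect_equal(classify_dlys(NA_real_, 70, 0), "unclassified")
})

test_that("decision rule is piecewise constant over a d_lys grid", {
  d <- seq(6, 20, by = 0.25)
  lab <- vapply(d, function(x)
    classify_dlys(x, spacing_for_dlys(x), 0), "")
  changes <- sum(lab[-1] != lab[-length(lab)])
  expect_lte(changes, 3)
  expect_true(all(lab[d <= 9] == "Arr-A"))
  expect_true(all(lab[d >= 13.5] == "Arr-B"))
  expect_true(all(lab[d >= 9.5 & d <= 12] == "Arr-C"))
})

test_that("survey labels all canonical lattices correctly", {
  lats <- lapply(canon[c("Arr-A", "Arr-B", "Arr-C", "Arr-D")],
                 make_lattice, n_hex = 3)
  sv <- survey(lats)
  expect_equal(nrow(sv), 12)
  expect_equal(sv$class, rep(c("Arr-A", "Arr-B", "Arr-C", "Arr-D"),
                             each = 3))
  expect_true(all(sv$note == ""))
  designed <- rep(unname(vapply(lats, function(l) l$truth$d_lys[1], 1)),
                  each = 3)
  expect_equal(sv$d_lys_min, designed, tolerance = 1e-6)
})

test_that("survey reports structures without a 2D layer", {
  far <- make_lattice(toy_lattice_spec(spacing = 200), n_hex = 3)
  sv <- survey(list(far = far))
  expect_equal(nrow(sv), 1)
  expect_match(sv$note, "no 2D layer")
  expect_true(is.na(sv$d_lys_min))
})

test_that("survey accepts file paths", {
  f <- tempfile(fileext = ".pdb")
  write_model(toy_crystal(), f)
  sv <- survey(list(xtal = f))
  expect_gte(nrow(sv), 3)
  expect_true(all(sv$class == "Arr-A"))
  expect_equal(sv$d_lys_min, rep(8, nrow(sv)), tolerance = 1e-2)
})

test_that("contact flags respect the distance cutoff in both directions", {
  lat <- make_lattice(canon[["Arr-A"]], n_hex = 2)
  a <- lat$hexamers[[1]]; b <- lat$hexamers[[2]]
  m <- pdua_landmarks()
  expect_true(bmchex:::contact_flag(a, b, m$arg_insert, m$pocket_acid, 4.5))
  expect_true(bmchex:::contact_flag(b, a, m$arg_insert, m$pocket_acid, 4.5))
  expect_false(bmchex:::contact_flag(a, b, m$arg_insert, m$pocket_acid, 1))
})
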