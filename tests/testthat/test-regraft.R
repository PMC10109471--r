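template <- as_trihexamer(make_lattice(canonical_specs()[["Arr-A"]], 3))
donor <- make_toy_hexamer()

test_that("superpose recovers constructed rigid motions to 1e-6", {
  tf0 <- list(R = rotation_about(c(0, 0, 1), 25), t = c(3, -7, 2))
  moved <- bmchex:::transform_atoms(donor$atoms, tf0)
  tf <- superpose(moved, donor$atoms)
  expect_lt(tf$rmsd, 1e-6)
  roundtrip <- apply_transform(atom_xyz(moved), tf)
  expect_lt(max(abs(roundtrip - atom_xyz(donor$atoms))), 1e-6)
})

test_that("template self-regraft is exact and clash-free", {
  rg <- regraft_arrA(donor, template)
  expect_lt(max(rg$rmsd), 1e-9)
  expect_equal(rg$spacing, rep(68.5, 3), tolerance = 1e-9)
  expect_equal(nrow(rg$clashes), 0)
  # placed coordinates coincide with the template
  key <- function(a) paste(a$chain, a$resno, a$atom)
  ta <- template$atoms
  ra <- rg$model$atoms[match(key(ta), key(rg$model$atoms)), ]
  expect_lt(max(abs(atom_xyz(ta) - atom_xyz(ra))), 1e-9)
})

test_that("regraft preserves intra-hexamer distances to 1e-9", {
  rg <- regraft_arrA(donor, template)
  xyz0 <- atom_xyz(donor$atoms)
  idx <- seq(1, nrow(xyz0), by = 101)
  d0 <- dist(xyz0[idx, ])
  for (h in rg$model$hexamers) {
    d1 <- dist(atom_xyz(h$atoms)[idx, ])
    expect_lt(max(abs(d1 - d0)), 1e-9)
  }
})

test_that("a rim bulge produces a populated clash report", {
  rg <- regraft_arrA(make_toy_hexamer(rim_bulge = TRUE), template)
  expect_gt(nrow(rg$clashes), 0)
  expect_true(91 %in% c(rg$clashes$resno_a, rg$clashes$resno_b))
  expect_lt(min(rg$clashes$min_dist), attr(rg$clashes, "cutoff"))
})

test_that("dissimilar donors are rejected", {
  expect_error(regraft_arrA(make_toy_hexamer(radius = 45), template),
               "too dissimilar")
})

test_that("alanine mutation edits exactly the requested copies", {
  m <- mutate_alanine(template, resno = 26, copies = "interface6")
  expect_equal(m$n_edited, 6)
  expect_equal(length(m$chains), 6)
  ed <- dplyr::filter(m$model$atoms, resno == 26, chain %in% m$chains)
  expect_true(all(ed$resname == "ALA"))
  expect_setequal(unique(ed$atom), c("N", "CA", "C", "O", "CB"))
  # lysine loses exactly CG, CD, CE, NZ in each edited copy
  before <- sum(template$atoms$resno == 26)
  after <- sum(m$model$atoms$resno == 26)
  expect_equal(before - after, 6 * 4)
  # untouched copies keep their side chains bitwise
  un <- dplyr::filter(m$model$atoms, resno == 26, !chain %in% m$chains)
  ref <- dplyr::filter(template$atoms, resno == 26, !chain %in% m$chains)
  expect_identical(un$x, ref$x)
})

test_that("alanine mutation copies variants behave", {
  m9 <- mutate_alanine(template, resno = 26, copies = "interface9",
                       contact_cutoff = 60)
  expect_equal(m9$n_edited, 9)
  mall <- mutate_alanine(template, resno = 79, copies = "all18")
  expect_equal(mall$n_edited, 18)
  mex <- mutate_alanine(template, resno = 26, copies = c("A", "J"))
  expect_equal(sort(mex$chains), c("A", "J"))
  expect_error(mutate_alanine(template, resno = 26, copies = "Z9"),
               "not in model")
  expect_error(mutate_alanine(template, resno = 1, copies = "all18"),
               "glycine")
  noop <- mutate_alanine(template, resno = 53, copies = "all18")
  expect_equal(noop$n_edited, 0)
  expect_error(mutate_alanine(template, resno = 999), "absent")
})

test_that("clash_report is empty on the relaxed template", {
  cr <- clash_report(template)
  expect_equal(nrow(cr), 0)
  expect_equal(attr(cr, "cutoff"), 2.6)
})
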