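test_that("generators are deterministic for a given seed", {
  expect_identical(make_toy_hexamer(seed = 3, jitter = 0.1),
                   make_toy_hexamer(seed = 3, jitter = 0.1))
  sp <- toy_lattice_spec(noise = 0.2, n_snapshots = 3, seed = 9)
  expect_identical(make_trajectory(sp)$coords, make_trajectory(sp)$coords)
  u <- model_potential("harmonic")
  expect_identical(make_umbrella_samples(u, centers = 0:2,
                                         n_per_window = 60, seed = 4),
                   make_umbrella_samples(u, centers = 0:2,
                                         n_per_window = 60, seed = 4))
})

test_that("the toy hexamer has exact C6 symmetry", {
  hx <- make_toy_hexamer()
  xyz <- atom_xyz(hx$atoms)
  rot <- rotate_about_line(xyz, c(0, 0, 0), c(0, 0, 1), 60)
  # chain i rotated by 60 degrees lands on chain i+1, atom for atom
  ch <- hx$chains
  for (i in 1:6) {
    src <- hx$atoms$chain == ch[i]
    dst <- hx$atoms$chain == ch[i %% 6 + 1]
    expect_lt(max(abs(rot[src, ] - xyz[dst, ])), 1e-6)
  }
  expect_lt(max(abs(hexamer_com(hx))), 1e-9)
})

test_that("landmark probes sit at their designed radii", {
  hx <- make_toy_hexamer()
  lm <- resolve_landmarks(hx, chain = hx$chains[1])
  r_of <- function(role) {
    a <- lm[lm$role == role, ]
    sqrt(a$x^2 + a$y^2)
  }
  expect_equal(r_of("lys_edge"), bmchex:::TOY_K26_RADIUS, tolerance = 1e-9)
  expect_equal(r_of("plane_probe"), 28, tolerance = 1e-9)
  expect_equal(r_of("tilt_a"), 30, tolerance = 1e-9)
})

test_that("spacing_for_dlys inverts the head-on lysine distance", {
  for (d in c(7.2, 8, 10.2, 17)) {
    lat <- make_lattice(toy_lattice_spec(spacing = spacing_for_dlys(d)), 2)
    im <- interface_metrics(lat$hexamers[[1]], lat$hexamers[[2]])
    expect_equal(im$d_lys, d, tolerance = 1e-9)
  }
  # and with a lateral offset
  sp <- toy_lattice_spec(spacing = spacing_for_dlys(17, 9), offset = 9)
  lat <- make_lattice(sp, 2)
  im <- interface_metrics(lat$hexamers[[1]], lat$hexamers[[2]])
  expect_equal(im$d_lys, 17, tolerance = 1e-9)
})

test_that("non-physical offsets are rejected", {
  expect_error(toy_lattice_spec(spacing = 60, offset = 31), "offset")
})

test_that("trajectory schedules shape the imposed angle series", {
  const <- make_trajectory(toy_lattice_spec(bend = -20, n_snapshots = 5))
  b <- dplyr::filter(const$truth, interface == "1-2")$bend_true
  expect_equal(b, rep(-20, 5))
  lin <- make_trajectory(toy_lattice_spec(bend = -20, schedule = "linear",
                                          n_snapshots = 5))
  bl <- dplyr::filter(lin$truth, interface == "1-2")$bend_true
  expect_equal(bl, seq(0, -20, length.out = 5))
  pl <- make_trajectory(toy_lattice_spec(bend = -20, schedule = "plateau",
                                         t0 = 3, n_snapshots = 5))
  bp <- dplyr::filter(pl$truth, interface == "1-2")$bend_true
  expect_equal(bp, c(0, -10, -20, -20, -20))
  # the coupled 2-3 interface carries NA truth
  expect_true(all(is.na(dplyr::filter(const$truth,
                                      interface == "2-3")$bend_true)))
})

test_that("canonical lattices are clash-free and carry truth tables", {
  for (nm in c("Arr-A", "Arr-B", "Arr-C")) {
    lat <- make_lattice(canonical_specs()[[nm]], n_hex = 3)
    expect_equal(nrow(clash_report(as_trihexamer(lat))), 0)
    expect_equal(nrow(lat$truth), 2)
    expect_true(all(lat$truth$class == nm))
  }
})

test_that("a too-large Metropolis step is rejected, not silently accepted", {
  u <- model_potential("harmonic")
  expect_error(make_umbrella_samples(u, centers = 0, n_per_window = 60,
                                     step = 5e5),
               "acceptance")
})

test_that("stiff-bias sample variance matches the Boltzmann prediction", {
  k <- 4000  # kJ/mol/nm^2 -> 40 kJ/mol/A^2 dominates kappa = 2
  s <- make_umbrella_samples(model_potential("harmonic", kappa = 0),
                             centers = 5, k = k, n_per_window = 4000,
                             seed = 2)
  kT <- bmchex:::BOLTZ_KJ * 298
  expect_equal(var(s$xi), kT / (k / 100), tolerance = 0.1)
  expect_equal(mean(s$xi), 5, tolerance = 0.05)
})

test_that("the clamp fixture exposes matched profiles, energy and mask", {
  fx <- make_clamp_fixture(seed = 1, n_runs = 1, n_snapshots = 12)
  expect_equal(length(fx$profiles), 1)
  expect_s3_class(fx$profiles[[1]], "residue_profile")
  expect_s3_class(fx$energy, "residue_profile")
  expect_equal(attr(fx$energy, "metric"), "energy")
  expect_equal(fx$resno, 26)
  planted <- dplyr::semi_join(
    fx$energy, dplyr::filter(fx$mask, interface, resno == 26),
    by = c("chain", "resno"))
  expect_true(all(planted$value < -5))
})
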