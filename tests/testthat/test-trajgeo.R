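flat_traj <- make_trajectory(toy_lattice_spec(n_snapshots = 1))
map <- pdua_landmarks()

test_that("flat lattices read exactly zero bending and tilting", {
  as0 <- angle_series(flat_traj)
  expect_lt(max(abs(as0$angles$bending)), 1e-9)
  expect_lt(max(abs(as0$angles$tilting)), 1e-9)
})

test_that("imposed pure bends and tilts are recovered exactly", {
  for (th in c(-40, -10, 25)) {
    trB <- make_trajectory(toy_lattice_spec(bend = th, n_snapshots = 1))
    aB <- dplyr::filter(angle_series(trB)$angles, interface != "2-3")
    expect_equal(aB$bending, rep(th, 2), tolerance = 1e-9)
    expect_lt(max(abs(aB$tilting)), 1e-9)
    trT <- make_trajectory(toy_lattice_spec(tilt = th, n_snapshots = 1))
    aT <- dplyr::filter(angle_series(trT)$angles, interface != "2-3")
    expect_equal(aT$tilting, rep(th, 2), tolerance = 1e-9)
    expect_lt(max(abs(aT$bending)), 1e-9)
  }
})

test_that("bending sign convention: negative = toward the convex face", {
  # the toy convex face is -z; bend = -25 rotates the neighbour toward -z
  tr <- make_trajectory(toy_lattice_spec(bend = -25, n_snapshots = 1))
  a <- dplyr::filter(angle_series(tr)$angles, interface == "1-2")
  expect_equal(a$bending, -25, tolerance = 1e-9)
  hb <- tr$crystal$hexamers[[2]]
  sel <- tr$atoms$chain %in% hb$chains
  z_shift <- mean(tr$coords[[1]][sel, 3]) - mean(atom_xyz(hb$atoms)[, 3])
  expect_lt(z_shift, 0)
})

test_that("angle measurements are invariant to global rigid motions", {
  tr <- make_trajectory(toy_lattice_spec(bend = 17, tilt = 0,
                                         n_snapshots = 1))
  xyz <- tr$coords[[1]]
  moved <- rotate_about_line(xyz, c(10, -5, 3), c(1, 1, 1) / sqrt(3), 33)
  moved <- moved + rep(c(100, -50, 20), each = nrow(moved))
  tr2 <- tr; tr2$coords <- list(moved)
  a1 <- dplyr::filter(angle_series(tr)$angles, interface != "2-3")
  a2 <- dplyr::filter(angle_series(tr2)$angles, interface != "2-3")
  expect_equal(a2$bending, a1$bending, tolerance = 1e-6)
  expect_equal(a2$tilting, a1$tilting, tolerance = 1e-6)
})

test_that("noisy angle series carry validity flags and outlier marks", {
  tr <- make_trajectory(toy_lattice_spec(bend = -25, noise = 0.3,
                                         n_snapshots = 30, seed = 4))
  as_ <- angle_series(tr)
  expect_true(all(as_$angles$valid))
  expect_true(all(c("bending_mean", "bending_sd") %in%
                    names(as_$by_interface)))
  expect_true(is.logical(as_$angles$outlier))
  expect_true(as_$angles$is_start[as_$angles$snapshot == 1][1])
})

test_that("average_structure averages away symmetric noise", {
  tr <- make_trajectory(toy_lattice_spec(noise = 0.3, n_snapshots = 40,
                                         seed = 5))
  avg <- average_structure(tr)
  ref <- atom_xyz(as_atoms(flat_traj))
  dev <- sqrt(mean(rowSums((atom_xyz(avg) - ref)^2)))
  expect_lt(dev, 0.3 / sqrt(40) * 4)
})

test_that("rmsd_series matches a hand-computed value and checks topology", {
  tr <- make_trajectory(toy_lattice_spec(noise = 0.2, n_snapshots = 5,
                                         seed = 6))
  rs <- rmsd_series(tr, tr$crystal)
  expect_equal(nrow(rs), 5)
  expect_true(all(rs$rmsd > 0))
  expect_equal(rs$rmsd, rep(0.2 * sqrt(3), 5), tolerance = 0.1)
  broken <- as_atoms(tr$crystal)[-1, ]
  expect_error(rmsd_series(tr, broken), "topolog")
})

test_that("com_deviation is zero for a flat noiseless trajectory", {
  avg <- average_structure(make_trajectory(toy_lattice_spec(n_snapshots = 2)))
  cd <- com_deviation(avg, flat_traj$crystal)
  expect_lt(max(abs(cd$per_pair$deviation)), 1e-6)
  expect_lt(abs(cd$mean), 1e-6)
})

test_that("com_deviation detects designed contraction", {
  # pulling the neighbours 2 A inward must read ~ -2 A on the 1-2/1-3 pairs
  lat <- make_lattice(toy_lattice_spec(spacing = 66.5), n_hex = 3)
  avg <- as_atoms(as_trihexamer(lat))
  cd <- com_deviation(avg, flat_traj$crystal)
  pp <- cd$per_pair
  expect_equal(sort(pp$deviation)[c(2, 3)], c(-2, -2), tolerance = 1e-6)
})

test_that("plane_representation reports oriented planes per hexamer", {
  pr <- plane_representation(flat_traj$crystal)
  expect_equal(nrow(pr), 4)           # 3 hexamer planes + COM plane
  expect_true(all(c("px", "nz") %in% names(pr)))
  nz <- pr$nz[pr$hexamer != "COM"]
  expect_equal(abs(nz), rep(1, 3), tolerance = 1e-6)
  expect_equal(unname(pr$pz[pr$hexamer == "COM"]), 0, tolerance = 1e-6)
})
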