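test_that("torsion_angle matches IUPAC reference geometries", {
  # d on +z above the a-b-c plane is -90 under the IUPAC sign convention
  expect_equal(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                             c(0, 1, 1)), -90)
  expect_equal(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                             c(0, 1, -1)), 90)
  expect_equal(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                             c(-1, 1, 0)), 180)
  expect_equal(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                             c(1, 1, 0)), 0)
})

test_that("torsion_angle rejects colinear spans", {
  expect_error(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                             c(3, 1, 0)), "colinear")
})

test_that("kabsch recovers constructed rigid motions to 1e-6", {
  set.seed(1)
  x <- matrix(rnorm(60), ncol = 3)
  R <- rotation_about(bmchex:::unitv(c(1, 2, 3)), 37)
  t <- c(4, -2, 7)
  y <- x %*% t(R) + rep(t, each = nrow(x))
  tf <- kabsch(x, y)
  expect_lt(max(abs(tf$R - R)), 1e-6)
  expect_lt(max(abs(tf$t - t)), 1e-6)
  expect_lt(tf$rmsd, 1e-6)
  expect_lt(max(abs(apply_transform(x, tf) - y)), 1e-6)
})

test_that("kabsch returns proper rotations even for reflected inputs", {
  set.seed(2)
  x <- matrix(rnorm(30), ncol = 3)
  y <- x
  y[, 3] <- -y[, 3]           # a reflection, not achievable by rotation
  tf <- kabsch(x, y)
  expect_equal(det(tf$R), 1, tolerance = 1e-9)
})

test_that("rotate_about_line fixes points on the axis", {
  p <- c(1, 1, 1); d <- bmchex:::unitv(c(0, 0, 1))
  on_axis <- rbind(p, p + 2 * d)
  out <- rotate_about_line(on_axis, p, d, 73)
  expect_equal(out, on_axis, tolerance = 1e-12, ignore_attr = TRUE)
  off <- matrix(c(2, 1, 1), 1)
  out90 <- rotate_about_line(off, p, d, 90)
  expect_equal(as.numeric(out90), c(1, 2, 1), tolerance = 1e-12)
})

test_that("fit_plane recovers constructed planes", {
  set.seed(3)
  u <- cbind(rnorm(50), rnorm(50), 0)
  u <- sweep(u, 2, colMeans(u))  # centroid exactly at the origin
  R <- rotation_about(bmchex:::unitv(c(1, 1, 0)), 30)
  pts <- u %*% t(R) + rep(c(5, 6, 7), each = 50)
  pl <- fit_plane(pts)
  n_true <- as.numeric(R %*% c(0, 0, 1))
  expect_lt(min(vec_angle(pl$normal, n_true),
                vec_angle(-pl$normal, n_true)), 1e-6)
  expect_equal(as.numeric(pl$point), c(5, 6, 7), tolerance = 1e-8)
})

test_that("vector helpers are exact on canonical inputs", {
  expect_equal(bmchex:::cross3(c(1, 0, 0), c(0, 1, 0)), c(0, 0, 1))
  expect_equal(vec_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_error(bmchex:::unitv(c(0, 0, 0)), "zero")
  m <- rotation_about(c(0, 0, 1), 60)
  expect_equal(m %*% c(1, 0, 0), cbind(c(cos(pi / 3), sin(pi / 3), 0)),
               tolerance = 1e-12)
})
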