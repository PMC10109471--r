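kT <- bmchex:::BOLTZ_KJ * 298

test_that("umbrella samples validate their shape", {
  s <- tibble::tibble(window = 1, center = 0, k = 1000, xi = rnorm(40))
  expect_error(wham(s), "fewer than")
  expect_error(wham(dplyr::select(s, -k)), "columns")
  s2 <- tibble::tibble(window = 1, center = 0, k = -5, xi = rnorm(100))
  expect_error(wham(s2), ">= 0")
})

test_that("unbiased single-window WHAM equals -kT ln(hist) exactly", {
  set.seed(5)
  s <- tibble::tibble(window = 1, center = 0, k = 0, xi = rnorm(2000))
  pm <- wham(s)
  h <- hist(s$xi, breaks = pm$breaks, plot = FALSE)
  ref <- -kT * log(h$counts)
  ref <- ref - min(ref[is.finite(ref)])
  ok <- is.finite(ref)
  expect_equal(pm$curve$G[ok], ref[ok], tolerance = 1e-12)
  expect_equal(is.finite(pm$curve$G), ok)
})

test_that("WHAM reconstructs a harmonic potential from exact samples", {
  kappa <- 1.5; centre <- 5; kbias <- 10
  set.seed(42)
  s <- dplyr::bind_rows(lapply(0:14, function(c0) {
    ktot <- kappa + kbias
    mu <- (kappa * centre + kbias * c0) / ktot
    tibble::tibble(window = c0 + 1, center = c0, k = 1000,
                   xi = rnorm(3000, mu, sqrt(kT / ktot)))
  }))
  pm <- wham(s)
  cv <- dplyr::filter(pm$curve, is.finite(G), n_samples >= 100)
  truth <- 0.5 * kappa * (cv$xi - centre)^2
  err <- cv$G - truth
  err <- err - mean(err)
  expect_lt(max(abs(err)), 0.5)
})

test_that("non-overlapping windows are rejected with their centers named", {
  s <- make_umbrella_samples(model_potential("harmonic"),
                             centers = c(0, 14), k = 4000,
                             n_per_window = 200)
  expect_error(wham(s), "0 and 14.*overlap")
})

test_that("bootstrap errors are deterministic and positive", {
  s <- make_umbrella_samples(model_potential("harmonic"), centers = 0:6,
                             n_per_window = 200)
  b1 <- bootstrap_error(s, B = 10, seed = 7, tol = 1e-5)
  b2 <- bootstrap_error(s, B = 10, seed = 7, tol = 1e-5)
  expect_identical(b1, b2)
  expect_true(all(b1$se[!is.na(b1$se)] >= 0))
  expect_gt(median(b1$se, na.rm = TRUE), 0)
  expect_error(bootstrap_error(s, B = 1), "at least 2")
})

test_that("binding_energy reads a Morse well depth and flags plateaus", {
  s <- make_umbrella_samples(model_potential("morse", x0 = 2, depth = 12,
                                             a = 0.8),
                             n_per_window = 1000)
  pm <- wham(s)
  be <- binding_energy(pm)
  expect_true(be$plateau)
  expect_equal(be$value, 12, tolerance = 1.5)
  # a rising tail is flagged
  s2 <- make_umbrella_samples(model_potential("harmonic", centre = 0,
                                              kappa = 2),
                              centers = 0:10, n_per_window = 300)
  expect_warning(be2 <- binding_energy(wham(s2)), "plateau")
  expect_false(be2$plateau)
})

test_that("restrained_profile annotates the arrangement loci", {
  s <- make_umbrella_samples(model_potential("harmonic", centre = 0,
                                             kappa = 0.3),
                             centers = seq(-16, 16, by = 2),
                             n_per_window = 400)
  rp <- restrained_profile(s)
  expect_s3_class(rp, "pmf_curve")
  expect_setequal(rp$annotations$label,
                  c("Arr-A", "Arr-B", "Arr-D"))
  expect_setequal(rp$annotations$offset, c(0, -9, 9, -15, 15))
})

test_that("umbrella TSV round-trips", {
  s <- make_umbrella_samples(model_potential("harmonic"), centers = 0:2,
                             n_per_window = 60)
  f <- tempfile(fileext = ".tsv")
  write_umbrella(s, f)
  back <- read_umbrella(f)
  expect_equal(back$xi, s$xi, tolerance = 1e-12)
  expect_equal(back$center, s$center)
})
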