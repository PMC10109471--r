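trihex <- as_trihexamer(make_lattice(toy_lattice_spec(), n_hex = 3))
mask <- interface_mask(trihex)

test_that("interface mask flags the designed contact residues", {
  hit <- sort(unique(mask$resno[mask$interface]))
  expect_true(all(c(26, 27, 79, 83) %in% hit))
  expect_equal(nrow(dplyr::distinct(mask, chain, resno)), 18 * 95)
  # zero cutoff flags nothing
  m0 <- interface_mask(trihex, contact_cutoff = 0)
  expect_false(any(m0$interface))
})

test_that("sidechain profile resolves clamped vs mobile copies", {
  spec <- toy_lattice_spec(noise = 0.05, flex_sigma = 0.6, clamp_resno = 26,
                           n_snapshots = 12, seed = 2)
  tr <- make_trajectory(spec)
  p <- sidechain_rmsd_profile(tr, average_structure(tr))
  expect_s3_class(p, "residue_profile")
  expect_equal(attr(p, "metric"), "sidechain_rmsd")
  k26 <- dplyr::left_join(dplyr::filter(p, resno == 26),
                          dplyr::select(mask, chain, resno, interface),
                          by = c("chain", "resno"))
  expect_lt(mean(k26$value[k26$interface]),
            min(k26$value[!k26$interface]))
  expect_error(sidechain_rmsd_profile(tr, average_structure(tr),
                                      exclude_first = 12), "exclude_first")
})

test_that("energy tables round-trip and validate", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("residue\tmonomer\tvalue", "26\tA\t-3.5", "26\tB\t0.25"), f)
  p <- read_energy_table(f)
  expect_equal(p$value, c(-3.5, 0.25))
  expect_equal(attr(p, "metric"), "energy")
  writeLines(c("residue\tvalue", "26\t-3.5"), f)
  expect_error(read_energy_table(f), "columns")
})

test_that("energy_interval equals the brute-force row spread exactly", {
  set.seed(10)
  prof <- tibble::tibble(chain = rep(LETTERS[1:6], times = 10),
                         resno = rep(1:10, each = 6),
                         value = rnorm(60))
  iv <- energy_interval(prof)
  brute <- tapply(prof$value, prof$resno, function(v) max(v) - min(v))
  expect_equal(iv$interval[order(iv$resno)],
               as.numeric(brute[order(as.integer(names(brute)))]))
  expect_false(is.unsorted(rev(iv$interval)))
  # constant matrix: all zero
  iv0 <- energy_interval(dplyr::mutate(prof, value = 1))
  expect_equal(iv0$interval, rep(0, 10))
  expect_error(energy_interval(dplyr::mutate(prof,
    value = replace(value, 3, NA))), "residue")
})

test_that("interface_enrichment recovers planted deltas and exclusions", {
  sub <- dplyr::filter(mask, hexamer == 1)
  prof <- dplyr::mutate(dplyr::select(sub, chain, resno),
                        value = 0)
  m1 <- dplyr::mutate(mask, interface = FALSE)
  sub_mask <- dplyr::filter(m1, hexamer == 1)
  sub_mask$interface[sub_mask$resno == 26 & sub_mask$chain == "A"] <- TRUE
  prof$value[prof$resno == 26 & prof$chain == "A"] <- -5
  en <- interface_enrichment(prof, sub_mask)
  expect_equal(en$delta[en$resno == 26], -5)
  expect_equal(en$delta[en$resno != 26], rep(0, nrow(en) - 1))
  # a residue interfacial in every copy is excluded with a report
  all_if <- sub_mask
  all_if$interface[all_if$resno == 30] <- TRUE
  en2 <- interface_enrichment(prof, all_if)
  expect_true(30 %in% attr(en2, "excluded"))
  expect_false(30 %in% en2$resno)
})

test_that("rank_key_residues flags the no-signal case", {
  sub <- dplyr::filter(mask, hexamer == 1)
  flat <- dplyr::mutate(dplyr::select(sub, chain, resno), value = 1)
  class(flat) <- c("residue_profile", class(flat))
  rk <- rank_key_residues(flat, flat, dplyr::filter(mask, hexamer == 1))
  expect_true(attr(rk, "no_signal"))
})

test_that("naive score vanishes for distant hexamers", {
  far <- make_lattice(toy_lattice_spec(spacing = 250), n_hex = 2)
  sc <- naive_residue_score(far$hexamers)
  expect_equal(max(abs(sc$value)), 0)
})

test_that("naive score stabilizes the acid of a constructed salt bridge", {
  lat <- make_lattice(canonical_specs()[["Arr-B"]], n_hex = 2)
  sc <- naive_residue_score(lat$hexamers)
  d49 <- sc$value[sc$resno == 49 & sc$chain %in% c("A", "J")]
  expect_equal(length(d49), 2)
  expect_true(all(d49 < -1))
  # the paired arginine sees both the acid (attractive) and its symmetry
  # mate across the interface (repulsive); its Coulomb term is nonzero
  r28 <- sc$coulomb[sc$resno == 28 & sc$chain == "A"]
  expect_gt(abs(r28), 1)
})

test_that("doubling charges scales the Coulomb part exactly fourfold", {
  lat <- make_lattice(toy_lattice_spec(), n_hex = 2)
  s1 <- naive_residue_score(lat$hexamers)
  s2 <- naive_residue_score(lat$hexamers,
                            naive_score_params(charge_scale = 2))
  expect_equal(s2$coulomb, 4 * s1$coulomb, tolerance = 1e-12)
  expect_equal(s2$lj, s1$lj, tolerance = 1e-12)
})

test_that("the planted-clamp fixture is recovered top-1", {
  fx <- make_clamp_fixture(seed = 3, n_runs = 2)
  rk <- rank_key_residues(fx$profiles, fx$energy, fx$mask)
  expect_equal(rk$resno[1], fx$resno)
  expect_true(rk$ordered_at_interface[1])
  expect_false(attr(rk, "no_signal"))
})

test_that("closest_snapshot picks the designed minimum", {
  tr <- make_trajectory(toy_lattice_spec(bend = -20, schedule = "linear",
                                         n_snapshots = 5))
  expect_equal(closest_snapshot(tr, tr$crystal), 1L)
})
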