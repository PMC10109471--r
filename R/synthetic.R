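# Synthetic fixtures
#
# Pseudo-protein hexamers, lattices, bent/tilted tri-hexamer trajectories and
# biased order-parameter samples, each with machine-readable ground truth.
# The toy hexamer is a geometric C6 construction, not a real sequence: each
# chain carries a full backbone plus the landmark residues (PduA numbering)
# at documented radii, so every geometric operator in the package can be
# validated against constructed truth without shipping PDB-derived data.
#
# Construction frame: hexamer centred at the origin, chains k = 0..5 obtained
# by rotating chain 0 by 60k degrees about z; chain 0 flanks the interface
# direction at 0 degrees (wedge centred at +30). Landmark geometry (chain-0
# frame, before vertical recentring):
#   K26  CA (30.25, 0, 0)      rim lysine on the interface axis; the
#                              inter-hexamer d_lys is spacing - 60.5 head-on
#   S27  CA (34.25, 3.5, 0)    bending hinge probe
#   I38  CA (34.25, 3.5, -8)   directly below S27: flat layers read exactly 0
#                              (8 A arm keeps the dihedral noise-robust)
#   M24  CA (25.98, 15, 0)     tilt probe at the wedge centre, radius 30
#   I18  CA (25.98, 15, -8)    directly below M24
#   V54  CA at radius 28, wedge centre (plane probe)
#   R79/E83 at z ~ +3          guanidinium-to-carboxylate insertion across the
#                              interface at Arr-A spacing (~2.7-3.4 A gaps)
#   R28/D49                    salt bridge that forms at the canonical Arr-B
#                              geometry (spacing 70.5, offset 9)
#   N29                        rim flank contact on the second interfacial
#                              monomer
# The convex face is -z (bending probes sit on the convex side of the rim).

TOY_K26_RADIUS <- 30.25

toy_landmark_atoms <- function() {
  bb <- function(nm, resno, ca) {
    tibble(resno = resno, resname = nm,
           atom = c("N", "CA", "C", "O"),
           x = ca[1] + c(-0.9, 0, 1.0, 1.6),
           y = ca[2] + c(0.6, 0, 0.5, 1.4),
           z = ca[3] + c(0.4, 0, -0.3, -0.4))
  }
  sc <- function(resno, resname, atoms, xyz) {
    tibble(resno = resno, resname = resname, atom = atoms,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  c30 <- cos(pi / 6); s30 <- sin(pi / 6)
  m24 <- c(30 * c30, 30 * s30, 0)
  i18 <- c(30 * c30, 30 * s30, -8)
  v54 <- c(28 * c30, 28 * s30, 0)
  a53 <- c(27 * cos(33 * pi / 180), 27 * sin(33 * pi / 180), 0.3)
  n29ca <- c(28 * cos(50 * pi / 180), 28 * sin(50 * pi / 180), 0.8)
  bind_rows(
    bb("ILE", 18, i18),
    sc(18, "ILE", c("CB", "CG1", "CG2", "CD1"),
       rbind(i18 + c(1.1, 0.7, -0.5), i18 + c(1.9, 1.1, -0.3),
             i18 + c(0.8, 1.5, -1.3), i18 + c(2.8, 1.6, -0.8))),
    bb("MET", 24, m24),
    sc(24, "MET", c("CB", "CG", "SD", "CE"),
       rbind(m24 + c(1.13, 0.65, 0.6), m24 + c(2.0, 1.2, 0.6),
             m24 + c(3.0, 1.8, 0.7), m24 + c(4.0, 2.3, 0.6))),
    bb("LYS", 26, c(TOY_K26_RADIUS, 0, 0)),
    sc(26, "LYS", c("CB", "CG", "CD", "CE", "NZ"),
       cbind(c(31.3, 32.3, 33.3, 34.3, 35.2),
             c(0.8, 1.2, 1.6, 2.0, 2.4),
             c(0.0, -0.2, 0.0, -0.2, 0.0))),
    bb("SER", 27, c(34.25, 3.5, 0)),
    sc(27, "SER", c("CB", "OG"),
       rbind(c(34.6, 4.0, 0.7), c(34.9, 4.6, 1.2))),
    bb("ARG", 28, c(30.0, 8.0, 0.5)),
    sc(28, "ARG", c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
       cbind(c(31.3, 32.7, 34.1, 35.4, 36.8, 38.2, 37.0),
             c(8.2, 8.4, 8.6, 8.8, 9.0, 9.4, 9.8),
             c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 1.1))),
    bb("ASN", 29, n29ca),
    sc(29, "ASN", c("CB", "CG", "OD1", "ND2"),
       rbind(c(18.0, 22.5, 1.1),
             c(17.95, 23.8, 1.4),
             c(17.4, 24.5, 2.0),
             c(31.2 * cos(55 * pi / 180), 31.2 * sin(55 * pi / 180), 1.8))),
    bb("ILE", 38, c(34.25, 3.5, -8)),
    sc(38, "ILE", c("CB", "CG1", "CG2", "CD1"),
       rbind(c(35.1, 3.9, -8.4), c(35.6, 2.9, -8.2),
             c(34.9, 4.6, -9.2), c(36.3, 2.7, -8.9))),
    bb("ASP", 49, c(30.4, 2.8, 1.8)),
    sc(49, "ASP", c("CB", "CG", "OD1", "OD2"),
       rbind(c(31.2, 2.0, 1.8), c(32.0, 1.0, 1.7),
             c(32.72, 0.0, 1.6), c(31.6, 0.3, 2.2))),
    bb("ALA", 53, a53),
    sc(53, "ALA", "CB", rbind(a53 + c(1.1, 0.7, 0.6))),
    bb("VAL", 54, v54),
    sc(54, "VAL", c("CB", "CG1", "CG2"),
       rbind(v54 + c(1.15, 0.6, 0.6), v54 + c(1.85, 1.0, 0.2),
             v54 + c(0.95, 1.3, 1.3))),
    bb("ARG", 79, c(29.0, 1.8, 3.0)),
    sc(79, "ARG", c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
       cbind(c(30.2, 31.2, 32.2, 32.9, 33.6, 34.2, 34.0),
             c(1.9, 1.9, 1.9, 2.2, 2.9, 3.6, 2.7),
             c(3.1, 3.1, 3.0, 3.0, 3.0, 3.0, 2.1))),
    bb("GLU", 83, c(29.0, -2.4, 4.0)),
    sc(83, "GLU", c("CB", "CG", "CD", "OE1", "OE2"),
       rbind(c(30.1, -2.4, 3.9), c(31.0, -2.3, 3.8), c(31.5, -2.4, 3.7),
             c(32.1, -2.0, 3.2), c(31.9, -3.1, 4.2))))
}

toy_scaffold_atoms <- function(radius = 30, n_res = 95, jitter = 0) {
  lm_res <- c(18, 24, 26, 27, 28, 29, 38, 49, 53, 54, 79, 83)
  idx <- setdiff(seq_len(n_res), lm_res)
  t <- (idx - 1) / (n_res - 1)
  phi <- -24 + 48 * ((idx * 0.6180339887) %% 1)           # wedge scatter, deg
  rho <- 9 + (radius - 9 - 6 * abs(phi) / 24) * t          # taper at edges
  ang <- (30 + phi) * pi / 180
  zz <- 1.8 * cos(2 * pi * idx / 13)
  ca <- cbind(rho * cos(ang), rho * sin(ang), zz)
  if (jitter > 0) ca <- ca + matrix(rnorm(length(ca), 0, jitter), ncol = 3)
  radial <- cbind(cos(ang), sin(ang), 0)
  per_res <- lapply(seq_along(idx), function(i) {
    resno <- idx[i]
    base <- tibble(resno = resno,
                   resname = if (resno == 1) "GLY" else "ALA",
                   atom = c("N", "CA", "C", "O"),
                   x = ca[i, 1] + c(-0.9, 0, 1.0, 1.6),
                   y = ca[i, 2] + c(0.6, 0, 0.5, 1.4),
                   z = ca[i, 3] + c(0.4, 0, -0.3, -0.4))
    if (resno != 1)
      base <- bind_rows(base, tibble(
        resno = resno, resname = "ALA", atom = "CB",
        x = ca[i, 1] + 1.3 * radial[i, 1],
        y = ca[i, 2] + 1.3 * radial[i, 2],
        z = ca[i, 3] + 0.8))
    base
  })
  bind_rows(per_res)
}

#' Generate a C6-symmetric toy hexamer
#'
#' Six identical pseudo-protein chains (A-F) related by exact 60-degree
#' rotations about z, each with 95 residues (full backbone + Cbeta) and the
#' landmark residues of the default PduA map at documented radii (see the
#' constants at the top of the generator source and the methods vignette).
#' The assembly is recentred so the core backbone centre of mass is exactly
#' at the origin; the convex face is -z.
#'
#' @param radius Outer scaffold radius (Angstrom); landmark radii are fixed.
#' @param seed Seed for the (optional) scaffold jitter.
#' @param jitter Gaussian jitter (Angstrom) on scaffold Calpha; default 0
#'   (bit-identical output for equal arguments).
#' @param rim_bulge Add an oversized side-chain atom on residue 91 reaching
#'   past the rim (used to provoke steric clashes in regraft tests).
#' @return A `bmc_hexamer`.
#' @export
make_toy_hexamer <- function(radius = 30, seed = 1, jitter = 0,
                             rim_bulge = FALSE) {
  set.seed(seed)
  chain0 <- bind_rows(toy_landmark_atoms(),
                      toy_scaffold_atoms(radius = radius, jitter = jitter)) %>%
    arrange(.data$resno, match(.data$atom, c(BACKBONE_ATOMS, "CB")))
  if (rim_bulge) {
    chain0$resname[chain0$resno == 91L] <- "TRP"
    chain0 <- bind_rows(chain0, tibble(resno = 91L, resname = "TRP",
                                       atom = "CH2", x = 36, y = 1, z = 0.8))
  }
  chains <- lapply(0:5, function(k) {
    xyz <- as.matrix(chain0[, c("x", "y", "z")]) %*% t(rot_z(60 * k))
    atom_table(chain = LETTERS[k + 1], resno = chain0$resno,
               resname = chain0$resname, atom = chain0$atom,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  atoms <- bind_rows(chains)
  atoms$z <- atoms$z - backbone_com(atoms, c(1, 90))[3]   # exact COM at origin
  bmc_hexamer(atoms, normal = c(0, 0, -1),
              provenance = "synthetic toy hexamer")
}

#' Specification of a synthetic lattice / trajectory
#'
#' @param spacing Centre-to-centre hexamer spacing (Angstrom).
#' @param offset In-plane lateral offset of each neighbour from the head-on
#'   position (Angstrom, perpendicular to the centre axis).
#' @param bend,tilt Target angles (degrees, signed; negative bends toward the
#'   convex face) reached by the trajectory schedule.
#' @param noise Isotropic Gaussian coordinate noise sigma (Angstrom).
#' @param flex_sigma Extra Gaussian jitter sigma (Angstrom) on side-chain
#'   atoms beyond Cbeta, modelling rotamer mobility. Copies of a residue in
#'   contact with a neighbouring hexamer are clamped: their side-chain jitter
#'   is scaled by `clamp`.
#' @param clamp Side-chain jitter scale factor at inter-hexamer contacts
#'   (0..1; default 0.25).
#' @param clamp_resno Residue numbers whose contact copies are clamped;
#'   default NULL clamps every residue in contact. Supplying a single number
#'   plants that residue as the sole clamp (all other side chains stay
#'   uniformly mobile).
#' @param n_snapshots Number of trajectory snapshots.
#' @param schedule "constant" (angle held for all snapshots), "linear"
#'   (0 to target across the run), or "plateau" (linear until snapshot `t0`,
#'   then held).
#' @param t0 Snapshot at which the plateau schedule reaches its target.
#' @param seed Random seed.
#' @return A `toy_lattice_spec` list.
#' @export
toy_lattice_spec <- function(spacing = 68.5, offset = 0, bend = 0, tilt = 0,
                             noise = 0, flex_sigma = 0, clamp = 0.25,
                             clamp_resno = NULL, n_snapshots = 81,
                             schedule = c("constant", "linear", "plateau"),
                             t0 = 5, seed = 1) {
  schedule <- match.arg(schedule)
  stopifnot(spacing > 0, noise >= 0, flex_sigma >= 0,
            clamp >= 0, clamp <= 1, n_snapshots >= 1)
  if (offset >= spacing / 2)
    abort("offset >= spacing/2 produces non-physical hexamer overlap")
  structure(list(spacing = spacing, offset = offset, bend = bend, tilt = tilt,
                 noise = noise, flex_sigma = flex_sigma, clamp = clamp,
                 clamp_resno = clamp_resno, n_snapshots = n_snapshots,
                 schedule = schedule, t0 = t0, seed = seed),
            class = "toy_lattice_spec")
}

#' Spacing that produces a target inter-lysine distance
#'
#' Inverts the toy construction: the rim lysines sit on the interface axis at
#' radius 30.25, so head-on d_lys = spacing - 60.5; with a lateral offset the
#' axial gap shortens accordingly.
#'
#' @param d_lys Target K26-K26 Calpha distance (Angstrom).
#' @param offset Lateral offset (Angstrom, must be <= d_lys).
#' @return Spacing in Angstrom.
#' @export
spacing_for_dlys <- function(d_lys, offset = 0) {
  stopifnot(d_lys >= offset)
  bx <- 2 * TOY_K26_RADIUS + sqrt(d_lys^2 - offset^2)
  sqrt(bx^2 + offset^2)
}

#' Generate a synthetic hexamer lattice with ground truth
#'
#' Places identical toy hexamers on a planar hexagonal net: a central hexamer
#' plus neighbours in the 0, 60, ... degree directions at the requested
#' spacing and lateral offset.
#'
#' @param spec A [toy_lattice_spec()].
#' @param n_hex Number of hexamers (2 = pair, 3 = triangle, up to 7 =
#'   centre + full ring).
#' @return A `toy_lattice`: list with `hexamers`, combined `atoms`, the
#'   ground-truth tibble `truth` (one row per centre-neighbour interface:
#'   spacing, offset, d_lys and arrangement class implied by the construction)
#'   and `spec`.
#' @export
make_lattice <- function(spec, n_hex = 3) {
  stopifnot(inherits(spec, "toy_lattice_spec"), n_hex >= 2, n_hex <= 7)
  base <- make_toy_hexamer(seed = spec$seed)
  s <- spec$spacing; o <- spec$offset
  bx <- sqrt(s^2 - o^2)
  dirs <- 60 * (seq_len(n_hex - 1) - 1)
  hexamers <- list(relabel_hexamer(base, 1))
  truth <- list()
  for (k in seq_along(dirs)) {
    u <- c(cos(dirs[k] * pi / 180), sin(dirs[k] * pi / 180), 0)
    p <- c(-u[2], u[1], 0)
    pos <- bx * u + o * p
    hk <- translate_hexamer(base, pos)
    hexamers[[k + 1]] <- relabel_hexamer(hk, k + 1)
    d_lys <- sqrt((bx - 2 * TOY_K26_RADIUS)^2 + o^2)
    truth[[k]] <- tibble(interface = paste0("1-", k + 1),
                         hex_i = 1L, hex_j = k + 1L,
                         spacing = s, offset = o, d_lys = d_lys,
                         class = classify_dlys(d_lys, s, o))
  }
  out <- list(hexamers = hexamers,
              atoms = bind_rows(lapply(hexamers, function(h) h$atoms)),
              truth = bind_rows(truth), spec = spec)
  class(out) <- "toy_lattice"
  out
}

#' @export
print.toy_lattice <- function(x, ...) {
  cat("<toy_lattice> ", length(x$hexamers), " hexamers, spacing ",
      x$spec$spacing, " A, offset ", x$spec$offset, " A\n", sep = "")
  print(x$truth)
  invisible(x)
}

translate_hexamer <- function(h, pos) {
  h$atoms <- set_atom_xyz(h$atoms, sweep(atom_xyz(h$atoms), 2, pos, "+"))
  h$com <- h$com + pos
  h
}

relabel_hexamer <- function(h, index) {
  old <- unique(h$atoms$chain)
  new <- chain_alphabet()[(index - 1) * 6 + seq_len(6)]
  h$atoms$chain <- new[match(h$atoms$chain, old)]
  h$chains <- new
  h$provenance <- paste0("toy lattice hexamer ", index)
  h
}

#' Canonical toy lattice specs, one per arrangement class
#'
#' Clash-free translation-lattice geometries whose constructed d_lys values
#' sit inside each class's decision bin: Arr-A head-on at spacing 68.5
#' (d_lys 8), Arr-C head-on with d_lys 10.2, Arr-B offset 9 A with d_lys 17
#' (the R28-D49 salt bridge forms there by construction), Arr-D at the
#' offset-stacked signature (offset 18 A; this fixture exercises the
#' classifier only and is not sterically relaxed).
#'
#' @param ... Overrides passed to every [toy_lattice_spec()].
#' @return Named list of `toy_lattice_spec` (Arr-A, Arr-B, Arr-C, Arr-D).
#' @export
canonical_specs <- function(...) {
  list(`Arr-A` = toy_lattice_spec(spacing = 68.5, offset = 0, ...),
       `Arr-B` = toy_lattice_spec(spacing = spacing_for_dlys(17, 9),
                                  offset = 9, ...),
       `Arr-C` = toy_lattice_spec(spacing = spacing_for_dlys(10.2),
                                  offset = 0, ...),
       `Arr-D` = toy_lattice_spec(spacing = spacing_for_dlys(20, 18),
                                  offset = 18, ...))
}

#' Crystal-structure form of the toy hexamer (P1 hexagonal cell)
#'
#' One toy hexamer in a P1 cell with a = b = spacing, gamma = 120 degrees, so
#' integer lattice translations regenerate the hexagonal layer.
#'
#' @param spacing Lattice constant (Angstrom).
#' @param c_axis Out-of-plane cell length (Angstrom; large by default so the
#'   layer is isolated).
#' @return A [crystal_structure()].
#' @export
toy_crystal <- function(spacing = 68.5, c_axis = 200) {
  h <- make_toy_hexamer()
  crystal_structure(h$atoms,
                    cell = c(a = spacing, b = spacing, c = c_axis,
                             alpha = 90, beta = 90, gamma = 120),
                    sym_ops = list(list(R = diag(3), t = c(0, 0, 0))),
                    spacegroup = "P 1")
}

#' Tri-hexamer form of a synthetic lattice
#' @param lattice A `toy_lattice` with at least 3 hexamers.
#' @param contact_cutoff Contact cutoff passed to [find_pairs()].
#' @return A `bmc_trihexamer`.
#' @export
as_trihexamer <- function(lattice, contact_cutoff = 5) {
  stopifnot(inherits(lattice, "toy_lattice"), length(lattice$hexamers) >= 3)
  bmc_trihexamer(lattice$hexamers[1:3],
                 find_pairs(lattice$hexamers[1:3], contact_cutoff))
}

schedule_values <- function(spec, target) {
  n <- spec$n_snapshots
  i <- seq_len(n)
  switch(spec$schedule,
         constant = rep(target, n),
         linear = if (n == 1) 0 else target * (i - 1) / (n - 1),
         plateau = target * pmin(1, (i - 1) / max(1, spec$t0 - 1)))
}

#' Generate a synthetic tri-hexamer trajectory with imposed angles
#'
#' Builds a flat triangle of toy hexamers and, per snapshot, rotates the two
#' neighbour hexamers about the exact hinge axes the angle operators measure:
#' bending about the line through the facing S27 probes (positive angles move
#' the neighbour toward the concave +z face, negative toward the convex
#' face), tilting about the axis through the facing M24 midpoints. Isotropic
#' Gaussian noise is added after the rotations. The third (neighbour-
#' neighbour) interface is geometrically coupled rather than driven, so its
#' ground truth is NA.
#'
#' @param spec A [toy_lattice_spec()] (bend/tilt targets, schedule, noise,
#'   snapshot count, seed).
#' @return A `bmc_trajectory` with extra fields `truth` (snapshot x interface
#'   table of imposed angles) and `crystal` (the flat starting tri-hexamer).
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "toy_lattice_spec"))
  lattice <- make_lattice(spec, n_hex = 3)
  trihex <- as_trihexamer(lattice)
  atoms <- trihex$atoms
  set.seed(spec$seed)
  bends <- schedule_values(spec, spec$bend)
  tilts <- schedule_values(spec, spec$tilt)
  hinges <- lapply(2:3, function(j)
    interface_axes(trihex$hexamers[[1]], trihex$hexamers[[j]],
                   trihex$hexamers[[1]]$map))
  idx <- lapply(2:3, function(j) atoms$chain %in% trihex$hexamers[[j]]$chains)
  base_xyz <- atom_xyz(atoms)
  flex_sd <- NULL
  if (spec$flex_sigma > 0) {
    sc_row <- !atoms$het & !atoms$atom %in% c(BACKBONE_ATOMS, "CB")
    mask <- interface_mask(trihex)
    key <- paste(atoms$chain, atoms$resno)
    clamped <- key %in% paste(mask$chain[mask$interface],
                              mask$resno[mask$interface])
    if (!is.null(spec$clamp_resno))
      clamped <- clamped & atoms$resno %in% spec$clamp_resno
    flex_sd <- ifelse(sc_row, spec$flex_sigma *
                        ifelse(clamped, spec$clamp, 1), 0)
  }
  coords <- lapply(seq_len(spec$n_snapshots), function(i) {
    xyz <- base_xyz
    for (m in 1:2) {
      sel <- idx[[m]]; hg <- hinges[[m]]
      if (tilts[i] != 0)
        xyz[sel, ] <- rotate_about_line(xyz[sel, ], hg$tilt_point,
                                        hg$tilt_dir, tilts[i])
      if (bends[i] != 0)
        xyz[sel, ] <- rotate_about_line(xyz[sel, ], hg$bend_point,
                                        hg$bend_dir, bends[i])
    }
    if (spec$noise > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), 0, spec$noise), ncol = 3)
    if (!is.null(flex_sd))
      xyz <- xyz + matrix(rnorm(length(xyz), 0, rep(flex_sd, 3)), ncol = 3)
    xyz
  })
  truth <- tidyr::expand_grid(snapshot = seq_len(spec$n_snapshots),
                              interface = c("1-2", "1-3", "2-3")) %>%
    mutate(bend_true = ifelse(.data$interface == "2-3", NA_real_,
                              bends[.data$snapshot]),
           tilt_true = ifelse(.data$interface == "2-3", NA_real_,
                              tilts[.data$snapshot]))
  traj <- new_trajectory(atoms, coords, dt_ps = 250,
                         provenance = "synthetic toy trajectory")
  traj$truth <- truth
  traj$crystal <- trihex
  traj
}

#' Planted-clamp fixture for residue ranking
#'
#' Builds the synthetic system in which one residue is the sole clamp:
#' a flat Arr-A tri-hexamer trajectory whose side chains are uniformly
#' mobile except the contact copies of `resno` (clamped), plus a matched
#' energy profile carrying a planted stabilizing signal at the contact
#' copies of the same residue. [rank_key_residues()] applied to the fixture
#' must recover `resno` as top-ranked.
#'
#' @param resno The planted residue (default 26, the rim lysine).
#' @param seed Random seed (varies trajectories and energy noise).
#' @param n_runs Independent trajectories for the RMSD criterion.
#' @param n_snapshots Snapshots per trajectory.
#' @param flex_sigma Side-chain mobility sigma (Angstrom).
#' @param energy_signal Planted interface energy for `resno` (kJ/mol).
#' @param energy_noise Gaussian noise sigma on every energy entry (kJ/mol).
#' @param map A [landmark_map()].
#' @return List: `profiles` (side-chain RMSD profiles, one per run),
#'   `energy` (residue_profile), `mask`, `resno`.
#' @export
make_clamp_fixture <- function(resno = 26, seed = 1, n_runs = 2,
                               n_snapshots = 16, flex_sigma = 0.6,
                               energy_signal = -10, energy_noise = 0.5,
                               map = pdua_landmarks()) {
  trihex <- as_trihexamer(make_lattice(toy_lattice_spec(), n_hex = 3))
  mask <- interface_mask(trihex)
  profiles <- lapply(seq_len(n_runs), function(r) {
    spec <- toy_lattice_spec(noise = 0.05, flex_sigma = flex_sigma,
                             clamp_resno = resno,
                             n_snapshots = n_snapshots,
                             seed = seed + 1000 * (r - 1))
    tr <- make_trajectory(spec)
    sidechain_rmsd_profile(tr, average_structure(tr, map = map))
  })
  set.seed(seed + 7)
  energy <- mask %>%
    select("chain", "resno") %>%
    mutate(value = rnorm(n(), 0, energy_noise) +
             ifelse(.data$resno == !!resno &
                      mask$interface, energy_signal, 0))
  attr(energy, "metric") <- "energy"
  class(energy) <- c("residue_profile", class(energy))
  list(profiles = profiles, energy = energy, mask = mask, resno = resno)
}

# Hinge axes of an interface, from the flat construction landmarks
interface_axes <- function(ha, hb, map) {
  ch <- interface_chains(ha, hb, map)
  lma <- resolve_landmarks(ha$atoms, map, ch$bend_chain_a)
  lmb <- resolve_landmarks(hb$atoms, map, ch$bend_chain_b)
  gp <- function(lm, role) unlist(lm[lm$role == role, c("x", "y", "z")])
  m24a <- midpoint_landmark(ha, map, ch$tilt_chains_a, "tilt_a")
  m24b <- midpoint_landmark(hb, map, ch$tilt_chains_b, "tilt_a")
  list(bend_point = (gp(lma, "lys_edge") + gp(lmb, "lys_edge")) / 2,
       bend_dir = unitv(gp(lmb, "bend_a") - gp(lma, "bend_a")),
       tilt_point = m24a, tilt_dir = unitv(m24b - m24a))
}

midpoint_landmark <- function(h, map, chains, role) {
  ps <- vapply(chains, function(cn) {
    lm <- resolve_landmarks(h$atoms, map, cn)
    unlist(lm[lm$role == role, c("x", "y", "z")])
  }, numeric(3))
  rowMeans(ps)
}

#' Named 1-D model potentials for umbrella-sampling fixtures
#'
#' `harmonic`: 0.5 kappa (xi - centre)^2. `double_well`: quartic with minima
#' at centre +/- half_sep and barrier height `barrier` at the centre.
#' `morse`: binding-like well of depth `depth` at `x0`, flat at large xi.
#'
#' @param name One of "harmonic", "double_well", "morse".
#' @param ... Parameters: harmonic (centre, kappa kJ/mol/A^2); double_well
#'   (centre, half_sep, barrier kJ/mol); morse (x0, depth kJ/mol, a 1/A).
#' @return Function U(xi) in kJ/mol.
#' @export
model_potential <- function(name = c("harmonic", "double_well", "morse"), ...) {
  name <- match.arg(name)
  p <- list(...)
  switch(name,
    harmonic = {
      centre <- p$centre %||% 0; kappa <- p$kappa %||% 2
      function(xi) 0.5 * kappa * (xi - centre)^2
    },
    double_well = {
      centre <- p$centre %||% 0; hs <- p$half_sep %||% 4
      barrier <- p$barrier %||% 6
      function(xi) barrier * (((xi - centre)^2 / hs^2) - 1)^2
    },
    morse = {
      x0 <- p$x0 %||% 0; depth <- p$depth %||% 10; a <- p$a %||% 0.8
      function(xi) depth * ((1 - exp(-a * (xi - x0)))^2 - 1)
    })
}

#' Draw biased samples from a known 1-D potential
#'
#' Metropolis sampling from exp(-(U(xi) + bias_w(xi)) / kT) per umbrella
#' window, with harmonic biases 0.5 k ((xi - centre)/10)^2 (k in kJ/mol/nm^2,
#' xi in Angstrom, matching the convention of the umbrella-sampling module).
#'
#' @param potential Function U(xi) in kJ/mol (e.g. [model_potential()]).
#' @param centers Window centres (Angstrom); default 15 windows at 1 A steps.
#' @param k Bias spring constant (kJ/mol/nm^2, default 1000).
#' @param n_per_window Samples kept per window.
#' @param temperature Kelvin.
#' @param seed Random seed (deterministic output).
#' @param step Metropolis step size (Angstrom); default NULL chooses
#'   2.4 x sd of the bias-only stationary density (the classic random-walk
#'   scaling), i.e. 2.4 sqrt(kT / (k/100)).
#' @param burn Burn-in sweeps before sampling; `thin` sweeps between samples.
#' @param thin Thinning interval.
#' @return Tibble of umbrella windows: window, center, k, xi.
#' @export
make_umbrella_samples <- function(potential, centers = 0:14, k = 1000,
                                  n_per_window = 500, temperature = 298,
                                  seed = 1, step = NULL, burn = 1000,
                                  thin = 10) {
  set.seed(seed)
  kT <- BOLTZ_KJ * temperature
  if (is.null(step))
    step <- if (k > 0) 2.4 * sqrt(kT / (k / 100)) else 1
  nw <- length(centers)
  energy <- function(xi) potential(xi) + 0.5 * k * ((xi - centers) / 10)^2
  xi <- centers
  e <- energy(xi)
  keep <- matrix(NA_real_, n_per_window, nw)
  acc <- 0; tot <- 0
  for (sweep in seq_len(burn + n_per_window * thin)) {
    prop <- xi + rnorm(nw, 0, step)
    ep <- potential(prop) + 0.5 * k * ((prop - centers) / 10)^2
    take <- log(runif(nw)) < (e - ep) / kT
    xi[take] <- prop[take]; e[take] <- ep[take]
    acc <- acc + sum(take); tot <- tot + nw
    if (sweep > burn && (sweep - burn) %% thin == 0)
      keep[(sweep - burn) / thin, ] <- xi
  }
  if (acc / tot < 0.01)
    abort("Metropolis acceptance < 1%: reduce the step size")
  tibble(window = rep(seq_len(nw), each = n_per_window),
         center = rep(centers, each = n_per_window),
         k = k,
         xi = as.numeric(keep))
}
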