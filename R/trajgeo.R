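# Trajectory geometry
#
# Signed bending/tilting angles per snapshot and interface, MD-average
# structures, RMSD-to-average series, COM-distance deviations and plane
# representations of tri-hexamer models.

#' Interface descriptors of a tri-hexamer
#'
#' One descriptor per contacting hexamer pair, recording the chain
#' bookkeeping the angle operators need: all chains of both hexamers, the
#' bending monomer pair (mutually nearest `lys_edge` Calphas) and the two
#' tilting monomers per hexamer (the contacting chains).
#'
#' @param trihex A `bmc_trihexamer`.
#' @param map A [landmark_map()].
#' @return List of `bmc_interface` descriptors (fields id, hex_i, hex_j,
#'   chains_a, chains_b, bend_chain_a, bend_chain_b, tilt_chains_a,
#'   tilt_chains_b).
#' @export
trihex_interfaces <- function(trihex, map = pdua_landmarks()) {
  stopifnot(inherits(trihex, "bmc_trihexamer"))
  lapply(seq_len(nrow(trihex$pairs)), function(r) {
    i <- trihex$pairs$i[r]; j <- trihex$pairs$j[r]
    a <- trihex$hexamers[[i]]; b <- trihex$hexamers[[j]]
    ch <- interface_chains(a, b, map)
    structure(list(id = paste0(i, "-", j), hex_i = i, hex_j = j,
                   chains_a = a$chains, chains_b = b$chains,
                   bend_chain_a = ch$bend_chain_a,
                   bend_chain_b = ch$bend_chain_b,
                   tilt_chains_a = ch$tilt_chains_a,
                   tilt_chains_b = ch$tilt_chains_b),
              class = "bmc_interface")
  })
}

landmark_ca_point <- function(ca, chain, resno) {
  row <- which(ca$chain == chain & ca$resno == resno)
  if (length(row) != 1)
    abort(paste0("cannot resolve CA of residue ", resno, " in chain '",
                 chain, "'"))
  c(ca$x[row], ca$y[row], ca$z[row])
}

ca_row <- function(atoms, chain, resno) {
  row <- which(!atoms$het & atoms$atom == "CA" & atoms$chain == chain &
                 atoms$resno == resno)
  if (length(row) != 1)
    abort(paste0("cannot resolve CA of residue ", resno, " in chain '",
                 chain, "'"))
  row
}

# precomputed row indices so angle evaluation on a snapshot is pure
# coordinate arithmetic (reused across trajectory snapshots)
angle_cache <- function(atoms, interface, map) {
  ca_rows_of <- function(chains, resno)
    vapply(chains, function(cn) ca_row(atoms, cn, resno), 1L)
  list(
    bend = c(ca_row(atoms, interface$bend_chain_a, map$bend_pair[2]),
             ca_row(atoms, interface$bend_chain_a, map$bend_pair[1]),
             ca_row(atoms, interface$bend_chain_b, map$bend_pair[1]),
             ca_row(atoms, interface$bend_chain_b, map$bend_pair[2])),
    tilt = list(a2 = ca_rows_of(interface$tilt_chains_a, map$tilt_pair[2]),
                a1 = ca_rows_of(interface$tilt_chains_a, map$tilt_pair[1]),
                b1 = ca_rows_of(interface$tilt_chains_b, map$tilt_pair[1]),
                b2 = ca_rows_of(interface$tilt_chains_b, map$tilt_pair[2])),
    plane_a = lapply(interface$chains_a, function(cn)
      which(!atoms$het & atoms$atom == "CA" & atoms$chain == cn)),
    s27_a = which(!atoms$het & atoms$atom == "CA" &
                    atoms$chain %in% interface$chains_a &
                    atoms$resno == map$bend_pair[1]),
    i38_a = which(!atoms$het & atoms$atom == "CA" &
                    atoms$chain %in% interface$chains_a &
                    atoms$resno == map$bend_pair[2]),
    com_b = which(!atoms$het & atoms$atom %in% BACKBONE_ATOMS &
                    atoms$chain %in% interface$chains_b &
                    atoms$resno >= map$core_range[1] &
                    atoms$resno <= map$core_range[2]))
}

bending_eval <- function(xyz, cache) {
  p <- xyz[cache$bend, , drop = FALSE]
  raw <- torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  coms <- do.call(rbind, lapply(cache$plane_a, function(rr)
    colMeans(xyz[rr, , drop = FALSE])))
  pl <- fit_plane(coms)
  up <- colMeans(xyz[cache$s27_a, , drop = FALSE]) -
    colMeans(xyz[cache$i38_a, , drop = FALSE])      # toward concave
  n <- if (sum(up * pl$normal) < 0) -pl$normal else pl$normal
  u <- unitv(p[3, ] - p[2, ])
  r <- colMeans(xyz[cache$com_b, , drop = FALSE]) - (p[2, ] + p[3, ]) / 2
  r <- r - sum(r * u) * u
  r <- r - sum(r * n) * n
  s <- sign(sum(cross3(u, unitv(r)) * n))
  if (s == 0) abort("degenerate interface geometry: bending sign undefined")
  s * raw
}

tilting_eval <- function(xyz, cache) {
  m <- function(rr) colMeans(xyz[rr, , drop = FALSE])
  torsion_angle(m(cache$tilt$a2), m(cache$tilt$a1),
                m(cache$tilt$b1), m(cache$tilt$b2))
}

#' Signed bending angle of an interface
#'
#' Dihedral over the Calpha quadruple bend_b(A) - bend_a(A) - bend_a(B) -
#' bend_b(B) (default I38-S27-S27-I38), taken on the bending monomer of each
#' hexamer, with the hinge along the S27(A)-S27(B) axis so flat layers read
#' exactly zero. The sign is anchored to the concave-face normal of hexamer
#' A recomputed from the snapshot: negative values bend the counterpart
#' hexamer toward the convex face. The value is unchanged when A and B are
#' swapped (reversal-invariant quadruple, symmetric anchor).
#'
#' @param x Snapshot: atom tibble, hexamer, tri-hexamer or structure.
#' @param interface A `bmc_interface` descriptor (see [trihex_interfaces()]).
#' @param map A [landmark_map()].
#' @return Signed angle in degrees, in (-180, 180].
#' @export
bending_angle <- function(x, interface, map = pdua_landmarks()) {
  atoms <- as_atoms(x)
  bending_eval(atom_xyz(atoms), angle_cache(atoms, interface, map))
}

#' Signed tilting angle of an interface
#'
#' Dihedral over midpoints: P1 = mid(tilt_b Calpha of the two interfacial
#' monomers of A), P2 = mid(tilt_a of A), P3 = mid(tilt_a of B), P4 =
#' mid(tilt_b of B) (defaults I18/M24). Flat layers read exactly zero;
#' positive values twist the counterpart hexamer right-handedly about the
#' interface axis. The value is unchanged when A and B are swapped.
#'
#' @inheritParams bending_angle
#' @return Signed angle in degrees, in (-180, 180].
#' @export
tilting_angle <- function(x, interface, map = pdua_landmarks()) {
  atoms <- as_atoms(x)
  tilting_eval(atom_xyz(atoms), angle_cache(atoms, interface, map))
}

#' Bending/tilting angle series over a trajectory
#'
#' Evaluates [bending_angle()] and [tilting_angle()] for every snapshot and
#' every interface of the tri-hexamer. Per-snapshot failures mark the row
#' invalid rather than aborting. The first snapshot is flagged as the
#' crystal/start reading; values more than 3 run-SDs from their interface
#' mean are flagged as outliers (flagged, never corrected).
#'
#' @param traj A `bmc_trajectory`.
#' @param map A [landmark_map()].
#' @param interfaces Optional list from [trihex_interfaces()]; by default the
#'   tri-hexamer topology is detected from the first snapshot (or taken from
#'   the trajectory's `crystal` field when present).
#' @return An `angle_series`: list with `angles` (tibble: snapshot, time_ps,
#'   interface, bending, tilting, is_start, valid, outlier), `by_interface`
#'   (mean/SD per interface) and `pooled` (grand mean/SD over all
#'   measurements).
#' @export
angle_series <- function(traj, map = pdua_landmarks(), interfaces = NULL) {
  stopifnot(inherits(traj, "bmc_trajectory"))
  if (is.null(interfaces)) {
    trihex <- traj$crystal %||% trihex_from_snapshot(traj, map)
    interfaces <- trihex_interfaces(trihex, map)
  }
  if (length(interfaces) == 0) abort("no interfaces to measure")
  caches <- lapply(interfaces, function(ifc)
    angle_cache(traj$atoms, ifc, map))
  rows <- lapply(seq_along(traj$coords), function(k) {
    xyz <- traj$coords[[k]]
    bind_rows(lapply(seq_along(interfaces), function(m) {
      b <- tryCatch(bending_eval(xyz, caches[[m]]),
                    error = function(e) NA_real_)
      t <- tryCatch(tilting_eval(xyz, caches[[m]]),
                    error = function(e) NA_real_)
      tibble(snapshot = k, time_ps = (k - 1) * traj$dt_ps,
             interface = interfaces[[m]]$id, bending = b, tilting = t,
             is_start = k == 1L, valid = is.finite(b) && is.finite(t))
    }))
  })
  angles <- bind_rows(rows) %>%
    group_by(.data$interface) %>%
    mutate(outlier =
             (is.finite(.data$bending) &
                abs(.data$bending - mean(.data$bending, na.rm = TRUE)) >
                  3 * sd(.data$bending, na.rm = TRUE)) |
             (is.finite(.data$tilting) &
                abs(.data$tilting - mean(.data$tilting, na.rm = TRUE)) >
                  3 * sd(.data$tilting, na.rm = TRUE))) %>%
    ungroup()
  by_interface <- angles %>%
    group_by(.data$interface) %>%
    summarise(bending_mean = mean(.data$bending, na.rm = TRUE),
              bending_sd = sd(.data$bending, na.rm = TRUE),
              tilting_mean = mean(.data$tilting, na.rm = TRUE),
              tilting_sd = sd(.data$tilting, na.rm = TRUE),
              n_valid = sum(.data$valid), .groups = "drop")
  pooled <- tibble(bending_mean = mean(angles$bending, na.rm = TRUE),
                   bending_sd = sd(angles$bending, na.rm = TRUE),
                   tilting_mean = mean(angles$tilting, na.rm = TRUE),
                   tilting_sd = sd(angles$tilting, na.rm = TRUE),
                   n_valid = sum(angles$valid))
  structure(list(angles = angles, by_interface = by_interface,
                 pooled = pooled, dt_ps = traj$dt_ps),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat("<angle_series> ", max(x$angles$snapshot), " snapshots x ",
      length(unique(x$angles$interface)), " interfaces\n", sep = "")
  print(x$by_interface)
  invisible(x)
}

trihex_from_snapshot <- function(traj, map) {
  det <- detect_hexamers(as_atoms(traj), map = map)
  if (length(det$hexamers) != 3)
    abort(paste0("expected 3 hexamers in the first snapshot, found ",
                 length(det$hexamers)))
  bmc_trihexamer(det$hexamers)
}

#' MD-average structure
#'
#' Superposes every snapshot on the first by the backbone atoms of the fit
#' selection (default: the chains of the first hexamer of the trajectory's
#' tri-hexamer topology), then averages coordinates atom-wise.
#'
#' @param traj A `bmc_trajectory` (>= 2 snapshots).
#' @param fit_chains Chains used for the fit; default the first hexamer.
#' @param map A [landmark_map()].
#' @return Atom tibble of the average model.
#' @export
average_structure <- function(traj, fit_chains = NULL, map = pdua_landmarks()) {
  stopifnot(inherits(traj, "bmc_trajectory"), length(traj$coords) >= 2)
  if (is.null(fit_chains)) {
    trihex <- traj$crystal %||% trihex_from_snapshot(traj, map)
    fit_chains <- trihex$hexamers[[1]]$chains
  }
  sel <- !traj$atoms$het & traj$atoms$atom %in% BACKBONE_ATOMS &
    traj$atoms$chain %in% fit_chains
  if (!any(sel)) abort("empty fit selection")
  ref <- traj$coords[[1]]
  acc <- matrix(0, nrow(ref), 3)
  for (k in seq_along(traj$coords)) {
    xyz <- traj$coords[[k]]
    tf <- kabsch(xyz[sel, , drop = FALSE], ref[sel, , drop = FALSE])
    acc <- acc + apply_transform(xyz, tf)
  }
  set_atom_xyz(traj$atoms, acc / length(traj$coords))
}

#' Backbone RMSD of each snapshot to a reference model
#'
#' Each snapshot is superposed on the reference by the backbone atoms of the
#' fit selection (default: all chains), then the backbone RMSD over the same
#' selection is reported.
#'
#' @param traj A `bmc_trajectory`.
#' @param reference Atom tibble with identical topology (e.g. from
#'   [average_structure()]).
#' @param fit_chains Chains used for fit and RMSD; default all.
#' @return Tibble: snapshot, time_ps, rmsd (Angstrom), in order.
#' @export
rmsd_series <- function(traj, reference, fit_chains = NULL) {
  stopifnot(inherits(traj, "bmc_trajectory"))
  reference <- as_atoms(reference)
  if (nrow(reference) != nrow(traj$atoms) ||
      !all(reference$chain == traj$atoms$chain &
             reference$resno == traj$atoms$resno &
             reference$atom == traj$atoms$atom))
    abort("reference topology does not match the trajectory")
  sel <- !traj$atoms$het & traj$atoms$atom %in% BACKBONE_ATOMS
  if (!is.null(fit_chains)) sel <- sel & traj$atoms$chain %in% fit_chains
  if (!any(sel)) abort("empty fit selection")
  ref <- atom_xyz(reference)[sel, , drop = FALSE]
  rmsd <- vapply(traj$coords, function(xyz)
    kabsch(xyz[sel, , drop = FALSE], ref)$rmsd, 1)
  tibble(snapshot = seq_along(traj$coords),
         time_ps = (seq_along(traj$coords) - 1) * traj$dt_ps,
         rmsd = rmsd)
}

#' Hexamer COM-distance deviation of an average model from the crystal
#'
#' Compares hexamer centre-of-mass spacings pair by pair; negative values
#' mean the average structure contracted relative to the crystal.
#'
#' @param avg Average model: atom tibble (or `bmc_trihexamer`).
#' @param crystal Reference `bmc_trihexamer` (or atom tibble).
#' @param map A [landmark_map()].
#' @return List with `per_pair` (tibble: pair, crystal_dist, avg_dist,
#'   deviation) and `mean` deviation over the three pairs.
#' @export
com_deviation <- function(avg, crystal, map = pdua_landmarks()) {
  coms_of <- function(x) {
    if (inherits(x, "bmc_trihexamer"))
      return(do.call(rbind, lapply(x$hexamers, function(h) h$com)))
    det <- detect_hexamers(as_atoms(x), map = map)
    if (length(det$hexamers) != 3)
      abort(paste0("expected 3 detectable hexamers, found ",
                   length(det$hexamers)))
    do.call(rbind, lapply(det$hexamers, function(h) h$com))
  }
  ca <- coms_of(avg); cc <- coms_of(crystal)
  # match hexamers by proximity (the average is fit on one hexamer, so the
  # assemblies share a frame)
  ord <- apply(cross_dist_matrix(cc, ca), 1, which.min)
  if (anyDuplicated(ord)) abort("cannot match hexamers between models")
  ca <- ca[ord, , drop = FALSE]
  idx <- rbind(c(1, 2), c(1, 3), c(2, 3))
  per_pair <- tibble(
    pair = paste0(idx[, 1], "-", idx[, 2]),
    crystal_dist = sqrt(rowSums((cc[idx[, 1], ] - cc[idx[, 2], ])^2)),
    avg_dist = sqrt(rowSums((ca[idx[, 1], ] - ca[idx[, 2], ])^2)))
  per_pair$deviation <- per_pair$avg_dist - per_pair$crystal_dist
  list(per_pair = per_pair, mean = mean(per_pair$deviation))
}

#' Plane representation of a tri-hexamer model
#'
#' Represents each hexamer by the exact plane through the plane-probe
#' Calphas of its three interface monomers (the chains in contact with the
#' other hexamers), plus the plane through the three hexamer centres.
#'
#' @param model A `bmc_trihexamer`.
#' @param map A [landmark_map()].
#' @return Tibble with one row per plane (three hexamers + "COM"): columns
#'   hexamer, px, py, pz (a point on the plane), nx, ny, nz (unit normal).
#' @export
plane_representation <- function(model, map = pdua_landmarks()) {
  stopifnot(inherits(model, "bmc_trihexamer"))
  ifcs <- trihex_interfaces(model, map)
  rows <- lapply(seq_along(model$hexamers), function(i) {
    h <- model$hexamers[[i]]
    chains <- unique(unlist(lapply(ifcs, function(f) {
      if (f$hex_i == i) f$tilt_chains_a
      else if (f$hex_j == i) f$tilt_chains_b
      else character()
    })))
    if (length(chains) < 3)
      chains <- unique(c(chains, unlist(lapply(ifcs, function(f) {
        if (f$hex_i == i) f$bend_chain_a
        else if (f$hex_j == i) f$bend_chain_b
        else character()
      }))))
    if (length(chains) < 3)
      abort(paste0("fewer than 3 interface monomers on hexamer ", i))
    ca <- ca_atoms(h$atoms)
    pts <- do.call(rbind, lapply(chains[1:3], function(cn)
      landmark_ca_point(ca, cn, map$plane_probe)))
    pl <- fit_plane(pts)
    n <- if (sum(pl$normal * h$normal) < 0) -pl$normal else pl$normal
    tibble(hexamer = as.character(i),
           px = pl$point[1], py = pl$point[2], pz = pl$point[3],
           nx = n[1], ny = n[2], nz = n[3])
  })
  coms <- unname(do.call(rbind, lapply(model$hexamers, function(h) h$com)))
  plc <- fit_plane(coms)
  bind_rows(bind_rows(rows),
            tibble(hexamer = "COM", px = plc$point[1], py = plc$point[2],
                   pz = plc$point[3], nx = plc$normal[1], ny = plc$normal[2],
                   nz = plc$normal[3]))
}
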