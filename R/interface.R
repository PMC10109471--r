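# Per-residue interface analytics
#
# Side-chain RMSD profiles over trajectories, interface masks, energy
# intervals and enrichment across the 18 monomers of a tri-hexamer, residue
# ranking, and a naive deterministic residue-pair score used as a stand-in
# for external force-field energies.

#' Interface mask of a multi-hexamer model
#'
#' Flags each (chain, residue) whose heavy atoms approach another hexamer
#' within `contact_cutoff`.
#'
#' @param model A `bmc_trihexamer` or list of `bmc_hexamer`.
#' @param contact_cutoff Heavy-atom cutoff (Angstrom); 0 flags nothing.
#' @return Tibble: hexamer, chain, resno, interface (logical).
#' @export
interface_mask <- function(model, contact_cutoff = 5) {
  hexamers <- if (inherits(model, "bmc_trihexamer")) model$hexamers else model
  stopifnot(length(hexamers) >= 1)
  rows <- lapply(seq_along(hexamers), function(i) {
    own <- heavy_atoms(hexamers[[i]]$atoms)
    res <- distinct(own, .data$chain, .data$resno)
    res$hexamer <- i
    res$interface <- FALSE
    others <- lapply(hexamers[-i], function(h) heavy_atoms(h$atoms))
    if (length(others) == 0 || contact_cutoff <= 0)
      return(select(res, "hexamer", "chain", "resno", "interface"))
    oth <- bind_rows(others)
    oxyz <- atom_xyz(oth)
    for (cn in unique(own$chain)) {
      sub <- filter(own, .data$chain == cn)
      sxyz <- atom_xyz(sub)
      ctr <- colMeans(sxyz)
      reach <- max(sqrt(rowSums(sweep(sxyz, 2, ctr)^2))) + contact_cutoff
      near <- oxyz[sqrt(rowSums(sweep(oxyz, 2, ctr)^2)) < reach, , drop = FALSE]
      if (nrow(near) == 0) next
      d <- cross_dist_matrix(sxyz, near)
      dmin <- apply(d, 1, min)
      hit <- unique(sub$resno[dmin < contact_cutoff])
      res$interface[res$chain == cn & res$resno %in% hit] <- TRUE
    }
    select(res, "hexamer", "chain", "resno", "interface")
  })
  bind_rows(rows)
}

sidechain_selector <- function(res_atoms) {
  sc <- filter(res_atoms, !.data$atom %in% c(BACKBONE_ATOMS, "CB"))
  if (nrow(sc) > 0) return(sc)
  cb <- filter(res_atoms, .data$atom == "CB")
  if (nrow(cb) > 0) return(cb)
  filter(res_atoms, .data$atom == "CA")
}

#' Side-chain RMSD profile over a trajectory
#'
#' For every residue of every monomer: each snapshot's residue backbone
#' (N, CA, C, O) is locally superposed on the reference residue, the RMSD of
#' the side-chain heavy atoms (beyond Cbeta; Ala falls back to Cbeta, Gly to
#' Calpha) is taken, and the mean over the included snapshots is reported.
#'
#' @param traj A `bmc_trajectory`.
#' @param avg Reference model (atom tibble, e.g. [average_structure()]) with
#'   matching topology.
#' @param exclude_first Number of leading snapshots to exclude (default 8).
#' @return A `residue_profile`: tibble chain, resno, value (Angstrom), with
#'   attribute `metric = "sidechain_rmsd"`.
#' @export
sidechain_rmsd_profile <- function(traj, avg, exclude_first = 8) {
  stopifnot(inherits(traj, "bmc_trajectory"))
  avg <- as_atoms(avg)
  n <- length(traj$coords)
  if (exclude_first >= n)
    abort("exclude_first must be smaller than the snapshot count")
  if (nrow(avg) != nrow(traj$atoms))
    abort("reference topology does not match the trajectory")
  keep <- !traj$atoms$het & !grepl("^H", traj$atoms$atom)
  ch <- traj$atoms$chain[keep]; rn <- traj$atoms$resno[keep]
  at <- traj$atoms$atom[keep]; orig <- which(keep)
  is_bb <- at %in% BACKBONE_ATOMS
  is_cb <- at == "CB"; is_ca <- at == "CA"
  keys <- split(seq_along(orig), paste(ch, rn))
  snaps <- (exclude_first + 1):n
  coords <- traj$coords[snaps]
  avg_xyz <- atom_xyz(avg)
  flip <- diag(c(1, 1, -1))
  res_rows <- lapply(keys, function(ii) {
    bb_idx <- orig[ii[is_bb[ii]]]
    sc <- ii[!is_bb[ii] & !is_cb[ii]]
    if (length(sc) == 0) sc <- ii[is_cb[ii]]
    if (length(sc) == 0) sc <- ii[is_ca[ii]]
    sc_idx <- orig[sc]
    if (length(bb_idx) < 3 || length(sc_idx) == 0)
      return(NULL)
    ref_bb <- avg_xyz[bb_idx, , drop = FALSE]
    ref_sc <- avg_xyz[sc_idx, , drop = FALSE]
    ct <- colMeans(ref_bb)
    q0 <- ref_bb - rep(ct, each = nrow(ref_bb))
    rsc0 <- ref_sc - rep(ct, each = nrow(ref_sc))
    vals <- vapply(coords, function(xyz) {
      m <- xyz[bb_idx, , drop = FALSE]
      cm <- colMeans(m)
      p0 <- m - rep(cm, each = nrow(m))
      s <- svd(crossprod(p0, q0))
      R <- if (det(s$u) * det(s$v) < 0)
        s$v %*% flip %*% t(s$u) else tcrossprod(s$v, s$u)
      sc0 <- xyz[sc_idx, , drop = FALSE] - rep(cm, each = length(sc_idx))
      sqrt(mean(rowSums((tcrossprod(sc0, R) - rsc0)^2)))
    }, 1)
    c(ii[1], mean(vals))
  })
  res_rows <- res_rows[!vapply(res_rows, is.null, TRUE)]
  mat <- do.call(rbind, res_rows)
  out <- tibble(chain = ch[mat[, 1]], resno = rn[mat[, 1]],
                value = mat[, 2]) %>%
    arrange(.data$chain, .data$resno)
  attr(out, "metric") <- "sidechain_rmsd"
  class(out) <- c("residue_profile", class(out))
  out
}

#' Read a per-residue energy table
#'
#' Tab-separated file with columns residue, monomer, value (any engine's
#' per-residue interaction energies).
#'
#' @param path File path.
#' @return A `residue_profile` tibble: chain, resno, value, with attribute
#'   `metric = "energy"`.
#' @export
read_energy_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("residue", "monomer", "value")
  if (!all(need %in% names(df)))
    abort("energy table needs columns: residue, monomer, value")
  out <- tibble(chain = as.character(df$monomer),
                resno = as.integer(df$residue),
                value = as.numeric(df$value))
  attr(out, "metric") <- "energy"
  class(out) <- c("residue_profile", class(out))
  out
}

#' Per-residue interval across monomers
#'
#' The spread (max - min) of a profile value across all monomer copies of
#' each residue, ranked descending (the "energy interval between the less
#' and most stabilizing position").
#'
#' @param profile A `residue_profile` (chain, resno, value).
#' @return Tibble: resno, interval, n_copies, sorted by interval descending.
#' @export
energy_interval <- function(profile) {
  if (anyNA(profile$value)) {
    bad <- unique(profile$resno[is.na(profile$value)])
    abort(paste0("missing profile entries for residue(s) ",
                 paste(bad, collapse = ", ")))
  }
  profile %>%
    group_by(.data$resno) %>%
    summarise(interval = max(.data$value) - min(.data$value),
              n_copies = n(), .groups = "drop") %>%
    arrange(desc(.data$interval))
}

#' Interface-vs-exposed enrichment per residue
#'
#' Signed difference mean(interface copies) - mean(off-interface copies) of a
#' profile value; negative values mean lower energy (stabilizing) or lower
#' RMSD (more ordered) at the interface. Residues lacking one of the two
#' classes are excluded and reported in the `excluded` attribute.
#'
#' @param profile A `residue_profile` (chain, resno, value).
#' @param mask Tibble from [interface_mask()].
#' @return Tibble: resno, delta, n_interface, n_exposed; attribute
#'   `excluded` lists the residues without both classes.
#' @export
interface_enrichment <- function(profile, mask) {
  joined <- left_join(profile, select(mask, "chain", "resno", "interface"),
                      by = c("chain", "resno"))
  if (anyNA(joined$interface))
    abort("mask does not cover all profile (chain, residue) entries")
  per <- joined %>%
    group_by(.data$resno) %>%
    summarise(n_interface = sum(.data$interface),
              n_exposed = sum(!.data$interface),
              delta = mean(.data$value[.data$interface]) -
                mean(.data$value[!.data$interface]),
              .groups = "drop")
  excluded <- per$resno[per$n_interface == 0 | per$n_exposed == 0]
  out <- filter(per, !.data$resno %in% excluded) %>%
    select("resno", "delta", "n_interface", "n_exposed")
  attr(out, "excluded") <- excluded
  out
}

#' Rank key interface residues
#'
#' Combines three criteria across monomer copies: (a) order at the
#' interface, operationalized as mean interface side-chain RMSD below the
#' 25th percentile of off-interface copies; (b) energy interval (spread
#' across copies); (c) interface enrichment (negative = stabilizing).
#' Residues are sorted by the mean of their per-criterion ranks; per-
#' criterion evidence is retained. When no residue discriminates (no (a)
#' hit, all intervals and enrichments below `tol`), the result carries
#' attribute `no_signal = TRUE`.
#'
#' @param rmsd_profile Side-chain RMSD `residue_profile` (or a list of them,
#'   one per independent trajectory; criterion (a) then requires the hit in
#'   at least two).
#' @param energy_profile Energy `residue_profile`.
#' @param mask Tibble from [interface_mask()].
#' @param tol Noise floor for the no-signal flag.
#' @return Tibble: resno, rank, rmsd_margin, ordered_at_interface, interval,
#'   enrichment; sorted by rank.
#' @export
rank_key_residues <- function(rmsd_profile, energy_profile, mask, tol = 1e-6) {
  profiles <- if (inherits(rmsd_profile, "residue_profile"))
    list(rmsd_profile) else rmsd_profile
  rmsd_crit <- lapply(profiles, function(p) {
    joined <- left_join(p, select(mask, "chain", "resno", "interface"),
                        by = c("chain", "resno"))
    joined %>%
      group_by(.data$resno) %>%
      summarise(margin = if (any(.data$interface) && any(!.data$interface))
                  mean(.data$value[.data$interface]) -
                    quantile(.data$value[!.data$interface], 0.25)
                else NA_real_,
                .groups = "drop")
  })
  margins <- bind_rows(rmsd_crit, .id = "run") %>%
    group_by(.data$resno) %>%
    summarise(rmsd_margin = mean(.data$margin),
              n_hits = sum(.data$margin < 0, na.rm = TRUE),
              .groups = "drop") %>%
    mutate(ordered_at_interface =
             .data$n_hits >= min(2, length(profiles)) &
               is.finite(.data$rmsd_margin))
  iv <- energy_interval(energy_profile)
  en <- interface_enrichment(energy_profile, mask)
  out <- margins %>%
    left_join(select(iv, "resno", "interval"), by = "resno") %>%
    left_join(select(en, "resno", "enrichment" = "delta"), by = "resno") %>%
    mutate(r_a = rank(.data$rmsd_margin, na.last = "keep"),
           r_b = rank(-.data$interval, na.last = "keep"),
           r_c = rank(.data$enrichment, na.last = "keep"),
           rank = rowMeans(cbind(.data$r_a, .data$r_b, .data$r_c),
                           na.rm = TRUE)) %>%
    arrange(.data$rank) %>%
    select("resno", "rank", "rmsd_margin", "ordered_at_interface",
           "interval", "enrichment")
  no_signal <- !any(out$ordered_at_interface, na.rm = TRUE) &&
    all(abs(out$interval) < tol, na.rm = TRUE) &&
    all(abs(out$enrichment) < tol, na.rm = TRUE)
  attr(out, "no_signal") <- no_signal
  out
}

# embedded formal charges (elementary units) for the naive score
naive_atom_charges <- function(atoms, his_charged = FALSE) {
  q <- numeric(nrow(atoms))
  q[atoms$resname %in% c("ASP") & atoms$atom %in% c("OD1", "OD2")] <- -0.5
  q[atoms$resname %in% c("GLU") & atoms$atom %in% c("OE1", "OE2")] <- -0.5
  q[atoms$resname == "LYS" & atoms$atom == "NZ"] <- 1
  q[atoms$resname == "ARG" & atoms$atom %in% c("NH1", "NH2")] <- 0.5
  if (his_charged)
    q[atoms$resname %in% c("HIS", "HSP") &
        atoms$atom %in% c("ND1", "NE2")] <- 0.5
  q
}

naive_atom_sigma <- function(atoms) {
  el <- substr(gsub("^[0-9]", "", atoms$atom), 1, 1)
  s <- unname(c(C = 3.4, N = 3.25, O = 3.0, S = 3.6)[el])
  s[is.na(s)] <- 3.4
  s
}

#' Parameters of the naive residue score
#'
#' @param lj_eps Lennard-Jones well depth (kJ/mol).
#' @param cutoff Pair cutoff (Angstrom).
#' @param his_charged Protonate histidine (+1 split over ND1/NE2).
#' @param charge_scale Multiplier on all formal charges.
#' @return Parameter list.
#' @export
naive_score_params <- function(lj_eps = 0.2, cutoff = 12, his_charged = FALSE,
                               charge_scale = 1) {
  list(lj_eps = lj_eps, cutoff = cutoff, his_charged = his_charged,
       charge_scale = charge_scale)
}

#' Naive per-residue inter-hexamer score
#'
#' Deterministic stand-in for external force-field evaluations: for each
#' residue copy, the sum over heavy-atom pairs with atoms of other hexamers
#' of a distance-dependent-dielectric Coulomb term (epsilon = r, embedded
#' integer formal charges on Asp/Glu/Lys/Arg, optional His+) plus a
#' Lennard-Jones term with embedded per-element radii. Intended for tests
#' and ranking only, not physical energies.
#'
#' @param model A `bmc_trihexamer` or list of `bmc_hexamer`.
#' @param params From [naive_score_params()].
#' @return A `residue_profile` tibble: chain, resno, value, coulomb, lj
#'   (kJ/mol), attribute `metric = "energy"`; residues without heavy atoms
#'   are listed in attribute `skipped`.
#' @export
naive_residue_score <- function(model, params = naive_score_params()) {
  hexamers <- if (inherits(model, "bmc_trihexamer")) model$hexamers else model
  ke <- 138.935485  # kJ mol^-1 A e^-2
  rows <- list(); skipped <- character()
  for (i in seq_along(hexamers)) {
    own <- heavy_atoms(hexamers[[i]]$atoms)
    oth <- bind_rows(lapply(hexamers[-i], function(h) heavy_atoms(h$atoms)))
    all_res <- distinct(hexamers[[i]]$atoms, .data$chain, .data$resno)
    oq <- naive_atom_charges(oth, params$his_charged) * params$charge_scale
    os <- naive_atom_sigma(oth)
    oxyz <- atom_xyz(oth)
    for (r in seq_len(nrow(all_res))) {
      sub <- filter(own, .data$chain == all_res$chain[r],
                    .data$resno == all_res$resno[r])
      if (nrow(sub) == 0) {
        skipped <- c(skipped, paste0(all_res$chain[r], ":", all_res$resno[r]))
        next
      }
      sxyz <- atom_xyz(sub)
      d <- cross_dist_matrix(sxyz, oxyz)
      within <- d < params$cutoff & d > 0
      if (!any(within)) {
        rows[[length(rows) + 1L]] <- tibble(
          chain = all_res$chain[r], resno = all_res$resno[r],
          value = 0, coulomb = 0, lj = 0)
        next
      }
      sq <- naive_atom_charges(sub, params$his_charged) * params$charge_scale
      ss <- naive_atom_sigma(sub)
      qq <- outer(sq, oq)
      sig <- outer(ss, os, "+") / 2
      coul <- sum((ke * qq / d^2)[within])     # epsilon = r => q q / r^2
      sr6 <- (sig[within] / d[within])^6
      lj <- sum(4 * params$lj_eps * (sr6^2 - sr6))
      rows[[length(rows) + 1L]] <- tibble(
        chain = all_res$chain[r], resno = all_res$resno[r],
        value = coul + lj, coulomb = coul, lj = lj)
    }
  }
  out <- bind_rows(rows)
  attr(out, "metric") <- "energy"
  attr(out, "skipped") <- skipped
  class(out) <- c("residue_profile", class(out))
  out
}

#' Snapshot closest to a reference model
#'
#' Index of the snapshot with the lowest backbone RMSD to the reference
#' (used to pick the minimized-snapshot candidate for energy analyses).
#'
#' @inheritParams rmsd_series
#' @return Integer snapshot index.
#' @export
closest_snapshot <- function(traj, reference, fit_chains = NULL) {
  rs <- rmsd_series(traj, reference, fit_chains)
  rs$snapshot[which.min(rs$rmsd)]
}
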