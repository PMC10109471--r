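# Hexamer layers
#
# Reconstruction of 2D hexamer layers from crystallographic symmetry, grouping
# of chains into C6 units, hexamer centres of mass, contact pairs, and
# tri-hexamer assembly (the simulation unit used for bending analysis).

#' Construct a hexamer container
#'
#' @param atoms Atom table holding exactly six chains.
#' @param normal Unit vector toward the declared convex face.
#' @param provenance Free-text or list provenance record.
#' @param map Landmark map used for the centre of mass (core residues).
#' @return A `bmc_hexamer` with fields atoms, chains, com, normal, provenance.
#' @export
bmc_hexamer <- function(atoms, normal = NULL, provenance = "",
                        map = pdua_landmarks()) {
  chains <- unique(atoms$chain)
  if (length(chains) != 6) abort("a hexamer must have exactly 6 chains")
  com <- backbone_com(atoms, map$core_range)
  if (is.null(normal)) {
    pl <- fit_plane(chain_coms(atoms))
    normal <- orient_convex(atoms, pl$normal, map)
  }
  if (abs(vnorm(normal) - 1) > 1e-6) abort("|normal| must be 1")
  out <- list(atoms = atoms, chains = chains, com = com, normal = normal,
              provenance = provenance, map = map)
  class(out) <- "bmc_hexamer"
  out
}

#' @export
print.bmc_hexamer <- function(x, ...) {
  cat("<bmc_hexamer> chains ", paste(x$chains, collapse = ""),
      ", com = (", paste(signif(x$com, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# unweighted mean of main-chain (N, CA, C, O) positions of core residues
backbone_com <- function(atoms, core_range) {
  bb <- backbone(atoms, core_range)
  if (nrow(bb) == 0) abort("empty core-range backbone selection")
  colMeans(atom_xyz(bb))
}

chain_coms <- function(atoms) {
  ca <- ca_atoms(atoms)
  do.call(rbind, lapply(split(ca, ca$chain), function(d) colMeans(atom_xyz(d))))
}

# Concave-face convention: the bending probe I38 sits below the S27 rim plane
# on the convex side, so the convex normal points from mean(S27) toward
# mean(I38) along the candidate plane normal.
orient_convex <- function(atoms, normal, map) {
  ca <- ca_atoms(atoms)
  s <- filter(ca, .data$resno == map$bend_pair[1])
  i <- filter(ca, .data$resno == map$bend_pair[2])
  if (nrow(s) == 0 || nrow(i) == 0) return(normal)  # orientation undecidable
  d <- colMeans(atom_xyz(i)) - colMeans(atom_xyz(s))
  if (sum(d * normal) < 0) -normal else normal
}

#' Hexamer centre of mass
#'
#' Unweighted mean of the N, CA, C, O positions of the core residues
#' (default 1-90) over all six chains.
#'
#' @param hexamer A `bmc_hexamer` (or atom table of one).
#' @param core_range Residue interval; default from the hexamer's map.
#' @return Length-3 numeric (Angstrom).
#' @export
hexamer_com <- function(hexamer, core_range = NULL) {
  atoms <- as_atoms(hexamer)
  if (is.null(core_range))
    core_range <- if (inherits(hexamer, "bmc_hexamer")) hexamer$map$core_range
                  else c(1, 90)
  backbone_com(atoms, core_range)
}

#' Expand a crystal into the surrounding layer
#'
#' Applies every symmetry operator and the integer lattice translations,
#' keeping copies whose protein centre of mass lies within `radius` of the
#' reference centre. Waters and other heteroatoms are removed. Duplicate
#' placements (operators mapping the contents onto itself) are dropped.
#'
#' @param crystal A [crystal_structure()] with a cell and operators.
#' @param radius Inclusion radius in Angstrom (> 0).
#' @return Tibble of atom sites with extra columns `copy`, `op`, and the
#'   translation indices `na`, `nb`, `nc`; chains are relabelled uniquely per
#'   copy in `chain`, with the original id kept in `chain_orig`.
#' @export
expand_layer <- function(crystal, radius = 100) {
  stopifnot(inherits(crystal, "crystal_structure"), radius > 0)
  if (!crystal$has_cell || length(crystal$sym_ops) == 0)
    abort("structure has no symmetry operators: supply a pre-expanded assembly")
  atoms <- filter(as_atoms(crystal), !.data$het)
  M <- orthogonalization_matrix(crystal$cell)
  Minv <- solve(M)
  frac <- atom_xyz(atoms) %*% t(Minv)
  ref_com <- colMeans(atom_xyz(backbone(atoms)))
  nmax <- ceiling(radius / min(crystal$cell[1:3])) + 1L
  grid <- expand.grid(na = -nmax:nmax, nb = -nmax:nmax, nc = -1:1)
  copies <- list(); seen <- character(); copy_id <- 0L
  for (k in seq_along(crystal$sym_ops)) {
    op <- crystal$sym_ops[[k]]
    f1 <- frac %*% t(op$R)
    base <- sweep(f1, 2, op$t, "+")
    for (g in seq_len(nrow(grid))) {
      shift <- as.numeric(grid[g, ])
      orth <- sweep(base, 2, shift, "+") %*% t(M)
      com <- colMeans(orth[atoms$atom %in% BACKBONE_ATOMS, , drop = FALSE])
      if (vnorm(com - ref_com) > radius) next
      key <- paste(round(com, 3), collapse = "_")
      if (key %in% seen) next
      seen <- c(seen, key)
      copy_id <- copy_id + 1L
      cp <- set_atom_xyz(atoms, orth)
      cp$copy <- copy_id; cp$op <- k
      cp$na <- shift[1]; cp$nb <- shift[2]; cp$nc <- shift[3]
      cp$chain_orig <- cp$chain
      copies[[copy_id]] <- cp
    }
  }
  out <- bind_rows(copies)
  # unique chain ids across copies
  ck <- paste(out$copy, out$chain_orig)
  out$chain <- chain_alphabet()[match(ck, unique(ck))]
  out
}

chain_alphabet <- function() {
  c(LETTERS, letters, as.character(0:9),
    apply(expand.grid(LETTERS, LETTERS), 1, paste0, collapse = ""))
}

#' Group chains into hexamer units
#'
#' Single-linkage clustering of chain centres (cutoff `cluster_cutoff`), then
#' a C6 check: six chains whose centres form a regular hexagon (equal radii,
#' consecutive 60 deg steps) and which are mutually superposable (backbone
#' RMSD after the optimal cyclic assignment below `rmsd_max`).
#'
#' @param assembly Atom tibble (e.g. from [expand_layer()]).
#' @param map Landmark map (core range, convex-face convention).
#' @param cluster_cutoff Chain-centre linkage cutoff in Angstrom.
#' @param rmsd_max C6 superposability tolerance (Angstrom).
#' @return List with `hexamers` (list of `bmc_hexamer`) and `ungrouped`
#'   (character vector of leftover chain ids).
#' @export
detect_hexamers <- function(assembly, map = pdua_landmarks(),
                            cluster_cutoff = 25, rmsd_max = 1.5) {
  atoms <- filter(as_atoms(assembly), !.data$het)
  chains <- unique(atoms$chain)
  if (length(chains) < 6)
    return(list(hexamers = list(), ungrouped = chains))
  coms <- chain_coms(atoms)
  coms <- coms[chains, , drop = FALSE]
  d <- cross_dist_matrix(coms, coms)
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"),
                      h = cluster_cutoff)
  hexamers <- list(); ungrouped <- character()
  for (g in unique(cl)) {
    ch <- chains[cl == g]
    sub <- filter(atoms, .data$chain %in% ch)
    if (length(ch) == 6 && is_c6_unit(sub, ch, coms[ch, , drop = FALSE], rmsd_max)) {
      hexamers[[length(hexamers) + 1L]] <- bmc_hexamer(sub, map = map)
    } else ungrouped <- c(ungrouped, ch)
  }
  list(hexamers = hexamers, ungrouped = ungrouped)
}

is_c6_unit <- function(atoms, chains, coms, rmsd_max) {
  ctr <- colMeans(coms)
  rel <- sweep(coms, 2, ctr)
  radii <- sqrt(rowSums(rel^2))
  if (max(radii) - min(radii) > 0.25 * mean(radii)) return(FALSE)
  # order chains around the ring and check ~60 deg steps
  pl <- tryCatch(fit_plane(coms), error = function(e) NULL)
  if (is.null(pl)) return(FALSE)
  e1 <- unitv(rel[1, ]); e2 <- cross3(pl$normal, e1)
  ang <- atan2(rel %*% e2, rel %*% e1) * 180 / pi
  ang_sorted <- sort((ang - ang[1]) %% 360)
  if (max(abs(ang_sorted - seq(0, 300, by = 60))) > 20) return(FALSE)
  ord <- chains[order(ang)]
  # adjacent chains mutually superposable (C6 symmetry)
  ca1 <- ca_atoms(filter(atoms, .data$chain == ord[1]))
  ca2 <- ca_atoms(filter(atoms, .data$chain == ord[2]))
  shared <- intersect(ca1$resno, ca2$resno)
  if (length(shared) < 10) return(FALSE)
  tf <- tryCatch(
    kabsch(atom_xyz(ca1[match(shared, ca1$resno), ]),
           atom_xyz(ca2[match(shared, ca2$resno), ])),
    error = function(e) NULL)
  !is.null(tf) && tf$rmsd < rmsd_max
}

#' Find contacting hexamer pairs
#'
#' A pair is accepted when the centre separation is below 80 Angstrom and the
#' minimal inter-hexamer heavy-atom distance is below `contact_cutoff`.
#' Interfacial monomers are the chains contributing any contact.
#'
#' @param hexamers List of `bmc_hexamer`.
#' @param contact_cutoff Heavy-atom contact cutoff (Angstrom, default 5).
#' @return Tibble with columns i, j, separation, min_dist and list-columns
#'   chains_i, chains_j of interfacial monomers. Empty tibble when none.
#' @export
find_pairs <- function(hexamers, contact_cutoff = 5) {
  if (length(hexamers) < 2)
    abort("need at least two hexamers")
  out <- list()
  for (i in seq_along(hexamers)) for (j in seq_along(hexamers)) {
    if (j <= i) next
    a <- hexamers[[i]]; b <- hexamers[[j]]
    sep <- vnorm(a$com - b$com)
    if (sep >= 80) next
    cc <- hexamer_contacts(a, b, contact_cutoff)
    if (nrow(cc$pairs) == 0) next
    out[[length(out) + 1L]] <- tibble(
      i = i, j = j, separation = sep, min_dist = cc$min_dist,
      chains_i = list(unique(cc$pairs$chain_a)),
      chains_j = list(unique(cc$pairs$chain_b)))
  }
  if (length(out) == 0)
    return(tibble(i = integer(), j = integer(), separation = numeric(),
                  min_dist = numeric(), chains_i = list(), chains_j = list()))
  bind_rows(out)
}

# heavy-atom contacts between two hexamers, with a midplane prefilter
hexamer_contacts <- function(a, b, cutoff) {
  ha <- heavy_atoms(a$atoms); hb <- heavy_atoms(b$atoms)
  axis <- b$com - a$com
  mid <- (a$com + b$com) / 2
  proj_a <- as.numeric(sweep(atom_xyz(ha), 2, mid) %*% unitv(axis))
  proj_b <- as.numeric(sweep(atom_xyz(hb), 2, mid) %*% unitv(axis))
  sa <- ha[proj_a > -(cutoff + 3), ]
  sb <- hb[proj_b < (cutoff + 3), ]
  if (nrow(sa) == 0 || nrow(sb) == 0)
    return(list(min_dist = Inf,
                pairs = tibble(chain_a = character(), chain_b = character())))
  d <- cross_dist_matrix(atom_xyz(sa), atom_xyz(sb))
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(list(min_dist = min(d),
                pairs = tibble(chain_a = character(), chain_b = character())))
  list(min_dist = min(d),
       pairs = tibble(chain_a = sa$chain[hit[, 1]], resno_a = sa$resno[hit[, 1]],
                      atom_a = sa$atom[hit[, 1]],
                      chain_b = sb$chain[hit[, 2]], resno_b = sb$resno[hit[, 2]],
                      atom_b = sb$atom[hit[, 2]],
                      dist = d[hit]))
}

#' Construct a tri-hexamer container
#'
#' @param hexamers List of three `bmc_hexamer`.
#' @param pairs Pair tibble as from [find_pairs()] (3 rows, closed triangle).
#' @return A `bmc_trihexamer` with combined atoms, hexamers, pairs and the
#'   best-fit layer plane of the three centres.
#' @export
bmc_trihexamer <- function(hexamers, pairs = NULL) {
  stopifnot(length(hexamers) == 3)
  atoms <- bind_rows(lapply(hexamers, function(h) h$atoms))
  if (length(unique(atoms$chain)) != 18)
    abort("tri-hexamer must have 18 distinct chains")
  if (is.null(pairs)) pairs <- find_pairs(hexamers)
  coms <- do.call(rbind, lapply(hexamers, function(h) h$com))
  out <- list(hexamers = hexamers, pairs = pairs, atoms = atoms,
              plane = fit_plane(coms))
  class(out) <- "bmc_trihexamer"
  out
}

#' @export
print.bmc_trihexamer <- function(x, ...) {
  d <- stats::dist(do.call(rbind, lapply(x$hexamers, function(h) h$com)))
  cat("<bmc_trihexamer> spacings:", paste(signif(d, 4), collapse = ", "), "A\n")
  invisible(x)
}

#' Build a tri-hexamer from a tiling crystal
#'
#' Expands the layer, detects hexamer units, restricts them to the layer
#' containing the reference hexamer (centres within `layer_tol` of the
#' best-fit plane) and returns the closed triangle of contacting hexamers.
#'
#' @param crystal A [crystal_structure()].
#' @param map Landmark map.
#' @param radius Expansion radius (Angstrom).
#' @param contact_cutoff Contact cutoff for pairing (Angstrom).
#' @param layer_tol Out-of-plane tolerance for layer membership (Angstrom).
#' @return A `bmc_trihexamer`. 1D-stripe or non-tiling packings raise an
#'   error naming the packing type.
#' @export
build_trihexamer <- function(crystal, map = pdua_landmarks(), radius = 100,
                             contact_cutoff = 5, layer_tol = 6) {
  layer <- expand_layer(crystal, radius = radius)
  det <- detect_hexamers(layer, map = map)
  hx <- det$hexamers
  if (length(hx) < 3)
    abort("fewer than three hexamers found within the expansion radius")
  # layer membership relative to the reference hexamer (first deposited chain)
  ref <- hx[[1]]
  nb <- order(vapply(hx, function(h) vnorm(h$com - ref$com), 1))
  near <- hx[nb[seq_len(min(7, length(hx)))]]
  pl <- fit_plane(do.call(rbind, lapply(near, function(h) h$com)))
  in_layer <- vapply(hx, function(h)
    abs(sum((h$com - pl$point) * pl$normal)) <= layer_tol, TRUE)
  hx <- hx[in_layer]
  pairs <- find_pairs(hx, contact_cutoff)
  ref_i <- which.min(vapply(hx, function(h) vnorm(h$com - ref$com), 1))
  partners <- unique(c(pairs$j[pairs$i == ref_i], pairs$i[pairs$j == ref_i]))
  has_pair <- function(a, b) any((pairs$i == min(a, b)) & (pairs$j == max(a, b)))
  tri <- NULL
  if (length(partners) >= 2) {
    cmb <- utils::combn(partners, 2)
    for (k in seq_len(ncol(cmb)))
      if (has_pair(cmb[1, k], cmb[2, k])) { tri <- c(ref_i, cmb[, k]); break }
  }
  if (is.null(tri))
    abort(paste0("no closed hexamer triangle: packing is ",
                 if (length(partners) >= 1) "a 1D stripe (contacts do not close)"
                 else "non-tiling (isolated hexamers)"))
  coms <- do.call(rbind, lapply(hx[tri], function(h) h$com))
  pl3 <- fit_plane(coms)
  if (max(abs(sweep(coms, 2, pl3$point) %*% pl3$normal)) > 3)
    abort("triangle centres are not coplanar within 3 Angstrom")
  bmc_trihexamer(hx[tri], find_pairs(hx[tri], contact_cutoff))
}
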