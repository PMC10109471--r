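# Regrafting and structure editing
#
# Superposition of hexamers onto template positions (Arr-A reconstitution),
# steric clash reporting, and alanine-scan edits.

#' Superpose one model on another
#'
#' Least-squares rigid superposition (Kabsch) of the mobile model's selection
#' onto the matching selection of the target. By default the selection is the
#' Calpha atoms of the core residue range, matched by (chain, residue);
#' supply `selection` as a list of two equal-length row-index vectors
#' (`mobile`, `target`) for explicit 1:1 matching.
#'
#' @param mobile,target Atom tibbles (or objects convertible via hexamer /
#'   structure accessors).
#' @param selection Optional list(mobile =, target =) of row indices.
#' @param map A [landmark_map()] providing the default core range.
#' @return A `rigid_transform` (fields R, t, rmsd) from [kabsch()].
#' @export
superpose <- function(mobile, target, selection = NULL,
                      map = pdua_landmarks()) {
  ma <- as_atoms(mobile); ta <- as_atoms(target)
  if (is.null(selection)) {
    mi <- which(!ma$het & ma$atom == "CA" &
                  ma$resno >= map$core_range[1] & ma$resno <= map$core_range[2])
    ti <- which(!ta$het & ta$atom == "CA" &
                  ta$resno >= map$core_range[1] & ta$resno <= map$core_range[2])
    key_m <- paste(ma$chain[mi], ma$resno[mi])
    key_t <- paste(ta$chain[ti], ta$resno[ti])
    shared <- intersect(key_m, key_t)
    selection <- list(mobile = mi[match(shared, key_m)],
                      target = ti[match(shared, key_t)])
  }
  if (length(selection$mobile) != length(selection$target))
    abort("selection does not map 1:1 between mobile and target")
  kabsch(atom_xyz(ma)[selection$mobile, , drop = FALSE],
         atom_xyz(ta)[selection$target, , drop = FALSE])
}

# order the six chains of a hexamer around its ring
ring_order <- function(h) {
  coms <- chain_coms(h$atoms)
  coms <- coms[h$chains, , drop = FALSE]
  rel <- sweep(coms, 2, colMeans(coms))
  e1 <- unitv(rel[1, ])
  e2 <- cross3(h$normal, e1)
  ang <- atan2(rel %*% e2, rel %*% e1)
  h$chains[order(ang)]
}

# best cyclic chain assignment of donor onto a template hexamer
best_hexamer_fit <- function(donor, tmpl, map) {
  d_ord <- ring_order(donor); t_ord <- ring_order(tmpl)
  dca <- ca_atoms(donor$atoms); tca <- ca_atoms(tmpl$atoms)
  core <- function(ca) filter(ca, .data$resno >= map$core_range[1],
                              .data$resno <= map$core_range[2])
  dca <- core(dca); tca <- core(tca)
  best <- NULL
  for (shift in 0:5) {
    assign <- setNames(t_ord[((seq_len(6) - 1 + shift) %% 6) + 1], d_ord)
    mx <- list(); tx <- list()
    ok <- TRUE
    for (dc in d_ord) {
      dsub <- filter(dca, .data$chain == dc)
      tsub <- filter(tca, .data$chain == assign[[dc]])
      shared <- intersect(dsub$resno, tsub$resno)
      if (length(shared) < 3) { ok <- FALSE; break }
      mx[[dc]] <- atom_xyz(dsub[match(shared, dsub$resno), ])
      tx[[dc]] <- atom_xyz(tsub[match(shared, tsub$resno), ])
    }
    if (!ok) next
    tf <- kabsch(do.call(rbind, mx), do.call(rbind, tx))
    if (is.null(best) || tf$rmsd < best$tf$rmsd)
      best <- list(tf = tf, assign = assign)
  }
  if (is.null(best)) abort("no residue overlap between donor and template")
  best
}

#' Regraft hexamers onto an Arr-A template
#'
#' Superposes each donor hexamer individually onto the corresponding hexamer
#' of the template tri-hexamer (core-range Calpha, best cyclic chain
#' assignment), producing a reconstituted assembly at the template geometry,
#' and reports residual steric clashes for downstream remediation.
#'
#' @param hexamers List of three donor `bmc_hexamer`, or a single
#'   `bmc_hexamer` used for all three positions.
#' @param template A `bmc_trihexamer` (or a `toy_lattice`, coerced via
#'   [as_trihexamer()]) defining the target geometry.
#' @param map A [landmark_map()] (core range for the fit).
#' @param clash_cutoff Heavy-atom clash cutoff (Angstrom, default 2.6).
#' @param max_rmsd Per-hexamer superposition RMSD above which the donor is
#'   rejected as too dissimilar (Angstrom, default 3).
#' @return List: `model` (`bmc_trihexamer` of the placed donors, chains
#'   relabelled to the template's), `clashes` (tibble from [clash_report()]),
#'   `rmsd` (per-hexamer fit RMSD), `spacing` (placed COM spacings).
#' @export
regraft_arrA <- function(hexamers, template, map = pdua_landmarks(),
                         clash_cutoff = 2.6, max_rmsd = 3) {
  if (inherits(hexamers, "bmc_hexamer"))
    hexamers <- list(hexamers, hexamers, hexamers)
  if (inherits(template, "toy_lattice")) template <- as_trihexamer(template)
  stopifnot(length(hexamers) == 3, inherits(template, "bmc_trihexamer"))
  placed <- list(); rmsds <- numeric(3)
  for (i in 1:3) {
    donor <- hexamers[[i]]; tmpl <- template$hexamers[[i]]
    fit <- best_hexamer_fit(donor, tmpl, map)
    if (fit$tf$rmsd > max_rmsd)
      abort(paste0("hexamer ", i, " too dissimilar to the template (RMSD ",
                   signif(fit$tf$rmsd, 3), " A > ", max_rmsd, ")"))
    rmsds[i] <- fit$tf$rmsd
    atoms <- transform_atoms(donor$atoms, fit$tf)
    atoms$chain <- unname(fit$assign[atoms$chain])
    placed[[i]] <- bmc_hexamer(atoms, provenance = paste0(
      "regrafted onto template hexamer ", i), map = map)
  }
  model <- bmc_trihexamer(placed, pairs = template$pairs)
  spacing <- as.numeric(stats::dist(do.call(rbind,
                                            lapply(placed, function(h) h$com))))
  list(model = model, clashes = clash_report(model, clash_cutoff),
       rmsd = rmsds, spacing = spacing)
}

#' Inter-hexamer steric clash report
#'
#' Heavy-atom pairs between different hexamers closer than `cutoff`,
#' aggregated per residue pair.
#'
#' @param model A `bmc_trihexamer` or list of `bmc_hexamer`.
#' @param cutoff Heavy-atom cutoff (Angstrom, default 2.6).
#' @return Tibble: chain_a, resno_a, resname_a, chain_b, resno_b, resname_b,
#'   min_dist; empty when clash-free. Attribute `cutoff` records the cutoff.
#' @export
clash_report <- function(model, cutoff = 2.6) {
  hexamers <- if (inherits(model, "bmc_trihexamer")) model$hexamers else model
  out <- list()
  for (i in seq_along(hexamers)) for (j in seq_along(hexamers)) {
    if (j <= i) next
    cc <- hexamer_contacts(hexamers[[i]], hexamers[[j]], cutoff)
    if (nrow(cc$pairs) == 0) next
    res_a <- distinct(hexamers[[i]]$atoms, .data$chain, .data$resno,
                      .data$resname)
    res_b <- distinct(hexamers[[j]]$atoms, .data$chain, .data$resno,
                      .data$resname)
    agg <- cc$pairs %>%
      group_by(.data$chain_a, .data$resno_a, .data$chain_b, .data$resno_b) %>%
      summarise(min_dist = min(.data$dist), .groups = "drop") %>%
      left_join(rename(res_a, chain_a = "chain", resno_a = "resno",
                       resname_a = "resname"),
                by = c("chain_a", "resno_a")) %>%
      left_join(rename(res_b, chain_b = "chain", resno_b = "resno",
                       resname_b = "resname"),
                by = c("chain_b", "resno_b"))
    out[[length(out) + 1L]] <- select(agg, "chain_a", "resno_a", "resname_a",
                                      "chain_b", "resno_b", "resname_b",
                                      "min_dist")
  }
  res <- if (length(out) == 0)
    tibble(chain_a = character(), resno_a = integer(), resname_a = character(),
           chain_b = character(), resno_b = integer(), resname_b = character(),
           min_dist = numeric())
  else bind_rows(out)
  attr(res, "cutoff") <- cutoff
  res
}

#' Alanine-scan mutation of a residue across monomers
#'
#' Truncates the side chain of `resno` to Cbeta and renames the residue ALA
#' in the selected monomer copies. Backbone and Cbeta coordinates are left
#' bitwise untouched. Copies already alanine count as zero edits; a glycine
#' target is an error.
#'
#' @param model A `bmc_trihexamer`.
#' @param resno Residue number to mutate.
#' @param copies `"interface6"` / `"interface9"` (the 6 or 9 interface
#'   monomers nearest a neighbouring hexamer), `"all18"`, or an explicit
#'   character vector of chain ids.
#' @param contact_cutoff Interface cutoff used for the interface-N choices.
#' @return List: `model` (edited `bmc_trihexamer`), `n_edited`, `chains`
#'   (chains actually edited).
#' @export
mutate_alanine <- function(model, resno, copies = "interface6",
                           contact_cutoff = 5) {
  stopifnot(inherits(model, "bmc_trihexamer"))
  all_atoms <- model$atoms
  if (!any(all_atoms$resno == resno & !all_atoms$het))
    abort(paste0("residue ", resno, " absent from the model"))
  if (is.character(copies) && length(copies) == 1 &&
      copies %in% c("interface6", "interface9", "all18")) {
    if (copies == "all18") {
      target <- unique(all_atoms$chain)
    } else {
      n_want <- if (copies == "interface6") 6L else 9L
      target <- interface_residue_chains(model, resno, contact_cutoff, n_want)
    }
  } else target <- as.character(copies)
  missing <- setdiff(target, unique(all_atoms$chain))
  if (length(missing) > 0)
    abort(paste0("chain(s) not in model: ", paste(missing, collapse = ", ")))
  hexamers <- lapply(model$hexamers, function(h) {
    at <- h$atoms
    for (cn in intersect(target, h$chains)) {
      sel <- at$chain == cn & at$resno == resno & !at$het
      if (!any(sel)) next
      rn <- unique(at$resname[sel])
      if (any(rn == "GLY"))
        abort(paste0("cannot truncate glycine at residue ", resno,
                     " (chain ", cn, ")"))
      if (all(rn == "ALA")) next
      drop <- sel & !at$atom %in% c(BACKBONE_ATOMS, "CB")
      at <- at[!drop, ]
      at$resname[at$chain == cn & at$resno == resno & !at$het] <- "ALA"
    }
    h$atoms <- at
    h
  })
  # recompute container bookkeeping without touching coordinates
  hexamers <- lapply(hexamers, function(h)
    bmc_hexamer(h$atoms, normal = h$normal, provenance = h$provenance,
                map = h$map))
  out <- bmc_trihexamer(hexamers, pairs = model$pairs)
  edited <- intersect(target, edited_chains(model, out, resno))
  list(model = out, n_edited = length(edited), chains = sort(edited))
}

# chains whose copy of `resno` differs between the two models
edited_chains <- function(before, after, resno) {
  cnt <- function(m) {
    at <- filter(m$atoms, .data$resno == !!resno, !.data$het)
    vapply(split(at, at$chain), nrow, 1L)
  }
  b <- cnt(before); a <- cnt(after)
  names(b)[b != a[names(b)]]
}

# the n interface monomers whose copy of `resno` is nearest another hexamer
interface_residue_chains <- function(model, resno, contact_cutoff, n_want) {
  hexamers <- model$hexamers
  d <- list()
  for (i in seq_along(hexamers)) {
    own <- filter(heavy_atoms(hexamers[[i]]$atoms), .data$resno == !!resno)
    oth <- bind_rows(lapply(hexamers[-i],
                            function(h) heavy_atoms(h$atoms)))
    oxyz <- atom_xyz(oth)
    for (cn in unique(own$chain)) {
      sxyz <- atom_xyz(filter(own, .data$chain == cn))
      d[[cn]] <- cross_dist_min(sxyz, oxyz)
    }
  }
  dd <- sort(unlist(d))
  close <- dd[dd < contact_cutoff + 10]
  if (length(close) < n_want)
    abort(paste0("only ", length(close), " interface copies of residue ",
                 resno, " found; ", n_want, " requested"))
  names(dd)[seq_len(n_want)]
}
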