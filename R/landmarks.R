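# Landmark maps
#
# Every geometric operator in the package is anchored to a small set of probe
# residues (PduA numbering by default). A landmark map is an explicit
# role -> residue-number table, making the operators portable to homologs by
# user-supplied renumbering rather than by sequence alignment.

LANDMARK_ROLES <- c("lys_edge", "bend_pair", "tilt_pair", "plane_probe",
                    "arg_insert", "pocket_acid", "saltbridge_pair")

#' Construct a landmark map
#'
#' Roles (defaults in PduA numbering): `lys_edge` the rim lysine whose
#' inter-hexamer Calpha distance discriminates arrangements (K26);
#' `bend_pair` the two bending probes on one interfacial monomer (S27, I38);
#' `tilt_pair` the two tilting probes taken on both interfacial monomers
#' (M24, I18); `plane_probe` the Calpha used for hexamer plane representations
#' (V54; A53 is the common alternative); `arg_insert` the arginine inserted
#' into the facing pocket in Arr-A (R79); `pocket_acid` the pocket carboxylate
#' (E83); `saltbridge_pair` the Arr-B-specific ion pair, CcmK numbering
#' (R28, D49). `core_range` bounds the residues used for hexamer
#' centre-of-mass and superposition selections.
#'
#' @param lys_edge,plane_probe,arg_insert,pocket_acid Single residue numbers.
#' @param bend_pair,tilt_pair,saltbridge_pair Length-2 residue numbers.
#' @param core_range Length-2 inclusive residue interval.
#' @return A `landmark_map` object.
#' @export
landmark_map <- function(lys_edge = 26, bend_pair = c(27, 38),
                         tilt_pair = c(24, 18), plane_probe = 54,
                         arg_insert = 79, pocket_acid = 83,
                         saltbridge_pair = c(28, 49),
                         core_range = c(1, 90)) {
  stopifnot(length(bend_pair) == 2, length(tilt_pair) == 2,
            length(saltbridge_pair) == 2, length(core_range) == 2,
            core_range[2] >= core_range[1])
  out <- list(lys_edge = as.integer(lys_edge),
              bend_pair = as.integer(bend_pair),
              tilt_pair = as.integer(tilt_pair),
              plane_probe = as.integer(plane_probe),
              arg_insert = as.integer(arg_insert),
              pocket_acid = as.integer(pocket_acid),
              saltbridge_pair = as.integer(saltbridge_pair),
              core_range = as.integer(core_range))
  class(out) <- "landmark_map"
  out
}

#' Default PduA landmark map
#' @return A `landmark_map` with PduA (3NGK) numbering.
#' @export
pdua_landmarks <- function() landmark_map()

#' @export
print.landmark_map <- function(x, ...) {
  cat("<landmark_map>\n")
  for (r in LANDMARK_ROLES)
    cat(" ", r, "=", paste(x[[r]], collapse = ", "), "\n")
  cat("  core_range =", paste(x$core_range, collapse = "-"), "\n")
  invisible(x)
}

#' Read landmark maps from a key-value config file
#'
#' Format: `[protein]` section headers, then `role = residue number(s)` lines
#' (comma-separated for two-residue roles); `#` starts a comment. Unstated
#' roles fall back to the PduA defaults.
#'
#' @param path Config file path.
#' @param protein Section to read; default: the first section.
#' @return A `landmark_map`.
#' @export
read_landmarks <- function(path, protein = NULL) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  sec <- cumsum(grepl("^\\[", ln))
  heads <- sub("^\\[(.*)\\]$", "\\1", ln[grepl("^\\[", ln)])
  if (length(heads) == 0) abort("no [protein] section in landmark config")
  pick <- if (is.null(protein)) 1L else match(protein, heads)
  if (is.na(pick)) abort(paste0("no section [", protein, "] in ", path))
  body <- ln[sec == pick & !grepl("^\\[", ln)]
  kv <- strsplit(body, "=")
  args <- list()
  for (p in kv) {
    if (length(p) != 2) next
    key <- trimws(p[1])
    val <- as.integer(trimws(strsplit(p[2], ",")[[1]]))
    args[[key]] <- val
  }
  do.call(landmark_map, args)
}

# flat role labels used in resolved tables
flatten_landmarks <- function(map) {
  tibble(role = c("lys_edge", "bend_a", "bend_b", "tilt_a", "tilt_b",
                  "plane_probe", "arg_insert", "pocket_acid",
                  "salt_arg", "salt_acid"),
         resno = c(map$lys_edge, map$bend_pair, map$tilt_pair,
                   map$plane_probe, map$arg_insert, map$pocket_acid,
                   map$saltbridge_pair))
}

#' Resolve landmark residues to Calpha coordinates
#'
#' @param x A structure, atom table, or hexamer.
#' @param map A [landmark_map()].
#' @param chain Chain identifier to resolve in.
#' @return Tibble with columns role, resno, chain, x, y, z (Calpha positions,
#'   Angstrom). Errors name the unresolvable role and chain.
#' @export
resolve_landmarks <- function(x, map = pdua_landmarks(), chain) {
  atoms <- as_atoms(x)
  ca <- ca_atoms(filter(atoms, .data$chain == !!chain))
  if (nrow(ca) == 0) abort(paste0("chain '", chain, "' not present"))
  lm <- flatten_landmarks(map)
  idx <- match(lm$resno, ca$resno)
  if (anyNA(idx)) {
    bad <- lm[is.na(idx), ]
    abort(paste0("cannot resolve landmark role(s) ",
                 paste0(bad$role, " (residue ", bad$resno, ")", collapse = ", "),
                 " in chain '", chain, "': residue or CA atom missing"))
  }
  tibble(role = lm$role, resno = lm$resno, chain = chain,
         x = ca$x[idx], y = ca$y[idx], z = ca$z[idx])
}

#' Coerce a structure-like object to its atom tibble
#'
#' Generic accessor returning the atom table (first model) of atom tibbles,
#' crystal structures, hexamers, tri-hexamers and trajectories.
#'
#' @param x The object.
#' @return An atom tibble.
#' @export
as_atoms <- function(x) UseMethod("as_atoms")

#' @export
as_atoms.data.frame <- function(x) x

#' @export
as_atoms.crystal_structure <- function(x) set_atom_xyz(x$atoms, x$models[[1]])

#' @export
as_atoms.bmc_hexamer <- function(x) x$atoms

#' @export
as_atoms.bmc_trihexamer <- function(x) x$atoms

#' @export
as_atoms.bmc_trajectory <- function(x) set_atom_xyz(x$atoms, x$coords[[1]])
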