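# Atom-site tables
#
# Every structure in the package is carried as a tibble of atom sites with
# columns: chain, resno, insert, resname, atom, alt, occ, het, x, y, z.
# Coordinates are in Angstrom; `het` flags HETATM records (waters, ligands).

ATOM_COLS <- c("chain", "resno", "insert", "resname", "atom", "alt",
               "occ", "het", "x", "y", "z")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Build an atom-site tibble
#'
#' Light constructor that fills optional bookkeeping columns with defaults and
#' validates invariants (finite coordinates, occupancy in \[0, 1\]).
#'
#' @param chain,resno,resname,atom,x,y,z Required per-atom vectors.
#' @param insert,alt,occ,het Optional; default "" / "" / 1 / FALSE.
#' @return A tibble of atom sites.
#' @export
atom_table <- function(chain, resno, resname, atom, x, y, z,
                       insert = "", alt = "", occ = 1, het = FALSE) {
  tb <- tibble(chain = as.character(chain), resno = as.integer(resno),
               insert = insert, resname = as.character(resname),
               atom = as.character(atom), alt = alt,
               occ = as.numeric(occ), het = het,
               x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  validate_atoms(tb)
  tb
}

validate_atoms <- function(atoms) {
  stopifnot(all(ATOM_COLS %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort("non-finite atom coordinates")
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    abort("occupancy outside [0, 1]")
  invisible(atoms)
}

#' Extract the coordinate matrix of an atom table
#' @param atoms Atom-site tibble.
#' @return n x 3 numeric matrix.
#' @export
atom_xyz <- function(atoms) cbind(x = atoms$x, y = atoms$y, z = atoms$z)

#' Replace the coordinates of an atom table
#' @param atoms Atom-site tibble.
#' @param xyz n x 3 matrix matching `nrow(atoms)`.
#' @return The atom table with new coordinates.
#' @export
set_atom_xyz <- function(atoms, xyz) {
  stopifnot(nrow(xyz) == nrow(atoms))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

transform_atoms <- function(atoms, tf) set_atom_xyz(atoms, apply_transform(atom_xyz(atoms), tf))

#' Atom subset selectors
#'
#' `heavy_atoms()` drops HETATM records and hydrogens; `backbone()` keeps
#' N/CA/C/O (optionally within a residue interval); `ca_atoms()` keeps
#' Calpha atoms.
#'
#' @param atoms An atom tibble.
#' @param core_range Optional inclusive residue interval.
#' @return The filtered atom tibble.
#' @export
heavy_atoms <- function(atoms) {
  filter(atoms, !.data$het, !grepl("^H|^[0-9]H", .data$atom))
}

#' @rdname heavy_atoms
#' @export
backbone <- function(atoms, core_range = NULL) {
  out <- filter(atoms, !.data$het, .data$atom %in% BACKBONE_ATOMS)
  if (!is.null(core_range))
    out <- filter(out, .data$resno >= core_range[1], .data$resno <= core_range[2])
  out
}

#' @rdname heavy_atoms
#' @export
ca_atoms <- function(atoms) filter(atoms, !.data$het, .data$atom == "CA")

# reduce alternate locations to the highest-occupancy conformer
# (tie broken alphabetically by alt-loc id)
reduce_altloc <- function(atoms) {
  if (!any(nzchar(atoms$alt))) return(atoms)
  atoms %>%
    mutate(.row = row_number()) %>%
    group_by(.data$chain, .data$resno, .data$insert, .data$atom) %>%
    arrange(desc(.data$occ), .data$alt, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    arrange(.data$.row) %>%
    select(-".row")
}
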