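# Coordinate file I/O
#
# PDB (and mmCIF) parsing is delegated to bio3d; the package adds the pieces
# bio3d does not expose: CRYST1 cell, REMARK 290 symmetry operators, a
# space-group fallback table, alt-loc reduction by occupancy, and the tidy
# atom-site container shared by all downstream operators.

#' Construct a crystal structure container
#'
#' @param atoms Atom-site tibble (topology + first-model coordinates).
#' @param models List of n x 3 coordinate matrices, one per MODEL.
#' @param cell Named numeric (a, b, c, alpha, beta, gamma) or NULL.
#' @param sym_ops List of `list(R = 3x3, t = length-3)` operators in
#'   fractional coordinates (identity included) or empty list.
#' @param spacegroup Hermann-Mauguin name, or "".
#' @return A `crystal_structure`.
#' @export
crystal_structure <- function(atoms, models = NULL, cell = NULL,
                              sym_ops = list(), spacegroup = "") {
  validate_atoms(atoms)
  if (is.null(models)) models <- list(atom_xyz(atoms))
  stopifnot(length(models) >= 1,
            all(vapply(models, nrow, 1L) == nrow(atoms)))
  if (!is.null(cell) && any(cell[1:3] <= 0)) abort("cell lengths must be > 0")
  out <- list(atoms = set_atom_xyz(atoms, models[[1]]), models = models,
              cell = cell, sym_ops = sym_ops, spacegroup = spacegroup,
              has_cell = !is.null(cell))
  class(out) <- "crystal_structure"
  out
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat("<crystal_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chains, ", length(x$models),
      " model(s)\n", sep = "")
  if (x$has_cell)
    cat("  cell:", paste(signif(x$cell, 6), collapse = " "),
        " sg:", x$spacegroup, " (", length(x$sym_ops), "ops )\n")
  else cat("  no unit cell\n")
  invisible(x)
}

#' Number of models (snapshots) in a structure or trajectory
#' @param x A `crystal_structure` or `bmc_trajectory`.
#' @export
n_models <- function(x) length(x$models %||% x$coords)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a coordinate file
#'
#' Loads all MODELs, the CRYST1 cell and the REMARK 290 symmetry operators
#' (falling back to an embedded space-group table keyed by the CRYST1
#' Hermann-Mauguin name when SMTRY records are absent). Alternate locations
#' are reduced to the highest-occupancy conformer (ties broken alphabetically).
#' Waters and heteroatoms are retained but flagged `het`; layer expansion
#' removes them downstream.
#'
#' @param path File path.
#' @param format "pdb" or "mmcif".
#' @return A [crystal_structure()]. If no cell is present the structure loads
#'   with an empty operator list and a warning.
#' @export
read_structure <- function(path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "pdb") read_structure_pdb(path) else read_structure_cif(path)
}

bio3d_to_atoms <- function(at) {
  atom_table(chain = ifelse(is.na(at$chain), "A", at$chain),
             resno = at$resno,
             resname = at$resid, atom = at$elety,
             x = at$x, y = at$y, z = at$z,
             insert = ifelse(is.na(at$insert), "", at$insert),
             alt = ifelse(is.na(at$alt), "", at$alt),
             occ = ifelse(is.na(at$o), 1, pmin(1, pmax(0, at$o))),
             het = at$type == "HETATM")
}

read_structure_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(paste0("cannot parse PDB file ", path, ": ",
                                     conditionMessage(e))))
  atoms <- bio3d_to_atoms(pdb$atom)
  nm <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  models <- lapply(seq_len(nm), function(i) {
    v <- if (is.matrix(pdb$xyz)) pdb$xyz[i, ] else as.numeric(pdb$xyz)
    matrix(v, ncol = 3, byrow = TRUE)
  })
  # alt-loc reduction, applied coherently to every model
  if (any(nzchar(atoms$alt))) {
    keep <- sort(reduce_altloc(mutate(atoms, .keep_row = row_number()))$.keep_row)
    atoms <- atoms[keep, ]
    models <- lapply(models, function(m) m[keep, , drop = FALSE])
  }

  hdr <- read_pdb_header(path)
  if (is.null(hdr$cell))
    warn(paste0("no CRYST1 record in ", path,
                ": structure loaded without cell or symmetry operators"))
  crystal_structure(atoms, models, cell = hdr$cell, sym_ops = hdr$ops,
                    spacegroup = hdr$spacegroup)
}

read_pdb_header <- function(path) {
  ln <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", ln, value = TRUE)
  cell <- NULL; sg <- ""; ops <- list()
  if (length(cr) >= 1) {
    f <- cr[1]
    cell <- setNames(as.numeric(c(substr(f, 7, 15), substr(f, 16, 24),
                                  substr(f, 25, 33), substr(f, 34, 40),
                                  substr(f, 41, 47), substr(f, 48, 54))),
                     c("a", "b", "c", "alpha", "beta", "gamma"))
    sg <- trimws(substr(f, 56, 66))
    sm <- grep("^REMARK 290 +SMTRY", ln, value = TRUE)
    if (length(sm) >= 3) {
      num <- lapply(sm, function(s) {
        p <- strsplit(trimws(substr(s, 12, nchar(s))), "\\s+")[[1]]
        as.numeric(p[-1])  # opno r1 r2 r3 t
      })
      opno <- vapply(num, function(v) v[1], 1)
      ops <- lapply(sort(unique(opno)), function(k) {
        rows <- do.call(rbind, num[opno == k])
        Rc <- rows[order(vapply(sm[opno == k], function(s)
          as.integer(substr(s, 18, 18)), 1L)), , drop = FALSE]
        list(R = Rc[, 2:4, drop = FALSE], t = Rc[, 5])
      })
      # SMTRY matrices act on orthogonal coordinates; convert to fractional
      M <- orthogonalization_matrix(cell)
      Minv <- solve(M)
      ops <- lapply(ops, function(o)
        list(R = Minv %*% o$R %*% M, t = as.numeric(Minv %*% o$t)))
    } else if (nzchar(sg)) {
      ops <- spacegroup_ops(sg)
      if (length(ops) == 0)
        warn(paste0("space group '", sg, "' not in the embedded table; ",
                    "only the identity operator is available"))
    }
    if (length(ops) == 0) ops <- list(list(R = diag(3), t = c(0, 0, 0)))
  }
  list(cell = cell, spacegroup = sg, ops = ops)
}

read_structure_cif <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) abort(paste0("cannot parse mmCIF file ", path, ": ",
                                     conditionMessage(e))))
  atoms <- reduce_altloc(bio3d_to_atoms(pdb$atom))
  ln <- readLines(path, warn = FALSE)
  getv <- function(key) {
    hit <- grep(paste0("^", key, "\\b"), ln, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    as.numeric(strsplit(trimws(hit[1]), "\\s+")[[1]][2])
  }
  cl <- c(a = getv("_cell.length_a"), b = getv("_cell.length_b"),
          c = getv("_cell.length_c"), alpha = getv("_cell.angle_alpha"),
          beta = getv("_cell.angle_beta"), gamma = getv("_cell.angle_gamma"))
  sg <- grep("_symmetry.space_group_name_H-M", ln, value = TRUE)
  sg <- if (length(sg)) gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sg[1]))) else ""
  cell <- NULL; ops <- list()
  if (all(is.finite(cl))) {
    cell <- cl
    ops <- spacegroup_ops(sg)
    if (length(ops) == 0) ops <- list(list(R = diag(3), t = c(0, 0, 0)))
  } else {
    warn(paste0("no _cell block in ", path, ": structure loaded without cell"))
  }
  crystal_structure(atoms, cell = cell, sym_ops = ops, spacegroup = sg)
}

#' Fractional -> orthogonal conversion matrix of a unit cell
#' @param cell Named numeric (a, b, c, alpha, beta, gamma in deg).
#' @return 3x3 matrix M with x_orth = M %*% x_frac.
#' @export
orthogonalization_matrix <- function(cell) {
  a <- cell[[1]]; b <- cell[[2]]; cc <- cell[[3]]
  al <- cell[[4]] * pi / 180; be <- cell[[5]] * pi / 180; ga <- cell[[6]] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)), 3, 3, byrow = TRUE)
}

# embedded operators (fractional) for the space groups met in BMC-H layers
spacegroup_ops <- function(name) {
  key <- toupper(gsub("[ ()]", "", name))
  hex6 <- list(  # powers of the hexagonal 6-fold: (x-y, x, z)
    diag(3),
    matrix(c(1, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    matrix(c(0, -1, 0, 1, -1, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    matrix(c(-1, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    matrix(c(0, 1, 0, -1, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  two_x <- matrix(c(1, -1, 0, 0, -1, 0, 0, 0, -1), 3, 3, byrow = TRUE)
  mk <- function(Rs, ts) purrr::map2(Rs, ts, function(R, t) list(R = R, t = t))
  switch(key,
    "P1" = mk(list(diag(3)), list(c(0, 0, 0))),
    "P6" = mk(hex6, rep(list(c(0, 0, 0)), 6)),
    "P63" = mk(hex6, lapply(0:5, function(k) c(0, 0, (k %% 2) / 2))),
    "P622" = mk(c(hex6, lapply(hex6, function(R) R %*% two_x)),
                rep(list(c(0, 0, 0)), 12)),
    "P6322" = mk(c(hex6, lapply(hex6, function(R) R %*% two_x)),
                 c(lapply(0:5, function(k) c(0, 0, (k %% 2) / 2)),
                   lapply(0:5, function(k) c(0, 0, (k %% 2) / 2)))),
    list())
}

#' Write atoms or a trajectory as a PDB file
#'
#' Produces standard ATOM records; multiple models are framed with
#' MODEL/ENDMDL. Coordinates round-trip through [read_structure()] to 1e-3 A.
#'
#' @param x Atom tibble, `crystal_structure`, `bmc_trajectory`, hexamer or
#'   tri-hexamer.
#' @param path Output file.
#' @param multi_model Write all models (default: TRUE when more than one).
#' @param cell Optional cell to emit as CRYST1 (named a,b,c,alpha,beta,gamma).
#' @return `path`, invisibly.
#' @export
write_model <- function(x, path, multi_model = NULL, cell = NULL) {
  atoms <- as_atoms(x)
  if (nrow(atoms) == 0) abort("empty model")
  models <- if (inherits(x, "crystal_structure")) x$models
            else if (inherits(x, "bmc_trajectory")) x$coords
            else list(atom_xyz(atoms))
  if (is.null(multi_model)) multi_model <- length(models) > 1
  if (!multi_model) models <- models[1]
  bad <- unique(atoms$chain[nchar(atoms$chain) != 1])
  if (length(bad))
    abort(paste0("chain id(s) not writable as single PDB characters: ",
                 paste(bad, collapse = ", ")))
  if (is.null(cell) && !is.null(x$cell)) cell <- x$cell
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cell))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                       cell[[1]], cell[[2]], cell[[3]], cell[[4]], cell[[5]],
                       cell[[6]], if (is.null(x$spacegroup) ||
                                      !nzchar(x$spacegroup)) "P 1"
                                  else x$spacegroup), con)
  rec <- ifelse(atoms$het, "HETATM", "ATOM  ")
  for (m in seq_along(models)) {
    if (multi_model) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- models[[m]]
    writeLines(sprintf(
      "%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
      rec, (seq_len(nrow(atoms)) - 1L) %% 99999L + 1L,
      ifelse(nchar(atoms$atom) < 4, paste0(" ", atoms$atom), atoms$atom),
      ifelse(nzchar(atoms$alt), atoms$alt, " "),
      atoms$resname, atoms$chain, atoms$resno,
      ifelse(nzchar(atoms$insert), atoms$insert, " "),
      xyz[, 1], xyz[, 2], xyz[, 3], atoms$occ, 0), con)
    if (multi_model) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Interpret a multi-model structure as a trajectory ensemble
#'
#' @param x A `crystal_structure` (or atom tibble for a single snapshot).
#' @param dt_ps Frame interval in picoseconds (default 250, the usual
#'   snapshot spacing of the simulations this package analyses).
#' @param provenance Free-text origin note.
#' @return A `bmc_trajectory`: topology tibble + list of coordinate matrices.
#' @export
as_trajectory <- function(x, dt_ps = 250, provenance = "") {
  if (inherits(x, "bmc_trajectory")) return(x)
  if (inherits(x, "crystal_structure")) {
    atoms <- x$atoms; coords <- x$models
  } else {
    atoms <- as_atoms(x); coords <- list(atom_xyz(atoms))
  }
  new_trajectory(atoms, coords, dt_ps, provenance)
}

new_trajectory <- function(atoms, coords, dt_ps = 250, provenance = "") {
  stopifnot(length(coords) >= 1,
            all(vapply(coords, nrow, 1L) == nrow(atoms)))
  out <- list(atoms = set_atom_xyz(atoms, coords[[1]]), coords = coords,
              dt_ps = dt_ps, provenance = provenance)
  class(out) <- "bmc_trajectory"
  out
}

#' @export
print.bmc_trajectory <- function(x, ...) {
  cat("<bmc_trajectory> ", length(x$coords), " snapshots x ", nrow(x$atoms),
      " atoms (dt = ", x$dt_ps, " ps)\n", sep = "")
  invisible(x)
}
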