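# Hexamer-hexamer arrangement classification
#
# Interface metrics (inter-lysine distance, spacing, lateral offset, contact
# flags) and the Arr-A/B/C/D decision rule.

ARR_PROTOTYPES <- tibble(
  label = c("Arr-A", "Arr-C", "Arr-B"),
  d_lys = c(8.0, 10.0, 16.0),
  spacing = c(68.5, 69.5, 70.5))

# Lateral offset at/above which an interface matches the single reported
# offset-stacked arrangement (Arr-D). Explicit stand-in signature; see the
# classify() documentation.
ARR_D_OFFSET <- 15

#' Interface metrics between two hexamers
#'
#' Computes the Fig-1-style interface descriptors for one hexamer pair:
#' the Calpha-Calpha distance between the `lys_edge` residues of facing
#' monomers (minimum and per facing pair), the equivalent `arg_insert`
#' Calpha distance, the centre-of-mass spacing, the in-plane lateral offset
#' from the head-on position, and two contact flags (arginine inserted into
#' the facing carboxylate pocket; cross-interface salt bridge of the
#' `saltbridge_pair`).
#'
#' Facing monomer pairs are the mutually nearest `lys_edge` Calpha pairs
#' across the interface, restricted to pairs closer than half the spacing.
#' Contact flags use a 4.5 A nitrogen-oxygen cutoff, either direction.
#'
#' @param a,b Two `bmc_hexamer` objects (or `a` a list of two).
#' @param map A [landmark_map()].
#' @param contact_cutoff N-O distance cutoff (Angstrom) for both flags.
#' @return An `interface_metrics` object: fields `d_lys` (minimum),
#'   `d_lys_max`, `pairs` (tibble chain_a, chain_b, d_lys, arg_ca),
#'   `spacing`, `lateral_offset`, `arg_inserted`, `saltbridge`.
#' @export
interface_metrics <- function(a, b = NULL, map = pdua_landmarks(),
                              contact_cutoff = 4.5) {
  if (is.null(b)) { stopifnot(is.list(a), length(a) == 2); b <- a[[2]]; a <- a[[1]] }
  stopifnot(inherits(a, "bmc_hexamer"), inherits(b, "bmc_hexamer"))
  lys_a <- chain_landmark_ca(a, map$lys_edge)
  lys_b <- chain_landmark_ca(b, map$lys_edge)
  arg_a <- chain_landmark_ca(a, map$arg_insert, required = FALSE)
  arg_b <- chain_landmark_ca(b, map$arg_insert, required = FALSE)
  spacing <- vnorm(b$com - a$com)
  dm <- cross_dist_matrix(lys_a, lys_b)
  # mutual nearest lysine pairs across the interface, near the interface
  ia <- apply(dm, 1, which.min)
  ib <- apply(dm, 2, which.min)
  mutual <- which(ib[ia] == seq_len(nrow(dm)))
  keep <- mutual[dm[cbind(mutual, ia[mutual])] < spacing / 2]
  if (length(keep) == 0)
    abort("no facing lysine pair within spacing/2: hexamers do not share an interface")
  pairs <- tibble(
    chain_a = rownames(lys_a)[keep],
    chain_b = rownames(lys_b)[ia[keep]],
    d_lys = dm[cbind(keep, ia[keep])],
    arg_ca = if (is.null(arg_a) || is.null(arg_b)) NA_real_ else
      sqrt(rowSums((arg_a[keep, , drop = FALSE] -
                    arg_b[ia[keep], , drop = FALSE])^2)))
  out <- list(
    d_lys = min(pairs$d_lys),
    d_lys_max = max(pairs$d_lys),
    pairs = arrange(pairs, .data$d_lys),
    spacing = spacing,
    lateral_offset = lateral_offset(
      a, b,
      lys_a[keep[which.min(pairs$d_lys)], ],
      lys_b[ia[keep[which.min(pairs$d_lys)]], ]),
    arg_inserted = contact_flag(a, b, map$arg_insert, map$pocket_acid,
                                contact_cutoff),
    saltbridge = contact_flag(a, b, map$saltbridge_pair[1],
                              map$saltbridge_pair[2], contact_cutoff))
  stopifnot(out$d_lys > 0, out$spacing > 0)
  class(out) <- "interface_metrics"
  out
}

#' @export
print.interface_metrics <- function(x, ...) {
  cat(sprintf(
    "<interface_metrics> d_lys %.2f-%.2f A, spacing %.2f A, offset %.2f A,\n  arg_inserted %s, saltbridge %s\n",
    x$d_lys, x$d_lys_max, x$spacing, x$lateral_offset,
    x$arg_inserted, x$saltbridge))
  invisible(x)
}

# Calpha positions of one residue across the chains of a hexamer
chain_landmark_ca <- function(h, resno, required = TRUE) {
  ca <- filter(ca_atoms(h$atoms), .data$resno == !!resno)
  ca <- ca[match(h$chains, ca$chain), ]
  if (anyNA(ca$x)) {
    if (!required) return(NULL)
    abort(paste0("cannot resolve landmark residue ", resno,
                 " (CA) in chain(s) ",
                 paste(h$chains[is.na(ca$x)], collapse = ", ")))
  }
  m <- atom_xyz(ca)
  rownames(m) <- ca$chain
  m
}

# in-plane displacement of b from the head-on position, measured
# symmetrically from both hexamers' facing-lysine radial axes
lateral_offset <- function(a, b, ka, kb) {
  n <- unitv(a$normal + b$normal * sign(sum(a$normal * b$normal)))
  inplane <- function(v) v - sum(v * n) * n
  d <- inplane(b$com - a$com)
  off_from <- function(lys, com, dvec) {
    u <- unitv(inplane(lys - com))
    sqrt(max(0, sum(dvec^2) - sum(dvec * u)^2))
  }
  mean(c(off_from(ka, a$com, d), off_from(kb, b$com, -d)))
}

# any sidechain N of residue res_n on one hexamer within cutoff of a
# sidechain O of residue res_o on the other (checked in both directions)
contact_flag <- function(a, b, res_n, res_o, cutoff) {
  pick <- function(h, res, pat) {
    at <- filter(heavy_atoms(h$atoms), .data$resno == !!res,
                 grepl(pat, .data$atom))
    if (nrow(at) == 0) NULL else atom_xyz(at)
  }
  one_way <- function(h1, h2) {
    n <- pick(h1, res_n, "^N[EHZD]")
    o <- pick(h2, res_o, "^O[EDG]")
    !is.null(n) && !is.null(o) && cross_dist_min(n, o) < cutoff
  }
  one_way(a, b) || one_way(b, a)
}

#' Classify a hexamer-hexamer arrangement
#'
#' Decision rule (boundaries made explicit because published descriptions
#' give exemplar ranges, not bins): Arr-A if minimum d_lys <= 9.0 A; Arr-C if
#' 9.0 < d_lys <= 12.0; Arr-B if d_lys >= 13.5; for d_lys in (12.0, 13.5)
#' the nearest prototype in (d_lys, spacing) space wins, with prototypes
#' (8.0, 68.5) Arr-A, (10, 69.5) Arr-C, (16, 70.5) Arr-B (ties broken in
#' that order). Arr-D, reported for a single offset-stacked crystal form, is
#' assigned whenever the lateral offset is at least 15 A. Non-finite or
#' implausibly large metrics (d_lys > 25 A) give "unclassified".
#'
#' @param metrics An [interface_metrics()] object.
#' @return An `arrangement_class`: fields `label`, `evidence`.
#' @export
classify <- function(metrics) {
  stopifnot(inherits(metrics, "interface_metrics"))
  label <- classify_dlys(metrics$d_lys, metrics$spacing,
                         metrics$lateral_offset)
  structure(list(label = label, evidence = metrics),
            class = "arrangement_class")
}

#' @export
print.arrangement_class <- function(x, ...) {
  cat("<arrangement_class>", x$label, "\n")
  print(x$evidence)
  invisible(x)
}

#' Arrangement label from raw metrics
#'
#' The bare decision rule of [classify()], for use on numeric metrics (for
#' example the ground truth of a synthetic lattice).
#'
#' @param d_lys Minimum inter-lysine Calpha distance (Angstrom).
#' @param spacing Centre-of-mass spacing (Angstrom).
#' @param offset Lateral offset (Angstrom).
#' @return Character label.
#' @export
classify_dlys <- function(d_lys, spacing, offset = 0) {
  if (!is.finite(d_lys) || !is.finite(spacing)) return("unclassified")
  if (is.finite(offset) && offset >= ARR_D_OFFSET) return("Arr-D")
  if (d_lys > 25) return("unclassified")
  if (d_lys <= 9.0) return("Arr-A")
  if (d_lys <= 12.0) return("Arr-C")
  if (d_lys >= 13.5) return("Arr-B")
  d2 <- (ARR_PROTOTYPES$d_lys - d_lys)^2 + (ARR_PROTOTYPES$spacing - spacing)^2
  ARR_PROTOTYPES$label[which.min(d2)]
}

#' Tabulate arrangements across structures
#'
#' Expands each crystal structure to a layer, detects hexamers, finds
#' contacting pairs and reports one row per structure x interface. Failures
#' (unreadable file, no tiling layer) produce an annotated row instead of an
#' error.
#'
#' @param structures List of inputs: file paths, [crystal_structure()]s, or
#'   `toy_lattice` objects. Names are used as ids when present.
#' @param map A [landmark_map()], or a list of maps (one per structure).
#' @param contact_cutoff Heavy-atom contact cutoff (Angstrom) for pairing.
#' @return Tibble: id, interface, d_lys_min, d_lys_max, arg_ca, spacing,
#'   lateral_offset, arg_inserted, saltbridge, class, note.
#' @export
survey <- function(structures, map = pdua_landmarks(), contact_cutoff = 5) {
  empty <- tibble(id = character(), interface = character(),
                  d_lys_min = numeric(), d_lys_max = numeric(),
                  arg_ca = numeric(), spacing = numeric(),
                  lateral_offset = numeric(), arg_inserted = logical(),
                  saltbridge = logical(), class = character(),
                  note = character())
  if (length(structures) == 0) return(empty)
  ids <- names(structures) %||% rep("", length(structures))
  maps <- if (inherits(map, "landmark_map"))
    rep(list(map), length(structures)) else map
  rows <- lapply(seq_along(structures), function(i) {
    x <- structures[[i]]
    id <- if (nzchar(ids[i])) ids[i] else
      if (is.character(x)) basename(x) else paste0("structure_", i)
    tryCatch(
      survey_one(x, id, maps[[i]], contact_cutoff),
      error = function(e) tibble(
        id = id, interface = NA_character_, d_lys_min = NA_real_,
        d_lys_max = NA_real_, arg_ca = NA_real_, spacing = NA_real_,
        lateral_offset = NA_real_, arg_inserted = NA, saltbridge = NA,
        class = NA_character_, note = conditionMessage(e)))
  })
  bind_rows(empty, bind_rows(rows))
}

survey_one <- function(x, id, map, contact_cutoff) {
  if (is.character(x)) x <- read_structure(x)
  if (inherits(x, "toy_lattice")) {
    hexes <- x$hexamers
  } else if (inherits(x, "crystal_structure")) {
    layer <- expand_layer(x)
    hexes <- detect_hexamers(layer, map = map)$hexamers
  } else abort("unsupported survey input")
  pairs <- tryCatch(find_pairs(hexes, contact_cutoff),
                    error = function(e) NULL)
  if (is.null(pairs) || nrow(pairs) == 0)
    return(tibble(id = id, interface = NA_character_, d_lys_min = NA_real_,
                  d_lys_max = NA_real_, arg_ca = NA_real_, spacing = NA_real_,
                  lateral_offset = NA_real_, arg_inserted = NA,
                  saltbridge = NA, class = NA_character_,
                  note = "no 2D layer"))
  bind_rows(lapply(seq_len(nrow(pairs)), function(r) {
    m <- interface_metrics(hexes[[pairs$i[r]]], hexes[[pairs$j[r]]], map)
    tibble(id = id, interface = paste0(pairs$i[r], "-", pairs$j[r]),
           d_lys_min = m$d_lys, d_lys_max = m$d_lys_max,
           arg_ca = min(m$pairs$arg_ca), spacing = m$spacing,
           lateral_offset = m$lateral_offset, arg_inserted = m$arg_inserted,
           saltbridge = m$saltbridge, class = classify(m)$label, note = "")
  }))
}

# Interfacial chain bookkeeping shared by the angle operators and the
# trajectory generator: which chains of each hexamer form the interface.
# The bending chain pair is the mutually nearest lys_edge pair; the tilting
# chains are the two contacting chains per hexamer (falling back to the two
# chains whose lys_edge is nearest the interface midpoint).
interface_chains <- function(a, b, map = pdua_landmarks(), contact_cutoff = 5) {
  lys_a <- chain_landmark_ca(a, map$lys_edge)
  lys_b <- chain_landmark_ca(b, map$lys_edge)
  dm <- cross_dist_matrix(lys_a, lys_b)
  best <- arrayInd(which.min(dm), dim(dm))
  bend_a <- rownames(lys_a)[best[1]]
  bend_b <- rownames(lys_b)[best[2]]
  contacts <- chain_contacts(a, b, contact_cutoff)
  mid <- (lys_a[best[1], ] + lys_b[best[2], ]) / 2
  tilt <- function(h, lys, contact_chains, bend_chain) {
    ch <- contact_chains
    if (length(ch) != 2) {
      d <- sqrt(colSums((t(lys) - mid)^2))
      ch <- union(bend_chain, names(sort(d))[1:2])[1:2]
    }
    ch
  }
  list(bend_chain_a = bend_a, bend_chain_b = bend_b,
       tilt_chains_a = tilt(a, lys_a, contacts$chains_a, bend_a),
       tilt_chains_b = tilt(b, lys_b, contacts$chains_b, bend_b))
}

chain_contacts <- function(a, b, cutoff = 5) {
  xa <- heavy_atoms(a$atoms); xb <- heavy_atoms(b$atoms)
  ma <- atom_xyz(xa); mb <- atom_xyz(xb)
  ca <- character(); cb <- character()
  for (ch in unique(xa$chain)) {
    if (cross_dist_min(ma[xa$chain == ch, , drop = FALSE], mb) < cutoff)
      ca <- c(ca, ch)
  }
  for (ch in unique(xb$chain)) {
    if (cross_dist_min(mb[xb$chain == ch, , drop = FALSE], ma) < cutoff)
      cb <- c(cb, ch)
  }
  list(chains_a = ca, chains_b = cb)
}
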