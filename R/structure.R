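# Van der Waals radii (Angstrom) used for surface calculations. A Bondi-style
# subset covering the elements present in protein heavy-atom models.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

#' Parse a PDB file into a structure model
#'
#' Reads ATOM records via `bio3d`, keeps a single chain (the first, unless
#' named), drops waters and heteroatoms, optionally drops hydrogens, and for
#' alternate locations keeps the highest-occupancy conformer (first wins on
#' ties).
#'
#' @param path PDB file.
#' @param chain chain identifier to keep; default the first chain present.
#' @param keep_hydrogens keep hydrogen atoms (default `FALSE`; crystal
#'   structures of this family rarely model them).
#' @return an object of class `structure_model`: list with `atoms` (data
#'   frame: `serial`, `name`, `element`, `resid`, `resno`, `chain`, `x`,
#'   `y`, `z`, `occ`) and `source`.
#' @export
parse_structure <- function(path, chain = NULL, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) {
      stop("failed to parse PDB file ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path, call. = FALSE)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in chain '", chain, "' of ", path, call. = FALSE)
  element <- at$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  if (any(missing_el)) {
    # fall back on the first alphabetic character of the atom name
    guess <- toupper(sub("^[0-9]*", "", at$elety[missing_el]))
    element[missing_el] <- substr(guess, 1L, 1L)
  }
  element <- toupper(trimws(element))
  if (!keep_hydrogens) {
    keep <- element != "H"
    at <- at[keep, , drop = FALSE]
    element <- element[keep]
  }
  if (!nrow(at)) stop("no heavy atoms left after filtering in ", path, call. = FALSE)
  occ <- at$o
  occ[is.na(occ)] <- 1
  # resolve altlocs: keep the highest-occupancy conformer per atom site
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -occ, alt)
  first_site <- !duplicated(key[ord])
  keep_idx <- sort(ord[first_site])
  at <- at[keep_idx, , drop = FALSE]
  element <- element[keep_idx]
  occ <- occ[keep_idx]
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = element,
    resid = at$resid,
    resno = at$resno,
    chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    occ = occ,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  structure(list(atoms = atoms, source = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(
    "structure_model:", nrow(x$atoms), "atoms,",
    length(unique(x$atoms$resno)), "residues, chain",
    unique(x$atoms$chain), "\n"
  )
  invisible(x)
}

# Assign vdW radii by element; errors on unknown elements unless a default
# radius is supplied.
assign_radii <- function(model, default_radius = NA_real_) {
  r <- VDW_RADII[model$atoms$element]
  unknown <- is.na(r)
  if (any(unknown)) {
    if (is.na(default_radius)) {
      stop("no vdW radius for element(s): ",
        paste(unique(model$atoms$element[unknown]), collapse = ", "),
        "; supply `default_radius`",
        call. = FALSE
      )
    }
    r[unknown] <- default_radius
  }
  unname(r)
}

# Deterministic quasi-uniform unit sphere points (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places a deterministic quasi-uniform point lattice on each atom's
#' solvent-expanded sphere (vdW radius + probe) and counts the points not
#' buried inside any neighbouring atom's expanded sphere. Per-atom SASA is
#' the accessible fraction times the full sphere area.
#'
#' @param model a [parse_structure()] result.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a water
#'   molecule).
#' @param n_points test points per atom (default 960).
#' @param default_radius vdW radius for elements missing from the built-in
#'   table; `NA` (default) makes unknown elements an error.
#' @return an object of class `sasa_result`: list with `area` (per-atom SASA,
#'   Angstrom^2), `total`, `radii`, and the parameters used.
#' @export
shrake_rupley_sasa <- function(model, probe_radius = 1.4, n_points = 960L,
                               default_radius = NA_real_) {
  stopifnot(inherits(model, "structure_model"))
  radii <- assign_radii(model, default_radius)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  expanded <- radii + probe_radius
  pts <- fibonacci_sphere(n_points)
  area <- numeric(n)
  # neighbour search on the expanded spheres
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cutoff2 <- (expanded[i] + expanded)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    sph <- pts * expanded[i]
    sph <- sweep(sph, 2, xyz[i, ], "+")
    ok <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(ok)) break
      dx <- sph[, 1] - xyz[j, 1]
      dy <- sph[, 2] - xyz[j, 2]
      dz <- sph[, 3] - xyz[j, 3]
      ok <- ok & (dx * dx + dy * dy + dz * dz >= expanded[j]^2)
    }
    area[i] <- 4 * pi * expanded[i]^2 * sum(ok) / n_points
  }
  structure(
    list(
      area = area,
      total = sum(area),
      radii = radii,
      probe_radius = probe_radius,
      n_points = as.integer(n_points)
    ),
    class = "sasa_result"
  )
}

#' Classify atoms as hydrophobic
#'
#' The operational rule is element-based: carbon and sulfur atoms are
#' hydrophobic; nitrogen, oxygen (and hydrogens, if present) are not. This is
#' the standard apolar/polar split used when colouring hydrophobic surface
#' patches.
#'
#' @param model a [parse_structure()] result.
#' @return logical vector, one entry per atom, `TRUE` for hydrophobic atoms.
#' @export
classify_hydrophobic_atoms <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  model$atoms$element %in% c("C", "S")
}

#' Define the substrate-binding pocket around the catalytic serine
#'
#' bHSL substrate pockets are tunnels leading from the surface to the
#' catalytic triad; operationally the pocket is the set of residues having at
#' least one atom within `cutoff` of the catalytic serine's side-chain oxygen
#' (O-gamma).
#'
#' @param model a [parse_structure()] result.
#' @param triad integer vector of catalytic triad residue numbers, serine
#'   first (e.g. `c(146, 240, 270)` for Ser/Glu/His in Est8).
#' @param cutoff inclusion radius in Angstrom from the serine O-gamma
#'   (default 10).
#' @param ref_atom_name name of the serine reference atom (default `"OG"`).
#' @return an object of class `pocket_definition`: list with `triad`,
#'   `cutoff`, `ref_atom` (serial), and `residues` (pocket residue numbers).
#' @export
define_pocket <- function(model, triad, cutoff = 10, ref_atom_name = "OG") {
  stopifnot(inherits(model, "structure_model"))
  atoms <- model$atoms
  missing_res <- setdiff(triad, unique(atoms$resno))
  if (length(missing_res)) {
    stop("catalytic triad residue(s) not found in model: ",
      paste(missing_res, collapse = ", "),
      call. = FALSE
    )
  }
  ser_resno <- triad[1]
  ref_idx <- which(atoms$resno == ser_resno & trimws(atoms$name) == ref_atom_name)
  if (!length(ref_idx)) {
    stop("reference atom '", ref_atom_name, "' not found in residue ",
      ser_resno,
      call. = FALSE
    )
  }
  ref_idx <- ref_idx[1]
  ref <- as.numeric(atoms[ref_idx, c("x", "y", "z")])
  d <- sqrt((atoms$x - ref[1])^2 + (atoms$y - ref[2])^2 + (atoms$z - ref[3])^2)
  residues <- sort(unique(atoms$resno[d <= cutoff]))
  structure(
    list(
      triad = triad,
      cutoff = cutoff,
      ref_atom = atoms$serial[ref_idx],
      residues = residues
    ),
    class = "pocket_definition"
  )
}

#' Hydrophobic pocket surface area
#'
#' Sums solvent-accessible surface area over the hydrophobic (carbon/sulfur)
#' atoms belonging to pocket residues. SASA is evaluated on the full model so
#' pocket atoms are scored in the context of the whole structure, then summed
#' over the pocket subset.
#'
#' @param model a [parse_structure()] result.
#' @param pocket a [define_pocket()] result.
#' @param sasa optional precomputed [shrake_rupley_sasa()] result for
#'   `model`; computed with defaults when `NULL`.
#' @param ... passed to [shrake_rupley_sasa()] when `sasa` is `NULL`.
#' @return an object of class `surface_result`: list with `pocket_area`
#'   (hydrophobic pocket SASA, Angstrom^2), `total_sasa`,
#'   `hydrophobic_sasa`, `polar_sasa`, `per_atom` (the per-atom SASA), and
#'   the SASA parameters.
#' @export
hydrophobic_pocket_area <- function(model, pocket, sasa = NULL, ...) {
  stopifnot(inherits(model, "structure_model"), inherits(pocket, "pocket_definition"))
  if (!length(pocket$residues)) stop("empty pocket", call. = FALSE)
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(model, ...)
  stopifnot(inherits(sasa, "sasa_result"))
  hyd <- classify_hydrophobic_atoms(model)
  in_pocket <- model$atoms$resno %in% pocket$residues
  structure(
    list(
      pocket_area = sum(sasa$area[hyd & in_pocket]),
      total_sasa = sasa$total,
      hydrophobic_sasa = sum(sasa$area[hyd]),
      polar_sasa = sum(sasa$area[!hyd]),
      per_atom = sasa$area,
      probe_radius = sasa$probe_radius,
      n_points = sasa$n_points,
      cutoff = pocket$cutoff
    ),
    class = "surface_result"
  )
}

#' @export
print.surface_result <- function(x, ...) {
  cat(sprintf(
    "surface_result: pocket hydrophobic area %.1f A^2 (total SASA %.1f, hydrophobic %.1f)\n",
    x$pocket_area, x$total_sasa, x$hydrophobic_sasa
  ))
  invisible(x)
}

#' Pearson correlation between cap scores and pocket areas
#'
#' Product-moment correlation computed from the covariance formula. Used to
#' validate that sequence-derived cap hydrophobicity scores track
#' structure-derived hydrophobic pocket areas.
#'
#' @param scores numeric vector of cap hydrophobicity scores.
#' @param areas numeric vector of pocket areas (Angstrom^2), same length.
#' @return an object of class `correlation_result`: list with `r`, `n`, and
#'   the paired observations.
#' @export
correlate_scores_areas <- function(scores, areas) {
  if (length(scores) != length(areas)) {
    stop("scores and areas must have equal length", call. = FALSE)
  }
  n <- length(scores)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(scores)) || any(!is.finite(areas))) {
    stop("non-finite value(s) in pairs", call. = FALSE)
  }
  dx <- scores - mean(scores)
  dy <- areas - mean(areas)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop("zero variance in scores or areas; correlation undefined", call. = FALSE)
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  structure(
    list(r = r, n = n, pairs = data.frame(score = scores, area = areas)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: Pearson r = %.4f (n = %d)\n", x$r, x$n))
  invisible(x)
}
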