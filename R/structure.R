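#' Build a fibril structure from an atom table
#'
#' The core single-conformation container: a tibble of atom records plus the
#' chain stacking order. All coordinates are in nanometres; conversion from
#' the PDB's Angstroms happens at file I/O only.
#'
#' @param atoms Data frame with columns `serial` (integer), `name` (atom name,
#'   e.g. `"CA"`), `element` (e.g. `"C"`), `resname` (three-letter residue
#'   name), `resid` (integer residue number), `chain` (chain identifier),
#'   `x`, `y`, `z` (nm) and `hetero` (logical, `TRUE` for HETATM/ligand
#'   atoms).
#' @param chain_order Character vector giving the fibril stacking order of
#'   chains. Defaults to order of first appearance in `atoms`.
#'
#' @return A `fibril_structure` object.
#' @export
fibril_structure <- function(atoms, chain_order = NULL) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("serial", "name", "element", "resname", "resid", "chain",
                "x", "y", "z", "hetero")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  atoms$hetero <- as.logical(atoms$hetero)
  if (nrow(atoms) == 0) abort("structure must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    abort("atom coordinates must be finite")
  }
  if (any(is.na(atoms$element) | atoms$element == "")) {
    abort("every atom needs a non-empty element symbol")
  }
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (chain, resid, name) atom record: ",
                 key[duplicated(key)][1]))
  }
  seen <- unique(atoms$chain)
  if (is.null(chain_order)) chain_order <- seen
  if (!setequal(chain_order, seen)) {
    abort("chain_order must list exactly the chains present in the atom table")
  }
  # residues must be contiguous runs within each chain
  for (ch in seen) {
    r <- atoms$resid[atoms$chain == ch]
    runs <- rle(r)$values
    if (anyDuplicated(runs)) {
      abort(paste0("residues of chain ", ch, " are not contiguous in the atom table"))
    }
  }
  structure(list(atoms = atoms, chain_order = as.character(chain_order)),
            class = "fibril_structure")
}

#' @export
print.fibril_structure <- function(x, ...) {
  a <- x$atoms
  cat("<fibril_structure> ", nrow(a), " atoms, ",
      length(x$chain_order), " chain(s) [",
      paste(x$chain_order, collapse = ""), "], ",
      sum(!a$hetero), " protein / ", sum(a$hetero), " hetero atoms\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure or trajectory topology
#' @param x A `fibril_structure` or `fibril_trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "fibril_trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Extract the coordinate matrix of a structure or of one trajectory frame
#'
#' @param x A `fibril_structure` or `fibril_trajectory`.
#' @param frame Frame index (1-based) when `x` is a trajectory.
#' @return An n x 3 numeric matrix in nm.
#' @export
coords <- function(x, frame = 1L) {
  if (inherits(x, "fibril_structure")) {
    return(unname(as.matrix(x$atoms[, c("x", "y", "z")])))
  }
  if (inherits(x, "fibril_trajectory")) {
    if (frame < 1 || frame > n_frames(x)) abort("frame index out of range")
    return(x$coords[, , frame])
  }
  abort("coords() expects a fibril_structure or fibril_trajectory")
}

#' Build a trajectory from a topology and per-frame coordinates
#'
#' @param topology A `fibril_structure` shared by all frames.
#' @param coords Numeric array of dimension `(n_atoms, 3, n_frames)`, nm.
#' @param time_per_frame Time spacing between frames in ns (> 0).
#' @return A `fibril_trajectory` object.
#' @export
fibril_trajectory <- function(topology, coords, time_per_frame = 1) {
  if (!inherits(topology, "fibril_structure")) {
    abort("topology must be a fibril_structure")
  }
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    abort("coords must be an (n_atoms, 3, n_frames) array")
  }
  if (dim(coords)[1] != n_atoms(topology)) {
    abort("every frame needs exactly one coordinate per topology atom")
  }
  if (!is.numeric(time_per_frame) || time_per_frame <= 0) {
    abort("time_per_frame must be > 0 (ns)")
  }
  structure(list(topology = topology, coords = coords,
                 time_per_frame = as.numeric(time_per_frame)),
            class = "fibril_trajectory")
}

#' @export
print.fibril_trajectory <- function(x, ...) {
  cat("<fibril_trajectory> ", n_frames(x), " frames x ", n_atoms(x),
      " atoms, ", x$time_per_frame, " ns/frame (",
      n_frames(x) * x$time_per_frame, " ns)\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `fibril_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) {
  dim(trajectory$coords)[3]
}

#' Select atoms by chain, residue range, atom name, element class
#'
#' Returns a strictly increasing index vector into the topology atom order,
#' carrying the query as a provenance attribute. All filters are conjunctive;
#' an empty selection is legal (downstream operations reject empty masks
#' where they must).
#'
#' @param x A `fibril_structure` or `fibril_trajectory`.
#' @param chains Chain identifiers to keep (default all).
#' @param resids Residue numbers to keep (default all).
#' @param names Atom names to keep, e.g. `"CA"` (default all).
#' @param heavy If `TRUE`, drop hydrogens.
#' @param hetero `NA` (default) keeps both; `TRUE` keeps only HETATM/ligand
#'   atoms; `FALSE` only protein atoms.
#' @return Integer vector of atom indices (class `atom_selection`).
#' @export
select_atoms <- function(x, chains = NULL, resids = NULL, names = NULL,
                         heavy = FALSE, hetero = NA) {
  if (inherits(x, "fibril_trajectory")) x <- x$topology
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(resids)) keep <- keep & a$resid %in% resids
  if (!is.null(names)) keep <- keep & a$name %in% names
  if (isTRUE(heavy)) keep <- keep & a$element != "H"
  if (!is.na(hetero)) keep <- keep & (a$hetero == hetero)
  idx <- which(keep)
  attr(idx, "query") <- paste0(
    "chains=", if (is.null(chains)) "*" else paste(chains, collapse = ","),
    " resids=", if (is.null(resids)) "*" else paste(range(resids), collapse = "-"),
    " names=", if (is.null(names)) "*" else paste(names, collapse = ","),
    " heavy=", heavy, " hetero=", hetero)
  class(idx) <- c("atom_selection", class(idx))
  idx
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("<atom_selection> ", length(x), " atoms [", attr(x, "query"), "]\n",
      sep = "")
  invisible(x)
}

# chains holding at least one non-hetero atom, in stacking order
protein_chains <- function(x) {
  if (inherits(x, "fibril_trajectory")) x <- x$topology
  keep <- vapply(x$chain_order,
                 function(ch) any(!x$atoms$hetero[x$atoms$chain == ch]),
                 logical(1))
  x$chain_order[keep]
}

# resolve a "last W ns" analysis window to frame indices
window_frames <- function(trajectory, window_ns) {
  nf <- n_frames(trajectory)
  if (is.null(window_ns)) return(seq_len(nf))
  w <- round(window_ns / trajectory$time_per_frame)
  if (w < 1) abort("window shorter than one frame")
  if (w > nf) abort("window longer than trajectory")
  seq.int(nf - w + 1L, nf)
}
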