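#' Read a (multi-model) PDB file
#'
#' Fixed-column ATOM/HETATM records are parsed via bio3d; coordinates are
#' converted from Angstrom to nm. A file with several MODEL/ENDMDL blocks
#' becomes a trajectory (atom order must be identical across models); a
#' single-model file yields a structure.
#'
#' Altloc handling keeps the first conformer with a warning; insertion codes
#' are not supported and raise an error (fibril models do not use them).
#'
#' @param path Path to a PDB file.
#' @param time_per_frame Frame spacing in ns assigned when the file holds
#'   several models (default 1 ns).
#' @param chain_order Optional explicit fibril stacking order; default is
#'   order of first appearance.
#' @return A `fibril_structure` (single model) or `fibril_trajectory`.
#' @export
read_pdb <- function(path, time_per_frame = 1, chain_order = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom

  if (any(!is.na(at$insert) & at$insert != "")) {
    abort("insertion codes are not supported")
  }
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(!alt %in% c("", "A"))) {
    warn("altloc records found: keeping first conformer only")
  }
  keep_alt <- alt %in% c("", "A")

  nmodel <- nrow(pdb$xyz)
  elesy <- at$elesy
  fallback <- is.na(elesy) | elesy == ""
  elesy[fallback] <- guess_element(at$elety[fallback])

  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    name = at$elety,
    element = toupper(elesy),
    resname = at$resid,
    resid = as.integer(at$resno),
    chain = as.character(at$chain),
    x = at$x / 10, y = at$y / 10, z = at$z / 10,
    hetero = at$type == "HETATM")
  atoms <- atoms[keep_alt, ]
  # drop duplicate altloc copies beyond the first per (chain, resid, name)
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "|")
  atoms <- atoms[!duplicated(key), ]

  topo <- fibril_structure(atoms, chain_order = chain_order)
  if (nmodel == 1) return(topo)

  na <- nrow(at)
  arr <- array(NA_real_, dim = c(nrow(atoms), 3, nmodel))
  sel <- which(keep_alt)[!duplicated(key)]
  for (m in seq_len(nmodel)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    if (nrow(xyz) != na) abort("models differ in atom count (topology mismatch)")
    if (any(!is.finite(xyz[sel, ]))) {
      abort("models differ in atom count (topology mismatch)")
    }
    arr[, , m] <- xyz[sel, , drop = FALSE] / 10
  }
  topo$atoms[, c("x", "y", "z")] <- as.data.frame(arr[, , 1])
  fibril_trajectory(topo, arr, time_per_frame = time_per_frame)
}

# pre-scan for malformed fixed-column coordinate fields so errors carry a
# line number (the wrapped reader does not report one)
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  models <- sum(grepl("^MODEL", lines))
  counts <- NULL
  if (models > 1) {
    # atom records per MODEL block must agree
    block <- cumsum(grepl("^MODEL", lines))
    counts <- table(block[rec & block > 0])
    if (length(unique(as.integer(counts))) > 1) {
      abort("models differ in atom count (topology mismatch)")
    }
  }
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(paste0("malformed PDB record at line ", i, ": too short"))
    }
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v)) {
        abort(paste0("malformed PDB record at line ", i,
                     ": unparseable coordinate field"))
      }
    }
  }
  invisible(TRUE)
}

guess_element <- function(name) {
  el <- sub("^[0-9']*", "", name)
  substr(el, 1, 1)
}

#' Write a structure or trajectory as a (multi-model) PDB file
#'
#' Frames are emitted as MODEL/ENDMDL blocks; coordinates are converted from
#' nm to Angstrom. Coordinates that would overflow the fixed 8.3 column
#' format raise an error rather than being truncated.
#'
#' @param x A `fibril_structure` or `fibril_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  traj <- NULL
  if (inherits(x, "fibril_trajectory")) {
    traj <- x
    x <- x$topology
  } else if (!inherits(x, "fibril_structure")) {
    abort("nothing to write: expected a fibril_structure or fibril_trajectory")
  }
  a <- x$atoms
  if (nrow(a) == 0) abort("nothing to write")
  if (any(nchar(a$chain) != 1)) {
    abort("chain ids must be single characters for PDB output")
  }
  if (is.null(traj)) {
    xyz <- matrix(as.vector(t(coords(x))), nrow = 1)
  } else {
    nf <- n_frames(traj)
    xyz <- t(vapply(seq_len(nf),
                    function(m) as.vector(t(traj$coords[, , m])),
                    numeric(3 * nrow(a))))
  }
  xyz <- xyz * 10  # nm -> Angstrom
  if (any(abs(xyz) >= 10000)) {
    abort("coordinate overflows PDB field width (|x| >= 1000 nm)")
  }
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$hetero, "HETATM", "ATOM"),
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, elesy = a$element)
  if (any(a$hetero)) {
    # the multi-model writer emits every record as ATOM; restore HETATM
    # cards (atom order is identical in every MODEL block)
    lines <- readLines(path, warn = FALSE)
    rec <- grep("^(ATOM  |HETATM)", lines)
    het <- rep_len(a$hetero, length(rec))
    lines[rec[het]] <- sub("^ATOM  ", "HETATM", lines[rec[het]])
    writeLines(lines, path)
  }
  invisible(path)
}
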