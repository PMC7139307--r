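# Kabsch-Sander beta assignment: the hydrogen-bond energy model and
# bridge/ladder rules, restricted to the beta classes (E, B); everything
# else is reported as C. Energies use Angstrom internally (the model's
# constants assume Angstrom); all public interfaces stay in nm.

KS_Q <- 0.084 * 332  # kcal/mol * Angstrom
KS_HBOND_CUTOFF <- -0.5  # kcal/mol
KS_CLAMP <- -9.9
KS_MINDIST_A <- 0.5  # Angstrom: closer contacts are clamped (clash rule)
KS_CA_PREFILTER_NM <- 0.9  # 9 Angstrom CA-CA prefilter, DSSP convention

# per-residue backbone atom bookkeeping for the protein part of a structure
backbone_table <- function(structure) {
  a <- structure$atoms
  prot <- a[!a$hetero, ]
  res <- dplyr::distinct(prot, .data$chain, .data$resid, .data$resname)
  # preserve file order within chains, chains in stacking order
  res <- res[order(match(res$chain, structure$chain_order),
                   match(paste(res$chain, res$resid),
                         unique(paste(prot$chain, prot$resid)))), ]
  find <- function(atom_name) {
    key_res <- paste(res$chain, res$resid)
    key_atm <- paste(a$chain, a$resid)
    idx <- rep(NA_integer_, nrow(res))
    hit <- which(a$name == atom_name & !a$hetero)
    idx[match(key_atm[hit], key_res)] <- hit
    idx
  }
  res$i_n <- find("N")
  res$i_ca <- find("CA")
  res$i_c <- find("C")
  res$i_o <- find("O")
  res$i_h <- find("H")
  n <- nrow(res)
  same_prev <- c(FALSE, res$chain[-1] == res$chain[-n])
  res$prev <- ifelse(same_prev, seq_len(n) - 1L, NA_integer_)
  res$nxt <- c(ifelse(same_prev[-1], seq_len(n - 1L) + 1L, NA_integer_),
               NA_integer_)
  res
}

#' Place amide hydrogens by the DSSP convention
#'
#' MD-exported PDB files often lack hydrogens; the Kabsch-Sander energy needs
#' the backbone amide H. It is placed 0.10 nm from N along the direction of
#' the previous residue's C minus O vector. Chain-first residues and prolines
#' get no amide hydrogen; residues with missing backbone atoms are flagged by
#' omission (they are excluded from the donor role).
#'
#' @param structure A `fibril_structure`.
#' @param frame_coords Optional n x 3 coordinate matrix overriding the
#'   structure's own coordinates (for trajectory frames).
#' @return Tibble with `chain`, `resid`, and hydrogen coordinates `x`, `y`,
#'   `z` (nm), one row per placeable amide hydrogen.
#' @export
place_amide_hydrogens <- function(structure, frame_coords = NULL) {
  xyz <- if (is.null(frame_coords)) coords(structure) else as.matrix(frame_coords)
  res <- backbone_table(structure)
  ok <- !is.na(res$prev) & res$resname != "PRO" & !is.na(res$i_n) &
    !is.na(res$i_c[res$prev]) & !is.na(res$i_o[res$prev])
  ok[is.na(ok)] <- FALSE
  idx <- which(ok)
  if (length(idx) == 0) {
    return(tibble::tibble(chain = character(), resid = integer(),
                          x = numeric(), y = numeric(), z = numeric()))
  }
  npos <- xyz[res$i_n[idx], , drop = FALSE]
  cprev <- xyz[res$i_c[res$prev[idx]], , drop = FALSE]
  oprev <- xyz[res$i_o[res$prev[idx]], , drop = FALSE]
  dvec <- cprev - oprev
  len <- sqrt(rowSums(dvec^2))
  if (any(len < 1e-9)) abort("degenerate C=O bond while placing amide H")
  h <- npos + 0.10 * dvec / len
  tibble::tibble(chain = res$chain[idx], resid = res$resid[idx],
                 x = h[, 1], y = h[, 2], z = h[, 3])
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' The DSSP electrostatic approximation
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol with
#' distances in Angstrom. Arguments are positions in nm (converted
#' internally). A bond is recorded when `E < -0.5` kcal/mol. If any of the
#' four distances falls below 0.05 nm the energy is clamped to -9.9
#' (clash convention).
#'
#' @param n_pos,h_pos Donor backbone N and amide H positions (nm).
#' @param c_pos,o_pos Acceptor backbone C and O positions (nm).
#' @return Energy in kcal/mol.
#' @export
ks_hbond_energy <- function(n_pos, h_pos, c_pos, o_pos) {
  d <- function(a, b) sqrt(sum((a - b)^2)) * 10  # nm -> Angstrom
  r_on <- d(o_pos, n_pos)
  r_ch <- d(c_pos, h_pos)
  r_oh <- d(o_pos, h_pos)
  r_cn <- d(c_pos, n_pos)
  if (min(r_on, r_ch, r_oh, r_cn) < KS_MINDIST_A) return(KS_CLAMP)
  KS_Q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# all-pairs energy matrix E[acceptor, donor]; vectorized over residues
ks_energy_matrix <- function(res, xyz, hpos_idx) {
  n <- nrow(res)
  acc <- !is.na(res$i_c) & !is.na(res$i_o)
  don <- hpos_idx$has_h & !is.na(res$i_n)
  get <- function(idx) {
    out <- matrix(NA_real_, n, 3)
    ok <- !is.na(idx)
    out[ok, ] <- xyz[idx[ok], , drop = FALSE]
    out
  }
  O <- get(res$i_o) * 10
  C <- get(res$i_c) * 10
  N <- get(res$i_n) * 10
  H <- hpos_idx$h * 10
  CA <- get(res$i_ca) * 10
  cross <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  }
  e <- matrix(NA_real_, n, n)
  ai <- which(acc)
  dj <- which(don)
  if (length(ai) == 0 || length(dj) == 0) return(e)
  r_on <- cross(O[ai, , drop = FALSE], N[dj, , drop = FALSE])
  r_ch <- cross(C[ai, , drop = FALSE], H[dj, , drop = FALSE])
  r_oh <- cross(O[ai, , drop = FALSE], H[dj, , drop = FALSE])
  r_cn <- cross(C[ai, , drop = FALSE], N[dj, , drop = FALSE])
  val <- KS_Q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  clash <- pmin(r_on, r_ch, r_oh, r_cn) < KS_MINDIST_A
  val[clash] <- KS_CLAMP
  # DSSP CA-CA prefilter: residues farther than 9 A cannot bond
  r_ca <- cross(CA[ai, , drop = FALSE], CA[dj, , drop = FALSE])
  val[r_ca >= KS_CA_PREFILTER_NM * 10 | is.na(r_ca)] <- 0
  e[ai, dj] <- val
  # self and sequence-adjacent exclusion (|delta resid| < 2 within a chain)
  same_chain <- outer(res$chain, res$chain, "==")
  close_seq <- abs(outer(res$resid, res$resid, "-")) < 2
  e[same_chain & close_seq] <- NA_real_
  e
}

# hydrogen positions aligned to the residue table
ks_hydrogens <- function(structure, res, xyz) {
  htab <- place_amide_hydrogens(structure, xyz)
  h <- matrix(NA_real_, nrow(res), 3)
  if (nrow(htab) > 0) {
    ix <- match(paste(htab$chain, htab$resid),
                paste(res$chain, res$resid))
    h[ix, ] <- as.matrix(htab[, c("x", "y", "z")])
  }
  list(h = h, has_h = !is.na(h[, 1]))
}

#' Assign beta secondary structure (Kabsch-Sander bridge/ladder rules)
#'
#' Hydrogen bonds (energy below -0.5 kcal/mol, at most the two best
#' acceptors per donor) define parallel and antiparallel bridges; bridges
#' chain into ladders; residues in ladders of length >= 2 are `E`
#' (extended strand), isolated bridges are `B`, everything else `C`.
#'
#' @param structure A `fibril_structure` (the topology).
#' @param frame_coords Optional n x 3 coordinate matrix for one trajectory
#'   frame; defaults to the structure's own coordinates.
#' @return Tibble with `chain`, `resid`, `resname`, `code` (one of
#'   `"E"`, `"B"`, `"C"`) for every protein residue.
#' @export
assign_beta <- function(structure, frame_coords = NULL) {
  xyz <- if (is.null(frame_coords)) coords(structure) else as.matrix(frame_coords)
  res <- backbone_table(structure)
  n <- nrow(res)
  hyd <- ks_hydrogens(structure, res, xyz)
  e <- ks_energy_matrix(res, xyz, hyd)

  # bond matrix hb[i, j]: CO of residue i accepts the NH of residue j
  hb <- matrix(FALSE, n, n)
  cand <- !is.na(e) & e < KS_HBOND_CUTOFF
  for (j in which(colSums(cand) > 0)) {
    acceptors <- which(cand[, j])
    if (length(acceptors) > 2) {
      acceptors <- acceptors[order(e[acceptors, j])][1:2]  # no-bifurcation rule
    }
    hb[acceptors, j] <- TRUE
  }

  pv <- ifelse(is.na(res$prev), n + 1L, res$prev)
  nx <- ifelse(is.na(res$nxt), n + 1L, res$nxt)
  pad <- function(m) rbind(cbind(m, FALSE), FALSE)
  H <- pad(hb)
  idx <- seq_len(n)

  # parallel bridge(i,j): Hbond(i-1,j) & Hbond(j,i+1), or the symmetric clause
  termA <- H[pv, idx, drop = FALSE] & t(H[idx, nx, drop = FALSE])
  par <- termA | t(termA)
  # antiparallel bridge(i,j): Hbond(i,j) & Hbond(j,i), or
  # Hbond(i-1,j+1) & Hbond(j-1,i+1)
  m3 <- H[pv, nx, drop = FALSE]
  anti <- (hb & t(hb)) | (m3 & t(m3))

  # bridges need non-overlapping stretches: exclude near-diagonal same-chain
  same_chain <- outer(res$chain, res$chain, "==")
  near <- abs(outer(idx, idx, "-")) < 3
  par[same_chain & near] <- FALSE
  anti[same_chain & near] <- FALSE

  # ladders: a bridge is extended when the adjacent bridge of its type exists
  Pa <- pad(par)
  Aa <- pad(anti)
  ext_par <- par & (Pa[nx, nx, drop = FALSE] | Pa[pv, pv, drop = FALSE])
  ext_anti <- anti & (Aa[nx, pv, drop = FALSE] | Aa[pv, nx, drop = FALSE])

  is_e <- rowSums(ext_par | ext_anti) > 0
  is_b <- !is_e & rowSums(par | anti) > 0
  code <- ifelse(is_e, "E", ifelse(is_b, "B", "C"))
  tibble::tibble(chain = res$chain, resid = res$resid,
                 resname = res$resname, code = code)
}

#' Per-frame beta-sheet content of a trajectory
#'
#' For each frame in the window, the fraction of protein residues assigned
#' to beta structure (`E`, and `B` unless `count_bridges = FALSE`). This is
#' the "beta-sheet structure probability" stability indicator.
#'
#' @param trajectory A `fibril_trajectory`.
#' @param window_ns Analysis window: the last `window_ns` nanoseconds
#'   (default `NULL` = all frames).
#' @param count_bridges Count isolated bridges (`B`) as beta (default TRUE).
#' @return Tibble with `frame`, `time_ns`, `beta_fraction`, carrying
#'   attributes `mean` and `sd` over the window.
#' @export
beta_content <- function(trajectory, window_ns = NULL, count_bridges = TRUE) {
  frames <- window_frames(trajectory, window_ns)
  if (length(frames) == 0) abort("empty analysis window")
  topo <- trajectory$topology
  codes <- c("E", if (count_bridges) "B")
  frac <- vapply(frames, function(f) {
    ss <- assign_beta(topo, trajectory$coords[, , f])
    mean(ss$code %in% codes)
  }, numeric(1))
  out <- tibble::tibble(frame = frames,
                        time_ns = frames * trajectory$time_per_frame,
                        beta_fraction = frac)
  attr(out, "mean") <- mean(frac)
  attr(out, "sd") <- if (length(frac) > 1) sd(frac) else 0
  out
}
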