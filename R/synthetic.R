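# Deterministic generator of idealized cross-beta fibril structures,
# pseudo-ligands, and distorted trajectories. The generator imitates the
# statistical structure the metrics respond to (stacking order, hydrogen-
# bond registry, buried interfaces, pocket contacts), not physics: no force
# field, no energies, no realistic side chains.

# Abeta residues 11-42 (the S-shaped fibril construct numbering)
ABETA_11_42 <- c("GLU", "VAL", "HIS", "HIS", "GLN", "LYS", "LEU", "VAL",
                 "PHE", "PHE", "ALA", "GLU", "ASP", "VAL", "GLY", "SER",
                 "ASN", "LYS", "GLY", "ALA", "ALA", "ILE", "ILE", "GLY",
                 "LEU", "MET", "VAL", "GLY", "GLY", "VAL", "VAL", "ALA")

#' Specification for the synthetic cross-beta fibril builder
#'
#' Defaults emulate the five-chain S-shaped Abeta42 stack: 5 chains of 32
#' residues (numbered 11-42), 0.48 nm stacking rise, 0.38 nm C-alpha step
#' along each strand, and a three-strand meander layout whose middle strand
#' faces a concave pocket.
#'
#' @param n_chains Number of stacked chains (default 5).
#' @param n_residues Residues per chain (default 32).
#' @param first_resid First residue number (default 11).
#' @param spacing Inter-chain rise along the fibril (z) axis, nm (default
#'   0.48).
#' @param segments Strand segment lengths forming the in-plane meander; must
#'   sum to `n_residues` (default `c(11, 10, 11)`).
#' @param ca_step C-alpha to C-alpha distance along a strand, nm (default
#'   0.38).
#' @param strand_sep In-plane separation between meander strands, nm
#'   (default 0.6).
#' @return A `fibril_spec` list.
#' @export
fibril_spec <- function(n_chains = 5, n_residues = 32, first_resid = 11,
                        spacing = 0.48, segments = c(11, 10, 11),
                        ca_step = 0.38, strand_sep = 0.6) {
  if (spacing <= 0) abort("spacing must be > 0")
  if (sum(segments) != n_residues) {
    abort("segment lengths must sum to n_residues")
  }
  structure(list(n_chains = n_chains, n_residues = n_residues,
                 first_resid = first_resid, spacing = spacing,
                 segments = segments, ca_step = ca_step,
                 strand_sep = strand_sep),
            class = "fibril_spec")
}

#' Build an idealized cross-beta fibril structure
#'
#' Chains are exact z-translates of one planar meander chain, stacked at
#' the spec's rise. Backbone N and C sit 0.19 nm before/after each C-alpha
#' along the strand and carbonyl oxygens alternate up/down along the chain
#' (the pleated-sheet registry), so Kabsch-Sander hydrogen bonds form
#' between in-register residues of stacked chains and the assignment
#' recovers parallel beta ladders. Deterministic: no randomness.
#'
#' @param spec A [fibril_spec()].
#' @return A `fibril_structure`.
#' @export
build_ideal_fibril <- function(spec = fibril_spec()) {
  ns <- spec$n_residues
  # in-plane meander walk: segments alternate +x / -x, stepping +y at turns
  ca <- matrix(0, ns, 3)
  dirs <- matrix(0, ns, 3)
  pos <- c(0, 0, 0)
  dirv <- c(1, 0, 0)
  i <- 0
  for (k in seq_along(spec$segments)) {
    for (s in seq_len(spec$segments[k])) {
      i <- i + 1
      if (i == 1) {
        # origin
      } else if (s == 1) {
        pos <- pos + c(0, spec$strand_sep, 0)
      } else {
        pos <- pos + dirv * spec$ca_step
      }
      ca[i, ] <- pos
      dirs[i, ] <- dirv
    }
    dirv <- -dirv
  }

  resnames <- rep(ABETA_11_42, length.out = ns)
  parity <- rep_len(c(1, -1), ns)  # carbonyl z direction alternates
  chain_atoms <- function() {
    n_at <- ca - 0.19 * dirs
    c_at <- ca + 0.19 * dirs
    o_at <- c_at + cbind(0, 0, 0.123 * parity)
    list(N = n_at, CA = ca, C = c_at, O = o_at)
  }
  bb <- chain_atoms()
  names_per_res <- c("N", "CA", "C", "O")
  elements <- c(N = "N", CA = "C", C = "C", O = "O")

  chains <- LETTERS[seq_len(spec$n_chains)]
  rows <- purrr::map_dfr(seq_along(chains), function(ci) {
    dz <- (ci - 1) * spec$spacing
    purrr::map_dfr(seq_len(ns), function(r) {
      xyz <- do.call(rbind, lapply(names_per_res, function(nm) bb[[nm]][r, ]))
      tibble::tibble(name = names_per_res,
                     element = unname(elements[names_per_res]),
                     resname = resnames[r],
                     resid = spec$first_resid + r - 1L,
                     chain = chains[ci],
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3] + dz,
                     hetero = FALSE)
    })
  })
  rows$serial <- seq_len(nrow(rows))
  fibril_structure(rows, chain_order = chains)
}

#' Add a rigid pseudo-ligand (carbon blob) to a fibril structure
#'
#' Sites: `"pocket"` = centre of the middle chain's meander concavity
#' (between the first two strands, facing the concave side); `"interchain"`
#' = midpoint between the centres of two adjacent middle chains; `"edge"` =
#' `offset` nm beyond the terminal chain along the fibril axis. The blob is
#' `n_atoms` carbon pseudo-atoms uniformly jittered in a 0.25 nm-radius
#' ball; chemistry is irrelevant to the geometric metrics under test.
#'
#' @param structure A fibril from [build_ideal_fibril()].
#' @param site One of `"pocket"`, `"interchain"`, `"edge"`.
#' @param n_atoms Pseudo-atoms in the blob (default 20).
#' @param seed RNG seed (default 1); same seed, same coordinates.
#' @param offset Edge-site distance beyond the terminal chain plane, nm
#'   (default 0.5).
#' @return A new `fibril_structure` including the ligand as chain `"L"`,
#'   residue `LIG 901`, HETATM.
#' @export
plant_ligand <- function(structure, site = c("pocket", "interchain", "edge"),
                         n_atoms = 20, seed = 1, offset = 0.5) {
  site <- match.arg(site)
  a <- structure$atoms
  chains <- protein_chains(structure)
  ca_of <- function(ch) {
    as.matrix(a[a$chain == ch & a$name == "CA", c("x", "y", "z")])
  }
  mid <- chains[ceiling(length(chains) / 2)]
  centre <- switch(site,
    pocket = colMeans(ca_of(mid)),
    interchain = {
      lo <- chains[floor(length(chains) / 2)]
      hi <- chains[floor(length(chains) / 2) + 1]
      (colMeans(ca_of(lo)) + colMeans(ca_of(hi))) / 2
    },
    edge = {
      last <- ca_of(chains[length(chains)])
      cm <- colMeans(last)
      cm + c(0, 0, offset)
    })
  pts <- with_local_seed(seed, {
    u <- matrix(rnorm(3 * n_atoms), n_atoms, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- 0.25 * runif(n_atoms)^(1 / 3)
    u * r
  })
  lig <- tibble::tibble(
    serial = max(a$serial) + seq_len(n_atoms),
    name = paste0("C", seq_len(n_atoms)),
    element = "C",
    resname = "LIG", resid = 901L, chain = "L",
    x = centre[1] + pts[, 1], y = centre[2] + pts[, 2],
    z = centre[3] + pts[, 3],
    hetero = TRUE)
  fibril_structure(dplyr::bind_rows(a, lig),
                   chain_order = c(structure$chain_order, "L"))
}

# run code under a temporary RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic fibril trajectory under a distortion regime
#'
#' Regimes emulate the mechanistic classes observed for fibril-binding
#' compounds: `stable` (i.i.d. Gaussian jitter, sd = `amplitude`), `melt`
#' (jitter sd growing linearly from 0 to `amplitude`; the desk-scale
#' analogue of whole-fibril disordering), `detach` (one chain rigidly
#' translated along +x after `onset`, final displacement `amplitude`, on
#' top of baseline jitter; inter-chain destabilization), `pocket_distort`
#' (a residue range displaced in-plane, growing after `onset`, on top of
#' baseline jitter), and `scramble` (each chain independently rotated by a
#' uniform random rotation about its own centre each frame; the null model
#' for the order parameter).
#'
#' @param structure Starting `fibril_structure` (frame 0 of every regime).
#' @param mode One of `"stable"`, `"melt"`, `"detach"`, `"pocket_distort"`,
#'   `"scramble"`.
#' @param amplitude Regime amplitude in nm (jitter sd or final
#'   displacement). Defaults: stable 0.01, melt 0.2, detach 3,
#'   pocket_distort 0.5.
#' @param n_frames Number of frames (default 150).
#' @param onset Frame after which detach/pocket_distort displacement grows
#'   (default halfway).
#' @param baseline Baseline jitter sd in nm for detach/pocket_distort
#'   (default 0.01).
#' @param target_chain Chain to detach (default the last in stacking
#'   order).
#' @param target_resids Residue numbers displaced in `pocket_distort`
#'   (default the middle meander strand, residues 22-31).
#' @param time_per_frame ns per frame (default 1).
#' @param seed RNG seed (default 1); fully deterministic given the seed.
#' @return A `fibril_trajectory` whose first frame is the input structure
#'   when `amplitude` or the ramp at frame 1 is zero.
#' @export
make_trajectory <- function(structure,
                            mode = c("stable", "melt", "detach",
                                     "pocket_distort", "scramble"),
                            amplitude = NULL, n_frames = 150,
                            onset = floor(n_frames / 2), baseline = 0.01,
                            target_chain = NULL, target_resids = 22:31,
                            time_per_frame = 1, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(amplitude)) {
    amplitude <- switch(mode, stable = 0.01, melt = 0.2, detach = 10,
                        pocket_distort = 0.5, scramble = 0)
  }
  if (amplitude < 0) abort("amplitude must be >= 0")
  if (onset >= n_frames) abort("onset must be before the last frame")
  x0 <- coords(structure)
  na <- nrow(x0)
  a <- structure$atoms
  chains <- protein_chains(structure)
  if (is.null(target_chain)) target_chain <- chains[length(chains)]

  arr <- with_local_seed(seed, {
    out <- array(0, dim = c(na, 3, n_frames))
    for (f in seq_len(n_frames)) {
      xyz <- x0
      sdv <- switch(mode,
        stable = amplitude,
        melt = amplitude * (f - 1) / max(n_frames - 1, 1),
        detach = baseline,
        pocket_distort = baseline,
        scramble = 0)
      if (sdv > 0) xyz <- xyz + rnorm(3 * na, sd = sdv)
      if (mode == "detach" && f > onset) {
        shift <- amplitude * (f - onset) / (n_frames - onset)
        sel <- a$chain == target_chain
        xyz[sel, 1] <- xyz[sel, 1] + shift
      }
      if (mode == "pocket_distort" && f > onset) {
        shift <- amplitude * (f - onset) / (n_frames - onset)
        sel <- a$resid %in% target_resids & !a$hetero
        xyz[sel, 2] <- xyz[sel, 2] + shift
      }
      if (mode == "scramble") {
        for (ch in chains) {
          sel <- a$chain == ch
          rot <- random_rotation()
          cm <- colMeans(xyz[sel, , drop = FALSE])
          xyz[sel, ] <- sweep(sweep(xyz[sel, , drop = FALSE], 2, cm) %*%
                                t(rot), 2, cm, "+")
        }
      }
      out[, , f] <- xyz
    }
    out
  })
  fibril_trajectory(structure, arr, time_per_frame = time_per_frame)
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
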