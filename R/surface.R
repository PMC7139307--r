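# Shrake-Rupley solvent-accessible surface area and the inter-chain
# interaction (buried) area metric derived from it.

#' Default van der Waals radii (nm) by element
#' @return Named numeric vector of radii in nm.
#' @export
default_vdw_radii <- function() {
  c(C = 0.17, N = 0.155, O = 0.152, S = 0.18, H = 0.12)
}

# deterministic quasi-uniform unit sphere point set (golden-spiral lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elements, radii_table) {
  r <- radii_table[elements]
  if (any(is.na(r))) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unique(elements[is.na(r)]), collapse = ", ")))
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere of radius (vdW + probe) carries a deterministic
#' Fibonacci-lattice point set; the accessible area is the exposed-point
#' fraction times the sphere area.
#'
#' @param structure A `fibril_structure` supplying elements.
#' @param frame_coords Optional n x 3 coordinate override (nm).
#' @param mask Atom indices to include (default all); excluded atoms do not
#'   occlude.
#' @param probe Probe radius in nm (default 0.14, a water molecule).
#' @param n_points Quadrature points per atom (default 960, minimum 60).
#' @param radii_table Named per-element radii (nm), see
#'   [default_vdw_radii()].
#' @return List with `atom_area` (per included atom, nm^2), `total` (nm^2),
#'   `mask`, `probe`, `n_points`.
#' @export
sasa <- function(structure, frame_coords = NULL, mask = NULL,
                 probe = 0.14, n_points = 960,
                 radii_table = default_vdw_radii()) {
  if (n_points < 60) abort("n_points must be >= 60")
  xyz <- if (is.null(frame_coords)) coords(structure) else as.matrix(frame_coords)
  if (is.null(mask)) mask <- seq_len(nrow(xyz))
  if (length(mask) == 0) abort("empty atom mask")
  r <- atom_radii(structure$atoms$element[mask], radii_table)
  area <- cpp_sasa(xyz[mask, , drop = FALSE], r, probe,
                   fibonacci_sphere(n_points))
  list(atom_area = area, total = sum(area), mask = mask, probe = probe,
       n_points = n_points)
}

#' Buried (interaction) surface area between two atom groups
#'
#' `0.5 * (SASA(A alone) + SASA(B alone) - SASA(A union B))`. Quadrature
#' noise can dip marginally below zero for well-separated groups; the result
#' is clamped at 0 with a warning in that case.
#'
#' @inheritParams sasa
#' @param mask_a,mask_b Disjoint, non-empty atom index vectors.
#' @return Buried area in nm^2 (>= 0).
#' @export
buried_area <- function(structure, frame_coords = NULL, mask_a, mask_b,
                        probe = 0.14, n_points = 960,
                        radii_table = default_vdw_radii()) {
  if (length(mask_a) == 0 || length(mask_b) == 0) {
    abort("both atom masks must be non-empty")
  }
  if (length(intersect(mask_a, mask_b)) > 0) {
    abort("atom masks must be disjoint")
  }
  s <- function(m) sasa(structure, frame_coords, mask = m, probe = probe,
                        n_points = n_points, radii_table = radii_table)$total
  val <- 0.5 * (s(mask_a) + s(mask_b) - s(sort(c(mask_a, mask_b))))
  if (val < 0) {
    if (val < -1e-6) warn("buried area slightly negative; clamped to 0")
    val <- 0
  }
  val
}

#' Per-frame inter-chain interaction area of a fibril trajectory
#'
#' For every frame in the window and every consecutive chain pair in
#' stacking order, the buried surface area between the two chains, plus a
#' secondary count-based contact metric (cross-chain heavy-atom pairs closer
#' than `contact_cutoff`). The per-frame total over the adjacent pairs is
#' the inter-chain interaction area stability indicator; its collapse for a
#' terminal pair signals chain detachment.
#'
#' @param trajectory A `fibril_trajectory` with >= 2 protein chains.
#' @param window_ns Analysis window (last `window_ns` ns; default all).
#' @param probe,n_points,radii_table SASA parameters, see [sasa()].
#' @param contact_cutoff Heavy-atom contact count cutoff in nm (default
#'   0.35).
#' @return Tibble with `frame`, `time_ns`, `chain_i`, `chain_j`,
#'   `buried_area_nm2`, `contact_pairs`; attributes `totals` (per-frame
#'   total tibble), `mean` and `sd` of the per-frame totals.
#' @export
interchain_area_series <- function(trajectory, window_ns = NULL,
                                   probe = 0.14, n_points = 960,
                                   radii_table = default_vdw_radii(),
                                   contact_cutoff = 0.35) {
  chains <- protein_chains(trajectory)
  if (length(chains) < 2) abort("need at least 2 protein chains")
  frames <- window_frames(trajectory, window_ns)
  topo <- trajectory$topology
  masks <- lapply(chains, function(ch) {
    select_atoms(topo, chains = ch, hetero = FALSE)
  })
  heavy <- lapply(chains, function(ch) {
    select_atoms(topo, chains = ch, heavy = TRUE, hetero = FALSE)
  })
  pairs <- seq_len(length(chains) - 1)
  rows <- purrr::map_dfr(frames, function(f) {
    xyz <- trajectory$coords[, , f]
    purrr::map_dfr(pairs, function(p) {
      tibble::tibble(
        frame = f,
        time_ns = f * trajectory$time_per_frame,
        chain_i = chains[p], chain_j = chains[p + 1],
        buried_area_nm2 = buried_area(topo, xyz, masks[[p]], masks[[p + 1]],
                                      probe = probe, n_points = n_points,
                                      radii_table = radii_table),
        contact_pairs = cpp_count_close(xyz, as.integer(heavy[[p]]),
                                        as.integer(heavy[[p + 1]]),
                                        contact_cutoff))
    })
  })
  totals <- dplyr::summarise(dplyr::group_by(rows, .data$frame),
                             time_ns = .data$time_ns[1],
                             total_area_nm2 = sum(.data$buried_area_nm2),
                             .groups = "drop")
  attr(rows, "totals") <- totals
  attr(rows, "mean") <- mean(totals$total_area_nm2)
  attr(rows, "sd") <- if (nrow(totals) > 1) sd(totals$total_area_nm2) else 0
  rows
}
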