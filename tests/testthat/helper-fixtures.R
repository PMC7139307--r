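# fixtures built in code: small fibrils, hand-made structures, random clouds

small_spec <- function(n_chains = 3) {
  fibril_spec(n_chains = n_chains, n_residues = 12, segments = c(6, 6))
}

small_fibril <- function(n_chains = 3) {
  build_ideal_fibril(small_spec(n_chains))
}

# minimal hand-made structure from bare coordinates (one atom per residue)
point_structure <- function(xyz, chain = "A", element = "C", name = NULL,
                            hetero = FALSE) {
  n <- nrow(xyz)
  fibril_structure(tibble::tibble(
    serial = seq_len(n),
    name = if (is.null(name)) paste0("C", seq_len(n)) else name,
    element = element,
    resname = "GLY",
    resid = seq_len(n),
    chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    hetero = hetero))
}

# trajectory from a list of coordinate matrices over one topology
coords_trajectory <- function(topology, frames, time_per_frame = 1) {
  arr <- array(0, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  fibril_trajectory(topology, arr, time_per_frame = time_per_frame)
}

random_cloud <- function(n, scale = 1) {
  matrix(stats::rnorm(3 * n, sd = scale), n, 3)
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# random proper rotation
random_rot <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# idealized two-strand antiparallel sheet: strand B runs in -x above strand A,
# residue j of B partners residue (n_res + 1 - j) of A; carbonyl parities are
# phased so the narrow/wide hydrogen-bond pairs both align vertically
antiparallel_duplex <- function(n_res = 8, rise = 0.48) {
  parity <- function(r) ifelse(r %% 2 == 0, 1, -1)
  rows <- list()
  serial <- 0
  add <- function(rows, chain, r, nm, el, p) {
    serial <<- serial + 1
    rows[[length(rows) + 1]] <- tibble::tibble(
      serial = serial, name = nm, element = el, resname = "ALA",
      resid = r, chain = chain, x = p[1], y = p[2], z = p[3],
      hetero = FALSE)
    rows
  }
  for (r in seq_len(n_res)) {  # strand A, +x direction
    ca <- c(0.38 * r, 0, 0)
    rows <- add(rows, "A", r, "N", "N", ca + c(-0.19, 0, 0))
    rows <- add(rows, "A", r, "CA", "C", ca)
    rows <- add(rows, "A", r, "C", "C", ca + c(0.19, 0, 0))
    rows <- add(rows, "A", r, "O", "O", ca + c(0.19, 0, 0.123 * parity(r)))
  }
  for (r in seq_len(n_res)) {  # strand B, -x direction, x-aligned partners
    ca <- c(0.38 * (n_res + 1 - r), 0, rise)
    rows <- add(rows, "B", r, "N", "N", ca + c(0.19, 0, 0))
    rows <- add(rows, "B", r, "CA", "C", ca)
    rows <- add(rows, "B", r, "C", "C", ca + c(-0.19, 0, 0))
    rows <- add(rows, "B", r, "O", "O", ca + c(-0.19, 0, 0.123 * parity(r)))
  }
  fibril_structure(dplyr::bind_rows(rows))
}
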