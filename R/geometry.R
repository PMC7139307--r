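#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD of
#' `mobile` onto `reference`. The reflection branch of the SVD solution is
#' handled so the returned rotation always has determinant +1.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), n >= 3,
#'   non-collinear reference.
#' @param weights Optional non-negative per-point weights (default uniform).
#' @return List with `rotation` (3 x 3), `translation` (length-3, applied as
#'   `x %*% t(R) + translation`), and `rmsd` (nm, weighted).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) abort("point sets must have equal size")
  if (n < 3) abort("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  m0 <- sweep(mobile, 2, cm)
  r0 <- sweep(reference, 2, cr)
  sv_ref <- svd(r0 * sqrt(w))$d
  if (sv_ref[2] < 1e-10 * max(sv_ref[1], 1e-300)) {
    abort("degenerate (collinear) reference point set")
  }
  a <- crossprod(r0 * w, m0)  # 3x3 covariance
  s <- svd(a)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- m0 %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - r0)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% t(rot)),
       rmsd = rmsd)
}

# apply a kabsch_superpose transform to an n x 3 matrix
apply_transform <- function(coords, transform) {
  sweep(coords %*% t(transform$rotation), 2, transform$translation, "+")
}

#' RMSD between two frames after least-squares fitting
#'
#' @param coords_a,coords_b Full n x 3 coordinate matrices (nm).
#' @param mask Atom indices used both for the fit and the RMSD (default all).
#' @return RMSD in nm.
#' @export
rmsd_after_fit <- function(coords_a, coords_b, mask = NULL) {
  if (is.null(mask)) mask <- seq_len(nrow(coords_a))
  if (length(mask) == 0) abort("empty atom mask")
  kabsch_superpose(coords_b[mask, , drop = FALSE],
                   coords_a[mask, , drop = FALSE])$rmsd
}

#' All-against-all RMSD matrix over trajectory frames
#'
#' Entry (i, j) is `rmsd_after_fit(frame_i, frame_j, mask)`; the upper
#' triangle is computed once, so the matrix is symmetric by construction with
#' a zero diagonal. This is the matrix that the receptor-selection cluster
#' cutoff (0.1 nm) thresholds.
#'
#' @param trajectory A `fibril_trajectory` with >= 2 frames.
#' @param mask Atom indices to fit on (default all C-alpha atoms).
#' @param frames Frame indices to include (default all).
#' @return A symmetric numeric matrix (nm) with `frames` as dimnames.
#' @export
pairwise_rmsd_matrix <- function(trajectory, mask = NULL, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  if (length(frames) < 2) abort("need at least 2 frames")
  if (is.null(mask)) {
    mask <- select_atoms(trajectory, names = "CA", hetero = FALSE)
  }
  if (length(mask) == 0) abort("empty atom mask")
  sub <- trajectory$coords[mask, , frames, drop = FALSE]
  nf <- length(frames)
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in seq.int(i + 1, nf)) {
      m[i, j] <- m[j, i] <- kabsch_superpose(sub[, , j], sub[, , i])$rmsd
    }
  }
  dimnames(m) <- list(frames, frames)
  m
}

#' Export an RMSD matrix as a tidy frame-pair table
#'
#' @param rmsd_matrix Symmetric matrix from [pairwise_rmsd_matrix()].
#' @return Tibble with columns `frame_i`, `frame_j`, `rmsd_nm` (upper
#'   triangle only).
#' @export
rmsd_matrix_tidy <- function(rmsd_matrix) {
  idx <- which(upper.tri(rmsd_matrix), arr.ind = TRUE)
  fr <- as.integer(rownames(rmsd_matrix) %||% seq_len(nrow(rmsd_matrix)))
  tibble::tibble(frame_i = fr[idx[, 1]], frame_j = fr[idx[, 2]],
                 rmsd_nm = rmsd_matrix[idx])
}

#' Minimum cross-group atom distance
#'
#' Exact minimum Euclidean distance over all pairs with one atom in each
#' group; this is the primitive behind the 0.35 nm contact cutoff.
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param mask_a,mask_b Disjoint, non-empty atom index vectors.
#' @return Distance in nm.
#' @export
min_distance <- function(coords, mask_a, mask_b) {
  if (length(mask_a) == 0 || length(mask_b) == 0) {
    abort("both atom masks must be non-empty")
  }
  if (length(intersect(mask_a, mask_b)) > 0) {
    abort("atom masks must be disjoint")
  }
  cpp_min_cross_dist(as.matrix(coords), as.integer(mask_a),
                     as.integer(mask_b))
}
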