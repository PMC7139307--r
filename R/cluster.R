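#' Single-linkage clustering of frames at an RMSD cutoff
#'
#' Frames i and j share a cluster iff they are connected by a path of frame
#' pairs with RMSD strictly below the cutoff (single-linkage connected
#' components, the `g_cluster -method linkage` semantics of GROMACS-style
#' pipelines). Cluster ids are ordered by decreasing size, ties broken by
#' the lowest member frame index. This is the receptor-selection stage that
#' feeds ensemble docking: the centroid of the most populated cluster is the
#' docking receptor.
#'
#' @param rmsd_matrix Symmetric RMSD matrix (nm), e.g. from
#'   [pairwise_rmsd_matrix()].
#' @param cutoff RMSD cutoff in nm (default 0.1); strictly-less comparison.
#' @param strict Use `<` (default, GROMACS convention) or `<=` at the cutoff.
#' @return A `cluster_result`: list with `labels` (per-frame cluster id),
#'   `sizes` (tibble of cluster id, size, centroid frame), `centroid_index`
#'   (frame index, within the matrix, of the most populated cluster's
#'   centroid) and `frames` (original frame indices, from dimnames).
#' @export
linkage_cluster <- function(rmsd_matrix, cutoff = 0.1, strict = TRUE) {
  m <- as.matrix(rmsd_matrix)
  n <- nrow(m)
  if (n < 1 || n != ncol(m)) abort("rmsd_matrix must be square")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-9))) {
    abort("rmsd_matrix must be symmetric")
  }
  if (any(m < 0) || any(abs(diag(m)) > 1e-12)) {
    abort("rmsd_matrix must be non-negative with zero diagonal")
  }
  if (!is.numeric(cutoff) || cutoff <= 0) abort("cutoff must be > 0 (nm)")

  adj <- if (strict) m < cutoff else m <= cutoff
  diag(adj) <- TRUE
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  # relabel: decreasing size, ties by lowest member frame index
  sizes <- tabulate(comp)
  first <- vapply(seq_len(max(comp)), function(k) min(which(comp == k)),
                  integer(1))
  ord <- order(-sizes, first)
  labels <- match(comp, ord)
  frames <- as.integer(rownames(m) %||% seq_len(n))

  size_tbl <- tibble::tibble(
    cluster = seq_along(ord),
    size = sizes[ord],
    centroid_frame = vapply(seq_along(ord), function(k) {
      frames[cluster_centroid(m, which(labels == k))]
    }, integer(1)))

  structure(list(labels = labels,
                 sizes = size_tbl,
                 centroid_index = cluster_centroid(m, which(labels == 1L)),
                 frames = frames,
                 cutoff = cutoff),
            class = "cluster_result")
}

#' Centroid (minimum mean-RMSD member) of a frame cluster
#'
#' The member with minimum mean RMSD to all other members; ties resolved to
#' the lowest frame index. A singleton cluster's centroid is its only member.
#'
#' @param rmsd_matrix Symmetric RMSD matrix.
#' @param member_indices Row/column indices of the cluster members.
#' @return Index (into the matrix) of the centroid member.
#' @export
cluster_centroid <- function(rmsd_matrix, member_indices) {
  if (length(member_indices) == 0) abort("empty member set")
  if (length(member_indices) == 1) return(as.integer(member_indices))
  sub <- rmsd_matrix[member_indices, member_indices, drop = FALSE]
  mean_rmsd <- rowSums(sub) / (length(member_indices) - 1)
  as.integer(member_indices[which.min(mean_rmsd)])
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$labels), " frames, ",
      nrow(x$sizes), " cluster(s) at cutoff ", x$cutoff, " nm; centroid frame ",
      x$frames[x$centroid_index], " (cluster of ", x$sizes$size[1],
      " frames)\n", sep = "")
  invisible(x)
}

#' @describeIn linkage_cluster Per-frame tibble of cluster assignments.
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(frame = x$frames, cluster = x$labels)
}

#' @describeIn linkage_cluster One-row summary of the clustering.
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_frames = length(x$labels),
                 n_clusters = nrow(x$sizes),
                 largest_size = x$sizes$size[1],
                 largest_fraction = x$sizes$size[1] / length(x$labels),
                 centroid_frame = x$frames[x$centroid_index],
                 cutoff_nm = x$cutoff)
}

#' @describeIn linkage_cluster Bar chart of cluster populations.
#' @param object A `cluster_result`.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  ggplot2::ggplot(object$sizes,
                  ggplot2::aes(x = factor(.data$cluster), y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster (by decreasing population)",
                  y = "frames",
                  title = paste0("Single-linkage clusters at ",
                                 object$cutoff, " nm RMSD cutoff")) +
    ggplot2::theme_minimal()
}
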