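# Fibril-order and ligand-contact stability metrics: the chain-orientation
# order parameter, bound-frame masking, per-residue contact probability and
# the per-complex stability report.

#' Chain-orientation order parameter of a fibril trajectory
#'
#' For every chain c and residue n, the connecting vector from the chain's
#' centre (of its C-alpha atoms, mode `"chain"`) to the residue's C-alpha is
#' normalized; the order parameter of frame t is the mean dot product of
#' these unit vectors with their reference-frame counterparts, averaged over
#' all chains and residues. A value of 1 means the initial orientation is
#' preserved; lower values indicate gradual structural distortion. Frames
#' are least-squares fitted (C-alpha) onto the reference by default so that
#' global rigid-body motion does not masquerade as disorder.
#'
#' @param trajectory A `fibril_trajectory`.
#' @param ca_mask C-alpha atom selection (default all protein `CA`).
#' @param reference_frame Reference frame index (default 1).
#' @param fit Least-squares fit each frame onto the reference before
#'   measuring (default TRUE).
#' @param window_ns Averaging window (last `window_ns` ns; default all
#'   frames).
#' @param com_mode `"chain"` (default): vectors fan out from each chain's
#'   centre; `"residue"`: each vector runs from the residue's own heavy-atom
#'   centre to its C-alpha.
#' @return Tibble with `frame`, `time_ns`, `ordp`; attributes `mean` (window
#'   average), `n_chains`, `n_residues`, `reference_frame`, `fit`.
#' @export
order_parameter <- function(trajectory, ca_mask = NULL, reference_frame = 1L,
                            fit = TRUE, window_ns = NULL,
                            com_mode = c("chain", "residue")) {
  com_mode <- match.arg(com_mode)
  topo <- trajectory$topology
  if (is.null(ca_mask)) {
    ca_mask <- select_atoms(topo, names = "CA", hetero = FALSE)
  }
  if (length(ca_mask) == 0) abort("empty C-alpha mask")
  if (reference_frame < 1 || reference_frame > n_frames(trajectory)) {
    abort("reference frame outside trajectory")
  }
  chain_of <- topo$atoms$chain[ca_mask]
  chains <- unique(chain_of)
  if (any(table(chain_of) < 2)) abort("every chain needs at least 2 residues")

  res_centres <- NULL
  if (com_mode == "residue") {
    key <- paste(topo$atoms$chain, topo$atoms$resid)
    res_centres <- lapply(ca_mask, function(i) {
      which(key == key[i] & topo$atoms$element != "H")
    })
  }

  unit_vectors <- function(xyz) {
    ca <- xyz[ca_mask, , drop = FALSE]
    if (com_mode == "chain") {
      centre <- rowsum(ca, chain_of)[chain_of, , drop = FALSE]
      centre <- centre / as.vector(table(chain_of)[chain_of])
    } else {
      centre <- t(vapply(res_centres, function(ix) {
        colMeans(xyz[ix, , drop = FALSE])
      }, numeric(3)))
    }
    v <- ca - centre
    len <- sqrt(rowSums(v^2))
    if (any(len < 1e-12)) abort("zero-length connecting vector")
    v / len
  }

  ref_xyz <- trajectory$coords[, , reference_frame]
  v0 <- unit_vectors(ref_xyz)
  ref_ca <- ref_xyz[ca_mask, , drop = FALSE]

  frames <- window_frames(trajectory, window_ns)
  ordp <- vapply(frames, function(f) {
    xyz <- trajectory$coords[, , f]
    if (fit && f != reference_frame) {
      tr <- kabsch_superpose(xyz[ca_mask, , drop = FALSE], ref_ca)
      xyz <- apply_transform(xyz, tr)
    }
    mean(rowSums(v0 * unit_vectors(xyz)))
  }, numeric(1))

  out <- tibble::tibble(frame = frames,
                        time_ns = frames * trajectory$time_per_frame,
                        ordp = ordp)
  attr(out, "mean") <- mean(ordp)
  attr(out, "n_chains") <- length(chains)
  attr(out, "n_residues") <- length(ca_mask) / length(chains)
  attr(out, "reference_frame") <- reference_frame
  attr(out, "fit") <- fit
  out
}

#' Frames in which a ligand is bound to the receptor
#'
#' A frame counts as bound when the minimum ligand-receptor atom distance is
#' strictly below the cutoff. Used to mask contact-probability estimation to
#' effectively-docked frames (a ligand that detaches during the run should
#' not dilute its own contact map).
#'
#' @param trajectory A `fibril_trajectory`.
#' @param ligand_mask,receptor_mask Disjoint, non-empty atom selections.
#' @param cutoff Distance cutoff in nm (default 0.35, strict `<`).
#' @param frames Frame indices to test (default all).
#' @return Logical vector over `frames`.
#' @export
bound_frames <- function(trajectory, ligand_mask, receptor_mask,
                         cutoff = 0.35, frames = NULL) {
  if (length(ligand_mask) == 0) abort("empty ligand mask")
  if (length(receptor_mask) == 0) abort("empty receptor mask")
  if (length(intersect(ligand_mask, receptor_mask)) > 0) {
    abort("ligand and receptor masks must be disjoint")
  }
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  vapply(frames, function(f) {
    cpp_min_cross_dist(trajectory$coords[, , f], as.integer(ligand_mask),
                       as.integer(receptor_mask)) < cutoff
  }, logical(1))
}

#' Per-residue ligand contact probability (chain-aggregated)
#'
#' For each frame and each residue identity (residue number + name,
#' chain-agnostic), a contact is counted when any chain's copy of the
#' residue has a heavy atom strictly within `cutoff` of a ligand heavy
#' atom. The probability is contact frames divided by considered frames.
#' Because the fibril is a stack of identical chains, only the residue
#' identity is informative, so equivalent residues of different chains are
#' pooled.
#'
#' @param trajectory A `fibril_trajectory`.
#' @param ligand_mask Ligand atom selection (non-empty).
#' @param cutoff Contact cutoff in nm (default 0.35, strict `<`).
#' @param frames Frame indices to consider (e.g. the analysis window
#'   intersected with [bound_frames()]); default all frames.
#' @param heavy_only Use heavy atoms only (default TRUE).
#' @return Tibble with `resid`, `resname`, `probability`, plus attributes
#'   `cutoff` and `n_frames` (frames considered).
#' @export
residue_contact_probability <- function(trajectory, ligand_mask,
                                        cutoff = 0.35, frames = NULL,
                                        heavy_only = TRUE) {
  if (length(ligand_mask) == 0) abort("empty ligand mask")
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  if (length(frames) == 0) abort("no bound frames to consider")
  topo <- trajectory$topology
  a <- topo$atoms
  rec <- which(!a$hetero & !(seq_len(nrow(a)) %in% ligand_mask) &
                 (!heavy_only | a$element != "H"))
  lig <- ligand_mask
  if (heavy_only) lig <- lig[a$element[lig] != "H"]
  if (length(lig) == 0) abort("empty ligand mask")

  ident <- paste0(a$resid[rec], "|", a$resname[rec])
  idents <- unique(ident)
  counts <- setNames(numeric(length(idents)), idents)
  c2 <- cutoff^2
  for (f in frames) {
    xyz <- trajectory$coords[, , f]
    lg <- xyz[lig, , drop = FALSE]
    rc <- xyz[rec, , drop = FALSE]
    d2 <- outer(rowSums(rc^2), rowSums(lg^2), "+") - 2 * tcrossprod(rc, lg)
    hit <- rowSums(d2 < c2) > 0  # any ligand atom within cutoff of this atom
    touched <- unique(ident[hit])
    counts[touched] <- counts[touched] + 1
  }
  parts <- strsplit(idents, "|", fixed = TRUE)
  out <- tibble::tibble(
    resid = as.integer(vapply(parts, `[`, character(1), 1)),
    resname = vapply(parts, `[`, character(1), 2),
    probability = unname(counts) / length(frames))
  out <- out[order(out$resid), ]
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- length(frames)
  out
}

#' Full stability report for one (apo or ligand-bound) fibril trajectory
#'
#' Computes, on a single analysis window (the last `window_ns` ns, default
#' 25), the three stability indicators -- beta-sheet content, chain-
#' orientation order parameter, inter-chain interaction area -- plus the
#' per-residue ligand contact probability map restricted to bound frames.
#' A ligand-free trajectory yields a wild-type report with an empty contact
#' map.
#'
#' @param trajectory A `fibril_trajectory`.
#' @param ligand_mask Ligand atom selection; `NULL` (default) auto-detects
#'   hetero atoms, and an apo structure yields an empty map.
#' @param config An [analysis_config()] carrying cutoffs, window and SASA
#'   parameters.
#' @return A `stability_report` object; see [tidy.stability_report()],
#'   [glance.stability_report()], [autoplot.stability_report()].
#' @export
summarize_complex <- function(trajectory, ligand_mask = NULL,
                              config = analysis_config()) {
  frames <- window_frames(trajectory, config$analysis_window_ns)
  topo <- trajectory$topology
  if (is.null(ligand_mask)) {
    ligand_mask <- select_atoms(topo, hetero = TRUE)
  }

  beta <- beta_content(trajectory, window_ns = config$analysis_window_ns,
                       count_bridges = config$beta_count_bridges)
  ordp <- order_parameter(trajectory, fit = config$ordp_fit,
                          window_ns = config$analysis_window_ns,
                          com_mode = config$ordp_com)
  area <- interchain_area_series(trajectory,
                                 window_ns = config$analysis_window_ns,
                                 probe = config$sasa_probe,
                                 n_points = config$sasa_points,
                                 contact_cutoff = config$contact_cutoff)

  contact_map <- tibble::tibble(resid = integer(), resname = character(),
                                probability = numeric())
  n_bound <- 0L
  if (length(ligand_mask) > 0) {
    receptor <- select_atoms(topo, hetero = FALSE, heavy = TRUE)
    bound <- bound_frames(trajectory, ligand_mask, receptor,
                          cutoff = config$contact_cutoff, frames = frames)
    n_bound <- sum(bound)
    if (n_bound > 0) {
      contact_map <- residue_contact_probability(
        trajectory, ligand_mask, cutoff = config$contact_cutoff,
        frames = frames[bound])
    }
  }

  totals <- attr(area, "totals")
  per_frame <- tibble::tibble(
    frame = beta$frame,
    time_ns = beta$time_ns,
    beta_fraction = beta$beta_fraction,
    ordp = ordp$ordp,
    interchain_area_nm2 = totals$total_area_nm2)

  structure(list(per_frame = per_frame,
                 pair_area = area,
                 contact_map = contact_map,
                 beta_pct_mean = 100 * attr(beta, "mean"),
                 beta_pct_sd = 100 * attr(beta, "sd"),
                 ordp_mean = attr(ordp, "mean"),
                 area_mean = attr(area, "mean"),
                 area_sd = attr(area, "sd"),
                 window_ns = config$analysis_window_ns %||%
                   (n_frames(trajectory) * trajectory$time_per_frame),
                 n_frames = length(frames),
                 n_bound_frames = n_bound,
                 has_ligand = length(ligand_mask) > 0,
                 config = config),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> last ", x$window_ns, " ns (", x$n_frames,
      " frames)\n", sep = "")
  cat(sprintf("  beta content     : %.1f%% +/- %.1f%%\n",
              x$beta_pct_mean, x$beta_pct_sd))
  cat(sprintf("  order parameter  : %.3f\n", x$ordp_mean))
  cat(sprintf("  inter-chain area : %.2f +/- %.2f nm^2\n",
              x$area_mean, x$area_sd))
  if (x$has_ligand) {
    cat("  ligand           : bound in ", x$n_bound_frames, "/", x$n_frames,
        " window frames\n", sep = "")
  } else {
    cat("  ligand           : none (wild type)\n")
  }
  invisible(x)
}

#' Tidy per-frame metrics of a stability report
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return Tibble with `frame`, `time_ns`, `beta_fraction`, `ordp`,
#'   `interchain_area_nm2`.
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) x$per_frame

#' One-row summary of a stability report
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return One-row tibble of the report triple and frame accounting.
#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(beta_pct_mean = x$beta_pct_mean,
                 beta_pct_sd = x$beta_pct_sd,
                 ordp_mean = x$ordp_mean,
                 interchain_area_mean_nm2 = x$area_mean,
                 interchain_area_sd_nm2 = x$area_sd,
                 window_ns = x$window_ns,
                 n_frames = x$n_frames,
                 n_bound_frames = x$n_bound_frames)
}

#' Plot the per-frame stability metrics of a report
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot with one facet per metric.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_frame,
                              c("beta_fraction", "ordp",
                                "interchain_area_nm2"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ns, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ns)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap-style strip of a residue contact map
#' @param contact_map Tibble from [residue_contact_probability()] or the
#'   `contact_map` element of a `stability_report`.
#' @return A ggplot tile strip of contact probability by residue.
#' @export
plot_contact_map <- function(contact_map) {
  cm <- dplyr::mutate(contact_map,
                      label = paste0(.data$resname, .data$resid))
  cm$label <- factor(cm$label, levels = cm$label[order(cm$resid)])
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$label, y = 1,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "contact\nprobability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
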