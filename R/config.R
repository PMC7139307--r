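#' Analysis configuration with field-standard defaults
#'
#' Collects every tunable of the pipeline. Defaults are the protocol's
#' stated parameters: 0.35 nm contact cutoff, 0.1 nm cluster RMSD cutoff,
#' analysis on the last 25 ns, clustering on the last 50 ns.
#'
#' @param contact_cutoff Ligand/inter-chain contact cutoff, nm.
#' @param cluster_cutoff Single-linkage RMSD cutoff, nm.
#' @param analysis_window_ns Stability metrics window (last N ns).
#' @param cluster_window_ns Clustering window (last N ns).
#' @param ordp_fit Least-squares fit frames before the order parameter.
#' @param ordp_com Order-parameter centre mode, `"chain"` or `"residue"`.
#' @param sasa_probe SASA probe radius, nm.
#' @param sasa_points SASA quadrature points per atom.
#' @param beta_count_bridges Count isolated bridges (B) as beta.
#' @param cluster_strict Strict `<` at the cluster cutoff (GROMACS
#'   convention).
#' @param seed Seed recorded in outputs and used by seeded pipeline stages.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(contact_cutoff = 0.35, cluster_cutoff = 0.1,
                            analysis_window_ns = 25, cluster_window_ns = 50,
                            ordp_fit = TRUE, ordp_com = "chain",
                            sasa_probe = 0.14, sasa_points = 960,
                            beta_count_bridges = TRUE, cluster_strict = TRUE,
                            seed = 1) {
  stopifnot(contact_cutoff > 0, cluster_cutoff > 0, analysis_window_ns > 0,
            cluster_window_ns > 0, sasa_probe > 0, sasa_points >= 60)
  structure(list(contact_cutoff = contact_cutoff,
                 cluster_cutoff = cluster_cutoff,
                 analysis_window_ns = analysis_window_ns,
                 cluster_window_ns = cluster_window_ns,
                 ordp_fit = isTRUE(ordp_fit),
                 ordp_com = match.arg(ordp_com, c("chain", "residue")),
                 sasa_probe = sasa_probe,
                 sasa_points = as.integer(sasa_points),
                 beta_count_bridges = isTRUE(beta_count_bridges),
                 cluster_strict = isTRUE(cluster_strict),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (k in names(x)) cat("  ", k, " = ", format(x[[k]]), "\n", sep = "")
  invisible(x)
}

#' Write an analysis configuration as flat key = value text
#' @param config An [analysis_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.logical(v)) {
      if (v) "true" else "false"
    } else {
      format(v, digits = 15)
    }
  }, character(1))
  writeLines(paste0(names(config), " = ", vals), path)
  invisible(path)
}

#' Read an analysis configuration from flat key = value text
#' @param path File written by [write_config()] (or hand-edited).
#' @return An `analysis_config`; round-trips losslessly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  defaults <- analysis_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  args <- lapply(seq_along(keys), function(i) {
    proto <- defaults[[keys[i]]]
    if (is.logical(proto)) return(vals[i] == "true")
    if (is.character(proto)) return(vals[i])
    as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(analysis_config, args)
}

# header lines recording the exact config + seed in every output file
config_header <- function(config, extra = character()) {
  vals <- vapply(config, function(v) {
    if (is.logical(v)) (if (v) "true" else "false") else format(v, digits = 15)
  }, character(1))
  c(paste0("# ", names(config), " = ", vals), paste0("# ", extra))
}

write_csv_with_header <- function(df, path, config, extra = character()) {
  writeLines(config_header(config, extra), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
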