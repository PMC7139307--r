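# brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths

oracle_min_distance <- function(coords, ia, ib) {
  best <- Inf
  for (i in ia) {
    for (j in ib) {
      best <- min(best, sqrt(sum((coords[i, ] - coords[j, ])^2)))
    }
  }
  best
}

# connected components under strict < cutoff via exhaustive path search
# (transitive closure by repeated squaring of the adjacency relation)
oracle_components <- function(m, cutoff) {
  n <- nrow(m)
  adj <- (m < cutoff)
  diag(adj) <- TRUE
  reach <- adj
  for (step in seq_len(ceiling(log2(max(n, 2))) + 1)) {
    reach <- (reach %*% reach) > 0
  }
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

oracle_centroid <- function(m, members) {
  if (length(members) == 1) return(members)
  means <- vapply(members, function(i) {
    mean(m[i, setdiff(members, i)])
  }, numeric(1))
  members[which.min(means)]
}

# per-chain exhaustive contact probability scan
oracle_contact_probability <- function(trajectory, ligand_idx, cutoff) {
  a <- trajectory$topology$atoms
  rec <- which(!a$hetero & a$element != "H")
  lig <- ligand_idx[a$element[ligand_idx] != "H"]
  ids <- unique(paste0(a$resid[rec], "|", a$resname[rec]))
  nf <- n_frames(trajectory)
  counts <- setNames(numeric(length(ids)), ids)
  for (f in seq_len(nf)) {
    xyz <- trajectory$coords[, , f]
    hit <- character()
    for (ch in unique(a$chain[rec])) {
      for (r in unique(a$resid[rec][a$chain[rec] == ch])) {
        atoms_r <- rec[a$chain[rec] == ch & a$resid[rec] == r]
        dmin <- oracle_min_distance(xyz, atoms_r, lig)
        if (dmin < cutoff) {
          hit <- c(hit, paste0(r, "|", a$resname[atoms_r[1]]))
        }
      }
    }
    hit <- unique(hit)
    counts[hit] <- counts[hit] + 1
  }
  counts / nf
}

# random symmetric non-negative matrix with zero diagonal
random_rmsd_matrix <- function(n, scale = 0.3) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, 0, scale)
  m + t(m)
}
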