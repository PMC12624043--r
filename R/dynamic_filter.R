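# Multi-step dynamical/structural filter: prune low-confidence segments,
# merge spatially packed segments into entries, gate by size, recompute
# RSA on the pruned entry, decompose into quasi-rigid domains from
# elastic-network normal modes, and drop sites whose side chains straddle
# a domain boundary (low proportion of intra-domain contacts, Pidc).

#' Split a structure into maximal high-confidence segments
#'
#' Removes loops, linkers and disordered regions predicted with low
#' confidence: a segment is a maximal run of consecutive residues with
#' pLDDT at or above `plddt_min`. Original numbering is preserved.
#'
#' @param s `cp_structure`
#' @param plddt_min confidence cut (default 65)
#' @return list of integer vectors of residue positions (possibly empty)
#' @export
prune_low_confidence <- function(s, plddt_min = 65) {
  stopifnot(inherits(s, "cp_structure"))
  keep <- s$residues$plddt >= plddt_min
  if (!any(keep)) return(list())
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- Map(function(a, b) s$residues$position[a:b],
              starts[r$values], ends[r$values])
  unname(segs)
}

# min heavy-atom distance between every residue of A and every residue of B
residue_pair_mindist <- function(s, posA, posB) {
  atA <- s$atoms[s$atoms$resno %in% posA, , drop = FALSE]
  atB <- s$atoms[s$atoms$resno %in% posB, , drop = FALSE]
  xa <- as.matrix(atA[, c("x", "y", "z")])
  xb <- as.matrix(atB[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  # reduce atom-atom to residue-residue minima
  fa <- factor(atA$resno, levels = posA)
  fb <- factor(atB$resno, levels = posB)
  m <- matrix(Inf, length(posA), length(posB), dimnames = list(posA, posB))
  for (i in seq_along(posA)) {
    sub <- d[fa == posA[i], , drop = FALSE]
    m[i, ] <- vapply(seq_along(posB),
                     function(j) min(sub[, fb == posB[j]]), numeric(1))
  }
  m
}

#' Merge spatially packed segments into single entries
#'
#' Two segments belong to the same entry when at least `min_pairs`
#' inter-segment residue pairs lie within `contact_dist` (minimal
#' heavy-atom distance, inclusive). Merging is transitive: entries are
#' the connected components of the contact graph.
#'
#' @param segments list of position vectors (from [prune_low_confidence()])
#' @param s the parent `cp_structure`
#' @param contact_dist pair distance cut in Angstrom (default 5.0)
#' @param min_pairs minimum qualifying pairs (default 5)
#' @return list of `cp_entry` objects (sub-structure + position map)
#' @export
merge_entries <- function(segments, s, contact_dist = 5.0, min_pairs = 5L) {
  if (length(segments) == 0L) return(list())
  n <- length(segments)
  adj <- diag(TRUE, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      m <- residue_pair_mindist(s, segments[[i]], segments[[j]])
      adj[i, j] <- adj[j, i] <- sum(m <= contact_dist) >= min_pairs
    }
  }
  comp <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        if (comp[v] == 0L) {
          comp[v] <- cid
          queue <- c(queue, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  lapply(seq_len(cid), function(k) {
    pos <- sort(unlist(segments[comp == k]))
    structure(list(parent_accession = s$source_name,
                   structure = structure_subset(s, pos),
                   positions = pos),
              class = "cp_entry")
  })
}

#' @export
print.cp_entry <- function(x, ...) {
  cat(sprintf("<cp_entry> %s: %d residues (%d..%d)\n", x$parent_accession,
              length(x$positions), min(x$positions), max(x$positions)))
  invisible(x)
}

#' Drop entries too small for reliable normal-mode analysis
#'
#' Entries with fewer than `min_size` residues are removed; cryptic
#' candidate sites inside them are excluded as `excluded:small_domain`.
#'
#' @param entries list of `cp_entry`
#' @param sites `cp_sites` (may be NULL)
#' @param min_size minimum entry size (default 40, kept inclusive)
#' @return list with `entries` (kept) and `sites` (statuses updated)
#' @export
size_gate <- function(entries, sites = NULL, min_size = 40L) {
  small <- vapply(entries, function(e) length(e$positions) < min_size, logical(1))
  if (!is.null(sites) && any(small)) {
    dropped_pos <- unlist(lapply(entries[small], `[[`, "positions"))
    idx <- which(sites$status == "cryptic" & sites$position %in% dropped_pos)
    sites <- set_status(sites, idx, "excluded:small_domain")
  }
  list(entries = entries[!small], sites = sites)
}

#' Recompute RSA on the pruned entry and drop newly exposed sites
#'
#' Pruning removes atoms; a site that was buried only under a
#' low-confidence loop becomes exposed once that loop is gone. SASA is
#' recomputed on the isolated entry's atoms; cryptic sites whose new RSA
#' exceeds the cut become `excluded:exposed_after_pruning`. The entry RSA
#' is stored in column `rsa_entry`.
#'
#' @param entry `cp_entry`
#' @param sites `cp_sites`; every cryptic site passed must lie in the entry
#' @param th `cp_thresholds`
#' @param params `sasa_params`
#' @param max_asa maximum-SASA table
#' @return updated `cp_sites`
#' @export
refilter_rsa <- function(entry, sites, th = cp_thresholds(),
                         params = sasa_params(), max_asa = MAX_ASA_GXG) {
  stopifnot(inherits(entry, "cp_entry"))
  idx <- which(sites$status == "cryptic")
  if (length(idx) == 0L) return(sites)
  if (!all(sites$position[idx] %in% entry$positions))
    stop("state error: cryptic site outside the entry")
  rsa <- residue_rsa(entry$structure, params, max_asa)
  if (!"rsa_entry" %in% names(sites)) sites$rsa_entry <- NA_real_
  m <- match(sites$position[idx], rsa$position)
  sites$rsa_entry[idx] <- rsa$rsa[m]
  exposed <- idx[rsa$rsa[m] > th$rsa_cryptic]
  set_status(sites, exposed, "excluded:exposed_after_pruning")
}

# --- beta-Gaussian elastic network -----------------------------------------

entry_structure <- function(x) {
  if (inherits(x, "cp_entry")) x$structure
  else if (inherits(x, "cp_structure")) x
  else stop("need a cp_entry or cp_structure")
}

# network nodes: one CA per residue plus one side-chain centroid for
# residues that have side-chain heavy atoms (none for Gly)
enm_nodes <- function(s) {
  pos <- s$residues$position
  ca <- t(vapply(pos, function(p) {
    at <- s$atoms[s$atoms$resno == p & s$atoms$name == "CA", , drop = FALSE]
    if (nrow(at) == 0L) stop("residue ", p, " has no CA atom")
    c(at$x[1L], at$y[1L], at$z[1L])
  }, numeric(3)))
  side <- lapply(pos, function(p) {
    at <- s$atoms[s$atoms$resno == p & !(s$atoms$name %in% BACKBONE_ATOMS), ,
                  drop = FALSE]
    if (nrow(at) == 0L) NULL else colMeans(as.matrix(at[, c("x", "y", "z")]))
  })
  has_side <- !vapply(side, is.null, logical(1))
  xyz <- rbind(ca, do.call(rbind, side[has_side]))
  list(xyz = xyz, n_ca = length(pos), positions = pos,
       side_of = which(has_side))
}

#' Low-frequency normal modes of a beta-Gaussian elastic network
#'
#' Builds a uniform-spring anisotropic network on Calpha nodes augmented
#' with side-chain centroids, integrates the side-chain nodes out (Schur
#' complement), and returns the lowest non-trivial modes of the
#' effective Calpha Hessian. The six near-zero rigid-body modes are
#' verified and discarded.
#'
#' @param entry `cp_entry` or `cp_structure` (>= 40 residues recommended)
#' @param cutoff spring distance cut in Angstrom (default 7.5)
#' @param n_modes number of non-zero modes to retain (default 10)
#' @return list of class `cp_enm_modes`: `values` (eigenvalues,
#'   ascending), `vectors` (3N x n_modes), `ca_xyz`, `positions`,
#'   `all_values`
#' @export
enm_modes <- function(entry, cutoff = 7.5, n_modes = 10L) {
  s <- entry_structure(entry)
  nodes <- enm_nodes(s)
  xyz <- nodes$xyz
  m <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= cutoff & upper.tri(d)
  # connectivity check on the spring graph
  comp <- rep(0L, m); cid <- 0L
  nb <- d <= cutoff
  for (i in seq_len(m)) if (comp[i] == 0L) {
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] == 0L) { comp[v] <- cid; queue <- c(queue, which(nb[v, ] & comp == 0L)) }
    }
  }
  if (cid > 1L)
    stop("elastic network disconnected at cutoff ", cutoff, " A: components of sizes ",
         paste(tabulate(comp), collapse = ", "))
  H <- matrix(0, 3 * m, 3 * m)
  pairs <- which(adj, arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    u <- xyz[j, ] - xyz[i, ]
    rij2 <- sum(u^2)
    if (rij2 < 1e-12) next
    blk <- tcrossprod(u) / rij2
    ii <- 3L * (i - 1L) + 1:3; jj <- 3L * (j - 1L) + 1:3
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  n_ca <- nodes$n_ca
  ia <- seq_len(3L * n_ca)
  ib <- setdiff(seq_len(3L * m), ia)
  Heff <- if (length(ib))
    H[ia, ia] - H[ia, ib] %*% solve(H[ib, ib], H[ib, ia])
  else H[ia, ia]
  Heff <- (Heff + t(Heff)) / 2
  eg <- eigen(Heff, symmetric = TRUE)
  vals <- rev(eg$values)
  vecs <- eg$vectors[, ncol(eg$vectors):1, drop = FALSE]
  if (any(vals < -1e-9 * max(vals)))
    stop("Hessian not positive semidefinite")
  scale7 <- vals[7L]
  if (any(vals[1:6] >= 1e-8 * scale7))
    warning("rigid-body null space not cleanly separated")
  sel <- 6L + seq_len(min(n_modes, length(vals) - 6L))
  structure(list(values = vals[sel], vectors = vecs[, sel, drop = FALSE],
                 ca_xyz = xyz[seq_len(n_ca), , drop = FALSE],
                 positions = nodes$positions, all_values = vals),
            class = "cp_enm_modes")
}

# pairwise distance-fluctuation matrix to quadratic order: fluctuation of
# |x_i - x_j| from the retained modes, amplitudes proportional to 1/eigenvalue
distance_fluctuations <- function(modes) {
  X <- modes$ca_xyz
  n <- nrow(X)
  ex <- outer(X[, 1], X[, 1], "-")
  ey <- outer(X[, 2], X[, 2], "-")
  ez <- outer(X[, 3], X[, 3], "-")
  dn <- sqrt(ex^2 + ey^2 + ez^2); diag(dn) <- 1
  ex <- ex / dn; ey <- ey / dn; ez <- ez / dn
  sig2 <- matrix(0, n, n)
  for (k in seq_along(modes$values)) {
    v <- matrix(modes$vectors[, k], ncol = 3L, byrow = TRUE)
    proj <- outer(v[, 1], v[, 1], "-") * ex +
      outer(v[, 2], v[, 2], "-") * ey +
      outer(v[, 3], v[, 3], "-") * ez
    sig2 <- sig2 + proj^2 / modes$values[k]
  }
  sqrt(sig2)
}

kmedoids_assign <- function(D, k, n_restarts = 25L, seed = 1L) {
  n <- nrow(D)
  best <- NULL; best_cost <- Inf
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      med <- sample.int(n, k)
      for (iter in 1:50) {
        lab <- apply(D[, med, drop = FALSE], 1L, which.min)
        new_med <- vapply(seq_len(k), function(c) {
          mem <- which(lab == c)
          if (!length(mem)) return(med[c])
          mem[which.min(colSums(D[mem, mem, drop = FALSE]))]
        }, integer(1))
        if (all(new_med == med)) break
        med <- new_med
      }
      cost <- sum(D[cbind(seq_len(n), med[lab])])
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- lab }
    }
  })
  best
}

#' Decompose an entry into quasi-rigid domains
#'
#' Distance fluctuations between residue pairs are estimated from the
#' retained elastic-network modes and converted to a similarity graph
#' (`exp(-sigma^2 / sigma_bar^2)`, `sigma_bar` the mean fluctuation over
#' spatially proximal pairs). Spectral clustering of that graph is run
#' for every k in `2..k_max`; each subdivision is scored by the mean
#' silhouette of the residues under the distance-fluctuation
#' dissimilarity itself — a quasi-rigid domain is a group whose internal
#' distances fluctuate little, so a good subdivision has small
#' within-domain and large between-domain fluctuations — and the
#' best-scoring k is chosen (ties and flat profiles resolve to k = 2).
#'
#' @param entry `cp_entry` or `cp_structure`
#' @param modes `cp_enm_modes` from [enm_modes()]
#' @param k_max largest number of domains tried (default 10)
#' @param proximal_cutoff distance defining "proximal" pairs for
#'   `sigma_bar` (default 7.5 A)
#' @param n_restarts seeded k-medoids restarts per k (default 25)
#' @param seed RNG seed for the restarts
#' @return object of class `cp_decomposition`: `labels` (named by
#'   position, chosen k), `quality` (named by k), `chosen_k`,
#'   `labels_by_k`, `sigma_bar`
#' @export
quasi_rigid_decompose <- function(entry, modes = NULL, k_max = 10L,
                                  proximal_cutoff = 7.5, n_restarts = 25L,
                                  seed = 1L) {
  if (is.null(modes)) modes <- enm_modes(entry)
  n <- nrow(modes$ca_xyz)
  if (k_max >= n) stop("k_max must be smaller than the number of residues")
  sig <- distance_fluctuations(modes)
  dn <- as.matrix(stats::dist(modes$ca_xyz))
  prox <- dn <= proximal_cutoff & upper.tri(dn)
  sigma_bar <- mean(sig[prox])
  S <- exp(-sig^2 / sigma_bar^2)
  diag(S) <- 1
  deg <- rowSums(S)
  M <- S / sqrt(outer(deg, deg))
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ks <- 2:k_max
  labels_by_k <- list()
  quality <- stats::setNames(numeric(length(ks)), ks)
  for (k in ks) {
    E <- eg$vectors[, seq_len(k), drop = FALSE]
    E <- E / pmax(sqrt(rowSums(E^2)), 1e-12)
    D <- as.matrix(stats::dist(E))
    lab <- kmedoids_assign(D, k, n_restarts = n_restarts, seed = seed + k)
    labels_by_k[[as.character(k)]] <- stats::setNames(lab, modes$positions)
    sil <- cluster::silhouette(lab, dmatrix = sig)
    quality[as.character(k)] <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else NA_real_
  }
  chosen_k <- ks[which.max(quality)]
  structure(list(labels = labels_by_k[[as.character(chosen_k)]],
                 quality = quality, chosen_k = chosen_k,
                 labels_by_k = labels_by_k, sigma_bar = sigma_bar),
            class = "cp_decomposition")
}

#' @export
print.cp_decomposition <- function(x, ...) {
  cat(sprintf("<cp_decomposition> %d residues, chosen k = %d (quality %.3f)\n",
              length(x$labels), x$chosen_k, max(x$quality)))
  invisible(x)
}

#' Proportion of intra-domain contacts of a phosphosite side chain
#'
#' Neighbours are all other entry residues whose heavy atoms come within
#' `radius` of the site's side-chain heavy atoms; Pidc is the fraction
#' of neighbours sharing the site's quasi-rigid domain label.
#'
#' @param site_position residue position of the site
#' @param entry `cp_entry` or `cp_structure`
#' @param decomposition `cp_decomposition`
#' @param radius neighbour cut in Angstrom (default 6.0)
#' @return list: `position`, `n_neighbors`, `n_same_domain`, `pidc`
#' @export
compute_pidc <- function(site_position, entry, decomposition, radius = 6.0) {
  s <- entry_structure(entry)
  side <- s$atoms[s$atoms$resno == site_position &
                    !(s$atoms$name %in% BACKBONE_ATOMS), , drop = FALSE]
  if (nrow(side) == 0L)
    stop("site ", site_position, " has no side-chain heavy atoms")
  others <- setdiff(s$residues$position, site_position)
  md <- residue_pair_mindist2(s, side, others)
  nb <- others[md <= radius]
  if (length(nb) == 0L)
    stop("data error: site ", site_position,
         " has no neighbours within ", radius, " A")
  lab <- decomposition$labels
  same <- sum(lab[as.character(nb)] == lab[as.character(site_position)])
  list(position = site_position, n_neighbors = length(nb),
       n_same_domain = same, pidc = same / length(nb))
}

# min distance from a fixed atom set to each residue in `others`
residue_pair_mindist2 <- function(s, side_atoms, others) {
  xs <- as.matrix(side_atoms[, c("x", "y", "z")])
  at <- s$atoms[s$atoms$resno %in% others, , drop = FALSE]
  xo <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(xs^2), rowSums(xo^2), "+") - 2 * tcrossprod(xs, xo)
  dmin <- sqrt(pmax(apply(d2, 2L, min), 0))
  vapply(others, function(p) min(dmin[at$resno == p]), numeric(1))
}

#' Exclude cryptic sites with too few intra-domain contacts
#'
#' Sites whose Pidc against the chosen (highest-quality) decomposition
#' falls below `pidc_min` sit on a quasi-rigid domain boundary and are
#' excluded as `excluded:boundary`; Pidc exactly at the cut is retained.
#' A site with no neighbours at all is flagged `excluded:no_neighbors`.
#'
#' @param sites `cp_sites`
#' @param entry `cp_entry`
#' @param decomposition `cp_decomposition`
#' @param pidc_min retention cut (default 0.80, inclusive)
#' @param radius neighbour cut passed to [compute_pidc()]
#' @return updated `cp_sites` with `pidc` and `n_neighbors` columns
#' @export
apply_dynamic_filter <- function(sites, entry, decomposition,
                                 pidc_min = 0.80, radius = 6.0) {
  if (!"pidc" %in% names(sites)) sites$pidc <- NA_real_
  if (!"n_neighbors" %in% names(sites)) sites$n_neighbors <- NA_integer_
  idx <- which(sites$status == "cryptic" &
                 sites$position %in% entry$positions)
  for (i in idx) {
    res <- tryCatch(compute_pidc(sites$position[i], entry, decomposition, radius),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(conditionMessage(res))
      sites <- set_status(sites, i, "excluded:no_neighbors")
      next
    }
    sites$pidc[i] <- res$pidc
    sites$n_neighbors[i] <- res$n_neighbors
    if (res$pidc < pidc_min)
      sites <- set_status(sites, i, "excluded:boundary")
  }
  sites
}
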