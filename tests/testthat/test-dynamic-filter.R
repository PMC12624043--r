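test_that("pruning splits chains at low-confidence runs and keeps numbering", {
  n <- 110
  ca <- cbind(seq_len(n) * 3.8, 0, 0)
  s <- tiny_structure(seq_len(n), rep("A", n),
                      c(rep(90, 50), rep(40, 10), rep(90, 50)), ca)
  segs <- prune_low_confidence(s)
  expect_length(segs, 2L)
  expect_equal(lengths(segs), c(50L, 50L))
  expect_equal(segs[[1]], 1:50)
  expect_equal(segs[[2]], 61:110)
  # all-high chain: one segment
  s2 <- tiny_structure(1:60, rep("A", 60), rep(90, 60), cbind(1:60 * 3.8, 0, 0))
  expect_equal(prune_low_confidence(s2), list(1:60))
  # all-low chain: nothing left
  s3 <- tiny_structure(1:60, rep("A", 60), rep(30, 60), cbind(1:60 * 3.8, 0, 0))
  expect_length(prune_low_confidence(s3), 0L)
  # planted loop boundaries on the globule
  fx <- glob_fixture()
  segs <- prune_low_confidence(fx$structure)
  expect_equal(sort(unlist(segs)),
               setdiff(fx$structure$residues$position, fx$truth$loop_positions))
})

test_that("segments merge on >= 5 close residue pairs, transitively", {
  # two parallel strands: k residues of A within 5 A of B
  strand <- function(pos0, n, y) cbind(seq_len(n) * 3.8, y, 0)
  mk <- function(n_close) {
    # strand B: first n_close residues at y = 4.5 (close), rest at y = 40
    caA <- strand(1, 10, 0)
    caB <- cbind(seq_len(10) * 3.8, c(rep(4.5, n_close), rep(40, 10 - n_close)), 0)
    s <- tiny_structure(1:20, rep("A", 20), rep(90, 20), rbind(caA, caB))
    merge_entries(list(1:10, 11:20), s)
  }
  expect_length(mk(8), 1L)   # 8 qualifying pairs -> merged
  expect_length(mk(4), 2L)   # 4 pairs -> separate entries
  # transitivity: A-B close, B-C close, A-C far -> one entry
  caA <- strand(1, 10, 0)
  caB <- strand(1, 10, 4.5)
  caC <- strand(1, 10, 9.0)
  s <- tiny_structure(1:30, rep("A", 30), rep(90, 30), rbind(caA, caB, caC))
  ents <- merge_entries(list(1:10, 11:20, 21:30), s)
  expect_length(ents, 1L)
  expect_equal(ents[[1]]$positions, 1:30)
  # sanity: A and C alone do not merge
  sAC <- tiny_structure(1:20, rep("A", 20), rep(90, 20), rbind(caA, caC))
  expect_length(merge_entries(list(1:10, 11:20), sAC), 2L)
})

test_that("the size gate drops sub-40-residue entries and flags their sites", {
  mk_entry <- function(n, offset = 0L) {
    ca <- cbind(seq_len(n) * 3.8, 0, 0)
    s <- tiny_structure(offset + seq_len(n), rep("A", n), rep(90, n), ca)
    structure(list(parent_accession = "X", structure = s,
                   positions = offset + seq_len(n)), class = "cp_entry")
  }
  sites <- make_sites_df("X", c(10L, 60L), "S", status = "cryptic")
  out <- size_gate(list(mk_entry(39L), mk_entry(40L, offset = 50L)), sites)
  expect_length(out$entries, 1L)
  expect_equal(length(out$entries[[1]]$positions), 40L)
  expect_equal(out$sites$status, c("excluded:small_domain", "cryptic"))
})

test_that("entry RSA recomputation exposes loop-buried sites only", {
  fx <- glob_fixture()
  truth <- fx$truth$planted_sites
  segs <- prune_low_confidence(fx$structure)
  ents <- merge_entries(segs, fx$structure)
  expect_length(ents, 1L)
  entry <- ents[[1]]
  core <- truth$position[truth$label == "core_cryptic"]
  occ <- truth$position[truth$label == "low_confidence_occluded"]
  sites <- make_sites_df(fx$truth$accession, c(core, occ), "S",
                         status = "cryptic")
  out <- suppressMessages(refilter_rsa(entry, sites))
  expect_true(all(out$status[out$position %in% core] == "cryptic"))
  expect_equal(out$status[out$position == occ], "excluded:exposed_after_pruning")
  # no-op pruning: an entry equal to the full chain leaves RSA unchanged
  full <- structure(list(parent_accession = "X",
                         structure = fx$structure,
                         positions = fx$structure$residues$position),
                    class = "cp_entry")
  rsa_full <- residue_rsa(fx$structure)
  sites2 <- make_sites_df(fx$truth$accession, core, "S", status = "cryptic")
  out2 <- refilter_rsa(full, sites2)
  expect_equal(out2$rsa_entry,
               rsa_full$rsa[match(core, rsa_full$position)], tolerance = 1e-9)
  expect_error(refilter_rsa(entry,
                            make_sites_df("X", max(entry$positions) + 500L, "S",
                                          status = "cryptic")),
               "state error")
})

test_that("the elastic network has a clean rigid-body null space", {
  fx <- hinge_fixture()
  m <- enm_modes(fx$structure)
  expect_equal(sum(m$all_values < 1e-8 * m$all_values[7]), 6L)
  expect_true(all(m$all_values > -1e-9 * max(m$all_values)))
  expect_length(m$values, 10L)
  expect_true(all(diff(m$values) >= -1e-12))
})

test_that("the lowest hinge mode is dominated by counter-moving rigid bodies", {
  fx <- hinge_fixture()
  m <- enm_modes(fx$structure)
  truth <- fx$truth$domain_labels
  groups <- list(which(truth == 1L), which(truth == 2L))
  xyz <- m$ca_xyz
  basis <- NULL
  for (g in groups) {
    ctr <- colMeans(xyz[g, ])
    for (c in 1:3) {
      b <- matrix(0, nrow(xyz), 3); b[g, c] <- 1
      basis <- cbind(basis, as.vector(t(b)))
    }
    rel <- sweep(xyz[g, ], 2, ctr)
    for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      b <- matrix(0, nrow(xyz), 3)
      b[g, ] <- cbind(ax[2] * rel[, 3] - ax[3] * rel[, 2],
                      ax[3] * rel[, 1] - ax[1] * rel[, 3],
                      ax[1] * rel[, 2] - ax[2] * rel[, 1])
      basis <- cbind(basis, as.vector(t(b)))
    }
  }
  mask <- rep(seq_len(nrow(xyz)) %in% unlist(groups), each = 3)
  v <- m$vectors[mask, 1]
  fit <- stats::lm.fit(basis[mask, ], v)
  explained <- 1 - sum(fit$residuals^2) / sum(v^2)
  expect_gt(explained, 0.7)
  # the per-body rigid motions differ (bodies move against each other)
  coefs <- fit$coefficients
  expect_gt(sum((coefs[1:6] - coefs[7:12])^2), 1e-6)
})

test_that("distance fluctuations are invariant under rigid-body transforms", {
  fx <- make_hinge_fixture(seed = 2)
  m1 <- enm_modes(fx$structure)
  s2 <- fx$structure
  th <- 1.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(s2$atoms[, c("x", "y", "z")]) %*% Rz
  s2$atoms$x <- xyz[, 1] + 3; s2$atoms$y <- xyz[, 2] - 8; s2$atoms$z <- xyz[, 3]
  m2 <- enm_modes(s2)
  sig1 <- cryptosite:::distance_fluctuations(m1)
  sig2 <- cryptosite:::distance_fluctuations(m2)
  expect_lt(max(abs(sig1 - sig2)) / max(sig1), 1e-6)
})

test_that("a disconnected network errors naming its components", {
  ca <- rbind(cbind(1:10 * 3.8, 0, 0), cbind(1:10 * 3.8, 100, 0))
  s <- tiny_structure(1:20, rep("A", 20), rep(90, 20), ca)
  expect_error(enm_modes(s), "components")
})

test_that("quasi-rigid decomposition recovers the planted hinge bodies", {
  fx <- hinge_fixture()
  m <- enm_modes(fx$structure)
  dec <- quasi_rigid_decompose(fx$structure, m)
  truth <- fx$truth$domain_labels
  bodies <- names(truth)[!is.na(truth)]
  tab <- table(dec$labels[bodies], truth[bodies])
  # perfect agreement up to label permutation, linker excluded (the
  # linker may form its own small domain, so chosen_k can exceed 2)
  expect_equal(sum(apply(tab, 2, max)), length(bodies))
  # the two bodies never share a cluster
  expect_false(any(rowSums(tab > 0) > 1))
  # quality is invariant under domain-id permutation by construction:
  # recompute the silhouette with permuted labels
  lab <- dec$labels[bodies]
  perm <- max(lab) + 1L - lab  # reverse the domain ids
  D <- as.matrix(stats::dist(m$ca_xyz[match(as.integer(bodies),
                                            m$positions), ]))
  s1 <- mean(cluster::silhouette(lab, dmatrix = D)[, "sil_width"])
  s2 <- mean(cluster::silhouette(perm, dmatrix = D)[, "sil_width"])
  expect_equal(s1, s2, tolerance = 1e-12)
  # determinism: same inputs and seed give identical labels
  dec2 <- quasi_rigid_decompose(fx$structure, m)
  expect_identical(dec$labels, dec2$labels)
  expect_error(quasi_rigid_decompose(fx$structure, m, k_max = 1000), "k_max")
})

test_that("a single compact body still yields labels, with weak quality", {
  fx <- make_globule_fixture(n_res = 125, n_core_sites = 1,
                             n_surface_sites = 1, seed = 4)
  m <- enm_modes(fx$structure)
  dec <- quasi_rigid_decompose(fx$structure, m)
  expect_length(dec$labels, 125L)
  hinge_q <- max(quasi_rigid_decompose(hinge_fixture()$structure)$quality)
  expect_lt(dec$quality[["2"]], hinge_q)
})

test_that("Pidc counts side-chain neighbourhood domain membership", {
  fx <- hinge_fixture()
  dec <- quasi_rigid_decompose(fx$structure)
  truth <- fx$truth$planted_sites
  core <- truth$position[truth$label == "core_cryptic"]
  bdry <- truth$position[truth$label == "boundary"]
  rc <- compute_pidc(core, fx$structure, dec)
  expect_equal(rc$pidc, 1.0)
  expect_equal(rc$n_same_domain / rc$n_neighbors, rc$pidc)
  rb <- compute_pidc(bdry, fx$structure, dec)
  expect_lt(rb$pidc, 0.8)
  expect_gt(rb$n_neighbors, 0)
})

test_that("the Pidc filter retains 0.80 and excludes 0.79", {
  # two far-apart mini-clusters around two sites; force labels by hand
  # so the boundary arithmetic is exact: 10 neighbours, 8 same-domain
  ca <- rbind(c(0, 0, 0),
              t(sapply(1:10, function(i) {
                th <- 2 * pi * i / 10
                c(3.0 * cos(th), 3.0 * sin(th), 0)
              })))
  cb <- ca; cb[, 3] <- cb[, 3] + 1.5
  s <- tiny_structure(1:11, rep("S", 11), rep(90, 11), ca, cb)
  entry <- structure(list(parent_accession = "X", structure = s,
                          positions = 1:11), class = "cp_entry")
  mk_dec <- function(n_same) {
    lab <- c(1L, rep(1L, n_same), rep(2L, 10L - n_same))
    structure(list(labels = stats::setNames(lab, 1:11), quality = c(`2` = 0.5),
                   chosen_k = 2L), class = "cp_decomposition")
  }
  sites <- make_sites_df("X", 1L, "S", status = "cryptic")
  kept <- apply_dynamic_filter(sites, entry, mk_dec(8L))
  expect_equal(kept$status, "cryptic")
  expect_equal(kept$pidc, 0.8)
  # 7.9/10 is impossible; use 79/100 via a finer ring
  ca2 <- rbind(c(0, 0, 0),
               t(sapply(1:100, function(i) {
                 th <- 2 * pi * i / 100
                 c(3.0 * cos(th), 3.0 * sin(th), 0.02 * i %% 2)
               })))
  cb2 <- ca2; cb2[, 3] <- cb2[, 3] + 1.5
  s2 <- tiny_structure(1:101, rep("S", 101), rep(90, 101), ca2, cb2)
  entry2 <- structure(list(parent_accession = "X", structure = s2,
                           positions = 1:101), class = "cp_entry")
  lab2 <- c(1L, rep(1L, 79L), rep(2L, 21L))
  dec2 <- structure(list(labels = stats::setNames(lab2, 1:101),
                         quality = c(`2` = 0.5), chosen_k = 2L),
                    class = "cp_decomposition")
  sites2 <- make_sites_df("X", 1L, "S", status = "cryptic")
  out2 <- apply_dynamic_filter(sites2, entry2, dec2)
  expect_equal(out2$pidc, 0.79)
  expect_equal(out2$status, "excluded:boundary")
})

test_that("planted core and boundary sites split correctly end to end", {
  fx <- hinge_fixture()
  dec <- quasi_rigid_decompose(fx$structure)
  entry <- structure(list(parent_accession = fx$truth$accession,
                          structure = fx$structure,
                          positions = fx$structure$residues$position),
                     class = "cp_entry")
  truth <- fx$truth$planted_sites
  sites <- make_sites_df(fx$truth$accession, truth$position, "S",
                         status = "cryptic")
  out <- apply_dynamic_filter(sites, entry, dec)
  expect_equal(out$status[truth$label == "core_cryptic"], "cryptic")
  expect_equal(out$status[truth$label == "boundary"], "excluded:boundary")
})
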