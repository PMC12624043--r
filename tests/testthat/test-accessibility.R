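sphere_structure <- function(coords, element = "C") {
  n <- nrow(coords)
  atoms <- data.frame(resno = seq_len(n), aa = "G",
                      name = "CA", element = element,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  cp_structure(atoms, stats::setNames(rep(90, n), seq_len(n)))
}

# analytic SASA of two equal spheres of expanded radius R at centre
# distance d < 2R: each loses a cap of height R - d/2
two_sphere_cap_area <- function(R, d) 4 * pi * R^2 - 2 * pi * R * (R - d / 2)

test_that("the sphere-point lattice is unit-norm, centred and even", {
  p1 <- sphere_points(1)
  expect_equal(sqrt(sum(p1^2)), 1)
  p <- sphere_points(960)
  expect_equal(max(abs(sqrt(rowSums(p^2)) - 1)), 0, tolerance = 1e-12)
  expect_lt(sqrt(sum(colMeans(p)^2)), 0.01)
  # nearest-neighbour angular spacing is near-uniform (brute force)
  cosd <- tcrossprod(p)
  diag(cosd) <- -1
  ang <- acos(pmin(1, apply(cosd, 1, max)))
  expect_lt(stats::sd(ang) / mean(ang), 0.3)
  expect_error(sphere_points(0), "positive")
})

test_that("an isolated carbon atom has the closed-form sphere area", {
  s <- sphere_structure(matrix(c(0, 0, 0), 1))
  expect_equal(shrake_rupley_sasa(s), 4 * pi * 3.1^2, tolerance = 1e-9)
  far <- sphere_structure(rbind(c(0, 0, 0), c(6.3, 0, 0)))
  expect_equal(shrake_rupley_sasa(far), rep(4 * pi * 3.1^2, 2),
               tolerance = 1e-9)
})

test_that("two-sphere SASA matches the spherical-cap closed form within 2%", {
  R <- 1.70 + 1.40
  for (d in c(0.5 * R, R, 1.5 * R)) {
    s <- sphere_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
    got <- shrake_rupley_sasa(s)
    want <- two_sphere_cap_area(R, d)
    expect_equal(got[1], want, tolerance = 0.02)
    expect_equal(got[2], want, tolerance = 0.02)
  }
})

test_that("SASA converges with lattice refinement", {
  # residue-level areas (what the pipeline consumes) converge within 2%;
  # single-atom slivers carry larger quadrature error by nature
  fx <- make_globule_fixture(n_res = 64, n_core_sites = 1,
                             n_surface_sites = 1, seed = 2)
  sub <- structure_subset(fx$structure, 1:20)
  r1 <- residue_rsa(sub, sasa_params(n_sphere_points = 960))
  r2 <- residue_rsa(sub, sasa_params(n_sphere_points = 3840))
  big <- r2$sasa > 1
  expect_true(any(big))
  expect_lt(max(abs(r1$sasa[big] - r2$sasa[big]) / r2$sasa[big]), 0.02)
})

test_that("SASA is invariant under rigid-body motion and monotone under occlusion", {
  fx <- make_globule_fixture(n_res = 64, n_core_sites = 1,
                             n_surface_sites = 1, seed = 2)
  sub <- structure_subset(fx$structure, 1:15)
  base <- shrake_rupley_sasa(sub)
  # translation leaves the areas exactly unchanged
  shifted <- sub
  shifted$atoms$x <- shifted$atoms$x + 11.3
  shifted$atoms$y <- shifted$atoms$y - 4.2
  shifted$atoms$z <- shifted$atoms$z + 0.9
  expect_equal(shrake_rupley_sasa(shifted), base, tolerance = 1e-12)
  # rotation with the point lattice carried along is exact too
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- sub
  xyz <- as.matrix(sub$atoms[, c("x", "y", "z")]) %*% t(Rz)
  moved$atoms$x <- xyz[, 1] + 2
  moved$atoms$y <- xyz[, 2]
  moved$atoms$z <- xyz[, 3] - 1
  expect_equal(shrake_rupley_sasa(moved, sasa_params(lattice_rotation = Rz)),
               base, tolerance = 1e-9)
  # with the fixed global lattice, rotation changes areas only at the
  # quadrature level
  expect_equal(shrake_rupley_sasa(moved), base, tolerance = 0.05)
  # adding an occluding atom never increases any other atom's SASA
  aug <- sub
  aug$atoms <- rbind(aug$atoms,
                     data.frame(resno = max(sub$residues$position), aa = "L",
                                name = "CG", element = "C",
                                x = mean(sub$atoms$x), y = mean(sub$atoms$y),
                                z = mean(sub$atoms$z), stringsAsFactors = FALSE))
  after <- shrake_rupley_sasa(aug)
  expect_true(all(after[seq_along(base)] <= base + 1e-9))
})

test_that("missing element radii raise a configuration error naming the element", {
  s <- sphere_structure(matrix(0, 1, 3), element = "SE")
  expect_error(shrake_rupley_sasa(s), "SE")
})

test_that("residue RSA divides by the GXG maximum and is left unclamped", {
  # an isolated glycine fragment has no GXG neighbours to occlude it,
  # so its area exceeds the tripeptide maximum: RSA > 1
  g <- sphere_structure(matrix(0, 1, 3))
  suppressMessages(r <- residue_rsa(g))
  expect_gt(r$rsa, 1)
  # planted truths on the globule
  fx <- glob_fixture()
  rsa <- residue_rsa(fx$structure)
  truth <- fx$truth$planted_sites
  core <- truth$position[truth$label == "core_cryptic"]
  surf <- truth$position[truth$label == "surface"]
  expect_true(all(rsa$rsa[rsa$position %in% core] <= 0.10))
  expect_true(all(rsa$rsa[rsa$position %in% surf] > 0.15))
})

test_that("site mapping attaches RSA/pLDDT and excludes mismatches per record", {
  fx <- glob_fixture()
  truth <- fx$truth$planted_sites
  sites <- make_sites_df(fx$truth$accession,
                         c(truth$position, 99999L),
                         c(rep("S", nrow(truth)), "S"))
  # residue-letter mismatch: claim a threonine where a serine sits
  sites$aa[1] <- "T"
  suppressMessages(mapped <- map_ptm_sites(sites, fx$structure))
  expect_equal(mapped$status[1], "excluded:mismatch")
  expect_equal(mapped$status[nrow(mapped)], "excluded:out_of_range")
  ok <- mapped$status == "mapped"
  expect_true(all(!is.na(mapped$rsa[ok])))
  expect_true(all(!is.na(mapped$plddt[ok])))
})

test_that("classification respects inclusive boundaries and partitions sites", {
  mk <- function(rsa, plddt) {
    s <- make_sites_df("X", 1L, "S")
    s$rsa <- rsa; s$plddt <- plddt; s$sasa <- 1; s$status <- "mapped"
    s
  }
  th <- cp_thresholds()
  expect_equal(classify_sites(mk(0.10, 90), th)$status, "cryptic")
  expect_equal(classify_sites(mk(0.10, 64.9), th)$status,
               "excluded:low_confidence")
  expect_equal(classify_sites(mk(0.150, 90), th)$status, "cryptic")
  expect_equal(classify_sites(mk(0.1500001, 90), th)$status, "confident")
  expect_equal(classify_sites(mk(0.10, 65), th)$status, "cryptic")
  # partition: every mapped site ends in exactly one terminal state
  set.seed(42)
  s <- make_sites_df("X", 1:50, "S")
  s$rsa <- runif(50); s$plddt <- runif(50, 40, 100); s$sasa <- 1
  s$status <- "mapped"
  out <- classify_sites(s, th)
  expect_true(all(out$status %in%
                    c("cryptic", "confident", "excluded:low_confidence")))
})

test_that("RSA histograms conserve counts and report the buried fraction", {
  s <- make_sites_df("X", 1:10, "S")
  s$rsa <- c(0.05, 0.1, 0.12, 0.14, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  d <- rsa_distribution(s)
  expect_equal(sum(d$histogram$count), 10L)
  expect_equal(d$cryptic_fraction$fraction, 0.4)
  # all mass in one bin when all values coincide
  s2 <- make_sites_df("X", 1:5, "S")
  s2$rsa <- rep(0.5, 5)
  d2 <- rsa_distribution(s2)
  occupied <- d2$histogram[d2$histogram$count > 0, ]
  expect_equal(nrow(occupied), 1L)
  expect_equal(occupied$bin_lo, 0.5)
  # per-class conservation
  s3 <- make_sites_df("X", 1:9, "S",
                      ptm_class = rep(c("phospho", "acetyl", "methyl"), 3))
  s3$rsa <- seq(0.05, 0.85, 0.1)
  d3 <- rsa_distribution(s3)
  counts <- tapply(d3$histogram$count, d3$histogram$ptm_class, sum)
  expect_true(all(counts == 3L))
  # empty input
  expect_equal(nrow(rsa_distribution(make_sites_df("X", integer(0), "S"))$histogram), 0L)
})
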