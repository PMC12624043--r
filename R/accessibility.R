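# Heavy-atom van der Waals radii (Angstrom). AlphaFold models carry no
# hydrogens, so plain heavy-atom radii with a 1.4 A water probe.
DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# Maximum per-residue SASA in an extended Gly-X-Gly tripeptide
# (Tien et al. theoretical values, A^2); denominator of the RSA.
MAX_ASA_GXG <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

#' Shrake-Rupley parameters
#'
#' @param probe_radius solvent probe radius in Angstrom (default 1.4,
#'   a water molecule).
#' @param n_sphere_points number of test points per atom (default 960).
#' @param radii_table named vector of van der Waals radii per element.
#' @param lattice_rotation 3 x 3 rotation applied to the test-point
#'   lattice (default identity). The lattice is attached in a fixed
#'   global orientation, so output is deterministic; rotating the
#'   lattice together with the molecule reproduces the original areas
#'   exactly.
#' @return list of class `sasa_params`
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960L,
                        radii_table = DEFAULT_VDW,
                        lattice_rotation = diag(3)) {
  stopifnot(probe_radius > 0, n_sphere_points >= 60L,
            all(c("C", "N", "O", "S") %in% names(radii_table)),
            all(dim(lattice_rotation) == c(3L, 3L)))
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii_table = radii_table,
                 lattice_rotation = lattice_rotation),
            class = "sasa_params")
}

#' Classification thresholds
#'
#' @param rsa_cryptic RSA at or below which a buried site counts as
#'   cryptic (default 0.15, inclusive).
#' @param plddt_min minimum model confidence; residues below it are
#'   excluded as low-confidence (default 65, inclusive keep).
#' @return list of class `cp_thresholds`
#' @export
cp_thresholds <- function(rsa_cryptic = 0.15, plddt_min = 65) {
  stopifnot(rsa_cryptic > 0, rsa_cryptic < 1, plddt_min >= 0, plddt_min <= 100)
  structure(list(rsa_cryptic = rsa_cryptic, plddt_min = plddt_min),
            class = "cp_thresholds")
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci) lattice; seedless and identical across
#' calls, so SASA output is deterministic and rigid-body invariant when
#' the same lattice orientation is attached to every atom.
#'
#' @param n number of points (>= 1)
#' @return n x 3 matrix of unit vectors
#' @export
sphere_points <- function(n) {
  if (length(n) != 1L || n < 1) stop("n must be a positive integer")
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

atom_radii <- function(elements, radii_table) {
  r <- radii_table[elements]
  if (anyNA(r)) {
    missing <- unique(elements[is.na(r)])
    stop("no van der Waals radius configured for element(s): ",
         paste(missing, collapse = ", "))
  }
  unname(r)
}

# Core lattice-occlusion routine on bare spheres; used for protein atoms
# and for the folding toy's beads alike.
sasa_spheres <- function(xyz, radii, probe_radius, n_points,
                         lattice_rotation = diag(3)) {
  m <- nrow(xyz)
  pts <- sphere_points(n_points) %*% t(lattice_rotation)
  R <- radii + probe_radius
  out <- numeric(m)
  # neighbour candidates: centre distance below sum of expanded radii
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(m)) {
    thr <- (R[i] + R)^2
    nb <- which(d2[i, ] < thr & seq_len(m) != i)
    P <- pts * R[i]
    P <- sweep(P, 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      # strictly inside the neighbour's expanded sphere occludes;
      # a point exactly on the surface stays exposed
      dj2 <- (P[, 1L] - xyz[j, 1L])^2 + (P[, 2L] - xyz[j, 2L])^2 +
        (P[, 3L] - xyz[j, 3L])^2
      exposed <- exposed & (dj2 >= R[j]^2)
      if (!any(exposed)) break
    }
    out[i] <- sum(exposed) / n_points * 4 * pi * R[i]^2
  }
  out
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom is expanded by the probe radius and covered with a
#' deterministic test-point lattice; a test point is occluded iff it
#' falls strictly inside another atom's expanded sphere. SASA is the
#' exposed fraction times the expanded sphere's area.
#'
#' @param s `cp_structure`
#' @param params `sasa_params`
#' @return numeric vector, one SASA (A^2) per row of `s$atoms`
#' @export
shrake_rupley_sasa <- function(s, params = sasa_params()) {
  stopifnot(inherits(s, "cp_structure"))
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  radii <- atom_radii(s$atoms$element, params$radii_table)
  sasa_spheres(xyz, radii, params$probe_radius, params$n_sphere_points,
               params$lattice_rotation)
}

#' Per-residue SASA and relative solvent accessibility
#'
#' Residue SASA is the sum over its heavy atoms; RSA divides by the
#' residue's maximum SASA in an extended Gly-X-Gly tripeptide. RSA is
#' not clamped: isolated or terminal residues can slightly exceed 1.
#'
#' @param s `cp_structure`
#' @param params `sasa_params`
#' @param max_asa named per-residue maximum-SASA table
#' @return data frame `position`, `aa`, `sasa`, `rsa`, `plddt`; rows
#'   with unknown residue type (X) carry `NA` RSA.
#' @export
residue_rsa <- function(s, params = sasa_params(), max_asa = MAX_ASA_GXG) {
  atom_sasa <- shrake_rupley_sasa(s, params)
  sasa <- vapply(s$residues$position,
                 function(p) sum(atom_sasa[s$atoms$resno == p]), numeric(1))
  rsa <- sasa / unname(max_asa[s$residues$aa])
  n_over <- sum(rsa > 1, na.rm = TRUE)
  if (n_over > 0)
    message(n_over, " residue(s) with RSA > 1 (unclamped)")
  data.frame(position = s$residues$position, aa = s$residues$aa,
             sasa = sasa, rsa = rsa, plddt = s$residues$plddt,
             stringsAsFactors = FALSE)
}

#' Map PTM sites onto a structure
#'
#' Each site acquires the structure's pLDDT, SASA and RSA at its
#' position. Sites whose residue letter disagrees with the structure are
#' excluded as `excluded:mismatch`; positions outside the chain as
#' `excluded:out_of_range`. Failures are per-record, never fatal.
#'
#' @param sites `cp_sites` table (status raw), one accession
#' @param s `cp_structure` for that accession
#' @param rsa optional precomputed [residue_rsa()] table
#' @param params `sasa_params` used when `rsa` is NULL
#' @return updated `cp_sites` (status mapped / excluded:*)
#' @export
map_ptm_sites <- function(sites, s, rsa = NULL, params = sasa_params()) {
  stopifnot(inherits(s, "cp_structure"))
  if (nrow(sites) == 0L) return(sites)
  if (is.null(rsa)) rsa <- residue_rsa(s, params)
  idx <- match(sites$position, rsa$position)
  out_of_range <- is.na(idx)
  mismatch <- !out_of_range & sites$aa != rsa$aa[idx]
  ok <- !out_of_range & !mismatch
  sites$plddt[ok] <- rsa$plddt[idx[ok]]
  sites$sasa[ok] <- rsa$sasa[idx[ok]]
  sites$rsa[ok] <- rsa$rsa[idx[ok]]
  sites <- set_status(sites, which(out_of_range), "excluded:out_of_range")
  sites <- set_status(sites, which(mismatch), "excluded:mismatch")
  sites <- set_status(sites, which(ok), "mapped")
  n_exc <- sum(out_of_range | mismatch)
  if (n_exc > 0) message(n_exc, " site(s) excluded during mapping")
  sites
}

#' Classify mapped sites as cryptic, confident or excluded
#'
#' Low-confidence residues (pLDDT below `plddt_min`) are excluded;
#' remaining sites with RSA at or below `rsa_cryptic` are cryptic,
#' the rest confidently exposed (non-cryptic). Both boundaries are
#' inclusive keeps: pLDDT 65 passes, RSA 0.15 is cryptic.
#'
#' @param sites mapped `cp_sites`
#' @param th `cp_thresholds`
#' @return updated `cp_sites`
#' @export
classify_sites <- function(sites, th = cp_thresholds()) {
  mapped <- which(sites$status == "mapped")
  if (length(mapped) == 0L) return(sites)
  if (anyNA(sites$rsa[mapped]) || anyNA(sites$plddt[mapped]))
    stop("state error: mapped sites must carry rsa and plddt")
  low <- mapped[sites$plddt[mapped] < th$plddt_min]
  rest <- setdiff(mapped, low)
  cry <- rest[sites$rsa[rest] <= th$rsa_cryptic]
  conf <- setdiff(rest, cry)
  sites <- set_status(sites, low, "excluded:low_confidence")
  sites <- set_status(sites, cry, "cryptic")
  sites <- set_status(sites, conf, "confident")
  sites
}

#' Binned RSA distribution per modification class
#'
#' Histogram of RSA values per PTM class on \[0, max RSA\], plus the
#' fraction of each class at or below the cryptic cut (0.15).
#'
#' @param sites `cp_sites` with RSA values
#' @param bin_width histogram bin width (default 0.05)
#' @param rsa_cryptic cut used for the reported buried fraction
#' @return list with `histogram` (data frame `ptm_class`, `bin_lo`,
#'   `bin_hi`, `count`) and `cryptic_fraction` (per class)
#' @export
rsa_distribution <- function(sites, bin_width = 0.05, rsa_cryptic = 0.15) {
  keep <- !is.na(sites$rsa)
  if (!any(keep))
    return(list(histogram = data.frame(ptm_class = character(0),
                                       bin_lo = numeric(0), bin_hi = numeric(0),
                                       count = integer(0)),
                cryptic_fraction = data.frame(ptm_class = character(0),
                                              fraction = numeric(0))))
  sites <- sites[keep, , drop = FALSE]
  breaks <- seq(0, (floor(max(sites$rsa) / bin_width) + 1L) * bin_width,
                by = bin_width)
  hist_list <- lapply(split(sites$rsa, sites$ptm_class), function(v) {
    idx <- pmin(findInterval(v, breaks, left.open = FALSE), length(breaks) - 1L)
    counts <- tabulate(idx, nbins = length(breaks) - 1L)
    data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
               count = counts)
  })
  histogram <- do.call(rbind, Map(function(cls, df)
    cbind(data.frame(ptm_class = cls, stringsAsFactors = FALSE), df),
    names(hist_list), hist_list))
  rownames(histogram) <- NULL
  frac <- vapply(split(sites$rsa, sites$ptm_class),
                 function(v) mean(v <= rsa_cryptic), numeric(1))
  list(histogram = histogram,
       cryptic_fraction = data.frame(ptm_class = names(frac),
                                     fraction = unname(frac),
                                     stringsAsFactors = FALSE))
}
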