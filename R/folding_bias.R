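# Ratchet-and-pawl biased dynamics on a coarse-grained Go-like chain.
# The bias acts along the contact-map overlap Q with the native state:
# plain dynamics whenever Q spontaneously progresses, a small restoring
# force toward the best-so-far value Q_m whenever it backtracks. Each
# trajectory accumulates a bias-functional score T (total squared bias
# work); smaller T marks a less perturbed, more realistic pathway.

#' Ratchet-and-pawl bias parameters
#'
#' Defaults follow the all-atom convention: contact scale `r0` 7.5 A,
#' switching cutoff `rc` 12.3 A, bias strength `k` 1e-4 and index
#' separation `sep_min` 35 (an atomic-index rule). The one-bead-per-
#' residue toy uses `sep_min = 3` and a toy-scale `k`; see the package
#' vignette.
#'
#' @param k bias strength (reduced energy units; >= 0)
#' @param r0 typical contact distance (A)
#' @param rc switching cutoff (A), beyond which a contact is 0
#' @param sep_min contacts restricted to index separation > `sep_min`
#' @param mass,friction per-particle mass and friction (scalars or
#'   vectors), used by the dynamics and the T score
#' @return list of class `bias_params`
#' @export
bias_params <- function(k = 1.0e-4, r0 = 7.5, rc = 12.3, sep_min = 35L,
                        mass = 1, friction = 1) {
  stopifnot(k >= 0, r0 > 0, rc > r0, sep_min >= 1)
  structure(list(k = k, r0 = r0, rc = rc, sep_min = as.integer(sep_min),
                 mass = mass, friction = friction),
            class = "bias_params")
}

#' Smooth switching function of the contact map
#'
#' `(1 - (r/r0)^6) / (1 - (r/r0)^10)` for `r < rc`, with the removable
#' singularity at `r = r0` filled by its limit 6/10, and 0 for
#' `r >= rc`. The value lies in \[0, 1\] for `r <= rc`; the small jump
#' left at `rc` by these parameter values is part of the definition.
#'
#' @param r distances (A), vectorized
#' @param p `bias_params`
#' @return contact-map entries in \[0, 1\]
#' @export
switching_value <- function(r, p = bias_params()) {
  x <- r / p$r0
  out <- numeric(length(r))
  at_r0 <- abs(x - 1) < 1e-9
  inside <- r < p$rc & !at_r0
  out[at_r0] <- 6 / 10
  out[inside] <- (1 - x[inside]^6) / (1 - x[inside]^10)
  out[r >= p$rc] <- 0
  out
}

# derivative of the switching function wrt r (0 beyond rc)
switching_deriv <- function(r, p = bias_params()) {
  x <- r / p$r0
  out <- numeric(length(r))
  near <- abs(x - 1) < 1e-6
  inside <- r < p$rc & !near
  xi <- x[inside]
  num <- 1 - xi^6
  den <- 1 - xi^10
  out[inside] <- ((-6 * xi^5) * den - num * (-10 * xi^9)) / den^2 / p$r0
  out[near & r < p$rc] <- -1.2 / p$r0   # series limit at x = 1
  out
}

contact_pair_indices <- function(n, sep_min) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij[ij[, 2] - ij[, 1] > sep_min, , drop = FALSE]
}

pair_distances <- function(X, pairs) {
  dx <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(dx^2))
}

#' Native contact map for the progress variable
#'
#' @param X_native native configuration (n x 3)
#' @param p `bias_params`
#' @return list of class `native_map`: `pairs`, `C_nat`, `Q_nat`
#'   (= sum of squared native entries, the value of Q at the native
#'   state), `n`
#' @export
native_contact_map <- function(X_native, p = bias_params()) {
  n <- nrow(X_native)
  pairs <- contact_pair_indices(n, p$sep_min)
  C_nat <- switching_value(pair_distances(X_native, pairs), p)
  structure(list(pairs = pairs, C_nat = C_nat,
                 Q_nat = sum(C_nat^2), n = n),
            class = "native_map")
}

#' Contact-map progress variable Q
#'
#' `Q(X) = sum over pairs of [C_nat^2 - (C(X) - C_nat)^2]`, restricted
#' to index separations above `sep_min`. Q equals `Q_nat` at the native
#' state and decreases as the instantaneous map departs from it;
#' equivalently `Q = Q_nat - z` with `z` the squared map distance.
#'
#' @param X configuration (n x 3), same indexing as the native map
#' @param native_map from [native_contact_map()]
#' @param p `bias_params`
#' @return scalar Q
#' @export
progress_Q <- function(X, native_map, p = bias_params()) {
  if (nrow(X) != native_map$n) stop("configuration/native indexing mismatch")
  C <- switching_value(pair_distances(X, native_map$pairs), p)
  sum(native_map$C_nat^2 - (C - native_map$C_nat)^2)
}

# analytic gradient of Q wrt all coordinates: n x 3 matrix
grad_Q <- function(X, native_map, p = bias_params()) {
  pr <- native_map$pairs
  dx <- X[pr[, 1], , drop = FALSE] - X[pr[, 2], , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  C <- switching_value(r, p)
  dC <- switching_deriv(r, p)
  w <- -2 * (C - native_map$C_nat) * dC / pmax(r, 1e-12)
  accumulate_pairs(native_map$n, pr[, 1], pr[, 2], w * dx)
}

# scatter-add per-pair vectors f (on i) and -f (on j) into an n x 3 field
accumulate_pairs <- function(n, i, j, f) {
  out <- rowsum(rbind(f, -f), c(i, j))
  F <- matrix(0, n, 3)
  F[as.integer(rownames(out)), ] <- out
  F
}

#' Ratchet-and-pawl bias force
#'
#' Zero whenever the system is at or beyond its best progress so far
#' (`Q >= Q_m`: plain dynamics, and `Q_m` should be updated by the
#' caller); otherwise the restoring force
#' `F_i = -k * grad_i Q * (Q - Q_m)`, which pushes Q back up toward
#' `Q_m`.
#'
#' @param X configuration (n x 3)
#' @param Q current progress value (from [progress_Q()])
#' @param Q_m running maximum of Q
#' @param native_map from [native_contact_map()]
#' @param p `bias_params`
#' @return n x 3 force matrix
#' @export
bias_force <- function(X, Q, Q_m, native_map, p = bias_params()) {
  if (Q >= Q_m) return(matrix(0, nrow(X), 3))
  -p$k * (Q - Q_m) * grad_Q(X, native_map, p)
}

#' Bias-functional score T of a trajectory
#'
#' Discretized `T = sum_i 1/(m_i gamma_i) * integral |F_i^B|^2 dtau`:
#' the accumulated squared bias work, the trajectory-realism score
#' (smaller = less biased).
#'
#' @param bias_forces list of n x 3 bias-force matrices, one per step
#' @param dt time step
#' @param mass,friction per-particle values (recycled)
#' @return scalar T
#' @export
bias_score_T <- function(bias_forces, dt, mass = 1, friction = 1) {
  if (length(bias_forces) == 0L) return(0)
  n <- nrow(bias_forces[[1L]])
  mg <- rep_len(mass, n) * rep_len(friction, n)
  sum(vapply(bias_forces, function(f) sum(rowSums(f^2) / mg), numeric(1))) * dt
}

# Go-like forces of the toy chain: harmonic bonds and 1-3 bends,
# 12-10 attractions on native contacts, 12th-power repulsion elsewhere
toy_forces <- function(X, chain, eps = 1, k_bond = 50, k_bend = 5,
                       sigma_rep = 4.0) {
  n <- nrow(X)
  F <- matrix(0, n, 3)
  for (set in list(list(p = chain$bonds, k = k_bond),
                   list(p = chain$angles13, k = k_bend))) {
    i <- set$p[, "i"]; j <- set$p[, "j"]
    dx <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    r <- sqrt(rowSums(dx^2))
    fmag <- set$k * (r - set$p[, "r0"])
    F <- F + accumulate_pairs(n, i, j, -fmag / pmax(r, 1e-9) * dx)
  }
  # native-contact 12-10 attraction
  i <- chain$contacts[, "i"]; j <- chain$contacts[, "j"]
  dx <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  s <- chain$contacts[, "r0"] / r
  fmag <- (60 * eps / r) * (s^10 - s^12)   # dV/dr of eps[5 s^12 - 6 s^10]
  F <- F + accumulate_pairs(n, i, j, -fmag / pmax(r, 1e-9) * dx)
  # excluded volume on non-native, non-local pairs within range
  nn <- chain$nonnative
  if (!is.null(nn) && nrow(nn)) {
    i <- nn[, 1]; j <- nn[, 2]
    dx <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    r2 <- rowSums(dx^2)
    close <- r2 < (1.6 * sigma_rep)^2
    if (any(close)) {
      i <- i[close]; j <- j[close]
      r <- sqrt(r2[close]); dxc <- dx[close, , drop = FALSE]
      s <- sigma_rep / r
      fmag <- -12 * eps * s^12 / r
      F <- F + accumulate_pairs(n, i, j, -fmag / pmax(r, 1e-9) * dxc)
    }
  }
  F
}

toy_energy <- function(X, chain, eps = 1, k_bond = 50, k_bend = 5,
                       sigma_rep = 4.0) {
  e <- 0
  for (set in list(list(p = chain$bonds, k = k_bond),
                   list(p = chain$angles13, k = k_bend))) {
    r <- pair_distances(X, set$p[, c("i", "j"), drop = FALSE])
    e <- e + sum(0.5 * set$k * (r - set$p[, "r0"])^2)
  }
  r <- pair_distances(X, chain$contacts[, c("i", "j"), drop = FALSE])
  s <- chain$contacts[, "r0"] / r
  e <- e + sum(eps * (5 * s^12 - 6 * s^10))
  nn <- chain$nonnative
  if (!is.null(nn) && nrow(nn)) {
    r <- pair_distances(X, nn)
    e <- e + sum(eps * (sigma_rep / r)^12)
  }
  e
}

# non-native non-local pair list, attached to the chain object once
with_nonnative <- function(chain) {
  if (!is.null(chain$nonnative)) return(chain)
  n <- chain$n_beads
  ij <- contact_pair_indices(n, 2L)
  key <- paste(ij[, 1], ij[, 2])
  nat <- paste(chain$contacts[, "i"], chain$contacts[, "j"])
  chain$nonnative <- ij[!(key %in% nat), , drop = FALSE]
  chain
}

#' Run the ratchet-and-pawl toy folding simulation
#'
#' Overdamped Langevin dynamics on the Go-like bead chain plus the
#' ratchet bias along Q. With `p$k = 0` this is plain dynamics and the
#' accumulated score T is exactly 0. Seeded and fully reproducible.
#'
#' @param chain `toy_chain` from [make_toy_chain_native()]
#' @param start starting configuration (n x 3); defaults to the native
#'   state (use [make_unfolded_config()] for folding runs)
#' @param p `bias_params` (toy scale: `sep_min = 3`)
#' @param n_steps number of integration steps
#' @param temperature reduced temperature (energy units of the contact
#'   strength)
#' @param dt time step (reduced units)
#' @param seed RNG seed
#' @param save_every save a frame (and Q sample) every this many steps
#' @return list: `trajectory` (list of frames), `Q` (per saved frame),
#'   `Q_series` (per step), `Q_m` (final best progress), `T` (bias
#'   score), `X` (final frame), `native_map`
#' @export
run_toy_ratchet <- function(chain, start = NULL, p = bias_params(sep_min = 3L),
                            n_steps = 3000L, temperature = 1.0, dt = 2e-4,
                            seed = 1L, save_every = 25L) {
  chain <- with_nonnative(chain)
  X <- if (is.null(start)) chain$xyz else start
  nm <- native_contact_map(chain$xyz, p)
  n <- chain$n_beads
  mg <- rep_len(p$mass, n) * rep_len(p$friction, n)
  mob <- dt / mg
  noise_sd <- sqrt(2 * temperature * dt / mg)
  Q_series <- numeric(n_steps)
  Tacc <- 0
  frames <- list(X)
  Qsaved <- progress_Q(X, nm, p)
  Q_m <- Qsaved
  with_seed(seed, {
    for (step in seq_len(n_steps)) {
      Fphys <- toy_forces(X, chain)
      Q <- progress_Q(X, nm, p)
      if (Q >= Q_m) {
        Q_m <- Q
        Fb <- NULL
      } else {
        Fb <- -p$k * (Q - Q_m) * grad_Q(X, nm, p)
        Tacc <- Tacc + sum(rowSums(Fb^2) / mg) * dt
      }
      Ftot <- if (is.null(Fb)) Fphys else Fphys + Fb
      if (!all(is.finite(Ftot)) || max(abs(Ftot)) > 1e8)
        stop("timestep instability (force divergence); reduce dt")
      X <- X + mob * Ftot +
        matrix(stats::rnorm(3 * n), n, 3) * noise_sd
      Q_series[step] <- Q
      if (step %% save_every == 0L) {
        frames[[length(frames) + 1L]] <- X
        Qsaved <- c(Qsaved, progress_Q(X, nm, p))
      }
    }
  })
  list(trajectory = frames, Q = Qsaved, Q_series = Q_series,
       Q_m = Q_m, T = Tacc, X = X, native_map = nm)
}

#' Generate a thermally unfolded starting configuration
#'
#' Plain (unbiased) dynamics at a high temperature starting from the
#' native state, mirroring thermal-unfolding preparation of folding
#' runs.
#'
#' @param chain `toy_chain`
#' @param temperature unfolding temperature (default 5, reduced units)
#' @param n_steps unfolding steps
#' @param seed RNG seed
#' @param dt time step
#' @return n x 3 unfolded configuration
#' @export
make_unfolded_config <- function(chain, temperature = 5, n_steps = 1500L,
                                 seed = 1L, dt = 2e-4) {
  p0 <- bias_params(k = 0, sep_min = 3L)
  run_toy_ratchet(chain, start = NULL, p = p0, n_steps = n_steps,
                  temperature = temperature, dt = dt, seed = seed,
                  save_every = n_steps)$X
}

#' Solvent exposure of a designated bead along a trajectory
#'
#' Bead-level RSA per frame: Shrake-Rupley SASA of the site bead among
#' all beads (treated as uniform spheres), normalized by the area of an
#' isolated bead. Optionally bins the (Q, RSA) pairs into a 2-D
#' occupancy table.
#'
#' @param trajectory list of n x 3 frames
#' @param site_index bead index of the site
#' @param bead_radius sphere radius per bead (A; default 2.0)
#' @param probe_radius probe radius (default 1.4)
#' @param n_points lattice points per bead (default 240)
#' @param Q optional per-frame Q values for the 2-D histogram
#' @param rsa_bin,q_bins histogram geometry
#' @return list: `rsa` series (one per frame), and `histogram`
#'   (data frame `q_lo`, `q_hi`, `rsa_lo`, `rsa_hi`, `count`) when `Q`
#'   is supplied
#' @export
exposure_along_path <- function(trajectory, site_index, bead_radius = 2.0,
                                probe_radius = 1.4, n_points = 240L,
                                Q = NULL, rsa_bin = 0.05, q_bins = 10L) {
  n <- nrow(trajectory[[1L]])
  if (site_index < 1L || site_index > n) stop("site_index out of range")
  iso <- 4 * pi * (bead_radius + probe_radius)^2
  rsa <- vapply(trajectory, function(X) {
    sasa_spheres(X, rep(bead_radius, n), probe_radius, n_points)[site_index] / iso
  }, numeric(1))
  out <- list(rsa = rsa)
  if (!is.null(Q)) {
    stopifnot(length(Q) == length(rsa))
    qb <- seq(min(Q), max(Q), length.out = q_bins + 1L)
    rb <- seq(0, max(rsa) + rsa_bin, by = rsa_bin)
    qi <- pmin(findInterval(Q, qb), q_bins)
    ri <- pmin(findInterval(rsa, rb), length(rb) - 1L)
    tab <- table(factor(qi, levels = seq_len(q_bins)),
                 factor(ri, levels = seq_len(length(rb) - 1L)))
    grid <- expand.grid(q = seq_len(q_bins), r = seq_len(length(rb) - 1L))
    out$histogram <- data.frame(
      q_lo = qb[grid$q], q_hi = qb[grid$q + 1L],
      rsa_lo = rb[grid$r], rsa_hi = rb[grid$r + 1L],
      count = as.integer(tab[cbind(grid$q, grid$r)]))
  }
  out
}
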