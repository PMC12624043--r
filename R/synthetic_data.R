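# Seeded geometric generators for every input format the pipeline
# consumes, with exact planted ground truth. These are constructions,
# not physical simulations: burial, rigidity and conservation are forced
# by geometry/sampling so that truth labels are verifiable by the stage
# they target.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

round3 <- function(x) round(x, 3)

# boustrophedon walk through an nx x ny x nz lattice: consecutive cells
# are always lattice neighbours, so the chain is spatially contiguous
snake_cells <- function(nx, ny, nz) {
  cells <- matrix(0L, nrow = nx * ny * nz, ncol = 3)
  i <- 1L
  for (iz in 0:(nz - 1L)) {
    ys <- if (iz %% 2L == 0L) 0:(ny - 1L) else (ny - 1L):0
    for (iy in ys) {
      xs <- if ((iz * ny + match(iy, ys) - 1L) %% 2L == 0L) 0:(nx - 1L) else (nx - 1L):0
      for (ix in xs) {
        cells[i, ] <- c(ix, iy, iz)
        i <- i + 1L
      }
    }
  }
  cells
}

# assemble residue atoms: CA at centre plus a pseudo side chain of
# `n_side` atoms marching along `dir` at 1.5 A steps (CB, CG, ...);
# planted Ser sites end in a gamma oxygen, lysines in NZ
SIDE_NAMES <- c("CB", "CG", "CD", "CE", "CZ")
build_atoms <- function(positions, aa, centres, cb_dirs, n_side) {
  rows <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    ca <- centres[i, ]
    at <- data.frame(resno = positions[i], aa = aa[i], name = "CA",
                     element = "C", x = ca[1], y = ca[2], z = ca[3],
                     stringsAsFactors = FALSE)
    ns <- n_side[i]
    if (aa[i] == "G") ns <- 0L
    if (ns > 0L) {
      nms <- SIDE_NAMES[seq_len(ns)]
      els <- rep("C", ns)
      if (aa[i] == "S") { nms[ns] <- "OG"; els[ns] <- "O" }
      if (aa[i] == "K") { nms[ns] <- "NZ"; els[ns] <- "N" }
      for (k in seq_len(ns)) {
        pt <- ca + (1.53 + (k - 1L) * 1.5) * cb_dirs[i, ]
        at <- rbind(at, data.frame(resno = positions[i], aa = aa[i],
                                   name = nms[k], element = els[k],
                                   x = pt[1], y = pt[2], z = pt[3],
                                   stringsAsFactors = FALSE))
      }
    }
    rows[[i]] <- at
  }
  out <- do.call(rbind, rows)
  out$x <- round3(out$x); out$y <- round3(out$y); out$z <- round3(out$z)
  out
}

random_units <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a compact globule structure with planted buried and exposed sites
#'
#' Residues are laid on a snake path through an elongated 5 x 5 x nz
#' lattice box (3.8 A spacing, light jitter): a compact single body
#' whose softest elastic deformations run along the long axis, so a
#' forced two-way quasi-rigid subdivision cuts at the transverse
#' mid-plane. Core sites are serines planted deep inside each half
#' (buried, RSA well below the cryptic cut, far from that cut plane),
#' surface sites at end-face cells with side chains pointing outward
#' (exposed). With `with_loop = TRUE` an extra serine on the long side
#' face is covered by a low-confidence loop appended at the chain end:
#' buried in the full model, exposed once the loop is pruned.
#'
#' @param n_res number of lattice residues (>= 60; default 200, a
#'   5 x 5 x 8 box)
#' @param n_core_sites,n_surface_sites numbers of planted serine sites
#' @param seed RNG seed; output is a pure function of arguments + seed
#' @param with_loop plant the low-confidence occluding loop (needs
#'   `n_res >= 150`, six layers)
#' @return list with `structure` (`cp_structure`), `pdb_text`, `truth`
#'   (planted site labels, lysine decoy positions, loop positions,
#'   accession)
#' @export
make_globule_fixture <- function(n_res = 200L, n_core_sites = 2L,
                                 n_surface_sites = 2L, seed = 1L,
                                 with_loop = FALSE) {
  if (n_res < 60L) stop("n_res must be >= 60")
  with_seed(seed, {
    a <- 3.8
    nx <- 5L; ny <- 5L
    nz <- ceiling(n_res / (nx * ny))
    if (with_loop && nz < 6L)
      stop("with_loop needs n_res >= 150 (six layers separate the loop",
           " patch from the planted sites)")
    cells <- snake_cells(nx, ny, nz)[seq_len(n_res), , drop = FALSE]
    zmid <- (nz - 1) / 2
    interior <- cells[, 1] >= 1L & cells[, 1] <= nx - 2L &
      cells[, 2] >= 1L & cells[, 2] <= ny - 2L &
      cells[, 3] >= 1L & cells[, 3] <= nz - 2L
    if (sum(interior) < n_core_sites)
      stop("generation error: not enough interior cells")
    # core sites: deep interior, as far as possible from the transverse
    # mid-plane (the expected 2-way cut), centre column preferred,
    # never adjacent to one another
    int_idx <- which(interior)
    score <- abs(cells[int_idx, 3] - zmid) -
      0.1 * (abs(cells[int_idx, 1] - 2) + abs(cells[int_idx, 2] - 2))
    core_idx <- integer(0)
    for (min_sep in c(1.9, 1.3, 0.9)) {   # relax separation on tight interiors
      core_idx <- integer(0)
      for (cand in int_idx[order(-score)]) {
        if (length(core_idx) == n_core_sites) break
        if (length(core_idx) == 0L ||
            all(sqrt(rowSums((cells[core_idx, , drop = FALSE] -
                              matrix(cells[cand, ], length(core_idx), 3,
                                     byrow = TRUE))^2)) > min_sep))
          core_idx <- c(core_idx, cand)
      }
      if (length(core_idx) == n_core_sites) break
    }
    if (length(core_idx) < n_core_sites)
      stop("generation error: could not place core sites")
    # surface serines on the z = 0 end face; lysine decoys and the
    # optional loop site on the y = 0 side face, well separated
    cell_at <- function(ix, iy, iz) which(cells[, 1] == ix & cells[, 2] == iy &
                                            cells[, 3] == iz)
    end_spots <- c(cell_at(1L, 1L, 0L), cell_at(3L, 3L, 0L),
                   cell_at(1L, 3L, 0L), cell_at(3L, 1L, 0L))
    if (length(end_spots) < n_surface_sites)
      stop("generation error: not enough end-face cells")
    surf_idx <- end_spots[seq_len(n_surface_sites)]
    side_z <- unique(pmin(pmax(c(1L, nz - 2L, 2L, nz - 3L), 1L), nz - 2L))
    lys_cand <- unlist(lapply(side_z, function(z) c(cell_at(1L, 0L, z),
                                                    cell_at(3L, 0L, z))))
    lys_cand <- setdiff(lys_cand, c(surf_idx, core_idx))
    lys_idx <- lys_cand[seq_len(min(4L, length(lys_cand)))]

    xyz <- cells * a + matrix(stats::runif(3 * n_res, -0.15, 0.15), ncol = 3)
    aa <- rep("L", n_res)
    aa[core_idx] <- "S"; aa[surf_idx] <- "S"; aa[lys_idx] <- "K"
    n_side <- rep(1L, n_res)
    n_side[c(core_idx, surf_idx)] <- 2L   # CB + OG
    n_side[lys_idx] <- 5L                 # full lysine arm, tip well exposed
    dirs <- random_units(n_res)
    ctr <- colMeans(xyz)
    rel <- sweep(xyz, 2L, ctr)
    to_centre <- -rel / (sqrt(rowSums(rel^2)) + 1e-9)
    dirs[core_idx, ] <- to_centre[core_idx, , drop = FALSE]
    dirs[surf_idx, ] <- matrix(c(0, 0, -1), length(surf_idx), 3, byrow = TRUE)
    dirs[lys_idx, ] <- matrix(c(0, -1, 0), length(lys_idx), 3, byrow = TRUE)
    # surface serines sit slightly proud of the face so the whole residue
    # is unambiguously exposed
    xyz[surf_idx, 3] <- xyz[surf_idx, 3] - 1.2

    positions <- seq_len(n_res)
    plddt <- rep(90, n_res)
    truth_sites <- data.frame(
      position = c(positions[core_idx], positions[surf_idx]),
      label = c(rep("core_cryptic", n_core_sites),
                rep("surface", n_surface_sites)),
      stringsAsFactors = FALSE)
    loop_positions <- integer(0)

    if (with_loop) {
      # one more serine on the side face, then a 3x3 low-confidence patch
      # hovering below its side chain (one patch spacing off the face)
      occ <- cell_at(2L, 0L, as.integer(round(zmid)))
      aa[occ] <- "S"; n_side[occ] <- 2L; dirs[occ, ] <- c(0, -1, 0)
      truth_sites <- rbind(truth_sites,
                           data.frame(position = positions[occ],
                                      label = "low_confidence_occluded",
                                      stringsAsFactors = FALSE))
      base <- xyz[occ, ] + c(0, -1, 0) * (1.53 + 1.40)   # OG position
      patch <- expand.grid(x = -1:1, z = -1:1)
      n_loop <- nrow(patch)
      loop_xyz <- cbind(base[1] + patch$x * 3.4, base[2] - 3.3,
                        base[3] + patch$z * 3.4)
      loop_positions <- n_res + seq_len(n_loop)
      xyz <- rbind(xyz, loop_xyz)
      aa <- c(aa, rep("G", n_loop))
      n_side <- c(n_side, rep(0L, n_loop))
      dirs <- rbind(dirs, random_units(n_loop))
      positions <- c(positions, loop_positions)
      plddt <- c(plddt, rep(50, n_loop))
    }

    atoms <- build_atoms(positions, aa, xyz, dirs, n_side)
    s <- cp_structure(atoms, stats::setNames(round(plddt, 2), positions),
                      source_name = sprintf("GLOB%04d", seed))
    list(structure = s, pdb_text = write_pdb_structure(s),
         truth = list(planted_sites = truth_sites,
                      lysine_positions = positions[lys_idx],
                      loop_positions = loop_positions,
                      accession = s$source_name))
  })
}

#' Generate a two-body hinge structure with known rigid-domain labels
#'
#' Two compact lattice bodies face each other across a narrow gap and
#' are joined by an extended linker arcing around the outside. One
#' serine is planted deep inside body 1 (buried, all contacts
#' intra-domain) and one on body 1's face inside the gap (buried
#' between the bodies but with many contacts across the domain
#' boundary, so its proportion of intra-domain contacts is low).
#'
#' @param n_per_body residues per body (>= 40; default 48, a 4x4x3 block)
#' @param linker_len residues in the connecting linker (default 6)
#' @param seed RNG seed
#' @param gap distance between the facing body surfaces (A)
#' @return list with `structure`, `pdb_text`, `truth` (`domain_labels`
#'   per position, NA on the linker; `planted_sites` with labels
#'   `core_cryptic` and `boundary`; accession)
#' @export
make_hinge_fixture <- function(n_per_body = 48L, linker_len = 6L, seed = 1L,
                               gap = 6.2) {
  if (n_per_body < 40L) stop("n_per_body must be >= 40")
  with_seed(seed, {
    a <- 3.8
    nz <- ceiling(n_per_body / 16)
    cellsA <- snake_cells(4L, 4L, nz)[seq_len(n_per_body), , drop = FALSE]
    xyzA <- cellsA * a
    w <- (nz - 1) * a   # z of body A's gap-facing layer (where its snake ends)
    # body B: z-mirrored across the gap, bead order reversed so its first
    # bead sits directly opposite body A's last bead
    xyzB <- xyzA[n_per_body:1, , drop = FALSE]
    xyzB[, 3] <- 2 * w + gap - xyzB[, 3]
    jitter <- function(n) matrix(stats::runif(3 * n, -0.1, 0.1), ncol = 3)
    xyzA <- xyzA + jitter(n_per_body)
    xyzB <- xyzB + jitter(n_per_body)

    # linker: arc from body A's last bead to body B's first bead, bulging
    # out in +y so it clears the gap and touches the bodies only at its ends
    p0 <- xyzA[n_per_body, ]
    p1 <- xyzB[1L, ]
    tseq <- seq_len(linker_len) / (linker_len + 1)
    mid <- (p0 + p1) / 2
    bulge <- c(0, 1, 0) * (2.5 * a)
    linker_xyz <- t(vapply(tseq, function(t)
      (1 - t)^2 * p0 + 2 * t * (1 - t) * (mid + bulge) + t^2 * p1,
      numeric(3)))
    linker_xyz <- linker_xyz + jitter(linker_len) * 0.5

    n_tot <- 2L * n_per_body + linker_len
    positions <- seq_len(n_tot)
    posA <- seq_len(n_per_body)
    posL <- n_per_body + seq_len(linker_len)
    posB <- n_per_body + linker_len + seq_len(n_per_body)
    xyz <- rbind(xyzA, linker_xyz, xyzB)

    # planted sites in body A: one deep interior, one centred on the
    # face that looks into the gap (side chain reaching across it)
    interior <- posA[cellsA[, 1] %in% c(1L, 2L) & cellsA[, 2] %in% c(1L, 2L) &
                       cellsA[, 3] >= 1L & cellsA[, 3] <= nz - 2L]
    core_site <- interior[1L]
    gapface <- posA[cellsA[, 3] == nz - 1L &
                      cellsA[, 1] %in% c(1L, 2L) & cellsA[, 2] %in% c(1L, 2L)]
    boundary_site <- gapface[1L]

    aa <- rep("L", n_tot)
    aa[c(core_site, boundary_site)] <- "S"
    n_side <- rep(1L, n_tot)
    n_side[c(core_site, boundary_site)] <- 2L
    dirs <- random_units(n_tot)
    ctrA <- colMeans(xyzA)
    dirs[core_site, ] <- (ctrA - xyz[core_site, ]) /
      sqrt(sum((ctrA - xyz[core_site, ])^2))
    dirs[boundary_site, ] <- c(0, 0, 1)   # into the gap, toward body B

    atoms <- build_atoms(positions, aa, xyz, dirs, n_side)
    s <- cp_structure(atoms, stats::setNames(rep(90, n_tot), positions),
                      source_name = sprintf("HING%04d", seed))
    domain_labels <- rep(NA_integer_, n_tot)
    domain_labels[posA] <- 1L
    domain_labels[posB] <- 2L
    list(structure = s, pdb_text = write_pdb_structure(s),
         truth = list(
           planted_sites = data.frame(
             position = c(core_site, boundary_site),
             label = c("core_cryptic", "boundary"), stringsAsFactors = FALSE),
           domain_labels = stats::setNames(domain_labels, positions),
           linker_positions = posL,
           accession = s$source_name))
  })
}

PTM_CLASS_SUFFIX <- c(phospho = "p", ubiquityl = "ub", acetyl = "ac",
                      methyl = "m1", sumoyl = "sm", glycosyl = "gl")

#' Generate a PhosphoSitePlus-dialect PTM table for fixture structures
#'
#' Emits rows for every planted phospho site of each fixture, decoy rows
#' of other modification classes at the fixtures' surface lysines, and
#' exactly one malformed row to exercise the parser's skip path.
#'
#' @param fixtures list of fixture objects (from the structure generators)
#' @param extra_classes PTM classes used for the lysine decoys
#' @param seed RNG seed
#' @return single string: TSV text with a 3-line preamble
#' @export
make_ptm_fixture <- function(fixtures, extra_classes = c("ubiquityl", "acetyl"),
                             seed = 1L) {
  with_seed(seed, {
    rows <- character(0)
    for (fx in fixtures) {
      acc <- fx$truth$accession
      st <- fx$structure
      for (i in seq_len(nrow(fx$truth$planted_sites))) {
        p <- fx$truth$planted_sites$position[i]
        aa <- st$residues$aa[st$residues$position == p]
        rows <- c(rows, sprintf("%s\t%s\t%s%d-p", acc, acc, aa, p))
      }
      for (p in fx$truth$lysine_positions) {
        cls <- sample(extra_classes, 1L)
        rows <- c(rows, sprintf("%s\t%s\tK%d-%s", acc, acc, p,
                                PTM_CLASS_SUFFIX[[cls]]))
      }
    }
    rows <- c(rows, sprintf("%s\t%s\t??", fixtures[[1L]]$truth$accession,
                            fixtures[[1L]]$truth$accession))
    paste(c("synthetic PTM site dataset", "generated fixture", "",
            "GENE\tACC_ID\tMOD_RSD", rows, ""), collapse = "\n")
  })
}

ALPHABET20 <- unname(AA3TO1)

#' Generate an aligned orthogroup FASTA with planted column conservation
#'
#' One human reference row plus `n_seq - 1` ortholog rows. Conserved
#' columns are identical down the alignment (entropic score 0), noisy
#' columns uniform over the 20 amino acids (score near 1 for large
#' alignments), remaining columns drawn from a 3-letter set. Gap columns
#' (gap in the human row, letters elsewhere) exercise position mapping.
#'
#' @param n_seq number of sequences (>= 10)
#' @param n_col alignment columns excluding inserted gap columns
#' @param conserved_cols,noisy_cols 1-based indices into the `n_col` grid
#' @param n_gap_cols number of human-gap columns to insert
#' @param seed RNG seed
#' @return list with `fasta_text`, `truth` (column classes on the final
#'   grid, human ungapped-position -> column map, human id)
#' @export
make_msa_fixture <- function(n_seq = 30L, n_col = 40L,
                             conserved_cols = c(5L, 15L),
                             noisy_cols = c(10L, 25L),
                             n_gap_cols = 3L, seed = 7L) {
  if (n_seq < 10L) stop("n_seq must be >= 10")
  with_seed(seed, {
    mat <- matrix("", nrow = n_seq, ncol = n_col)
    cls <- rep("moderate", n_col)
    cls[conserved_cols] <- "conserved"
    cls[noisy_cols] <- "noisy"
    for (j in seq_len(n_col)) {
      mat[, j] <- switch(
        cls[j],
        conserved = rep(sample(ALPHABET20, 1L), n_seq),
        noisy = sample(ALPHABET20, n_seq, replace = TRUE),
        moderate = sample(sample(ALPHABET20, 3L), n_seq, replace = TRUE,
                          prob = c(0.7, 0.2, 0.1)))
    }
    # insert gap columns at deterministic interior positions
    gap_at <- if (n_gap_cols > 0L)
      sort(sample(2:(n_col - 1L), n_gap_cols)) else integer(0)
    full <- matrix("", nrow = n_seq, ncol = 0L)
    full_cls <- character(0)
    for (j in seq_len(n_col)) {
      if (j %in% gap_at) {
        gcol <- sample(ALPHABET20, n_seq, replace = TRUE)
        gcol[1L] <- "-"
        full <- cbind(full, gcol)
        full_cls <- c(full_cls, "human_gap")
      }
      full <- cbind(full, mat[, j])
      full_cls <- c(full_cls, cls[j])
    }
    ids <- c("QUERY_HUMAN", sprintf("ORTH%03d_SP%03d", seq_len(n_seq - 1L),
                                    seq_len(n_seq - 1L)))
    seqs <- apply(full, 1L, paste, collapse = "")
    fasta <- paste(paste0(">", ids, "\n", seqs, collapse = "\n"), "\n", sep = "")
    ungapped <- unname(which(full[1L, ] != "-"))
    list(fasta_text = fasta,
         truth = list(column_class = full_cls,
                      human_pos_to_column = ungapped,
                      human_id = "QUERY_HUMAN"))
  })
}

#' Generate a COSMIC-like mutation screen table with planted hits
#'
#' Raw screen rows (one per mutated sample): phosphomimetic S/T/Y -> D/E
#' substitutions planted at a subset of the cryptic sites, non-mimetic
#' decoys, duplicated rows to exercise count collapsing, negative-screen
#' rows that must be eliminated, and one malformed protein-change row.
#'
#' @param sites data frame with `accession`, `position`, `aa` and logical
#'   `cryptic` describing the site universe to draw from
#' @param seed RNG seed
#' @return list with `tsv_text` and `truth` (expected hit counts)
#' @export
make_mutation_fixture <- function(sites, seed = 1L) {
  with_seed(seed, {
    stopifnot(all(c("accession", "position", "aa", "cryptic") %in% names(sites)))
    cry <- sites[sites$cryptic & sites$aa %in% c("S", "T", "Y"), , drop = FALSE]
    if (nrow(cry) < 2L) stop("need at least two cryptic S/T/Y sites")
    non <- sites[!sites$cryptic, , drop = FALSE]
    mk <- function(acc, pos, from, to, n_pos, n_neg, annot = "") {
      cds <- sprintf("c.%dA>G", pos * 3L)
      aa_chg <- sprintf("p.%s%d%s", from, pos, to)
      c(sprintf("%s\t%s\t%d\t%s\t%s\tS%06d\tpositive\t%s",
                acc, acc, pos, cds, aa_chg,
                sample.int(999999L, n_pos), annot)[seq_len(n_pos)],
        sprintf("%s\t%s\t%d\t%s\t%s\tS%06d\tnegative\t%s",
                acc, acc, pos, cds, aa_chg,
                sample.int(999999L, max(n_neg, 1L)), annot)[seq_len(n_neg)])
    }
    rows <- character(0)
    # two phosphomimetic hits at cryptic sites (duplicates + a negative row)
    mims <- cry[1:2, ]
    rows <- c(rows, mk(mims$accession[1], mims$position[1], mims$aa[1], "E",
                       n_pos = 3L, n_neg = 1L, annot = "cancer-related"))
    rows <- c(rows, mk(mims$accession[2], mims$position[2], mims$aa[2], "D",
                       n_pos = 2L, n_neg = 0L))
    # non-mimetic hits at remaining cryptic sites
    extra <- cry[-(1:2), , drop = FALSE]
    n_extra_hits <- min(3L, nrow(extra))
    for (i in seq_len(n_extra_hits))
      rows <- c(rows, mk(extra$accession[i], extra$position[i], extra$aa[i],
                         "A", n_pos = 1L, n_neg = 0L))
    # decoys away from cryptic sites
    if (nrow(non) > 0L)
      for (i in seq_len(min(3L, nrow(non))))
        rows <- c(rows, mk(non$accession[i], non$position[i], non$aa[i], "F",
                           n_pos = 1L, n_neg = 1L))
    rows <- c(rows, sprintf("%s\t%s\t1\tc.3A>G\tp.?\tS999999\tpositive\t",
                            cry$accession[1], cry$accession[1]))
    header <- "ACC_ID\tGENE\tPOSITION\tMUTATION_CDS\tMUTATION_AA\tSAMPLE_ID\tSCREEN_STATUS\tANNOTATION"
    list(tsv_text = paste(c(header, rows, ""), collapse = "\n"),
         truth = list(n_hits = 2L + n_extra_hits,
                      n_phosphomimetic = 2L,
                      n_cancer_annotated = 1L,
                      positive_rows = sum(grepl("\tpositive\t", rows))))
  })
}

#' Generate a compact native conformation for the folding toy
#'
#' Beads on a snake path through a small lattice with jitter: a compact
#' self-avoiding chain whose centre bead is the designated buried "site".
#' The native contact list (sequence separation >= 3, distance <= 8 A)
#' defines the Go-like attractive interactions of the toy simulator.
#'
#' @param n_beads chain length (default 30)
#' @param seed RNG seed
#' @param bond_length lattice spacing = bond length (A)
#' @return list of class `toy_chain`: `xyz` native coordinates, `bonds`,
#'   `angles13` (1-3 distances), `contacts` (pairs + native distances),
#'   `core_bead`, `n_beads`, `bond_length`
#' @export
make_toy_chain_native <- function(n_beads = 30L, seed = 1L, bond_length = 3.8) {
  with_seed(seed, {
    side <- ceiling(n_beads^(1 / 3) - 1e-9)
    cells <- snake_cells(side, side, side)[seq_len(n_beads), , drop = FALSE]
    xyz <- cells * bond_length +
      matrix(stats::runif(3 * n_beads, -0.1, 0.1), ncol = 3)
    xyz <- round3(xyz)
    ctr <- (side - 1) / 2
    core_bead <- which.min(rowSums((cells - ctr)^2))
    d <- as.matrix(stats::dist(xyz))
    ij <- which(upper.tri(d), arr.ind = TRUE)
    sep <- ij[, 2] - ij[, 1]
    keep <- sep >= 3L & d[ij] <= 8
    contacts <- cbind(i = ij[keep, 1], j = ij[keep, 2])
    structure(list(
      xyz = xyz,
      bonds = cbind(i = 1:(n_beads - 1L), j = 2:n_beads,
                    r0 = d[cbind(1:(n_beads - 1L), 2:n_beads)]),
      angles13 = cbind(i = 1:(n_beads - 2L), j = 3:n_beads,
                       r0 = d[cbind(1:(n_beads - 2L), 3:n_beads)]),
      contacts = cbind(contacts, r0 = d[contacts]),
      core_bead = core_bead, n_beads = n_beads, bond_length = bond_length),
      class = "toy_chain")
  })
}
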