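AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a single-chain structure object
#'
#' The shared structural data model of the pipeline: an ordered set of
#' residues, each carrying its heavy atoms and a per-residue model
#' confidence (pLDDT, 0-100). Residue numbering is 1-based and assumed to
#' equal UniProt numbering, as in AlphaFold models.
#'
#' @param atoms data frame with columns `resno` (integer), `aa`
#'   (one-letter residue code), `name` (atom name, unique within a
#'   residue), `element` (C/N/O/S/P), `x`, `y`, `z` (Angstrom).
#' @param plddt named numeric vector of per-residue confidences in
#'   \[0, 100\]; names are residue numbers.
#' @param chain_id single chain identifier (default "A").
#' @param source_name free-text provenance label.
#' @return An object of class `cp_structure` with elements `atoms`
#'   (atom table), `residues` (data frame `position`, `aa`, `plddt`),
#'   `chain_id`, `source_name`.
#' @export
cp_structure <- function(atoms, plddt, chain_id = "A", source_name = "") {
  stopifnot(is.data.frame(atoms),
            all(c("resno", "aa", "name", "element", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  resno <- sort(unique(atoms$resno))
  if (is.null(names(plddt))) names(plddt) <- resno
  plddt <- plddt[as.character(resno)]
  if (anyNA(plddt) || any(plddt < 0 | plddt > 100))
    stop("every residue needs a pLDDT in [0, 100]")
  aa <- vapply(resno, function(r) atoms$aa[atoms$resno == r][1L], character(1))
  bad <- !aa %in% c(AA3TO1, "X")
  if (any(bad)) stop("unknown residue letter(s): ", paste(unique(aa[bad]), collapse = ", "))
  for (r in resno) {
    nm <- atoms$name[atoms$resno == r]
    if (anyDuplicated(nm)) stop("duplicate atom name in residue ", r)
  }
  structure(
    list(atoms = atoms[order(atoms$resno), , drop = FALSE],
         residues = data.frame(position = resno, aa = aa,
                               plddt = unname(plddt), stringsAsFactors = FALSE),
         chain_id = chain_id, source_name = source_name),
    class = "cp_structure")
}

#' @export
print.cp_structure <- function(x, ...) {
  cat(sprintf("<cp_structure> %s chain %s: %d residues, %d heavy atoms, pLDDT %.1f-%.1f\n",
              x$source_name, x$chain_id, nrow(x$residues), nrow(x$atoms),
              min(x$residues$plddt), max(x$residues$plddt)))
  invisible(x)
}

#' Subset a structure to a set of residue positions
#'
#' Original residue numbering is preserved, so positions keep their
#' full-chain (UniProt) meaning in pruned entries.
#'
#' @param s `cp_structure`
#' @param positions integer vector of residue positions to keep
#' @return `cp_structure` restricted to `positions`
#' @export
structure_subset <- function(s, positions) {
  keep <- s$atoms$resno %in% positions
  if (!any(keep)) stop("no residues left after subsetting")
  cp_structure(s$atoms[keep, , drop = FALSE],
               stats::setNames(s$residues$plddt, s$residues$position)[
                 as.character(sort(intersect(s$residues$position, positions)))],
               chain_id = s$chain_id, source_name = s$source_name)
}

infer_element <- function(atom_name) {
  # AlphaFold files carry no hydrogens; first alphabetic character of the
  # stripped atom name identifies the heavy element for standard residues.
  nm <- toupper(gsub("[^A-Z]", "", toupper(atom_name)))
  el <- substr(nm, 1L, 1L)
  el[el == ""] <- "C"
  el
}

#' Read an AlphaFold-style PDB file into the structure model
#'
#' Parses ATOM records of a single-chain model in which the B-factor
#' column stores the per-residue pLDDT confidence (identical for every
#' atom of a residue in AlphaFold output; the first atom's value is
#' taken). HETATM records, waters and hydrogens are ignored. altLoc
#' indicators and insertion codes are hard format errors: the pipeline's
#' site mapping relies on plain 1-based UniProt-equal numbering.
#'
#' @param pdb_text PDB file content as a single string (or character
#'   vector of lines).
#' @param source_name provenance label stored on the structure.
#' @return `cp_structure`
#' @export
read_pdb_structure <- function(pdb_text, source_name = "pdb") {
  lines <- if (length(pdb_text) == 1L) strsplit(pdb_text, "\n", fixed = TRUE)[[1L]] else pdb_text
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) stop("not parseable as PDB: ", conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("format error: no ATOM records")
  if (length(unique(at$chain)) > 1L)
    stop("format error: multi-chain models are not supported")
  if (any(!is.na(at$alt) & at$alt != ""))
    stop("format error: altLoc indicators present")
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("format error: insertion codes present")
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- infer_element(at$elety)
  elem[is.na(elem) | elem == ""] <- infer_element(at$elety[is.na(elem) | elem == ""])
  elem <- toupper(trimws(elem))
  heavy <- elem != "H" & !(at$resid %in% c("HOH", "WAT"))
  at <- at[heavy, , drop = FALSE]
  elem <- elem[heavy]
  if (nrow(at) == 0L) stop("format error: no heavy ATOM records")
  aa <- unname(AA3TO1[at$resid])
  aa[is.na(aa)] <- "X"
  atoms <- data.frame(resno = at$resno, aa = aa, name = trimws(at$elety),
                      element = elem, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  # residue blocks must be contiguous: a position that reappears after a
  # different one is a duplicate-residue format error
  runs <- rle(atoms$resno)$values
  if (anyDuplicated(runs)) stop("format error: duplicate residue position ",
                                runs[duplicated(runs)][1L])
  plddt <- numeric(0)
  for (r in runs) {
    b <- at$b[at$resno == r]
    if (diff(range(b)) > 0.01)
      warning("B-factors differ within residue ", r, "; first atom wins")
    plddt[as.character(r)] <- b[1L]
  }
  cp_structure(atoms, plddt, chain_id = unique(at$chain)[1L], source_name = source_name)
}

#' Write a structure as PDB text
#'
#' Standard fixed-width ATOM records; pLDDT goes to the B-factor column
#' with two decimals, coordinates with three. Reading the result back
#' reproduces the data model exactly provided coordinates are stored at
#' millinagstrom precision (all package generators do).
#'
#' @param s `cp_structure`
#' @return single string of PDB text
#' @export
write_pdb_structure <- function(s) {
  stopifnot(inherits(s, "cp_structure"))
  a <- s$atoms
  if (nrow(a) == 0L) stop("empty structure")
  if (any(abs(c(a$x, a$y, a$z)) >= 10000))
    stop("formatting error: coordinate magnitude >= 10000 A")
  plddt <- stats::setNames(s$residues$plddt, s$residues$position)
  # PDB convention: atom names of 1-3 characters start in column 14
  nm <- ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name)
  lines <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(nrow(a)), nm, AA1TO3[a$aa], s$chain_id, a$resno,
                   a$x, a$y, a$z, 1.00, plddt[as.character(a$resno)], a$element)
  paste(c(lines, "END", ""), collapse = "\n")
}

PTM_SUFFIX <- c(p = "phospho", ub = "ubiquityl", ac = "acetyl",
                m1 = "methyl", m2 = "methyl", m3 = "methyl",
                sm = "sumoyl", gl = "glycosyl", ga = "glycosyl")

#' Read a PhosphoSitePlus-dialect PTM site table
#'
#' Expects a tab-separated table with columns `ACC_ID` and `MOD_RSD`,
#' the latter in the form `"S417-p"` (residue letter, 1-based position,
#' modification-class suffix). Rows whose `MOD_RSD` cannot be parsed, or
#' whose suffix is unknown, are skipped with a warning and counted in
#' `attr(, "skipped")`.
#'
#' @param tsv_text TSV content as a single string or vector of lines.
#' @param skip_preamble number of preamble lines before the header
#'   (default 3, the public PhosphoSitePlus download's banner).
#' @return data frame of class `cp_sites` with columns `accession`,
#'   `position`, `aa`, `ptm_class`, `sasa`, `rsa`, `plddt`, `status`
#'   (all `status` equal `"raw"`).
#' @export
read_ptm_table <- function(tsv_text, skip_preamble = 3L) {
  lines <- if (length(tsv_text) == 1L) strsplit(tsv_text, "\n", fixed = TRUE)[[1L]] else tsv_text
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          skip = skip_preamble, stringsAsFactors = FALSE,
                          check.names = TRUE)
  names(df) <- toupper(names(df))
  if (!all(c("ACC_ID", "MOD_RSD") %in% names(df)))
    stop("format error: PTM table needs ACC_ID and MOD_RSD columns")
  m <- regmatches(df$MOD_RSD,
                  regexec("^([A-Z])([0-9]+)-([a-z0-9]+)$", df$MOD_RSD))
  ok <- lengths(m) == 4L
  cls <- rep(NA_character_, nrow(df))
  cls[ok] <- PTM_SUFFIX[vapply(m[ok], `[`, character(1), 4L)]
  ok <- ok & !is.na(cls)
  skipped <- sum(!ok)
  if (skipped > 0L)
    warning(skipped, " PTM row(s) skipped (unparseable MOD_RSD or unknown suffix)")
  sites <- data.frame(
    accession = df$ACC_ID[ok],
    position = as.integer(vapply(m[ok], `[`, character(1), 3L)),
    aa = vapply(m[ok], `[`, character(1), 2L),
    ptm_class = unname(cls[ok]),
    sasa = NA_real_, rsa = NA_real_, plddt = NA_real_,
    status = "raw", stringsAsFactors = FALSE)
  class(sites) <- c("cp_sites", "data.frame")
  attr(sites, "skipped") <- skipped
  sites
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' All sequences must have equal length (Clustal Omega-style output).
#' Letters are kept verbatim, including gaps and ambiguity codes.
#'
#' @param fasta_text FASTA content as a single string or vector of lines.
#' @param human_id optional id of the human (reference) row; defaults to
#'   the first id containing "HUMAN", else the first sequence.
#' @return object of class `cp_alignment`: list with `ids`, `matrix`
#'   (n_seq x n_col character matrix) and `human_id`.
#' @export
read_alignment_fasta <- function(fasta_text, human_id = NULL) {
  lines <- if (length(fasta_text) == 1L) strsplit(fasta_text, "\n", fixed = TRUE)[[1L]] else fasta_text
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  aln <- tryCatch(Biostrings::readBStringSet(tf),
                  error = function(e) stop("format error: ", conditionMessage(e)))
  if (length(aln) == 0L) stop("format error: empty alignment")
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("format error: ragged alignment (sequence lengths ",
         paste(unique(w), collapse = ", "), ")")
  ids <- sub("\\s.*$", "", names(aln))
  mat <- do.call(rbind, strsplit(toupper(as.character(aln)), "", fixed = TRUE))
  rownames(mat) <- ids
  if (is.null(human_id)) {
    hit <- grep("HUMAN", ids, value = TRUE)
    human_id <- if (length(hit)) hit[1L] else ids[1L]
  }
  if (!human_id %in% ids) stop("human_id not among alignment ids")
  structure(list(ids = ids, matrix = mat, human_id = human_id),
            class = "cp_alignment")
}

#' @export
print.cp_alignment <- function(x, ...) {
  cat(sprintf("<cp_alignment> %d sequences x %d columns (reference: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$human_id))
  invisible(x)
}

# append-only status update: records already excluded keep their reason
set_status <- function(sites, idx, status) {
  free <- !startsWith(sites$status[idx], "excluded")
  sites$status[idx[free]] <- status
  sites
}
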