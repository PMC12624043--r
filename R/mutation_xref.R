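# Cancer-mutation cross-referencing: ingest COSMIC/PTMVar-style screen
# tables, collapse duplicate records with counts, and flag phosphomimetic
# substitutions (S/T/Y -> D/E) at cryptic phosphosites.

#' Parse protein-change strings
#'
#' Accepts the `"p.S417E"` and bare `"S417E"` dialects.
#'
#' @param x character vector of protein-change strings
#' @return data frame `aa_from`, `position`, `aa_to`; unparseable rows
#'   are NA
#' @export
parse_protein_change <- function(x) {
  m <- regmatches(x, regexec("^(?:p\\.)?([A-Z])([0-9]+)([A-Z])$", x))
  ok <- lengths(m) == 4L
  out <- data.frame(aa_from = NA_character_, position = NA_integer_,
                    aa_to = NA_character_, stringsAsFactors = FALSE)[rep(1L, length(x)), ]
  rownames(out) <- NULL
  out$aa_from[ok] <- vapply(m[ok], `[`, character(1), 2L)
  out$position[ok] <- as.integer(vapply(m[ok], `[`, character(1), 3L))
  out$aa_to[ok] <- vapply(m[ok], `[`, character(1), 4L)
  out
}

#' Read a raw mutation-screen TSV
#'
#' Expects (case-insensitively) columns `ACC_ID`, `MUTATION_AA`,
#' `SCREEN_STATUS`, optionally `GENE`, `MUTATION_CDS`, `ANNOTATION`.
#'
#' @param tsv_text TSV content as a single string or vector of lines
#' @param skip_preamble preamble lines to skip
#' @return raw data frame, one row per screened sample
#' @export
read_mutation_table <- function(tsv_text, skip_preamble = 0L) {
  lines <- if (length(tsv_text) == 1L) strsplit(tsv_text, "\n", fixed = TRUE)[[1L]] else tsv_text
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          skip = skip_preamble, stringsAsFactors = FALSE)
  names(df) <- toupper(names(df))
  need <- c("ACC_ID", "MUTATION_AA", "SCREEN_STATUS")
  if (!all(need %in% names(df)))
    stop("format error: mutation table needs columns ",
         paste(need, collapse = ", "))
  df
}

#' Preprocess raw screen rows into counted mutation records
#'
#' Negative-screen rows are eliminated; surviving identical mutations
#' (same accession, position, amino-acid change and CDS change) are
#' collapsed into one record whose `count` is their multiplicity.
#' Unparseable protein-change strings are skipped with a warning.
#'
#' @param raw data frame from [read_mutation_table()]
#' @return data frame of class `cp_mutations`: `accession`, `gene`,
#'   `position`, `aa_from`, `aa_to`, `cds_change`, `count`, `annotation`
#' @export
preprocess_mutations <- function(raw) {
  pos_rows <- raw[tolower(raw$SCREEN_STATUS) != "negative", , drop = FALSE]
  chg <- parse_protein_change(pos_rows$MUTATION_AA)
  bad <- is.na(chg$position) | chg$aa_from == chg$aa_to
  if (any(bad))
    warning(sum(bad), " mutation row(s) skipped (unparseable protein change)")
  pos_rows <- pos_rows[!bad, , drop = FALSE]
  chg <- chg[!bad, , drop = FALSE]
  rec <- data.frame(
    accession = pos_rows$ACC_ID,
    gene = if ("GENE" %in% names(pos_rows)) pos_rows$GENE else pos_rows$ACC_ID,
    position = chg$position, aa_from = chg$aa_from, aa_to = chg$aa_to,
    cds_change = if ("MUTATION_CDS" %in% names(pos_rows)) pos_rows$MUTATION_CDS else "",
    annotation = if ("ANNOTATION" %in% names(pos_rows)) pos_rows$ANNOTATION else "",
    stringsAsFactors = FALSE)
  key <- paste(rec$accession, rec$position, rec$aa_from, rec$aa_to,
               rec$cds_change, sep = "|")
  agg <- rec[!duplicated(key), , drop = FALSE]
  agg$count <- as.integer(table(key)[key[!duplicated(key)]])
  agg <- agg[order(agg$accession, agg$position), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("cp_mutations", "data.frame")
  agg
}

#' Is a substitution phosphomimetic?
#'
#' A phosphomimetic replaces the phosphorylatable residue (S, T or Y)
#' with an aspartate or glutamate, mimicking the phosphate's negative
#' charge.
#'
#' @param aa_from,aa_to one-letter codes (vectorized)
#' @return logical vector
#' @export
is_phosphomimetic <- function(aa_from, aa_to) {
  aa_from %in% c("S", "T", "Y") & aa_to %in% c("D", "E")
}

#' Cross-reference cryptic phosphosites with counted mutations
#'
#' Inner join on accession and position; a hit additionally requires the
#' mutation's reference residue to equal the site's residue letter
#' (disagreements are rejected and counted). Each hit is flagged
#' phosphomimetic or not.
#'
#' @param cryptic_sites data frame with `accession`, `position`, `aa`
#' @param mutations `cp_mutations` from [preprocess_mutations()]
#' @return hit data frame with a `summary` attribute: `n_hits`,
#'   `n_phosphomimetic`, `n_cancer_annotated`, `n_rejected`
#' @export
cross_reference <- function(cryptic_sites, mutations) {
  hits <- merge(cryptic_sites[, c("accession", "position", "aa")], mutations,
                by = c("accession", "position"))
  rejected <- hits$aa_from != hits$aa
  if (any(rejected))
    message(sum(rejected), " hit(s) rejected: mutation reference residue ",
            "disagrees with the site residue")
  hits <- hits[!rejected, , drop = FALSE]
  hits$phosphomimetic <- is_phosphomimetic(hits$aa_from, hits$aa_to)
  hits$cancer_annotated <- grepl("cancer", hits$annotation, ignore.case = TRUE)
  hits <- hits[order(hits$accession, hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "summary") <- list(
    n_hits = nrow(hits),
    n_phosphomimetic = sum(hits$phosphomimetic),
    n_cancer_annotated = sum(hits$cancer_annotated),
    n_rejected = sum(rejected))
  hits
}

#' Two-proportion z test for mutation rates
#'
#' Compares the fraction of mutated sites between two site groups
#' (e.g., disease-mutation rates at cryptic vs non-cryptic sites).
#'
#' @param x1,n1 mutated and total counts, group 1
#' @param x2,n2 mutated and total counts, group 2
#' @return list: `p1`, `p2`, `z`, `p_value` (two-sided)
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(p1 = p1, p2 = p2, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}
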