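# Evolutionary conservation of alignment columns: normalized Shannon
# entropy ("entropic score"), proteome QC by the BUSCO IQR rule, and
# effect-size comparison of cryptic vs non-cryptic score distributions.

#' Entropic-score parameters
#'
#' The alphabet is fixed: 20 amino acids, the gap symbol and a pooled
#' ambiguity symbol 'X' (K = 22 by default). K is the alphabet size,
#' not the per-column count of distinct letters: only then does a fully
#' conserved column score 0 and a uniformly occupied one score 1.
#'
#' @param alphabet ordered symbol set
#' @return list of class `es_params` with `alphabet` and `K`
#' @export
es_params <- function(alphabet = c(unname(AA3TO1), "-", "X")) {
  if (length(alphabet) < 2L) stop("alphabet must have K >= 2 symbols")
  if (!"-" %in% alphabet) stop("alphabet must contain the gap symbol")
  structure(list(alphabet = alphabet, K = length(alphabet)),
            class = "es_params")
}

#' Map a human (ungapped) sequence position to its alignment column
#'
#' @param aln `cp_alignment`
#' @param human_pos 1-based position in the ungapped human sequence
#' @param human_id reference row id (defaults to the alignment's)
#' @return 1-based column index
#' @export
map_position_to_column <- function(aln, human_pos, human_id = aln$human_id) {
  row <- aln$matrix[human_id, ]
  nongap <- which(row != "-")
  if (human_pos < 1L || human_pos > length(nongap))
    stop("position ", human_pos, " beyond the ungapped human length ",
         length(nongap))
  nongap[human_pos]
}

#' Map an alignment column back to the human sequence position
#'
#' Inverse of [map_position_to_column()]; errors if the human row has a
#' gap in that column.
#'
#' @inheritParams map_position_to_column
#' @param column 1-based column index
#' @return 1-based ungapped position
#' @export
map_column_to_position <- function(aln, column, human_id = aln$human_id) {
  row <- aln$matrix[human_id, ]
  if (column < 1L || column > length(row)) stop("column out of range")
  if (row[column] == "-") stop("human row is gapped at column ", column)
  sum(row[seq_len(column)] != "-")
}

#' Normalized Shannon entropy of an alignment column
#'
#' `S = -sum(p_a * ln p_a) / ln K` with `p_a` the relative frequency of
#' symbol `a` in the column and `K` the fixed alphabet size; `0 ln 0` is
#' taken as 0. A perfectly conserved column scores 0; a column in which
#' all K symbols are equally frequent scores 1. Symbols outside the
#' alphabet (ambiguity codes B, Z, U, O and anything else) are pooled
#' into 'X' with a warning.
#'
#' @param column character vector of residues (one per sequence)
#' @param params `es_params`
#' @return entropic score in \[0, 1\]
#' @export
entropic_score <- function(column, params = es_params()) {
  if (length(column) == 0L) stop("empty alignment column")
  column <- toupper(column)
  outside <- !(column %in% params$alphabet)
  if (any(outside)) {
    warning(sum(outside), " symbol(s) outside the alphabet pooled into 'X'")
    column[outside] <- "X"
  }
  p <- table(factor(column, levels = params$alphabet)) / length(column)
  p <- as.numeric(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(params$K) + 0  # +0 normalizes IEEE -0
}

#' Cohen's d effect size (pooled-variance form)
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with the pooled sample standard
#' deviation; sign follows the first argument minus the second.
#'
#' @param x,y numeric vectors of length >= 2
#' @return Cohen's d
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least two observations per group")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero; d undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Drop proteomes with outlying BUSCO completeness
#'
#' Tukey-style lower fence: organisms whose score falls strictly below
#' `Q1 - 1.5 * IQR` (quartiles by linear interpolation, type 7) are
#' excluded.
#'
#' @param scores named numeric vector of BUSCO scores (>= 4 organisms)
#' @return the kept subset of `scores`
#' @export
busco_iqr_filter <- function(scores) {
  if (length(scores) < 4L) stop("need at least 4 organisms")
  q <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  cutoff <- q[1L] - 1.5 * (q[2L] - q[1L])
  scores[!(scores < cutoff)]
}

#' Compare cryptic vs non-cryptic entropic-score distributions
#'
#' @param cryptic_es,noncryptic_es numeric score vectors
#' @param bin_width histogram bin width (default 0.05)
#' @return list: group medians, `median_diff` (cryptic minus
#'   non-cryptic), `cohens_d`, Mann-Whitney `p_value`, `histogram`
#'   (long-format per-group bin counts)
#' @export
compare_es_distributions <- function(cryptic_es, noncryptic_es,
                                     bin_width = 0.05) {
  stopifnot(length(cryptic_es) > 0, length(noncryptic_es) > 0)
  identical_sets <- isTRUE(all.equal(sort(cryptic_es), sort(noncryptic_es)))
  d <- if (identical_sets && stats::var(c(cryptic_es, noncryptic_es)) == 0) 0
  else cohens_d(cryptic_es, noncryptic_es)
  p <- tryCatch(
    suppressWarnings(stats::wilcox.test(cryptic_es, noncryptic_es)$p.value),
    error = function(e) NA_real_)
  all_v <- c(cryptic_es, noncryptic_es)
  breaks <- seq(floor(min(all_v) / bin_width) * bin_width,
                (floor(max(all_v) / bin_width) + 1L) * bin_width,
                by = bin_width)
  mk_hist <- function(v, g) {
    idx <- pmin(findInterval(v, breaks), length(breaks) - 1L)
    data.frame(group = g, bin_lo = breaks[-length(breaks)],
               bin_hi = breaks[-1L],
               count = tabulate(idx, nbins = length(breaks) - 1L))
  }
  list(median_cryptic = stats::median(cryptic_es),
       median_noncryptic = stats::median(noncryptic_es),
       median_diff = stats::median(cryptic_es) - stats::median(noncryptic_es),
       cohens_d = d, p_value = p,
       histogram = rbind(mk_hist(cryptic_es, "cryptic"),
                         mk_hist(noncryptic_es, "noncryptic")))
}

#' Entropic scores for a table of sites against orthogroup alignments
#'
#' @param site_table data frame with `accession`, `position`, `cryptic`
#' @param alignments named list of `cp_alignment`, keyed by accession
#' @param params `es_params`
#' @return the table with `column` and `es` columns added (NA where no
#'   alignment is available)
#' @export
score_sites_conservation <- function(site_table, alignments,
                                     params = es_params()) {
  site_table$column <- NA_integer_
  site_table$es <- NA_real_
  for (i in seq_len(nrow(site_table))) {
    aln <- alignments[[site_table$accession[i]]]
    if (is.null(aln)) next
    col <- tryCatch(map_position_to_column(aln, site_table$position[i]),
                    error = function(e) NA_integer_)
    if (is.na(col)) next
    site_table$column[i] <- col
    site_table$es[i] <- suppressWarnings(
      entropic_score(aln$matrix[, col], params))
  }
  site_table
}
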