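# End-to-end orchestration of the cryptic-phosphosite workflow:
# map sites onto structures -> confidence filter -> RSA classification
# (the scan), then prune / merge / size-gate / RSA-refilter /
# quasi-rigid decomposition / Pidc (the full dynamical refinement).

#' Default pipeline configuration
#'
#' All thresholds default to the workflow's canonical values: RSA cut
#' 0.15, pLDDT cut 65, minimum domain size 40 residues, merge rule 5
#' residue pairs within 5 A, Pidc cut 0.80, elastic-network cutoff
#' 7.5 A with 10 retained modes, up to 10 domains.
#'
#' @param ... named overrides of any config entry
#' @return list of class `cp_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    rsa_cryptic = 0.15, plddt_min = 65,
    min_domain_size = 40L, merge_dist = 5.0, merge_min_pairs = 5L,
    pidc_min = 0.80, pidc_radius = 6.0,
    enm_cutoff = 7.5, n_modes = 10L, k_max = 10L,
    probe_radius = 1.4, n_sphere_points = 960L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "cp_config")
}

cfg_thresholds <- function(cfg) cp_thresholds(cfg$rsa_cryptic, cfg$plddt_min)
cfg_sasa <- function(cfg) sasa_params(cfg$probe_radius, cfg$n_sphere_points)

status_counts <- function(sites) {
  tab <- table(sites$status)
  stats::setNames(as.integer(tab), names(tab))
}

#' Scan PTM sites against structures (accessibility stage)
#'
#' Maps each site onto its accession's structure, excludes
#' low-confidence residues, classifies by RSA and emits the per-class
#' RSA distribution. Sites without a structure become
#' `excluded:no_structure`.
#'
#' @param structures named list of `cp_structure`, keyed by accession
#' @param sites `cp_sites` (status raw)
#' @param config `cp_config`
#' @return list: `sites`, `rsa_histogram`, `cryptic_fraction`,
#'   `summary` (per-status counts)
#' @export
run_scan <- function(structures, sites, config = default_config()) {
  th <- cfg_thresholds(config)
  sp <- cfg_sasa(config)
  no_struct <- which(!sites$accession %in% names(structures))
  sites <- set_status(sites, no_struct, "excluded:no_structure")
  for (acc in intersect(unique(sites$accession), names(structures))) {
    idx <- which(sites$accession == acc & sites$status == "raw")
    if (!length(idx)) next
    rsa <- residue_rsa(structures[[acc]], sp)
    sub <- map_ptm_sites(sites[idx, , drop = FALSE], structures[[acc]], rsa = rsa)
    sub <- classify_sites(sub, th)
    sites[idx, names(sub)] <- sub
  }
  dist <- rsa_distribution(sites[sites$status %in% c("cryptic", "confident"), ,
                                 drop = FALSE],
                           rsa_cryptic = config$rsa_cryptic)
  list(sites = sites, rsa_histogram = dist$histogram,
       cryptic_fraction = dist$cryptic_fraction,
       summary = status_counts(sites))
}

#' Run the full pipeline including the dynamical filter
#'
#' [run_scan()] followed, per accession that still carries cryptic
#' candidates, by low-confidence pruning, contact merging of segments,
#' the 40-residue size gate, RSA recomputation on the pruned entries,
#' quasi-rigid decomposition and the Pidc boundary filter. Each record
#' ends in exactly one terminal status; the summary reports the
#' stage-count waterfall.
#'
#' @inheritParams run_scan
#' @return list: `sites`, `domains` (per-residue domain labels of every
#'   decomposed entry), `entries` (per-entry chosen k and quality),
#'   `rsa_histogram`, `summary`
#' @export
run_full <- function(structures, sites, config = default_config()) {
  scan <- run_scan(structures, sites, config)
  sites <- scan$sites
  th <- cfg_thresholds(config)
  sp <- cfg_sasa(config)
  domains <- list()
  entries_info <- list()
  for (acc in intersect(unique(sites$accession), names(structures))) {
    if (!any(sites$accession == acc & sites$status == "cryptic")) next
    s <- structures[[acc]]
    segs <- prune_low_confidence(s, config$plddt_min)
    ents <- merge_entries(segs, s, config$merge_dist, config$merge_min_pairs)
    acc_idx <- which(sites$accession == acc)
    gated <- size_gate(ents, sites[acc_idx, , drop = FALSE],
                       config$min_domain_size)
    sites[acc_idx, names(gated$sites)] <- gated$sites
    for (entry in gated$entries) {
      in_entry <- acc_idx[sites$position[acc_idx] %in% entry$positions]
      cry <- in_entry[sites$status[in_entry] == "cryptic"]
      if (!length(cry)) next
      sub <- refilter_rsa(entry, sites[in_entry, , drop = FALSE], th, sp)
      sites[in_entry, names(sub)] <- sub
      cry <- in_entry[sites$status[in_entry] == "cryptic"]
      if (!length(cry)) next
      modes <- enm_modes(entry, config$enm_cutoff, config$n_modes)
      dec <- quasi_rigid_decompose(entry, modes,
                                   k_max = min(config$k_max,
                                               length(entry$positions) - 1L),
                                   seed = config$seed)
      sub <- apply_dynamic_filter(sites[in_entry, , drop = FALSE], entry, dec,
                                  config$pidc_min, config$pidc_radius)
      sites[in_entry, names(sub)] <- sub
      eid <- sprintf("%s:%d-%d", acc, min(entry$positions), max(entry$positions))
      domains[[eid]] <- data.frame(
        accession = acc, entry = eid,
        position = as.integer(names(dec$labels)),
        domain_id = unname(dec$labels), stringsAsFactors = FALSE)
      entries_info[[eid]] <- data.frame(
        accession = acc, entry = eid, n_res = length(entry$positions),
        chosen_k = dec$chosen_k, quality = max(dec$quality),
        stringsAsFactors = FALSE)
    }
  }
  domains <- if (length(domains)) do.call(rbind, c(domains, make.row.names = FALSE)) else NULL
  entries_info <- if (length(entries_info))
    do.call(rbind, c(entries_info, make.row.names = FALSE)) else NULL
  list(sites = sites, domains = domains, entries = entries_info,
       rsa_histogram = scan$rsa_histogram,
       summary = status_counts(sites),
       config = config)
}

#' Write and read a run-manifest (the full configuration) as JSON
#'
#' A manifest read back with [read_config_json()] reproduces the run
#' bit for bit.
#'
#' @param config `cp_config`
#' @param path JSON file
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  int_fields <- c("min_domain_size", "merge_min_pairs", "n_modes", "k_max",
                  "n_sphere_points", "seed")
  vals[int_fields] <- lapply(vals[int_fields], as.integer)
  dbl_fields <- setdiff(names(vals), int_fields)
  vals[dbl_fields] <- lapply(vals[dbl_fields], as.numeric)
  do.call(default_config, vals)
}

#' Write a site table as TSV
#'
#' @param sites `cp_sites`
#' @param path output file
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run summary as JSON
#'
#' @param summary named counts (from `run_scan`/`run_full`)
#' @param path output file
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(as.list(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
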