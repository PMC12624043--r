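# Shared fixtures, built once per test run. All generators are pure
# functions of their seeds, so these are deterministic.

glob_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_globule_fixture(seed = 1, with_loop = TRUE)
    cache
  }
})

hinge_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_hinge_fixture(seed = 1)
    cache
  }
})

toy_chain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_chain_native(30, seed = 1)
    cache
  }
})

# tiny hand-built structure: `spec` rows of (position, aa, plddt),
# coords supplied as a matrix, one CA (+ optional CB) per residue
tiny_structure <- function(pos, aa, plddt, ca, cb = NULL) {
  atoms <- data.frame(resno = pos, aa = aa, name = "CA", element = "C",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3],
                      stringsAsFactors = FALSE)
  if (!is.null(cb)) {
    atoms <- rbind(atoms,
                   data.frame(resno = pos, aa = aa, name = "CB", element = "C",
                              x = cb[, 1], y = cb[, 2], z = cb[, 3],
                              stringsAsFactors = FALSE))
  }
  cp_structure(atoms, stats::setNames(plddt, pos), source_name = "TINY")
}

make_sites_df <- function(accession, position, aa, ptm_class = "phospho",
                          status = "raw") {
  n <- length(position)
  df <- data.frame(accession = rep_len(accession, n), position = position,
                   aa = rep_len(aa, n), ptm_class = rep_len(ptm_class, n),
                   sasa = rep(NA_real_, n), rsa = rep(NA_real_, n),
                   plddt = rep(NA_real_, n),
                   status = rep_len(status, n), stringsAsFactors = FALSE)
  class(df) <- c("cp_sites", "data.frame")
  df
}
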