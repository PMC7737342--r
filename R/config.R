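#' Pipeline configuration
#'
#' All tunable thresholds in one list. Defaults reproduce the documented
#' behaviour of every stage; the list round-trips losslessly through YAML
#' via [write_pnp_config()] / [read_pnp_config()].
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `pnp_config`.
#' @export
pnp_config <- function(...) {
  cfg <- list(
    min_orf_aa = 50L,          # minimum ORF length, residues
    sp_h_min_len = 7L,         # signal peptide: min h-region window
    sp_h_min_hydropathy = 2.0, # min mean Kyte-Doolittle hydropathy
    sp_h_search_end = 30L,     # h-region search limit
    sp_c_range = c(15L, 40L),  # allowed cleavage positions
    min_pep_aa = 3L,           # mature peptide length bounds
    max_pep_aa = 50L,
    motif_min_freq = 0.6,      # consensus frequency for motif positions
    gap_open = 11,             # affine gap: gap of length k costs open+k*ext
    gap_extend = 1,
    evalue_max = 1e-5,         # homology-screen E-value cutoff
    min_identity = 0.5,        # family assignment identity threshold
    alpha = 0.05,              # expression / qPCR significance level
    p_adjust = "none",         # or "BH"
    calibrator = "LT",         # qPCR calibrator stage
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("pnp_config", "list"))
}

#' @rdname pnp_config
#' @param config A `pnp_config` list.
#' @param path File path for the YAML configuration.
#' @export
write_pnp_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pnp_config
#' @export
read_pnp_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pnp_config, raw)
  # yaml reads numeric scalars as double; restore integer-valued fields
  ints <- c("min_orf_aa", "sp_h_min_len", "sp_h_search_end", "min_pep_aa",
            "max_pep_aa", "sp_c_range", "seed")
  for (f in ints) cfg[[f]] <- as.integer(cfg[[f]])
  cfg
}
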