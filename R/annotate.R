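#' Annotate one protein as a putative neuropeptide precursor
#'
#' Runs the full prohormone-processing chain on one protein: signal-peptide
#' prediction, cleavage-site scanning, mature-peptide derivation with
#' amidation/pyroglutamate calls, and repeated-motif discovery, then applies
#' the candidate decision rule.
#'
#' @param protein Amino-acid string.
#' @param id Protein identifier.
#' @param config Threshold list from [pnp_config()].
#' @return An object of class `pnp_annotation`: `protein_id`, `length_aa`,
#'   `sp`, `sites`, `peptides` (with `motif_label` filled for motif members),
#'   `motif`, `copy_number`, `is_candidate`, `evidence` (set later by
#'   [merge_evidence()]), `family`, `tier`.
#' @export
annotate_precursor <- function(protein, id = "protein", config = pnp_config()) {
  protein <- toupper(protein)
  sp <- predict_signal_peptide(protein,
                               h_min_len = config$sp_h_min_len,
                               h_min_hydropathy = config$sp_h_min_hydropathy,
                               h_search_end = config$sp_h_search_end,
                               c_range = config$sp_c_range)
  sites <- scan_cleavage_sites(protein, sp)
  peptides <- derive_mature_peptides(protein, sp, sites,
                                     min_pep_aa = config$min_pep_aa,
                                     max_pep_aa = config$max_pep_aa)
  rep_motif <- discover_repeat_motif(peptides, min_freq = config$motif_min_freq)
  if (nrow(peptides)) {
    peptides$motif_label <- ifelse(rep_motif$assignments, rep_motif$motif, "")
  }
  a <- structure(list(
    protein_id = id,
    length_aa = nchar(protein),
    protein = protein,
    sp = sp,
    sites = sites,
    peptides = peptides,
    motif = rep_motif$motif,
    copy_number = rep_motif$copy_number,
    is_candidate = FALSE,
    evidence = "none",
    family = "",
    tier = ""), class = "pnp_annotation")
  a$is_candidate <- is_candidate_precursor(a)
  a
}

#' Candidate-precursor decision rule
#'
#' A protein is called a de-novo candidate precursor when it has a predicted
#' signal peptide and at least one of: (1) two or more amidated peptides
#' sharing a C-terminal motif; (2) three or more peptides flanked by
#' cleavage sites; (3) a peptide with four or more cysteines (insulin-like
#' disulfide-rich architecture).
#'
#' @param a A `pnp_annotation` object.
#' @return Logical.
#' @export
is_candidate_precursor <- function(a) {
  stopifnot(inherits(a, "pnp_annotation"))
  if (!isTRUE(a$sp$present)) return(FALSE)
  p <- a$peptides
  if (!nrow(p)) return(FALSE)
  clause_motif <- nzchar(a$motif) && a$copy_number >= 2L &&
    all(p$amidated[nzchar(p$motif_label)])
  n_flanked <- sum(flanked_by_sites(a))
  clause_multi <- n_flanked >= 3L
  clause_cys <- any(p$cys_count >= 4L)
  clause_motif || clause_multi || clause_cys
}

# which peptides have a cleavage site (or the SP cleavage point) at their
# left boundary and a cleavage site at their right boundary
flanked_by_sites <- function(a) {
  p <- a$peptides
  if (!nrow(p)) return(logical())
  cuts <- a$sites$cleave_after
  sp_end <- if (isTRUE(a$sp$present)) a$sp$cleave_after else 0L
  left_ok <- vapply(p$start, function(s)
    any(cuts < s) || (sp_end > 0L && sp_end < s), logical(1L))
  right_ok <- vapply(p$end, function(e) any(cuts > e), logical(1L))
  left_ok & right_ok
}

#' @export
print.pnp_annotation <- function(x, ...) {
  cat(sprintf("<pnp_annotation> %s (%d aa)\n", x$protein_id, x$length_aa))
  print(x$sp)
  cat(sprintf("cleavage sites: %d (%d dibasic, %d monobasic)\n",
              nrow(x$sites), sum(x$sites$kind == "dibasic"),
              sum(x$sites$kind == "monobasic")))
  cat(sprintf("mature peptides: %d (%d amidated)\n", nrow(x$peptides),
              sum(x$peptides$amidated)))
  if (nzchar(x$motif)) {
    cat(sprintf("repeat motif: %s x %d copies\n", x$motif, x$copy_number))
  }
  cat("candidate:", x$is_candidate)
  if (x$evidence != "none") cat("  evidence:", x$evidence)
  if (nzchar(x$family)) cat("  family:", x$family, " tier:", x$tier)
  cat("\n")
  invisible(x)
}

#' Tabulate an annotation as a per-feature report
#'
#' One row per feature (signal peptide, cleavage site, mature peptide) with
#' 1-based inclusive protein coordinates, the layout used by the TSV report.
#'
#' @param x A `pnp_annotation`.
#' @param ... Unused.
#' @return Data frame with columns `protein_id`, `feature`, `start`, `end`,
#'   `kind`, `seq`, `amidated`, `pyroglu`.
#' @export
as.data.frame.pnp_annotation <- function(x, ...) {
  rows <- list()
  if (isTRUE(x$sp$present)) {
    rows[[1L]] <- data.frame(protein_id = x$protein_id, feature = "SP",
                             start = 1L, end = x$sp$cleave_after, kind = "",
                             seq = substr(x$protein, 1L, x$sp$cleave_after),
                             amidated = FALSE, pyroglu = FALSE,
                             stringsAsFactors = FALSE)
  }
  if (nrow(x$sites)) {
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = x$protein_id, feature = "site",
      start = x$sites$cleave_after, end = x$sites$cleave_after,
      kind = x$sites$kind, seq = x$sites$motif,
      amidated = FALSE, pyroglu = FALSE, stringsAsFactors = FALSE)
  }
  if (nrow(x$peptides)) {
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = x$protein_id, feature = "peptide",
      start = x$peptides$start, end = x$peptides$end,
      kind = x$peptides$motif_label, seq = x$peptides$processed_seq,
      amidated = x$peptides$amidated, pyroglu = x$peptides$pyroglu,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(protein_id = character(), feature = character(),
                      start = integer(), end = integer(), kind = character(),
                      seq = character(), amidated = logical(),
                      pyroglu = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Annotate a whole protein set
#'
#' @param proteins Data frame with `id` and `sequence` columns.
#' @param config Threshold list from [pnp_config()].
#' @return Named list of `pnp_annotation` objects.
#' @export
annotate_proteome <- function(proteins, config = pnp_config()) {
  anns <- lapply(seq_len(nrow(proteins)), function(i)
    annotate_precursor(proteins$sequence[i], proteins$id[i], config))
  names(anns) <- proteins$id
  anns
}
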