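#' Run the full precursor discovery and prioritisation screen
#'
#' Composes the pipeline end-to-end: transcripts are translated to their
#' longest ORFs (or a protein set is used directly), every protein is
#' annotated by the prohormone-processing rules, the de-novo candidate calls
#' are merged with the homology screen against the query panel into evidence
#' classes, the union is classified against the family catalog and tallied
#' by phylogenetic tier, and (when an FPKM matrix is supplied) the
#' stage-expression screen flags settlement candidates.
#'
#' @param proteins FASTA-style data frame of proteins, or NULL to derive
#'   proteins from `transcripts`.
#' @param transcripts FASTA-style data frame of transcripts (used when
#'   `proteins` is NULL).
#' @param panel Query-panel FASTA data frame.
#' @param catalog A `family_catalog`, or NULL to skip classification.
#' @param fpkm An `expression_matrix`, or NULL to skip the expression screen.
#' @param config A [pnp_config()] list.
#' @param out_dir Output directory for the TSV reports and manifest, or NULL
#'   to skip writing.
#' @return Object of class `pnp_screen` with `annotations` (precursors in
#'   the evidence union), `evidence`, `tally_evidence`, `tier_tally`,
#'   `hits`, `screen` (candidate table), `candidates` (gene ids), `config`.
#' @export
run_screen <- function(proteins = NULL, transcripts = NULL, panel = NULL,
                       catalog = NULL, fpkm = NULL, config = pnp_config(),
                       out_dir = NULL) {
  if (is.null(proteins)) {
    if (is.null(transcripts)) stop("supply proteins or transcripts")
    if (!nrow(transcripts)) stop("empty transcript set")
    orfs <- find_orfs_all(transcripts, min_orf_aa = config$min_orf_aa,
                          longest_only = TRUE)
    if (!nrow(orfs)) stop("no ORFs found in transcripts")
    proteins <- data.frame(id = orfs$transcript_id, sequence = orfs$protein,
                           description = orfs$orf_id,
                           stringsAsFactors = FALSE)
  }
  if (!nrow(proteins)) stop("empty protein set")

  anns <- annotate_proteome(proteins, config)
  denovo <- names(anns)[vapply(anns, `[[`, TRUE, "is_candidate")]

  hits <- NULL
  homology <- character()
  if (!is.null(panel) && nrow(panel)) {
    hits <- search_translated(
      data.frame(orf_id = proteins$id, protein = proteins$sequence,
                 stringsAsFactors = FALSE),
      panel, evalue_max = config$evalue_max, config = config)
    homology <- unique(hits$target_id)
  }
  ev <- merge_evidence(denovo, homology)

  union_ids <- names(ev$evidence)
  precursors <- anns[union_ids]
  for (id in union_ids) precursors[[id]]$evidence <- ev$evidence[[id]]
  if (!is.null(catalog)) {
    precursors <- lapply(precursors, assign_family_and_tier, catalog = catalog,
                         min_identity = config$min_identity, config = config)
  }
  tier_tally <- if (!is.null(catalog)) tally_tiers(precursors) else NULL

  screen <- NULL
  candidates <- character()
  if (!is.null(fpkm)) {
    screen <- screen_candidates(fpkm, alpha = config$alpha,
                                p_adjust = config$p_adjust)
    candidates <- screen$gene[screen$candidate]
  }

  res <- structure(list(
    annotations = precursors, evidence = ev$evidence,
    tally_evidence = ev$tally, tier_tally = tier_tally, hits = hits,
    screen = screen, candidates = candidates, config = config),
    class = "pnp_screen")
  if (!is.null(out_dir)) write_screen_outputs(res, out_dir)
  res
}

# write the TSV reports plus a manifest of outputs and thresholds
write_screen_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feat <- do.call(rbind, lapply(res$annotations, as.data.frame))
  paths <- character()
  p <- file.path(out_dir, "annotations.tsv")
  write.table(feat, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  smry <- data.frame(
    protein_id = names(res$annotations),
    length_aa = vapply(res$annotations, `[[`, 0L, "length_aa"),
    sp = vapply(res$annotations, function(a) a$sp$present, TRUE),
    n_sites = vapply(res$annotations, function(a) nrow(a$sites), 0L),
    n_peptides = vapply(res$annotations, function(a) nrow(a$peptides), 0L),
    motif = vapply(res$annotations, `[[`, "", "motif"),
    copy_number = vapply(res$annotations, `[[`, 0L, "copy_number"),
    evidence = vapply(res$annotations, `[[`, "", "evidence"),
    family = vapply(res$annotations, `[[`, "", "family"),
    tier = vapply(res$annotations, `[[`, "", "tier"),
    stringsAsFactors = FALSE)
  p <- file.path(out_dir, "precursors.tsv")
  write.table(smry, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(res$hits)) {
    p <- file.path(out_dir, "hits.tsv")
    write_hit_table(res$hits, p)
    paths <- c(paths, p)
  }
  if (!is.null(res$screen)) {
    p <- file.path(out_dir, "candidates.tsv")
    write.table(res$screen, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- c(
    "# pnpscreen run manifest",
    paste0("outputs: ", paste(basename(paths), collapse = ", ")),
    paste0("config: ", paste(names(res$config), vapply(res$config, function(x)
      paste(x, collapse = ","), ""), sep = "=", collapse = "; ")))
  writeLines(manifest, file.path(out_dir, "MANIFEST.txt"))
  invisible(out_dir)
}

#' @export
print.pnp_screen <- function(x, ...) {
  cat("<pnp_screen>\n")
  cat(sprintf("precursors: %d (homology_only %d, denovo_only %d, both %d)\n",
              length(x$annotations), x$tally_evidence[["homology_only"]],
              x$tally_evidence[["denovo_only"]], x$tally_evidence[["both"]]))
  if (!is.null(x$tier_tally)) {
    cat("tier tally:\n")
    print(x$tier_tally)
  }
  if (!is.null(x$screen)) {
    cat(sprintf("expression: %d up ES->SL, %d settlement candidates\n",
                sum(x$screen$up_ES_SL), length(x$candidates)))
  }
  invisible(x)
}

#' @export
summary.pnp_screen <- function(object, ...) print(object)
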