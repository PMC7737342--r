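# Karlin-Altschul constants for gapped BLOSUM62 with 11/1 gap costs
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Karlin-Altschul expectation value
#'
#' E = K * m * n * exp(-lambda * S) with the conventional gapped BLOSUM62
#' (11,1) constants lambda = 0.267, K = 0.041.
#'
#' @param score Alignment score in matrix units.
#' @param m Query length (residues).
#' @param n Database size (total residues searched).
#' @return Expectation value.
#' @export
karlin_evalue <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

#' Screen translated ORFs against a query panel
#'
#' Smith-Waterman search of every ORF protein against every panel query,
#' with Karlin-Altschul E-values computed over the whole database (n = total
#' ORF residues). Hits with E <= `evalue_max` are retained; within each ORF
#' the best (lowest-E) hit is reported first.
#'
#' @param orfs Data frame with `orf_id` (or `id`) and `protein` (or
#'   `sequence`) columns.
#' @param queries Query panel: data frame with `id` and `sequence` columns
#'   ([read_fasta()] output).
#' @param evalue_max E-value cutoff (default 1e-5).
#' @param config [pnp_config()] list supplying gap penalties.
#' @return Data frame of hits: `query_id`, `target_id`, `score`, `evalue`,
#'   `q_start`, `q_end`, `t_start`, `t_end`.
#' @export
search_translated <- function(orfs, queries, evalue_max = 1e-5,
                              config = pnp_config()) {
  if (!nrow(queries)) stop("query panel is empty")
  empty <- data.frame(query_id = character(), target_id = character(),
                      score = numeric(), evalue = numeric(),
                      q_start = integer(), q_end = integer(),
                      t_start = integer(), t_end = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(orfs)) return(empty)
  tid <- if ("orf_id" %in% names(orfs)) orfs$orf_id else orfs$id
  tseq <- if ("protein" %in% names(orfs)) orfs$protein else orfs$sequence
  n_db <- sum(nchar(tseq))
  scores <- sw_score_matrix(setNames(queries$sequence, queries$id),
                            setNames(tseq, tid),
                            gap_open = config$gap_open,
                            gap_extend = config$gap_extend)
  qlen <- nchar(queries$sequence)
  ev <- sweep(exp(-KA_LAMBDA * scores) * KA_K * n_db, 1L, qlen, `*`)
  keep <- which(ev <= evalue_max, arr.ind = TRUE)
  if (!nrow(keep)) return(empty)
  hits <- lapply(seq_len(nrow(keep)), function(r) {
    qi <- keep[r, 1L]; ti <- keep[r, 2L]
    aln <- local_align(queries$sequence[qi], tseq[ti],
                       gap_open = config$gap_open,
                       gap_extend = config$gap_extend)
    data.frame(query_id = queries$id[qi], target_id = tid[ti],
               score = aln$score, evalue = ev[qi, ti],
               q_start = aln$a_span[1L], q_end = aln$a_span[2L],
               t_start = aln$b_span[1L], t_end = aln$b_span[2L],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, hits)
  res <- res[order(match(res$target_id, tid), res$evalue), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge de-novo and homology evidence into evidence classes
#'
#' @param denovo Character vector of protein ids passing the de-novo
#'   candidate rule.
#' @param homology Character vector of protein ids with panel hits.
#' @return List with `evidence` (named character vector over the union:
#'   `both`, `denovo_only`, `homology_only`) and `tally` (named integer
#'   vector; sums to the union size).
#' @export
merge_evidence <- function(denovo, homology) {
  denovo <- unique(denovo)
  homology <- unique(homology)
  ids <- sort(union(denovo, homology))
  ev <- ifelse(ids %in% denovo & ids %in% homology, "both",
               ifelse(ids %in% denovo, "denovo_only", "homology_only"))
  names(ev) <- ids
  tally <- c(homology_only = sum(ev == "homology_only"),
             denovo_only = sum(ev == "denovo_only"),
             both = sum(ev == "both"))
  list(evidence = ev, tally = tally)
}

#' Read / write a homology hit table
#' @param hits Hit data frame from [search_translated()].
#' @param path TSV path.
#' @return The data frame (read) or `path` invisibly (write).
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
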