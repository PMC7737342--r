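# BLOSUM62 from Biostrings, loaded once per session
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# map an amino-acid string to 0-based indices into the matrix rows;
# residues absent from the matrix become X
encode_aa <- function(s, rows) {
  aa <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  idx <- match(aa, rows)
  idx[is.na(idx)] <- match("X", rows)
  idx - 1L
}

#' Optimal local alignment of two protein sequences
#'
#' Exact affine-gap Smith-Waterman (Gotoh). A gap of length k costs
#' `gap_open + k * gap_extend`. Unknown residues are treated as X.
#'
#' @param a,b Amino-acid strings.
#' @param matrix Substitution matrix (residues x residues); default BLOSUM62.
#' @param gap_open,gap_extend Gap penalties (defaults 11 and 1, the
#'   conventional BLOSUM62 gapped parameters).
#' @return List with `score`, `a_span`, `b_span` (1-based inclusive aligned
#'   spans, `c(0, 0)` when the best score is 0), `a_aln`, `b_aln` (aligned
#'   strings with `-` gaps) and `identity` (identical positions / alignment
#'   length, NA for an empty alignment).
#' @export
local_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                        gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  rows <- rownames(matrix)
  res <- .sw_align_cpp(encode_aa(a, rows), encode_aa(b, rows),
                       matrix, gap_open, gap_extend, TRUE)
  decode <- function(v) {
    ch <- rep("-", length(v))
    ch[v >= 0L] <- rows[v[v >= 0L] + 1L]
    paste(ch, collapse = "")
  }
  a_aln <- decode(res$a_aln)
  b_aln <- decode(res$b_aln)
  ident <- if (nchar(a_aln)) {
    av <- strsplit(a_aln, "", fixed = TRUE)[[1L]]
    bv <- strsplit(b_aln, "", fixed = TRUE)[[1L]]
    mean(av == bv & av != "-")
  } else NA_real_
  list(score = res$score, a_span = res$a_span, b_span = res$b_span,
       a_aln = a_aln, b_aln = b_aln, identity = ident)
}

# batched score-only screen: returns queries x targets matrix of SW scores
sw_score_matrix <- function(queries, targets, matrix = blosum62(),
                            gap_open = 11, gap_extend = 1) {
  rows <- rownames(matrix)
  q <- lapply(queries, encode_aa, rows = rows)
  t <- lapply(targets, encode_aa, rows = rows)
  m <- .sw_score_matrix_cpp(q, t, matrix, gap_open, gap_extend)
  dimnames(m) <- list(names(queries), names(targets))
  m
}
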