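#' Discover a shared C-terminal peptide motif
#'
#' Repetitive prohormones carry many peptide copies with a conserved
#' C-terminal motif (e.g. FRWamide). Over the amidated peptides' last three
#' processed residues, per-position residue frequencies are tabulated;
#' positions dominated by a single residue at frequency >= `min_freq` are
#' fixed, others become the wildcard `x`. The motif is reported only when at
#' least two peptides match it; `amide` is suffixed when the matching
#' peptides are amidated.
#'
#' @param peptides Data frame from [derive_mature_peptides()].
#' @param min_freq Per-position consensus frequency threshold (default 0.6).
#' @return List with `motif` (string, `""` when no repeat), `copy_number`
#'   (matching-peptide count; 1 when no motif) and `assignments` (logical
#'   vector over `peptides` rows flagging motif members).
#' @export
discover_repeat_motif <- function(peptides, min_freq = 0.6) {
  none <- list(motif = "", copy_number = if (nrow(peptides)) 1L else 0L,
               assignments = rep(FALSE, nrow(peptides)))
  if (!nrow(peptides)) return(none)
  cand <- which(peptides$amidated & nchar(peptides$processed_seq) >= 3L &
                  !grepl("X", peptides$processed_seq, fixed = TRUE))
  if (length(cand) < 2L) return(none)
  tails <- substr(peptides$processed_seq[cand],
                  nchar(peptides$processed_seq[cand]) - 2L,
                  nchar(peptides$processed_seq[cand]))
  cols <- do.call(rbind, strsplit(tails, "", fixed = TRUE))
  pat <- vapply(1:3, function(j) {
    tab <- table(cols[, j]) / nrow(cols)
    top <- names(tab)[which.max(tab)]
    if (max(tab) >= min_freq) top else "x"
  }, "")
  if (all(pat == "x")) return(none)
  matches <- vapply(seq_len(nrow(cols)), function(i)
    all(pat == "x" | pat == cols[i, ]), logical(1L))
  if (sum(matches) < 2L) return(none)
  motif <- paste0(paste(pat, collapse = ""), "amide")
  assignments <- rep(FALSE, nrow(peptides))
  assignments[cand[matches]] <- TRUE
  list(motif = motif, copy_number = sum(matches), assignments = assignments)
}

#' Build a C-terminally aligned residue-frequency (logo) matrix
#'
#' Peptides are right-aligned; shorter peptides are left-padded with a gap
#' symbol that is excluded from the frequencies, so every column sums to 1
#' over the residues present.
#'
#' @param peptides Character vector of peptide sequences (>= 2), or a
#'   [derive_mature_peptides()] data frame (its `processed_seq` is used).
#' @param width Number of C-terminal columns to report (>= 1).
#' @return Numeric matrix, residues x `width` positions; columns sum to 1.
#' @export
build_logo_matrix <- function(peptides, width) {
  if (is.data.frame(peptides)) peptides <- peptides$processed_seq
  if (length(peptides) < 2L) stop("need at least 2 peptides")
  if (!is.numeric(width) || width < 1L) stop("width must be >= 1")
  width <- as.integer(width)
  maxlen <- max(max(nchar(peptides)), width)
  padded <- vapply(peptides, function(p)
    paste0(strrep("-", maxlen - nchar(p)), p), "", USE.NAMES = FALSE)
  cols <- do.call(rbind, strsplit(padded, "", fixed = TRUE))
  cols <- cols[, seq.int(maxlen - width + 1L, maxlen), drop = FALSE]
  residues <- sort(setdiff(unique(as.vector(cols)), "-"))
  mat <- matrix(0, nrow = length(residues), ncol = width,
                dimnames = list(residues, paste0("p", seq_len(width))))
  for (j in seq_len(width)) {
    obs <- cols[, j]
    obs <- obs[obs != "-"]
    if (length(obs)) {
      tab <- table(obs) / length(obs)
      mat[names(tab), j] <- as.numeric(tab)
    }
  }
  mat
}
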