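#' Read a FASTA file into a data frame
#'
#' Reads nucleotide or amino-acid FASTA (wrapped or unwrapped). Record ids are
#' taken as the header up to the first whitespace; the remainder becomes the
#' description. Nucleotide sequences are uppercased and U is mapped to T.
#'
#' @param path Path to a FASTA file.
#' @param type `"nt"` for nucleotide (default) or `"aa"` for protein.
#' @return A data frame with columns `id`, `sequence`, `description`.
#' @export
read_fasta <- function(path, type = c("nt", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA header with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1L])
  seqs <- toupper(as.character(set))
  if (type == "nt") seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence in ", path)
  data.frame(id = ids, sequence = unname(seqs), description = desc,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x Data frame with columns `id`, `sequence` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  desc <- if ("description" %in% names(x)) x$description else rep("", nrow(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(desc[i])) paste(x$id[i], desc[i]) else x$id[i]
    writeLines(paste0(">", hdr), con)
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#' @param x A nucleotide string (A/C/G/T/N).
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""), "",
    USE.NAMES = FALSE))
}

# translate one nucleotide string in frame 0; N-containing codons become X;
# stop codons become "*"
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find open reading frames in a transcript
#'
#' Scans all six frames for maximal ATG-to-stop ORFs (one ORF per stop codon,
#' starting at the 5'-most ATG after the previous in-frame stop). ORFs that
#' run off the 3' end without a stop are reported with `incomplete = TRUE`.
#' Coordinates are 1-based inclusive on the input (plus) strand for both
#' strands; the strand is stored separately.
#'
#' @param transcript A single row of a [read_fasta()] data frame, or a list
#'   with elements `id` and `sequence`.
#' @param min_orf_aa Minimum protein length in residues (default 50, >= 10).
#' @return A data frame with columns `transcript_id`, `strand`, `frame`,
#'   `nt_start`, `nt_end`, `aa_len`, `protein`, `incomplete`, sorted by
#'   decreasing protein length.
#' @export
find_orfs <- function(transcript, min_orf_aa = 50L) {
  stopifnot(min_orf_aa >= 10L)
  id <- transcript$id
  seq <- toupper(transcript$sequence)
  len <- nchar(seq)
  out <- list()
  if (len >= 3L * min_orf_aa) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp(seq)
      for (frame in 0:2) {
        sub <- substr(s, frame + 1L, len)
        ncod <- nchar(sub) %/% 3L
        if (ncod < min_orf_aa) next
        aa <- strsplit(translate_nt(sub), "", fixed = TRUE)[[1L]]
        stops <- which(aa == "*")
        starts <- which(aa == "M")
        prev_stop <- 0L
        bounds <- c(stops, length(aa) + 1L)  # sentinel: 3'-open segment
        for (st in bounds) {
          cand <- starts[starts > prev_stop & starts < st]
          if (length(cand)) {
            a0 <- cand[1L]
            prot <- paste(aa[a0:(st - 1L)], collapse = "")
            incomplete <- st > length(aa)
            if (nchar(prot) >= min_orf_aa) {
              # codon span on the working strand; stop codon excluded so the
              # span translates exactly to `protein`
              c_start <- frame + 3L * (a0 - 1L) + 1L
              c_end <- frame + 3L * (st - 1L)
              if (strand == "+") {
                nt_start <- c_start; nt_end <- c_end
              } else {
                nt_start <- len - c_end + 1L; nt_end <- len - c_start + 1L
              }
              out[[length(out) + 1L]] <- data.frame(
                transcript_id = id, strand = strand, frame = frame,
                nt_start = nt_start, nt_end = nt_end,
                aa_len = nchar(prot), protein = prot,
                incomplete = incomplete, stringsAsFactors = FALSE)
            }
          }
          prev_stop <- st
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), nt_start = integer(),
                      nt_end = integer(), aa_len = integer(),
                      protein = character(), incomplete = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(-res$aa_len, res$strand, res$frame, res$nt_start), , drop = FALSE]
}

#' Extract ORFs from every transcript in a set
#'
#' @param transcripts Data frame from [read_fasta()].
#' @param min_orf_aa Minimum protein length (default 50).
#' @param longest_only Keep only the longest ORF per transcript (default
#'   TRUE), the convention downstream annotation uses.
#' @return Combined ORF data frame with an `orf_id` column
#'   (`<transcript_id>|<strand><frame>|<nt_start>`).
#' @export
find_orfs_all <- function(transcripts, min_orf_aa = 50L, longest_only = TRUE) {
  pieces <- lapply(seq_len(nrow(transcripts)), function(i) {
    o <- find_orfs(transcripts[i, ], min_orf_aa = min_orf_aa)
    if (nrow(o) && longest_only) o <- o[1L, , drop = FALSE]
    o
  })
  res <- do.call(rbind, pieces)
  if (is.null(res) || !nrow(res)) {
    res <- find_orfs(list(id = "x", sequence = ""), min_orf_aa = min_orf_aa)
  }
  res$orf_id <- paste0(res$transcript_id, "|", res$strand, res$frame, "|",
                       res$nt_start)
  res
}
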