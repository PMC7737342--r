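# Independent oracles used by unit and acceptance tests. They are written
# as direct transcriptions of the documented rules, structured differently
# from the package implementations (character-by-character scans and
# exhaustive enumeration instead of rle/dynamic programming).

# Brute-force cleavage-site oracle: left-to-right scan. Runs of >= 2 basic
# residues cut after the last residue of the run; an isolated R cuts when a
# basic residue sits at -3, -5 or -7 and the cut is at least `min_spacing`
# residues after the previous cut.
oracle_cleavage <- function(protein, from = 0L, min_spacing = 4L) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  basic <- aa %in% c("K", "R")
  pos <- integer()
  kind <- character()
  motif <- character()
  prev <- from
  i <- 1L
  while (i <= n) {
    if (!basic[i]) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && basic[j + 1L]) j <- j + 1L
    if (j > i) {
      if (j > from) {
        pos <- c(pos, j)
        kind <- c(kind, "dibasic")
        motif <- c(motif, paste0(aa[j - 1L], aa[j]))
        prev <- j
      }
    } else if (i > from && aa[i] == "R" && i - prev >= min_spacing) {
      back <- i - c(3L, 5L, 7L)
      back <- back[back >= 1L]
      if (length(back) && any(basic[back])) {
        pos <- c(pos, i)
        kind <- c(kind, "monobasic")
        motif <- c(motif, "R")
        prev <- i
      }
    }
    i <- j + 1L
  }
  data.frame(cleave_after = pos, kind = kind, motif = motif,
             stringsAsFactors = FALSE)
}

# Exhaustive affine-gap local alignment: recursively enumerates every
# alignment path (no dynamic programming). A gap of length k costs
# open + k * ext. Optimal local alignments start and end with an aligned
# residue pair, so enumeration starts from every (i, j) match column.
# Feasible only for short sequences.
oracle_local_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  m <- length(av)
  n <- length(bv)
  best <- 0
  rec <- function(i, j, score, state) {
    if (score > best) best <<- score
    if (i < m && j < n) {
      rec(i + 1L, j + 1L, score + mat[av[i + 1L], bv[j + 1L]], "M")
    }
    if (i < m) {
      rec(i + 1L, j, score - ext - if (state != "X") open else 0, "X")
    }
    if (j < n) {
      rec(i, j + 1L, score - ext - if (state != "Y") open else 0, "Y")
    }
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      rec(i, j, mat[av[i], bv[j]], "M")
    }
  }
  best
}

# Biostrings local alignment score with the same gap convention
# (gap of length k costs gapOpening + k * gapExtension).
biostrings_local_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = e$BLOSUM62,
    gapOpening = gap_open, gapExtension = gap_extend)))
}

# all strings of lengths 1..max_len over an alphabet
enumerate_strings <- function(alphabet, max_len) {
  out <- character()
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), L),
                      list(stringsAsFactors = FALSE)))
    out <- c(out, do.call(paste0, grid))
  }
  out
}

# brute-force average-linkage clustering oracle: merges the closest pair of
# clusters under the mean of all pairwise distances, returning merge heights
avg_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}
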