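# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

# residues allowed at the -1 and -3 positions of the signal-peptidase site
SP_MINUS1 <- c("A", "G", "S", "C", "T")
SP_MINUS3 <- c("A", "G", "S", "C", "T", "V", "L", "I")

#' Predict an N-terminal signal peptide
#'
#' Deterministic two-part heuristic standing in for neural-network signal
#' peptide predictors. A signal peptide is called when (a) an h-region
#' exists: a window of at least `h_min_len` residues within positions
#' 2..`h_search_end`, free of D/E/K/R, with mean Kyte-Doolittle hydropathy at
#' least `h_min_hydropathy`; and (b) a c-site exists: the smallest position p in
#' `c_range`, beyond the end of the best-scoring h-window, whose residue is
#' small/neutral (A,G,S,C,T) and whose p-2 residue is in the extended
#' (-3)-position set (A,G,S,C,T,V,L,I) -- the von-Heijne (-3,-1) rule.
#' Cleavage is after residue p.
#'
#' @param protein Amino-acid string (length >= 30 for a call to be possible).
#' @param h_min_len Minimum h-region window length (residues, default 7).
#' @param h_min_hydropathy Minimum mean window hydropathy (default 2.0).
#' @param h_search_end Last residue considered for the h-region (default 30).
#' @param c_range Two-element integer vector: allowed cleavage positions
#'   (default `c(15, 40)`).
#' @return A list of class `sp_call`: `present`, `cleave_after` (0 if
#'   absent), `h_region_score` (mean hydropathy of the best window, NA if
#'   none), `c_site_ok`, and `note`.
#' @export
predict_signal_peptide <- function(protein, h_min_len = 7L,
                                   h_min_hydropathy = 2.0,
                                   h_search_end = 30L,
                                   c_range = c(15L, 40L)) {
  out <- structure(list(present = FALSE, cleave_after = 0L,
                        h_region_score = NA_real_, c_site_ok = FALSE,
                        note = ""), class = "sp_call")
  n <- nchar(protein)
  if (n < 30L) {
    out$note <- "too short"
    return(out)
  }
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  kd <- KD_SCALE[aa]
  kd[is.na(kd)] <- 0
  charged <- aa %in% c("D", "E", "K", "R")

  # best h-window: maximal mean hydropathy over qualifying windows of any
  # length >= h_min_len; ties resolved to the earliest, then shortest window
  last <- min(h_search_end, n)
  best_score <- -Inf
  best_end <- 0L
  for (i in 2L:(last - h_min_len + 1L)) {
    if (i > last - h_min_len + 1L) break
    for (j in (i + h_min_len - 1L):last) {
      if (any(charged[i:j])) break  # charged residue ends every window at i
      m <- mean(kd[i:j])
      if (m >= h_min_hydropathy && m > best_score + 1e-12) {
        best_score <- m
        best_end <- j
      }
    }
  }
  if (!is.finite(best_score)) {
    out$note <- "no h-region"
    return(out)
  }
  out$h_region_score <- best_score

  p_lo <- max(c_range[1L], best_end + 1L)
  p_hi <- min(c_range[2L], n)
  if (p_lo <= p_hi) {
    for (p in p_lo:p_hi) {
      if (aa[p] %in% SP_MINUS1 && aa[p - 2L] %in% SP_MINUS3) {
        out$present <- TRUE
        out$c_site_ok <- TRUE
        out$cleave_after <- p
        break
      }
    }
  }
  if (!out$present) out$note <- "no c-site"
  out
}

#' @export
print.sp_call <- function(x, ...) {
  if (x$present) {
    cat(sprintf("signal peptide: residues 1-%d (h-score %.2f)\n",
                x$cleave_after, x$h_region_score))
  } else {
    cat("signal peptide: absent", if (nzchar(x$note)) paste0(" (", x$note, ")"),
        "\n", sep = "")
  }
  invisible(x)
}
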