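#' Scan a precursor for prohormone-convertase cleavage sites
#'
#' Scans the region C-terminal to the signal peptide. Every run of two or
#' more basic residues (K/R) yields a single dibasic site cut after the last
#' residue of the run (rightmost-cut convention, so overlapping pairs such as
#' KRR give one cut); the site motif is the last two residues of the run. An
#' isolated arginine is accepted as a monobasic site only when another basic
#' residue lies at relative position -3, -5 or -7 (the helical spacing
#' characteristic of processed precursors); isolated lysines are never cut.
#' A monobasic site closer than `min_spacing` residues to the preceding cut
#' (or to the signal-peptide cleavage point) is suppressed: it would excise
#' a sub-minimal fragment, and single arginines that close to a processing
#' site are part of the released peptide (e.g. the R of an FRWamide motif
#' three residues after its upstream dibasic flank).
#'
#' @param protein Amino-acid string.
#' @param sp A [predict_signal_peptide()] call, or NULL; scanning starts
#'   after `sp$cleave_after`.
#' @param min_spacing Minimum distance (residues) between a monobasic cut
#'   and the preceding cut; default 4, one more than the minimum retained
#'   peptide length.
#' @return Data frame with columns `cleave_after` (1-based residue index;
#'   the bond after this residue is cut), `kind` (`dibasic`/`monobasic`)
#'   and `motif`, sorted ascending. Zero rows when no site exists.
#' @export
scan_cleavage_sites <- function(protein, sp = NULL, min_spacing = 4L) {
  from <- if (!is.null(sp) && isTRUE(sp$present)) sp$cleave_after else 0L
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  basic <- aa %in% c("K", "R")
  empty <- data.frame(cleave_after = integer(), kind = character(),
                      motif = character(), stringsAsFactors = FALSE)
  if (n == 0L || !any(basic)) return(empty)
  # maximal runs of basic residues, scanned left to right
  r <- rle(basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- empty
  prev_cut <- from
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    if (e <= from) next
    if (r$lengths[k] >= 2L) {
      out <- rbind(out, data.frame(
        cleave_after = e, kind = "dibasic",
        motif = paste0(aa[e - 1L], aa[e]), stringsAsFactors = FALSE))
      prev_cut <- e
    } else if (aa[s] == "R" && s - prev_cut >= min_spacing) {
      back <- s - c(3L, 5L, 7L)
      back <- back[back >= 1L]
      if (length(back) && any(basic[back])) {
        out <- rbind(out, data.frame(
          cleave_after = s, kind = "monobasic", motif = "R",
          stringsAsFactors = FALSE))
        prev_cut <- s
      }
    }
  }
  out[order(out$cleave_after), , drop = FALSE]
}

#' Derive mature peptides from a cleaved precursor
#'
#' Splits the precursor at the signal-peptide cleavage point and at every
#' cleavage site, strips flanking basic residues from each segment, and
#' applies post-translational modification rules: a stripped segment ending
#' in glycine that is followed by a cleavage site (or, for the terminal
#' segment, whose glycine preceded stripped basic residues) is amidated (the
#' glycine is removed and `amidated` set); an N-terminal glutamine flags
#' putative pyroglutamination. Segments whose processed sequence is shorter
#' than `min_pep_aa` or whose raw sequence exceeds `max_pep_aa` are dropped.
#'
#' @param protein Amino-acid string.
#' @param sp Signal-peptide call (may be absent).
#' @param sites Cleavage-site data frame from [scan_cleavage_sites()],
#'   sorted ascending.
#' @param min_pep_aa,max_pep_aa Retained peptide length bounds (defaults 3
#'   and 50 residues).
#' @return Data frame with columns `start`, `end` (1-based inclusive span of
#'   the raw peptide), `raw_seq`, `processed_seq`, `amidated`, `pyroglu`,
#'   `cys_count`, `motif_label` (filled later by motif discovery).
#' @export
derive_mature_peptides <- function(protein, sp = NULL, sites = NULL,
                                   min_pep_aa = 3L, max_pep_aa = 50L) {
  n <- nchar(protein)
  sp_end <- if (!is.null(sp) && isTRUE(sp$present)) sp$cleave_after else 0L
  all_cuts <- if (is.null(sites) || !nrow(sites)) integer() else
    sort(unique(sites$cleave_after))
  cuts <- all_cuts[all_cuts > sp_end & all_cuts < n]
  bounds <- unique(c(sp_end, cuts, n))
  empty <- data.frame(start = integer(), end = integer(),
                      raw_seq = character(), processed_seq = character(),
                      amidated = logical(), pyroglu = logical(),
                      cys_count = integer(), motif_label = character(),
                      stringsAsFactors = FALSE)
  if (sp_end >= n) return(empty)
  lefts <- bounds[-length(bounds)] + 1L
  rights <- bounds[-1L]
  out <- empty
  n_seg <- length(lefts)
  for (i in seq_len(n_seg)) {
    seg <- substr(protein, lefts[i], rights[i])
    aa <- strsplit(seg, "", fixed = TRUE)[[1L]]
    keep <- !(aa %in% c("K", "R"))
    if (!any(keep)) next
    first <- which(keep)[1L]
    last <- max(which(keep))
    start <- lefts[i] + first - 1L
    end <- lefts[i] + last - 1L
    raw <- substr(protein, start, end)
    # non-terminal segments end at a cut; the terminal segment counts as
    # site-followed only when its stripped basics form an actual site
    followed_by_site <- i < n_seg || any(all_cuts > end)
    amidated <- followed_by_site && substr(raw, nchar(raw), nchar(raw)) == "G"
    processed <- if (amidated) substr(raw, 1L, nchar(raw) - 1L) else raw
    if (nchar(processed) < min_pep_aa || nchar(raw) > max_pep_aa) next
    out <- rbind(out, data.frame(
      start = start, end = end, raw_seq = raw, processed_seq = processed,
      amidated = amidated,
      pyroglu = substr(raw, 1L, 1L) == "Q",
      cys_count = lengths(regmatches(processed, gregexpr("C", processed,
                                                         fixed = TRUE))),
      motif_label = "", stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Does a mature peptide carry a cysteine stretch?
#'
#' TRUE when the processed sequence contains at least two cysteines, i.e.
#' at least one putative disulfide linkage (an even count is not required;
#' pairing is putative).
#'
#' @param peptide A row of [derive_mature_peptides()] output, or a list with
#'   a `processed_seq` element, or a plain amino-acid string.
#' @return Logical.
#' @export
detect_cys_stretch <- function(peptide) {
  s <- if (is.character(peptide)) peptide else peptide$processed_seq
  vapply(s, function(x)
    lengths(regmatches(x, gregexpr("C", x, fixed = TRUE))) >= 2L,
    logical(1L), USE.NAMES = FALSE)
}
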