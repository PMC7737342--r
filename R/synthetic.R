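# run expr under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# residue pools: peptide bodies avoid K/R (no spurious cleavage), C (no
# spurious disulfide clause) and X; motif positions likewise avoid G
PEP_BODY_AA <- c("A", "S", "N", "Q", "D", "E", "P", "T", "H", "Y", "F",
                 "L", "I", "V", "M", "W", "G")
MOTIF_AA <- c("F", "W", "L", "I", "M", "Y", "H", "V", "N", "Q")
X_FILL_AA <- c("S", "N", "T", "D")  # cycled at wildcard motif positions

# a signal peptide of exactly sp_len residues that the h-region/(-3,-1)
# heuristic resolves at exactly sp_len: M + hydrophobic core + PPVNA cap
make_signal_peptide <- function(sp_len) {
  stopifnot(sp_len >= 15L, sp_len <= 40L)
  core <- sample(c("L", "I", "V", "F"), sp_len - 6L, replace = TRUE)
  paste(c("M", core, "P", "P", "V", "N", "A"), collapse = "")
}

# one planted multi-copy precursor; motif3 may contain "x" wildcards
make_precursor <- function(sp_len, copies, motif3, pep_len_range = c(4L, 20L),
                           with_sp = TRUE) {
  pat <- strsplit(motif3, "", fixed = TRUE)[[1L]]
  stopifnot(length(pat) == 3L)
  peptides <- character(copies)
  for (k in seq_len(copies)) {
    tail3 <- ifelse(pat == "x",
                    X_FILL_AA[(k - 1L) %% length(X_FILL_AA) + 1L], pat)
    plen <- sample(seq(pep_len_range[1L], pep_len_range[2L]), 1L)
    plen <- max(plen, 4L)
    body <- sample(PEP_BODY_AA, plen - 3L, replace = TRUE)
    peptides[k] <- paste(c(body, tail3), collapse = "")
  }
  leader <- if (with_sp) {
    make_signal_peptide(sp_len)
  } else {
    # same length, but acidic/polar: no h-region, hence no signal peptide
    paste(c("M", sample(c("D", "E", "S", "N", "Q"), sp_len - 1L,
                        replace = TRUE)), collapse = "")
  }
  protein <- paste0(leader,
                    paste(paste0(peptides, "G", "KR"), collapse = ""))
  list(protein = protein, peptides = peptides,
       motif = paste0(motif3, "amide"))
}

#' Dipeptide-preserving sequence shuffles
#'
#' Two decoy constructions that preserve dipeptide composition. The default
#' `"tile"` method keeps the initial residue, cuts the remainder into
#' non-overlapping dipeptide tiles (plus a possible terminal singleton) and
#' permutes the tiles: residue and non-overlapping dipeptide composition are
#' preserved while longer-range architecture (hydrophobic runs, basic-site
#' junctions) is destroyed, which is what makes a usable negative control.
#' The `"eulerian"` method is an Altschul-Erickson shuffle preserving the
#' full multiset of overlapping dipeptides (first and last residue fixed);
#' note that for tandem-repeat prohormones the overlapping-dipeptide
#' transitions nearly determine the sequence, so Eulerian shuffles retain
#' most of the diagnostic precursor architecture and are not suitable
#' negatives (see the package vignette).
#'
#' @param seq Amino-acid string.
#' @param method `"tile"` (default) or `"eulerian"`.
#' @return A shuffled string of the same length and residue composition.
#' @export
dipeptide_shuffle <- function(seq, method = c("tile", "eulerian")) {
  method <- match.arg(method)
  if (method == "tile") tile_shuffle(seq) else eulerian_shuffle(seq)
}

# non-overlapping dipeptide tile permutation; first residue fixed
tile_shuffle <- function(seq) {
  n <- nchar(seq)
  if (n < 4L) return(seq)
  body <- substr(seq, 2L, n)
  m <- nchar(body)
  starts <- seq(1L, m, by = 2L)
  tiles <- substring(body, starts, pmin(starts + 1L, m))
  paste0(substr(seq, 1L, 1L),
         paste(tiles[sample.int(length(tiles))], collapse = ""))
}

# Altschul-Erickson Eulerian-path shuffle: preserves the multiset of
# overlapping dipeptides exactly, first and last residue fixed
eulerian_shuffle <- function(seq, max_tries = 1000L) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  if (n < 3L) return(seq)
  verts <- unique(aa)
  vi <- match(aa, verts)
  nv <- length(verts)
  adj <- split(vi[-1L], vi[-n])  # out-edges per source vertex
  src <- as.integer(names(adj))
  last_v <- vi[n]
  for (try in seq_len(max_tries)) {
    # choose a random "last edge" per vertex (except the terminal vertex)
    last_edge <- rep(NA_integer_, nv)
    for (i in seq_along(src)) {
      v <- src[i]
      if (v != last_v) last_edge[v] <- adj[[i]][sample.int(length(adj[[i]]), 1L)]
    }
    # the chosen edges must form an arborescence into the terminal vertex
    ok <- TRUE
    for (v in seq_len(nv)) {
      if (v == last_v || is.na(last_edge[v])) next
      seen <- logical(nv)
      w <- v
      while (w != last_v && !is.na(last_edge[w]) && !seen[w]) {
        seen[w] <- TRUE
        w <- last_edge[w]
      }
      if (w != last_v) { ok <- FALSE; break }
    }
    if (!ok) next
    # random order for the remaining edges, chosen last edge at the end
    walk_adj <- vector("list", nv)
    for (i in seq_along(src)) {
      v <- src[i]
      e <- adj[[i]]
      if (!is.na(last_edge[v])) {
        pos <- which(e == last_edge[v])[1L]
        e <- e[-pos]
      }
      e <- if (length(e)) e[sample.int(length(e))] else integer()
      if (!is.na(last_edge[v])) e <- c(e, last_edge[v])
      walk_adj[[v]] <- e
    }
    out <- integer(n)
    out[1L] <- vi[1L]
    ptr <- integer(nv)
    v <- vi[1L]
    for (k in 2:n) {
      ptr[v] <- ptr[v] + 1L
      w <- walk_adj[[v]][ptr[v]]
      out[k] <- w
      v <- w
    }
    return(paste(verts[out], collapse = ""))
  }
  seq  # arborescence sampling failed; return the input unchanged
}

# random protein of given length starting with M
random_protein <- function(len) {
  pool <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
  # roughly uniform composition; mildly hydrophilic like real spacers
  paste(c("M", sample(pool, len - 1L, replace = TRUE)), collapse = "")
}

# reverse-translate a protein (random synonymous codons) into an
# ATG..stop ORF embedded between random UTRs
embed_transcript <- function(protein, utr5 = NULL, utr3 = NULL) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  codons <- vapply(aa, function(a) {
    ch <- by_aa[[a]]
    ch[sample.int(length(ch), 1L)]
  }, "", USE.NAMES = FALSE)
  codons[1L] <- "ATG"
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  if (is.null(utr5)) utr5 <- paste(sample(c("A", "C", "G", "T"),
                                          sample(20:80, 1L), replace = TRUE),
                                   collapse = "")
  if (is.null(utr3)) utr3 <- paste(sample(c("A", "C", "G", "T"),
                                          sample(20:80, 1L), replace = TRUE),
                                   collapse = "")
  paste0(utr5, paste(codons, collapse = ""), stop_codon, utr3)
}

#' Generate a planted-truth proteome and transcriptome
#'
#' Plants `n_precursors` multi-copy prohormones -- a signal peptide the
#' package's own heuristic resolves exactly, peptide copies flanked by KR
#' dibasic sites, trailing glycines on the amidated copies, and a shared
#' C-terminal motif -- among composition-matched decoys (dipeptide-preserving
#' shuffles of the planted precursors plus random proteins, in equal parts).
#' Every protein is also embedded as an ATG..stop ORF in a transcript with
#' random UTRs.
#'
#' @param seed Integer seed; outputs are byte-identical for equal seeds.
#' @param n_precursors Number of planted precursors (default 20).
#' @param n_decoys Number of decoy proteins (default 100).
#' @param arch_ranges List with `sp_len`, `copies`, `pep_len` two-element
#'   ranges (defaults 15-40, 2-15, 4-20).
#' @param sp_len_pool Optional vector of signal-peptide lengths to sample
#'   from instead of the `sp_len` range.
#' @return List with `proteins` and `transcripts` (FASTA-style data frames),
#'   `truth` (per-protein data frame: `id`, `kind`, `sp_len`, `copies`,
#'   `motif`, `peptide_seqs`) and `seed`.
#' @export
gen_truth_set <- function(seed, n_precursors = 20L, n_decoys = 100L,
                          arch_ranges = list(sp_len = c(15L, 40L),
                                             copies = c(2L, 15L),
                                             pep_len = c(4L, 20L)),
                          sp_len_pool = NULL) {
  rng_ok <- arch_ranges$sp_len[1L] >= 15L && arch_ranges$sp_len[2L] <= 40L &&
    arch_ranges$copies[1L] >= 2L && arch_ranges$copies[2L] <= 15L &&
    arch_ranges$pep_len[1L] >= 4L && arch_ranges$pep_len[2L] <= 20L &&
    all(vapply(arch_ranges, function(r) r[1L] <= r[2L], logical(1L)))
  if (!rng_ok) stop("impossible arch_ranges")
  with_seed(seed, {
    planted <- vector("list", n_precursors)
    truth <- vector("list", n_precursors)
    for (i in seq_len(n_precursors)) {
      L <- if (!is.null(sp_len_pool)) sample(sp_len_pool, 1L) else
        sample(seq(arch_ranges$sp_len[1L], arch_ranges$sp_len[2L]), 1L)
      cp <- sample(seq(arch_ranges$copies[1L], arch_ranges$copies[2L]), 1L)
      motif3 <- paste(c(sample(MOTIF_AA, 1L),
                        if (runif(1) < 0.25) "x" else sample(MOTIF_AA, 1L),
                        sample(MOTIF_AA, 1L)), collapse = "")
      pr <- make_precursor(L, cp, motif3, arch_ranges$pep_len)
      id <- sprintf("pnp%03d", i)
      planted[[i]] <- data.frame(id = id, sequence = pr$protein,
                                 description = "planted precursor",
                                 stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(id = id, kind = "planted", sp_len = L,
                               copies = cp, motif = pr$motif,
                               peptide_seqs = paste(pr$peptides,
                                                    collapse = ";"),
                               stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, planted)
    n_shuf <- ceiling(n_decoys / 2)
    decoys <- vector("list", n_decoys)
    for (i in seq_len(n_decoys)) {
      if (i <= n_shuf) {
        template <- planted$sequence[(i - 1L) %% n_precursors + 1L]
        s <- dipeptide_shuffle(template)
      } else {
        s <- random_protein(sample(80:400, 1L))
      }
      decoys[[i]] <- data.frame(id = sprintf("decoy%03d", i), sequence = s,
                                description = if (i <= n_shuf)
                                  "dipeptide shuffle" else "random protein",
                                stringsAsFactors = FALSE)
    }
    decoys <- do.call(rbind, decoys)
    proteins <- rbind(planted, decoys)
    truth <- do.call(rbind, truth)
    transcripts <- data.frame(
      id = paste0("t_", proteins$id),
      sequence = vapply(proteins$sequence, embed_transcript, "",
                        USE.NAMES = FALSE),
      description = proteins$description, stringsAsFactors = FALSE)
    list(proteins = proteins, transcripts = transcripts, truth = truth,
         seed = seed)
  })
}

#' Build a homology query panel from planted precursors
#'
#' Takes the post-signal-peptide mature region (up to `max_len` residues) of
#' each selected planted precursor, emulating a curated panel of known
#' precursors from related taxa.
#'
#' @param ts A [gen_truth_set()] result.
#' @param ids Planted ids to include (default: all planted).
#' @param max_len Maximum query length (default 40).
#' @return FASTA-style data frame (`id` = `q_<planted id>`).
#' @export
gen_query_panel <- function(ts, ids = NULL, max_len = 40L) {
  tr <- ts$truth
  if (is.null(ids)) ids <- tr$id
  rows <- lapply(ids, function(id) {
    prot <- ts$proteins$sequence[ts$proteins$id == id]
    L <- tr$sp_len[tr$id == id]
    mature <- substr(prot, L + 1L, nchar(prot))
    data.frame(id = paste0("q_", id),
               sequence = substr(mature, 1L, max_len),
               description = "panel query", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a stage-expression FPKM matrix with planted candidates
#'
#' Log-normal FPKM across the four larval stages (LT, ES, SL, WL) in
#' `n_reps` replicates. Planted candidate genes rise `effect`-fold from ES
#' to SL and fall back `effect`-fold from SL to WL; genes in `up_only_ids`
#' rise ES to SL and stay high; remaining genes are flat
#' (`noncandidate_profile = "flat"`) or decline from ES to SL
#' (`"decreasing"`).
#'
#' @param seed Integer seed.
#' @param genes Character vector of gene ids.
#' @param candidate_ids Genes with the planted up-then-down pattern.
#' @param effect Fold change (>= 1, default 4).
#' @param cv Coefficient of variation of the log-normal noise (default 0.2).
#' @param n_reps Replicates per stage (default 3).
#' @param up_only_ids Genes planted up ES->SL but not down SL->WL.
#' @param noncandidate_profile `"flat"` or `"decreasing"`.
#' @return List with `fpkm` (an [expression_matrix()]) and `truth` (per-gene
#'   planted stage means and `is_candidate`).
#' @export
gen_expression <- function(seed, genes, candidate_ids, effect = 4, cv = 0.2,
                           n_reps = 3L, up_only_ids = character(),
                           noncandidate_profile = c("flat", "decreasing")) {
  stopifnot(effect >= 1, cv > 0)
  noncandidate_profile <- match.arg(noncandidate_profile)
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (g in genes) {
      base <- runif(1, 10, 50)
      mu <- if (g %in% candidate_ids) {
        c(LT = 0.9 * base, ES = base, SL = effect * base, WL = base)
      } else if (g %in% up_only_ids) {
        c(LT = 0.9 * base, ES = base, SL = effect * base,
          WL = 1.3 * effect * base)
      } else if (noncandidate_profile == "decreasing") {
        c(LT = base, ES = base, SL = base / max(effect, 2),
          WL = base / max(effect, 2))
      } else {
        c(LT = base, ES = base, SL = base, WL = base)
      }
      for (s in PNP_STAGES) {
        vals <- stats::rlnorm(n_reps, meanlog = log(mu[[s]]) - sdlog^2 / 2,
                              sdlog = sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, stage = s, replicate = seq_len(n_reps), fpkm = vals,
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        gene = g, mean_LT = mu[["LT"]], mean_ES = mu[["ES"]],
        mean_SL = mu[["SL"]], mean_WL = mu[["WL"]],
        is_candidate = g %in% candidate_ids, stringsAsFactors = FALSE)
    }
    list(fpkm = expression_matrix(do.call(rbind, rows)),
         truth = do.call(rbind, truth))
  })
}

#' Generate a qPCR Ct table with a planted fold profile
#'
#' Ct(target) = Ct(reference) + baseline - log2(fold(stage)), with Gaussian
#' noise of SD `noise_sd` added per technical replicate; `noise_sd = 0`
#' recovers the planted folds exactly.
#'
#' @param seed Integer seed.
#' @param gene Gene id (default "gene1").
#' @param stages Stage labels (default the qPCR sampling design LT, PL, CL,
#'   POL, WL).
#' @param fold_profile Named numeric vector of planted fold changes per
#'   stage (relative to the first stage).
#' @param noise_sd Technical noise SD in Ct units (default 0.1).
#' @param n_bio,n_tech Biological and technical replicates (default 3 each).
#' @param ct_reference Reference-gene Ct (default 18).
#' @param baseline Baseline dCt of the calibrator stage (default 8).
#' @return List with `ct` (a Ct table data frame) and `truth`.
#' @export
gen_ct <- function(seed, gene = "gene1",
                   stages = c("LT", "PL", "CL", "POL", "WL"),
                   fold_profile = c(LT = 1, PL = 2, CL = 8, POL = 3, WL = 1.5),
                   noise_sd = 0.1, n_bio = 3L, n_tech = 3L,
                   ct_reference = 18, baseline = 8) {
  stopifnot(noise_sd >= 0, all(stages %in% names(fold_profile)))
  with_seed(seed, {
    rows <- list()
    for (s in stages) {
      for (b in seq_len(n_bio)) {
        for (tech in seq_len(n_tech)) {
          ctt <- ct_reference + baseline - log2(fold_profile[[s]]) +
            rnorm(1L, 0, noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = gene, stage = s, biological_replicate = b,
            technical_replicate = tech, ct_target = ctt,
            ct_reference = ct_reference, stringsAsFactors = FALSE)
        }
      }
    }
    list(ct = do.call(rbind, rows),
         truth = list(fold_profile = fold_profile, baseline = baseline))
  })
}
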