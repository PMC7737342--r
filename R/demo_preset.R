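#' The "urechis-demo" end-to-end preset
#'
#' A desk-scale synthetic study emulating the published echiuran survey:
#' 54 planted precursors with the phylogenetic-tier composition
#' 10 eumetazoan / 24 bilaterian / 3 protostome / 9 lophotrochozoan /
#' 3 annelid / 5 species-specific; evidence classes planted as 42 found by
#' both routes, 7 by homology only (their leaders carry no signal peptide,
#' so the de-novo rule rejects them), and 5 de novo only (absent from the
#' query panel); and a stage-expression matrix in which 11 genes rise
#' significantly from ES to SL, 8 of which fall again from SL to WL
#' (settlement candidates). Non-candidate genes are planted with a
#' decreasing ES-to-SL profile so the planted counts are recovered exactly
#' rather than inflated by alpha-level false positives.
#'
#' @param seed Integer seed (default 1).
#' @return List with `proteins`, `transcripts`, `panel` (FASTA-style data
#'   frames), `catalog` (a `family_catalog`), `fpkm` (an
#'   [expression_matrix()]), and `truth` (planted per-precursor table plus
#'   `evidence`, `tier`, `family`, expression truth and the planted tallies).
#' @export
gen_urechis_demo <- function(seed = 1L) {
  tier_counts <- c(eumetazoan = 10L, bilaterian = 24L, protostome = 3L,
                   lophotrochozoan = 9L, annelid = 3L, species_specific = 5L)
  n <- sum(tier_counts)  # 54
  with_seed(seed, {
    tiers <- rep(names(tier_counts), tier_counts)
    prefix <- c(eumetazoan = "eum", bilaterian = "bil", protostome = "pro",
                lophotrochozoan = "lop", annelid = "ann",
                species_specific = "uu")
    fam_idx <- stats::ave(seq_len(n), tiers, FUN = seq_along)
    families <- sprintf("%s%02d", prefix[tiers], fam_idx)
    ids <- sprintf("pnp%02d", seq_len(n))

    # unique C-terminal motifs; a quarter carry a wildcard middle position
    wob <- seq_len(n) %in% sample.int(n, round(n / 4))
    gen_one <- function(w) paste0(sample(MOTIF_AA, 1L),
                                  if (w) "x" else sample(MOTIF_AA, 1L),
                                  sample(MOTIF_AA, 1L))
    motifs3 <- vapply(wob, gen_one, "")
    while (anyDuplicated(motifs3)) {
      dup <- which(duplicated(motifs3))
      motifs3[dup] <- vapply(wob[dup], gen_one, "")
    }

    # evidence planting: 7 homology-only (no SP), 5 de novo only, 42 both
    homol_only <- sample(ids, 7L)
    denovo_only <- sample(setdiff(ids, homol_only), 5L)

    rows <- vector("list", n)
    truth <- vector("list", n)
    catalog <- vector("list", n)
    for (i in seq_len(n)) {
      with_sp <- !(ids[i] %in% homol_only)
      L <- if (with_sp) sample(18:33, 1L) else 30L
      cp <- sample(3:9, 1L)
      pr <- make_precursor(L, cp, motifs3[i], pep_len_range = c(6L, 16L),
                           with_sp = with_sp)
      rows[[i]] <- data.frame(id = ids[i], sequence = pr$protein,
                              description = families[i],
                              stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        id = ids[i], kind = "planted", family = families[i], tier = tiers[i],
        sp_len = if (with_sp) L else 0L, copies = cp, motif = pr$motif,
        evidence = if (!with_sp) "homology_only" else
          if (ids[i] %in% denovo_only) "denovo_only" else "both",
        peptide_seqs = paste(pr$peptides, collapse = ";"),
        stringsAsFactors = FALSE)
      catalog[[i]] <- list(family = families[i], tier = tiers[i],
                           motif = pr$motif,
                           peptides = pr$peptides[1L])
    }
    proteins <- do.call(rbind, rows)
    truth <- do.call(rbind, truth)
    catalog <- structure(catalog, class = "family_catalog")
    transcripts <- data.frame(
      id = paste0("t_", proteins$id),
      sequence = vapply(proteins$sequence, embed_transcript, "",
                        USE.NAMES = FALSE),
      description = proteins$description, stringsAsFactors = FALSE)

    panel <- gen_query_panel(list(proteins = proteins, truth = truth),
                             ids = setdiff(ids, denovo_only))

    # expression: 8 settlement candidates and 3 up-only genes among the 11
    up_genes <- sample(ids, 11L)
    cand_genes <- sample(up_genes, 8L)
    up_only <- setdiff(up_genes, cand_genes)
    expr <- gen_expression(seed + 1L, genes = ids,
                           candidate_ids = cand_genes, effect = 4, cv = 0.2,
                           n_reps = 3L, up_only_ids = up_only,
                           noncandidate_profile = "decreasing")
    truth_tallies <- list(n_precursors = n, tiers = tier_counts,
                          evidence = c(homology_only = 7L, denovo_only = 5L,
                                       both = 42L),
                          n_up = 11L, n_candidates = 8L)
    list(proteins = proteins, transcripts = transcripts, panel = panel,
         catalog = catalog, fpkm = expr$fpkm,
         truth = list(precursors = truth, up_genes = sort(up_genes),
                      candidate_genes = sort(cand_genes),
                      expression = expr$truth, tallies = truth_tallies),
         seed = seed)
  })
}
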