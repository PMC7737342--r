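test_that("generators are seed-deterministic and leave the RNG untouched", {
  set.seed(123)
  before <- .Random.seed
  a <- gen_truth_set(7, n_precursors = 5L, n_decoys = 6L)
  expect_identical(.Random.seed, before)
  b <- gen_truth_set(7, n_precursors = 5L, n_decoys = 6L)
  expect_identical(a, b)
  c <- gen_truth_set(8, n_precursors = 5L, n_decoys = 6L)
  expect_false(identical(a$proteins$sequence, c$proteins$sequence))
  e1 <- gen_expression(3, paste0("g", 1:4), "g1")
  e2 <- gen_expression(3, paste0("g", 1:4), "g1")
  expect_identical(e1, e2)
  q1 <- gen_ct(5)
  q2 <- gen_ct(5)
  expect_identical(q1, q2)
})

test_that("tile shuffles preserve length, composition and the first residue", {
  set.seed(33)
  for (k in 1:30) {
    s <- paste(sample(c("A", "K", "R", "L", "G", "F", "W"),
                      sample(4:80, 1L), TRUE), collapse = "")
    sh <- dipeptide_shuffle(s, method = "tile")
    expect_equal(nchar(sh), nchar(s))
    expect_equal(substr(sh, 1L, 1L), substr(s, 1L, 1L))
    expect_equal(sort(strsplit(sh, "")[[1L]]), sort(strsplit(s, "")[[1L]]))
  }
})

test_that("eulerian shuffles preserve the overlapping-dipeptide multiset", {
  dimers <- function(x) {
    aa <- strsplit(x, "", fixed = TRUE)[[1L]]
    sort(paste0(aa[-length(aa)], aa[-1L]))
  }
  set.seed(34)
  for (k in 1:20) {
    s <- paste(sample(c("A", "K", "R", "L", "G"), sample(10:60, 1L), TRUE),
               collapse = "")
    sh <- dipeptide_shuffle(s, method = "eulerian")
    expect_equal(dimers(sh), dimers(s))
  }
})

test_that("planted truth is consistent with the emitted proteins", {
  ts <- gen_truth_set(11, n_precursors = 10L, n_decoys = 4L)
  expect_equal(nrow(ts$proteins), 14L)
  expect_equal(nrow(ts$truth), 10L)
  for (i in seq_len(nrow(ts$truth))) {
    tr <- ts$truth[i, ]
    prot <- ts$proteins$sequence[ts$proteins$id == tr$id]
    peps <- strsplit(tr$peptide_seqs, ";", fixed = TRUE)[[1L]]
    expect_length(peps, tr$copies)
    # the precursor is leader + (peptide G KR) blocks, in order
    expect_equal(prot, paste0(substr(prot, 1L, tr$sp_len),
                              paste(paste0(peps, "GKR"), collapse = "")))
    # every peptide ends with the motif (wildcards aside)
    pat <- sub("amide$", "", tr$motif)
    fixed <- strsplit(pat, "", fixed = TRUE)[[1L]]
    for (p in peps) {
      tail3 <- strsplit(substr(p, nchar(p) - 2L, nchar(p)), "")[[1L]]
      expect_true(all(fixed == "x" | fixed == tail3))
    }
  }
})

test_that("impossible architecture ranges are rejected", {
  expect_error(gen_truth_set(1, arch_ranges = list(sp_len = c(10L, 40L),
                                                   copies = c(2L, 15L),
                                                   pep_len = c(4L, 20L))),
               "impossible arch_ranges")
})

test_that("transcripts embed each protein as the longest recoverable ORF", {
  ts <- gen_truth_set(21, n_precursors = 4L, n_decoys = 2L)
  orfs <- find_orfs_all(ts$transcripts, min_orf_aa = 50L)
  found <- setNames(orfs$protein, sub("^t_", "", orfs$transcript_id))
  for (id in ts$truth$id) {
    expect_equal(unname(found[id]),
                 ts$proteins$sequence[ts$proteins$id == id])
  }
})

test_that("query panel rows are the post-SP mature regions", {
  ts <- gen_truth_set(5, n_precursors = 6L, n_decoys = 0L)
  panel <- gen_query_panel(ts, max_len = 40L)
  expect_equal(panel$id, paste0("q_", ts$truth$id))
  for (i in seq_len(nrow(panel))) {
    prot <- ts$proteins$sequence[i]
    L <- ts$truth$sp_len[i]
    expect_equal(panel$sequence[i],
                 substr(prot, L + 1L, min(nchar(prot), L + 40L)))
  }
})

test_that("gen_expression plants the documented stage-mean profiles", {
  res <- gen_expression(13, paste0("g", 1:6), candidate_ids = c("g1", "g2"),
                        effect = 4, up_only_ids = "g3")
  tr <- res$truth
  cand <- tr[tr$gene == "g1", ]
  expect_equal(cand$mean_SL / cand$mean_ES, 4)
  expect_equal(cand$mean_WL, cand$mean_ES)
  uponly <- tr[tr$gene == "g3", ]
  expect_gt(uponly$mean_WL, uponly$mean_SL)
  flat <- tr[tr$gene == "g5", ]
  expect_equal(flat$mean_ES, flat$mean_SL)
  expect_true(all(as.data.frame(res$fpkm)$fpkm >= 0))
})

test_that("gen_ct encodes the fold profile in the target Ct values", {
  g <- gen_ct(9, noise_sd = 0)
  ct <- g$ct
  for (s in unique(ct$stage)) {
    expect_equal(unique(ct$ct_target[ct$stage == s]),
                 18 + 8 - log2(g$truth$fold_profile[[s]]))
  }
})

test_that("the urechis-demo preset plants its documented totals", {
  demo <- gen_urechis_demo(1)
  tr <- demo$truth$precursors
  expect_equal(nrow(tr), 54L)
  expect_equal(as.vector(table(factor(tr$tier, levels = c(
    "eumetazoan", "bilaterian", "protostome", "lophotrochozoan",
    "annelid", "species_specific")))), c(10L, 24L, 3L, 9L, 3L, 5L))
  expect_equal(sum(tr$evidence == "homology_only"), 7L)
  expect_equal(sum(tr$evidence == "denovo_only"), 5L)
  expect_equal(sum(tr$evidence == "both"), 42L)
  expect_length(demo$truth$up_genes, 11L)
  expect_length(demo$truth$candidate_genes, 8L)
  # homology-only precursors have no signal peptide planted
  expect_true(all(tr$sp_len[tr$evidence == "homology_only"] == 0L))
  # de-novo-only precursors are absent from the query panel
  expect_false(any(paste0("q_", tr$id[tr$evidence == "denovo_only"]) %in%
                     demo$panel$id))
})
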