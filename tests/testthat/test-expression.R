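mk_matrix <- function(values) {
  # values: named list stage -> per-gene list of replicate vectors
  rows <- list()
  for (g in names(values)) {
    for (s in names(values[[g]])) {
      v <- values[[g]][[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, stage = s, replicate = seq_along(v), fpkm = v,
        stringsAsFactors = FALSE)
    }
  }
  expression_matrix(do.call(rbind, rows))
}

test_that("expression_matrix validates stages and non-negative FPKM", {
  df <- data.frame(gene = "g", stage = "XX", replicate = 1L, fpkm = 1)
  expect_error(expression_matrix(df), "unknown stage")
  df2 <- data.frame(gene = "g", stage = "ES", replicate = 1L, fpkm = -2)
  expect_error(expression_matrix(df2), ">= 0")
})

test_that("FPKM tables round-trip through TSV", {
  m <- mk_matrix(list(g1 = list(LT = c(1, 2), ES = c(2, 3), SL = c(9, 11),
                                WL = c(2, 2.5))))
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  write_fpkm(m, p)
  m2 <- read_fpkm(p)
  expect_equal(as.data.frame(m2)$fpkm, as.data.frame(m)$fpkm)
  expect_equal(attr(m2, "stages"), attr(m, "stages"))
})

test_that("stage_contrast reproduces a hand-run Welch test on log2(FPKM+1)", {
  a <- c(3, 4, 5)
  b <- c(30, 42, 37)
  m <- mk_matrix(list(g = list(ES = a, SL = b, LT = c(1, 1, 1),
                               WL = c(1, 1, 1))))
  ct <- stage_contrast(m, "g", "ES", "SL")
  ref <- t.test(log2(b + 1), log2(a + 1), var.equal = FALSE)
  expect_equal(ct$p, ref$p.value)
  expect_equal(ct$direction, 1)
  expect_true(ct$significant)
  # direction flips when the stages swap
  expect_equal(stage_contrast(m, "g", "SL", "ES")$direction, -1)
})

test_that("constant groups get the documented degenerate p-values", {
  m <- mk_matrix(list(g = list(ES = c(2, 2), SL = c(2, 2), LT = c(2, 2),
                               WL = c(8, 8))))
  expect_equal(stage_contrast(m, "g", "ES", "SL")$p, 1)
  expect_equal(stage_contrast(m, "g", "SL", "WL")$p, 0)
})

test_that("screen_candidates flags exactly the up-then-down pattern", {
  m <- mk_matrix(list(
    updown = list(LT = c(5, 6, 5), ES = c(5, 6, 5.5), SL = c(40, 44, 42),
                  WL = c(6, 5, 5.5)),
    uponly = list(LT = c(5, 6, 5), ES = c(5, 6, 5.5), SL = c(40, 44, 42),
                  WL = c(50, 52, 49)),
    flat = list(LT = c(5, 6, 5), ES = c(5, 6, 5.5), SL = c(5.5, 6, 5),
                WL = c(6, 5, 5.5))))
  sc <- screen_candidates(m)
  expect_equal(sc$candidate[match(c("updown", "uponly", "flat"), sc$gene)],
               c(TRUE, FALSE, FALSE))
  expect_equal(sc$up_ES_SL[match(c("updown", "uponly", "flat"), sc$gene)],
               c(TRUE, TRUE, FALSE))
})

test_that("BH adjustment never produces smaller adjusted p-values", {
  set.seed(2)
  genes <- paste0("g", 1:12)
  m <- gen_expression(3, genes, candidate_ids = genes[1:3])$fpkm
  raw <- screen_candidates(m, p_adjust = "none")
  adj <- screen_candidates(m, p_adjust = "BH")
  expect_true(all(adj$p_up >= raw$p_up - 1e-12))
  expect_true(all(adj$candidate <= raw$candidate))
})

test_that("cluster_genes groups correlated profiles and exports valid Newick", {
  m <- mk_matrix(list(
    a1 = list(LT = c(1, 1), ES = c(2, 2), SL = c(9, 9), WL = c(2, 2)),
    a2 = list(LT = c(2, 2), ES = c(4, 4), SL = c(17, 17), WL = c(4, 4)),
    b1 = list(LT = c(9, 9), ES = c(8, 8), SL = c(2, 2), WL = c(8, 8)),
    const = list(LT = c(3, 3), ES = c(3, 3), SL = c(3, 3), WL = c(3, 3))))
  cl <- cluster_genes(m)
  # constant gene is excluded from the tree and appended last
  expect_equal(tail(cl$order, 1L), "const")
  expect_false("const" %in% cl$hclust$labels)
  # the two correlated genes merge first
  first_pair <- cl$hclust$labels[abs(cl$hclust$merge[1L, ])]
  expect_setequal(first_pair, c("a1", "a2"))
  # Newick string parses back to the same leaf set
  tr <- ape::read.tree(text = cl$newick)
  expect_setequal(tr$tip.label, c("a1", "a2", "b1"))
  # z rows of variable genes are standardised
  expect_equal(unname(rowMeans(cl$z[c("a1", "b1"), ])), c(0, 0))
  expect_equal(unname(apply(cl$z[c("a1", "b1"), ], 1L, sd)), c(1, 1))
})

test_that("average-linkage merge heights match a brute-force oracle", {
  set.seed(17)
  genes <- paste0("g", 1:8)
  m <- gen_expression(9, genes, candidate_ids = genes[1:2],
                      up_only_ids = genes[3:4])$fpkm
  cl <- cluster_genes(m)
  d <- as.dist(1 - cor(t(cl$z[cl$hclust$labels, ])))
  expect_equal(cl$hclust$height, avg_linkage_heights(d), tolerance = 1e-10)
})

test_that("clustering is invariant to per-gene affine rescaling of profiles", {
  set.seed(23)
  genes <- paste0("g", 1:6)
  m <- gen_expression(5, genes, candidate_ids = genes[1:2])$fpkm
  df <- as.data.frame(m)
  # scale each gene's FPKM on the log scale: z-scoring removes gene-level
  # location/scale, so the tree topology is unchanged
  df2 <- df
  for (i in seq_along(genes)) {
    g <- genes[i]
    df2$fpkm[df2$gene == g] <- (df2$fpkm[df2$gene == g] + 1)^(1 + 0.1 * i) - 1
  }
  cl1 <- cluster_genes(m)
  cl2 <- cluster_genes(expression_matrix(df2))
  expect_equal(cl1$hclust$merge, cl2$hclust$merge)
})
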