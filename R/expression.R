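PNP_STAGES <- c("LT", "ES", "SL", "WL")

#' Construct a stage-expression matrix
#'
#' Container for gene x (stage, replicate) FPKM values with a fixed
#' developmental stage ordering (default LT < ES < SL < WL: late-trochophore,
#' early-segmented, segmented/competent, worm-shaped larva).
#'
#' @param df Long data frame with columns `gene`, `stage`, `replicate`,
#'   `fpkm`.
#' @param stages Ordered character vector of stages.
#' @return Object of class `expression_matrix` (the validated long data
#'   frame with an ordered `stage` factor, plus attributes).
#' @export
expression_matrix <- function(df, stages = PNP_STAGES) {
  stopifnot(all(c("gene", "stage", "replicate", "fpkm") %in% names(df)))
  if (any(df$fpkm < 0)) stop("FPKM values must be >= 0")
  bad <- setdiff(unique(df$stage), stages)
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
  df$stage <- factor(df$stage, levels = stages, ordered = TRUE)
  df <- df[order(df$gene, df$stage, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("expression_matrix", "data.frame"),
            stages = stages)
}

#' Read an FPKM table
#' @param path TSV with columns gene, stage, replicate, fpkm.
#' @param stages Stage ordering (default LT, ES, SL, WL).
#' @return An `expression_matrix`.
#' @export
read_fpkm <- function(path, stages = PNP_STAGES) {
  expression_matrix(read.delim(path, stringsAsFactors = FALSE), stages)
}

#' Write an FPKM table
#' @param m An `expression_matrix`.
#' @param path Output TSV path.
#' @export
write_fpkm <- function(m, path) {
  write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Two-stage expression contrast
#'
#' Two-sided Welch t-test on log2(FPKM + 1) between two stages of one gene.
#' When both groups are constant with equal means the p-value is defined
#' as 1.
#'
#' @param m An `expression_matrix`.
#' @param gene Gene id.
#' @param stageA,stageB Stage labels; direction is the sign of
#'   mean(B) - mean(A) on the log scale.
#' @param alpha Significance level (default 0.05).
#' @return List with `direction` (-1, 0, +1), `p`, `significant`.
#' @export
stage_contrast <- function(m, gene, stageA, stageB, alpha = 0.05) {
  xa <- log2(m$fpkm[m$gene == gene & m$stage == stageA] + 1)
  xb <- log2(m$fpkm[m$gene == gene & m$stage == stageB] + 1)
  if (length(xa) < 2L || length(xb) < 2L) {
    stop("need >= 2 replicates per stage for gene ", gene)
  }
  delta <- mean(xb) - mean(xa)
  if (sd(xa) == 0 && sd(xb) == 0) {
    p <- if (delta == 0) 1 else 0
  } else {
    p <- t.test(xb, xa, var.equal = FALSE)$p.value
  }
  list(direction = sign(delta), p = p, significant = p < alpha)
}

#' Screen for the up-then-down settlement expression pattern
#'
#' A gene is a settlement candidate when it is significantly up-regulated
#' from ES to SL and significantly down-regulated again from SL to WL, both
#' at level `alpha` (per-contrast Welch tests; optional BH adjustment across
#' genes within each contrast).
#'
#' @param m An `expression_matrix` whose stages include ES, SL and WL.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame with one row per gene: `gene`, `up_ES_SL`,
#'   `down_SL_WL`, `p_up`, `p_down`, `candidate`.
#' @export
screen_candidates <- function(m, alpha = 0.05, p_adjust = "none") {
  stages <- attr(m, "stages")
  stopifnot(all(c("ES", "SL", "WL") %in% stages))
  genes <- sort(unique(m$gene))
  up <- lapply(genes, function(g) stage_contrast(m, g, "ES", "SL", alpha))
  dn <- lapply(genes, function(g) stage_contrast(m, g, "SL", "WL", alpha))
  p_up <- stats::p.adjust(vapply(up, `[[`, 0, "p"), method = p_adjust)
  p_dn <- stats::p.adjust(vapply(dn, `[[`, 0, "p"), method = p_adjust)
  up_sig <- p_up < alpha & vapply(up, `[[`, 0, "direction") > 0
  dn_sig <- p_dn < alpha & vapply(dn, `[[`, 0, "direction") < 0
  data.frame(gene = genes, up_ES_SL = up_sig, down_SL_WL = dn_sig,
             p_up = p_up, p_down = p_dn,
             candidate = up_sig & dn_sig, stringsAsFactors = FALSE)
}

# per-gene stage means of log2(FPKM + 1), genes x stages
stage_mean_matrix <- function(m) {
  ag <- aggregate(log2(fpkm + 1) ~ gene + stage, data = as.data.frame(m),
                  FUN = mean)
  names(ag)[3L] <- "value"
  genes <- sort(unique(ag$gene))
  stages <- attr(m, "stages")
  mat <- matrix(NA_real_, length(genes), length(stages),
                dimnames = list(genes, stages))
  mat[cbind(ag$gene, as.character(ag$stage))] <- ag$value
  mat
}

#' Hierarchically cluster genes by stage-expression profile
#'
#' Rows are z-scores of per-stage mean log2(FPKM + 1); distance is
#' 1 - Pearson correlation; average linkage. Genes are pre-sorted by id so
#' the leaf order is deterministic; constant genes (zero variance, z-row of
#' zeros) are excluded from the tree and appended last.
#'
#' @param m An `expression_matrix` with >= 2 genes.
#' @return List with `order` (gene ids, dendrogram leaf order, constants
#'   last), `z` (gene x stage z-score matrix), `hclust` (the tree over
#'   non-constant genes, or NULL), `newick` (Newick string, or "").
#' @export
cluster_genes <- function(m) {
  mat <- stage_mean_matrix(m)
  if (nrow(mat) < 2L) stop("need >= 2 genes")
  sds <- apply(mat, 1L, sd)
  z <- mat
  z[sds > 0, ] <- t(scale(t(mat[sds > 0, , drop = FALSE])))
  z[sds == 0, ] <- 0
  variable <- rownames(mat)[sds > 0]
  hc <- NULL
  nwk <- ""
  if (length(variable) >= 2L) {
    d <- as.dist(1 - cor(t(z[variable, , drop = FALSE])))
    hc <- hclust(d, method = "average")
    nwk <- ape::write.tree(ape::as.phylo(hc))
    ord <- variable[hc$order]
  } else {
    ord <- variable
  }
  list(order = c(ord, rownames(mat)[sds == 0]), z = z, hclust = hc,
       newick = nwk)
}
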