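#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged within each biological replicate first;
#' dCt = Ct(target) - Ct(reference); ddCt subtracts the gene's mean dCt in
#' the calibrator stage; the fold change is 2^-ddCt. The calibrator stage's
#' mean fold is exactly 1 in the absence of noise.
#'
#' @param ct Data frame with columns `gene`, `stage`, `biological_replicate`,
#'   `technical_replicate`, `ct_target`, `ct_reference`. Rows with a missing
#'   reference Ct are dropped with a warning.
#' @param calibrator_stage Calibrator stage label (default "LT").
#' @return List with `folds` (per biological replicate: `gene`, `stage`,
#'   `biological_replicate`, `dct`, `fold`) and `summary` (per stage: mean
#'   fold and SD over biological replicates).
#' @export
relative_expression <- function(ct, calibrator_stage = "LT") {
  need <- c("gene", "stage", "biological_replicate", "ct_target",
            "ct_reference")
  stopifnot(all(need %in% names(ct)))
  bad <- is.na(ct$ct_reference) | is.na(ct$ct_target)
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing Ct excluded")
    ct <- ct[!bad, , drop = FALSE]
  }
  if (!calibrator_stage %in% ct$stage) {
    stop("calibrator stage '", calibrator_stage, "' not present")
  }
  if (any(ct$ct_target <= 0 | ct$ct_target >= 45 |
            ct$ct_reference <= 0 | ct$ct_reference >= 45)) {
    stop("Ct values must lie in (0, 45)")
  }
  # average technical replicates within biological replicate
  bio <- aggregate(cbind(ct_target, ct_reference) ~
                     gene + stage + biological_replicate,
                   data = ct, FUN = mean)
  bio$dct <- bio$ct_target - bio$ct_reference
  cal <- aggregate(dct ~ gene, data = bio[bio$stage == calibrator_stage, ,
                                          drop = FALSE], FUN = mean)
  names(cal)[2L] <- "cal_dct"
  bio <- merge(bio, cal, by = "gene")
  bio$fold <- 2^-(bio$dct - bio$cal_dct)
  bio <- bio[order(bio$gene, bio$stage, bio$biological_replicate), ,
             drop = FALSE]
  smry <- aggregate(fold ~ gene + stage, data = bio,
                    FUN = function(x) c(mean = mean(x), sd = sd(x),
                                        n = length(x)))
  smry <- cbind(smry[c("gene", "stage")], as.data.frame(smry$fold))
  rownames(bio) <- rownames(smry) <- NULL
  list(folds = bio[c("gene", "stage", "biological_replicate", "dct", "fold")],
       summary = smry)
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Fits a one-way ANOVA of the response (fold changes by default) on stage,
#' runs Tukey's HSD over all stage pairs, and assigns letters so that two
#' stages share a letter if and only if they are not significantly different
#' at level `alpha`. Letters are assigned over stages ordered by decreasing
#' mean: each maximal run of mutually non-different stages gets one letter.
#'
#' @param values Numeric response (e.g. per-replicate fold changes).
#' @param groups Stage labels, one per value; >= 2 stages with >= 2
#'   replicates each.
#' @param alpha Significance level (default 0.05).
#' @return List with `anova_p`, `anova_F`, `tukey` (the TukeyHSD pair
#'   table) and `letters` (named character vector per stage).
#' @export
tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 replicates")
  fit <- aov(values ~ groups)
  an <- anova(fit)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  means <- tapply(values, groups, mean)
  lev <- names(sort(means, decreasing = TRUE))
  k <- length(lev)
  # significance lookup from the Tukey pair table
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
    s <- tk[i, "p adj"] < alpha
    sig[a, b] <- sig[b, a] <- s
  }
  # maximal runs over mean-ordered groups; run i..j valid iff no pair
  # within it is significantly different
  run_ok <- function(i, j) !any(sig[lev[i:j], lev[i:j]])
  letters_by_group <- setNames(rep("", k), lev)
  letter_idx <- 0L
  i <- 1L
  while (i <= k) {
    j <- i
    while (j < k && run_ok(i, j + 1L)) j <- j + 1L
    # only emit a run if it is not contained in the previous one
    letter_idx <- letter_idx + 1L
    ltr <- letters[letter_idx]
    for (g in lev[i:j]) {
      letters_by_group[g] <- paste0(letters_by_group[g], ltr)
    }
    if (j == k) break
    # next run starts at the first group that cannot join the current run
    nxt <- j + 1L
    while (nxt > i + 1L && run_ok(nxt - 1L, j + 1L)) nxt <- nxt - 1L
    i <- nxt
  }
  list(anova_p = an[["Pr(>F)"]][1L], anova_F = an[["F value"]][1L],
       tukey = tk, letters = letters_by_group[levels(groups)])
}
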