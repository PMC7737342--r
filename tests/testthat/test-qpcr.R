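test_that("noise-free Ct tables recover the planted fold profile exactly", {
  g <- gen_ct(1, noise_sd = 0)
  rel <- relative_expression(g$ct, calibrator_stage = "LT")
  smry <- rel$summary
  for (s in names(g$truth$fold_profile)) {
    expect_equal(smry$mean[smry$stage == s],
                 unname(g$truth$fold_profile[s]))
  }
  expect_equal(smry$sd[smry$stage == "CL"], 0)
})

test_that("the calibrator stage has mean fold 1 even with noise", {
  g <- gen_ct(2, noise_sd = 0.3)
  rel <- relative_expression(g$ct, calibrator_stage = "LT")
  cal <- rel$folds[rel$folds$stage == "LT", ]
  # ddCt subtracts the calibrator mean dCt, so the mean log2 fold is 0
  expect_equal(mean(log2(cal$fold)), 0, tolerance = 1e-12)
})

test_that("technical replicates are averaged before dCt", {
  ct <- data.frame(
    gene = "g", stage = rep(c("LT", "CL"), each = 4L),
    biological_replicate = rep(c(1L, 1L, 2L, 2L), 2L),
    technical_replicate = rep(c(1L, 2L), 4L),
    # technical reps straddle the mean: averaging gives exact folds
    ct_target = c(26.5, 25.5, 26.2, 25.8, 23.5, 22.5, 23.2, 22.8),
    ct_reference = 18, stringsAsFactors = FALSE)
  rel <- relative_expression(ct, calibrator_stage = "LT")
  expect_equal(nrow(rel$folds), 4L)  # one row per biological replicate
  smry <- rel$summary
  expect_equal(smry$mean[smry$stage == "CL"], 8)  # 2^-(23-26)
  expect_equal(smry$mean[smry$stage == "LT"], 1)
})

test_that("2^-ddCt worked example: one cycle earlier means twofold more", {
  ct <- data.frame(
    gene = "g", stage = rep(c("LT", "SL"), each = 2L),
    biological_replicate = rep(1:2, 2L), technical_replicate = 1L,
    ct_target = c(28, 28, 27, 27), ct_reference = 18,
    stringsAsFactors = FALSE)
  rel <- relative_expression(ct, "LT")
  expect_equal(rel$summary$mean[rel$summary$stage == "SL"], 2)
})

test_that("Ct sanity checks fire", {
  g <- gen_ct(3)
  ct <- g$ct
  ct$ct_target[1L] <- 50
  expect_error(relative_expression(ct), "must lie in")
  ct2 <- g$ct
  ct2$ct_reference[1L] <- NA
  expect_warning(relative_expression(ct2), "missing Ct")
  expect_error(relative_expression(g$ct, calibrator_stage = "ZZ"),
               "not present")
})

test_that("tukey_letters separates a strong peak and groups equal stages", {
  g <- gen_ct(4, noise_sd = 0.05)
  rel <- relative_expression(g$ct, "LT")
  tl <- tukey_letters(rel$folds$fold, rel$folds$stage)
  expect_lt(tl$anova_p, 0.05)
  # CL (fold 8) is significantly above everything else: a unique letter
  others <- setdiff(names(tl$letters), "CL")
  expect_false(any(vapply(others, function(s)
    any(strsplit(tl$letters[["CL"]], "")[[1L]] %in%
          strsplit(tl$letters[[s]], "")[[1L]]), logical(1L))))
})

test_that("letters satisfy the sharing iff non-significant relation", {
  check_letters <- function(tl, alpha = 0.05) {
    lev <- names(tl$letters)
    for (i in seq_along(lev)) {
      for (j in seq_along(lev)) {
        if (i >= j) next
        pr <- rownames(tl$tukey)
        r <- which(pr %in% c(paste0(lev[i], "-", lev[j]),
                             paste0(lev[j], "-", lev[i])))
        sig <- tl$tukey[r, "p adj"] < alpha
        share <- any(strsplit(tl$letters[[lev[i]]], "")[[1L]] %in%
                       strsplit(tl$letters[[lev[j]]], "")[[1L]])
        # significantly different pairs must never share a letter
        if (sig) expect_false(share)
        # non-different pairs must share one
        if (!sig) expect_true(share)
      }
    }
  }
  set.seed(6)
  for (k in 1:25) {
    groups <- rep(paste0("s", 1:4), each = 4L)
    values <- rnorm(16L, mean = rep(sample(0:3, 4L, TRUE), each = 4L),
                    sd = 0.8)
    check_letters(tukey_letters(values, groups))
  }
})

test_that("letters agree with multcomp's compact letter display", {
  set.seed(19)
  for (k in 1:20) {
    groups <- factor(rep(paste0("s", 1:5), each = 4L))
    # widely separated means: both methods agree on every pairwise call,
    # so the letter partitions must coincide
    values <- rnorm(20L, mean = rep(sample(c(0, 6, 12, 18, 24), 5L, TRUE),
                                    each = 4L), sd = 0.7)
    tl <- tukey_letters(values, groups)
    fit <- stats::aov(values ~ groups)
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(groups = "Tukey"))
    cld <- multcomp::cld(glht, level = 0.05)$mcletters$Letters
    # same partition: two groups share a letter in ours iff they do in cld
    for (i in 1:4) {
      for (j in (i + 1):5) {
        a <- levels(groups)[i]
        b <- levels(groups)[j]
        ours <- any(strsplit(tl$letters[[a]], "")[[1L]] %in%
                      strsplit(tl$letters[[b]], "")[[1L]])
        theirs <- any(strsplit(cld[[a]], "")[[1L]] %in%
                        strsplit(cld[[b]], "")[[1L]])
        expect_equal(ours, theirs,
                     info = paste("seed block", k, a, b))
      }
    }
  }
})

test_that("letters are invariant to adding a constant to all values", {
  set.seed(44)
  groups <- rep(c("a", "b", "c"), each = 5L)
  values <- rnorm(15L, rep(c(0, 0.3, 4), each = 5L), 0.5)
  t1 <- tukey_letters(values, groups)
  t2 <- tukey_letters(values + 100, groups)
  expect_equal(t1$letters, t2$letters)
  expect_equal(t1$anova_F, t2$anova_F)
})

test_that("tukey_letters validates its inputs", {
  expect_error(tukey_letters(1:4, rep("a", 4L)), ">= 2 groups")
  expect_error(tukey_letters(1:3, c("a", "a", "b")), ">= 2 replicates")
})
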