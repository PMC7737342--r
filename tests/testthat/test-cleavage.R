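test_that("dibasic runs cut once, after the last residue of the run", {
  s <- scan_cleavage_sites("AAKRAA")
  expect_equal(s$cleave_after, 4L)
  expect_equal(s$kind, "dibasic")
  expect_equal(s$motif, "KR")
  # KRR is one run -> a single cut after the run, motif = last two residues
  s2 <- scan_cleavage_sites("AAKRRAA")
  expect_equal(s2$cleave_after, 5L)
  expect_equal(s2$motif, "RR")
  # all four dibasic pairs are recognised
  for (pair in c("KR", "RR", "KK", "RK")) {
    sp <- scan_cleavage_sites(paste0("AAAA", pair, "AAAA"))
    expect_equal(sp$kind, "dibasic")
    expect_equal(sp$motif, pair)
  }
})

test_that("monobasic R needs a basic residue at -3, -5 or -7", {
  # R at 8 with K at 5 (-3): cut
  s <- scan_cleavage_sites("AAAAKAARAAAA")
  expect_equal(s[s$kind == "monobasic", "cleave_after"], 8L)
  # R at 8 with K at 4 (-4): no monobasic cut
  s2 <- scan_cleavage_sites("AAAKAAARAAAA")
  expect_equal(nrow(s2), 0L)
  # isolated K is never a site
  s3 <- scan_cleavage_sites("AAAAKAAKAAAA")
  expect_equal(nrow(s3), 0L)
})

test_that("monobasic cuts too close to the previous cut are suppressed", {
  # the R of each SFRW copy sits -3 from the upstream KR flank and must not
  # cut inside the peptide
  prot <- "MAAAKRAFRWGKRSFRWGKRAA"
  sites <- scan_cleavage_sites(prot)
  expect_equal(sites$kind, rep("dibasic", 3L))
  expect_equal(sites$cleave_after, c(6L, 13L, 20L))
})

test_that("scanning starts after the signal peptide", {
  sp <- list(present = TRUE, cleave_after = 6L)
  s <- scan_cleavage_sites("AAKRAAAAKRAA", sp = sp)
  expect_equal(s$cleave_after, 10L)
})

test_that("cleavage scan matches the brute-force oracle on random {A,K,R} strings", {
  set.seed(99)
  for (k in 1:400) {
    s <- paste(sample(c("A", "K", "R"), sample(1:12, 1L), TRUE), collapse = "")
    got <- scan_cleavage_sites(s)
    want <- oracle_cleavage(s)
    expect_equal(got$cleave_after, want$cleave_after, info = s)
    expect_equal(got$kind, want$kind, info = s)
    expect_equal(got$motif, want$motif, info = s)
  }
})

test_that("the worked FRWamide precursor yields two amidated FRW peptides", {
  prot <- "MAAAKRAFRWGKRSFRWGKRAA"
  sp <- list(present = FALSE, cleave_after = 0L)
  sites <- scan_cleavage_sites(prot)
  peps <- derive_mature_peptides(prot, sp, sites)
  frw <- peps[peps$amidated, ]
  expect_equal(frw$processed_seq, c("AFRW", "SFRW"))
  expect_equal(frw$raw_seq, c("AFRWG", "SFRWG"))
})

test_that("flanking basics are stripped and modifications are flagged", {
  # QLDPF: pyroglutamate, no trailing G, no amidation
  prot <- "AAAKRQLDPFKRAAA"
  peps <- derive_mature_peptides(prot, NULL, scan_cleavage_sites(prot))
  q <- peps[peps$raw_seq == "QLDPF", ]
  expect_equal(nrow(q), 1L)
  expect_true(q$pyroglu)
  expect_false(q$amidated)
  expect_equal(q$processed_seq, "QLDPF")
})

test_that("zero cleavage sites yield at most one non-amidated peptide", {
  prot <- "MAAAAAAAGGG"
  peps <- derive_mature_peptides(prot, NULL, NULL)
  expect_lte(nrow(peps), 1L)
  if (nrow(peps)) expect_false(peps$amidated)
})

test_that("terminal segments are amidated only when their G preceded a site", {
  # trailing ...FGKR: the KR cut at the end makes the last G amide-donating
  prot <- "AAKRAAFGKR"
  peps <- derive_mature_peptides(prot, NULL, scan_cleavage_sites(prot))
  expect_true(peps[peps$raw_seq == "AAFG", "amidated"])
  # trailing ...FG with no site after it stays unmodified
  prot2 <- "AAKRAAFG"
  peps2 <- derive_mature_peptides(prot2, NULL, scan_cleavage_sites(prot2))
  expect_false(peps2[peps2$raw_seq == "AAFG", "amidated"])
})

test_that("peptide length bounds use processed length (min) and raw length (max)", {
  # processed "AF" (2) after amidation: dropped at min_pep_aa 3
  prot <- "AAKRAFGKRAAAA"
  peps <- derive_mature_peptides(prot, NULL, scan_cleavage_sites(prot))
  expect_false("AF" %in% peps$processed_seq)
  # raw length above max_pep_aa: dropped
  long <- paste0("AAKR", strrep("A", 60L), "KRAAAA")
  peps2 <- derive_mature_peptides(long, NULL, scan_cleavage_sites(long))
  expect_false(any(nchar(peps2$raw_seq) > 50L))
})

test_that("peptide coordinates reconstruct the raw sequence", {
  set.seed(12)
  for (k in 1:50) {
    prot <- paste(sample(c("A", "G", "K", "R", "F", "S", "Q"), 60, TRUE),
                  collapse = "")
    peps <- derive_mature_peptides(prot, NULL, scan_cleavage_sites(prot))
    for (i in seq_len(nrow(peps))) {
      expect_equal(substr(prot, peps$start[i], peps$end[i]), peps$raw_seq[i])
    }
  }
})

test_that("detect_cys_stretch needs at least two cysteines", {
  expect_false(detect_cys_stretch("AFRW"))
  expect_false(detect_cys_stretch("ACRW"))
  expect_true(detect_cys_stretch("ACCW"))
  expect_true(detect_cys_stretch("CACAC"))
  expect_equal(detect_cys_stretch(c("CC", "AA")), c(TRUE, FALSE))
})
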