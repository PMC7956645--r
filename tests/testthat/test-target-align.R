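# A 21-nt miRNA with G and U bases available inside and outside the
# seed-proximal region, used throughout.
MIR <- "TGACAGAAGAGAGTGAGCACA"

perfect_site <- function(mir) {
  paste(rev(COMP[strsplit(mir, "")[[1L]]]), collapse = "")
}

edit_site <- function(site, mir, mir_pos, kind) {
  s <- strsplit(site, "")[[1L]]
  mb <- strsplit(mir, "")[[1L]][[mir_pos]]
  j <- length(s) - mir_pos + 1L
  s[[j]] <- switch(kind,
                   gu = c(G = "T", T = "G")[[mb]],
                   mm = setdiff(BASES, c(COMP[[mb]], c(G = "T", T = "G",
                                                       A = NA, C = NA)[[mb]]))[[1L]])
  paste(s, collapse = "")
}

test_that("hand-scored duplex penalties match the default scheme", {
  site <- perfect_site(MIR)
  expect_equal(score_pairing(MIR, site), 0)

  # G:U outside the doubled region (position 15) costs 0.5
  expect_equal(score_pairing(MIR, edit_site(site, MIR, 15, "gu")), 0.5)
  # the same wobble inside positions 2-13 costs double
  expect_equal(score_pairing(MIR, edit_site(site, MIR, 5, "mm")), 2.0)
  expect_equal(score_pairing(MIR, edit_site(site, MIR, 2, "gu")), 1.0)
  # one mismatch at position 10 (seed region) costs 2.0
  expect_equal(score_pairing(MIR, edit_site(site, MIR, 10, "mm")), 2.0)
  # mismatch outside the seed costs 1.0; effects are additive
  s2 <- edit_site(edit_site(site, MIR, 15, "gu"), MIR, 21, "mm")
  expect_equal(score_pairing(MIR, s2), 1.5)
})

test_that("penalty is zero iff all states are Watson-Crick", {
  site <- perfect_site(MIR)
  expect_equal(score_pairing(MIR, site), 0)
  set.seed(7)
  for (i in 1:20) {
    pos <- sample(21, 1)
    kind <- if (strsplit(MIR, "")[[1]][pos] %in% c("G", "T"))
      sample(c("gu", "mm"), 1) else "mm"
    p <- score_pairing(MIR, edit_site(site, MIR, pos, kind))
    expect_gt(p, 0)
  }
})

test_that("adding an extra defect never decreases the penalty", {
  set.seed(19)
  site <- perfect_site(MIR)
  for (i in 1:25) {
    positions <- sample(21, 3)
    s <- site
    prev <- 0
    for (pos in positions) {
      kind <- if (strsplit(MIR, "")[[1]][pos] %in% c("G", "T"))
        sample(c("gu", "mm"), 1) else "mm"
      s <- edit_site(s, MIR, pos, kind)
      p <- score_pairing(MIR, s)
      expect_gte(p, prev)
      prev <- p
    }
  }
})

test_that("explicit states are validated against sequences", {
  site <- perfect_site(MIR)
  expect_equal(score_pairing(MIR, site, states = rep("WC", 21)), 0)
  bad <- c("MISMATCH", rep("WC", 20))
  expect_error(score_pairing(MIR, site, states = bad), "inconsistent")
  expect_error(score_pairing(MIR, states = c(rep("WC", 10), "BULGE_TARGET",
                                             "BULGE_MIRNA", rep("WC", 10))),
               "one bulge")
})

test_that("bulge penalties follow the charged miRNA position", {
  scheme <- scoring_scheme()
  # target bulge between miRNA positions 14 and 15: charged at 15, outside
  # the doubled region
  st_out <- c(rep("WC", 14), "BULGE_TARGET", rep("WC", 7))
  expect_equal(score_pairing(MIR, states = st_out), 2.0)
  # target bulge between positions 4 and 5: charged at 5, doubled
  st_in <- c(rep("WC", 4), "BULGE_TARGET", rep("WC", 17))
  expect_equal(score_pairing(MIR, states = st_in), 4.0)
  # unpaired miRNA nt at position 15 vs inside the seed
  expect_equal(score_pairing(MIR, states = c(rep("WC", 14), "BULGE_MIRNA",
                                             rep("WC", 6))), 2.0)
  expect_equal(score_pairing(MIR, states = c(rep("WC", 4), "BULGE_MIRNA",
                                             rep("WC", 16))), 4.0)
})

test_that("scan finds a planted perfect site exactly once at penalty 0", {
  set.seed(11)
  site <- perfect_site(MIR)
  tx <- paste0(random_seq(150), site, random_seq(90))
  hits <- scan_transcript(MIR, tx)
  p0 <- hits[hits$penalty == 0, ]
  expect_equal(nrow(p0), 1L)
  expect_equal(p0$start, 151L)
  expect_equal(p0$end, 171L)
  expect_equal(p0$pairing, strrep("|", 21))
})

test_that("the retention ceiling keeps penalty <= 4 and rejects above", {
  set.seed(13)
  # a site with penalty exactly 4 (two out-of-seed mismatches + one
  # out-of-seed G:U + ... ) and one with 4.5
  site4 <- perfect_site(MIR)
  for (pos in c(16, 17, 19, 21)) site4 <- edit_site(site4, MIR, pos, "mm")
  expect_equal(score_pairing(MIR, site4), 4)
  site45 <- edit_site(site4, MIR, 15, "gu")
  expect_equal(score_pairing(MIR, site45), 4.5)

  tx4 <- paste0(random_seq(60), site4, random_seq(60))
  hits <- scan_transcript(MIR, tx4)
  expect_true(any(hits$start == 61 & hits$penalty == 4))
  expect_true(all(hits$penalty <= 4))

  tx45 <- paste0(random_seq(60), site45, random_seq(60))
  hits45 <- scan_transcript(MIR, tx45)
  expect_false(any(hits45$start == 61 & hits45$end == 81))
  expect_true(all(hits45$penalty <= 4))
})

test_that("scan agrees with brute-force window enumeration on random input", {
  set.seed(17)
  scheme <- scoring_scheme()
  for (i in 1:10) {
    mir <- random_seq(21)
    tx <- paste0(random_seq(40), perfect_site(mir), random_seq(40))
    hits <- scan_transcript(mir, tx, scheme)
    orc <- oracle_scan(mir, tx, scheme)
    expect_equal(hits$start, orc$start, info = paste("case", i))
    expect_equal(hits$end, orc$end, info = paste("case", i))
    expect_equal(hits$penalty, orc$penalty, info = paste("case", i))
  }
})

test_that("cleavage positions follow the antiparallel pairing geometry", {
  gapless <- function(s, e) {
    duplex_alignment("m", "t", s, e, rep("WC", e - s + 1L))
  }
  expect_equal(cleavage_positions(gapless(1, 21)),
               c(site10 = 12L, site11 = 11L))
  # published duplex ranges and their printed cleavage sites
  expect_equal(cleavage_positions(gapless(1053, 1073))[["site10"]], 1064L)
  expect_equal(cleavage_positions(gapless(954, 974))[["site10"]], 965L)
  expect_equal(cleavage_positions(gapless(489, 510))[["site11"]], 500L)
  expect_error(cleavage_positions(duplex_alignment("m", "t", 1, 10,
                                                   rep("WC", 10))),
               "shorter than 11")
  # site10/site11 adjacency for gapless duplexes
  set.seed(23)
  for (i in 1:10) {
    s <- sample(1000, 1)
    e <- s + sample(20:23, 1)
    cp <- cleavage_positions(gapless(s, e))
    expect_equal(cp[["site11"]], cp[["site10"]] - 1L)
    expect_true(all(cp >= s & cp <= e))
  }
  # a target bulge 5' of position 10 shifts the paired positions
  st <- c(rep("WC", 4), "BULGE_TARGET", rep("WC", 17))
  a <- duplex_alignment("m", "t", 100, 121, st)
  cp <- cleavage_positions(a)
  expect_equal(cp[["site10"]], 121L - 10L)  # one extra target nt consumed
  # a bulged miRNA nucleotide 10 has no paired position
  st <- c(rep("WC", 9), "BULGE_MIRNA", rep("WC", 11))
  a <- duplex_alignment("m", "t", 100, 119, st)
  expect_true(is.na(cleavage_positions(a)[["site10"]]))
})

test_that("retained alignments are sorted by penalty then start", {
  set.seed(29)
  site <- perfect_site(MIR)
  tx <- paste0(random_seq(30), edit_site(site, MIR, 15, "gu"),
               random_seq(30), site, random_seq(30))
  hits <- scan_transcript(MIR, tx)
  expect_true(!is.unsorted(hits$penalty))
  same_p <- split(hits$start, hits$penalty)
  for (v in same_p) expect_true(!is.unsorted(v))
})
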