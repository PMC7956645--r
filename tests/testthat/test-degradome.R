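test_that("5' signatures map at every perfect-match position, 1-based", {
  txs <- data.frame(id = c("t1", "t2"),
                    seq = c("AAACCCGGGTTTAAACCCGGGTTT", "GGGTTTAAACCC"),
                    alphabet = "DNA", stringsAsFactors = FALSE)
  reads <- data.frame(id = "r1", seq = "CGGGTTT", stringsAsFactors = FALSE)
  res <- map_signatures(reads, txs, min_read_len = 5L)
  # exact substring occurrences: t1 at 6 and 18, none in t2
  expect_equal(res$profiles$t1, c("6" = 1L, "18" = 1L))
  expect_equal(length(res$profiles$t2), 0L)

  # a multi-mapping read contributes full weight to every transcript it
  # matches perfectly
  reads2 <- data.frame(id = "r2", seq = "GGGTTTAAACCC", stringsAsFactors = FALSE)
  res2 <- map_signatures(reads2, txs, min_read_len = 5L)
  expect_equal(res2$profiles$t1, c("7" = 1L))
  expect_equal(res2$profiles$t2, c("1" = 1L))

  # unmapped and short reads are tallied, not silently lost
  reads3 <- data.frame(seq = c("TTTTTTTTTTTTTTTTTT", "ACG"),
                       count = c(2L, 5L), stringsAsFactors = FALSE)
  res3 <- map_signatures(reads3, txs, min_read_len = 15L)
  expect_equal(res3$n_unmapped, 2L)
  expect_equal(res3$n_discarded, 5L)
})

test_that("tag-count input weights positions by abundance and mass is conserved", {
  set.seed(5)
  txg <- generate_transcriptome(3, c(200, 300), 0.5, seed = 6)
  pos <- c(11L, 57L, 140L)
  reads <- data.frame(
    seq = vapply(1:3, function(i) substr(txg$seq[[i]], pos[[i]],
                                         pos[[i]] + 19L), ""),
    count = c(7L, 3L, 12L), stringsAsFactors = FALSE)
  res <- map_signatures(reads, txg)
  got <- unlist(lapply(res$profiles, sum))
  expect_equal(sum(got), sum(reads$count))  # no multimapping here
  for (i in 1:3) {
    expect_equal(res$profiles[[txg$id[[i]]]][[as.character(pos[[i]])]],
                 reads$count[[i]])
  }
})

test_that("category definitions are applied literally", {
  expect_equal(classify_category(c("3" = 5L, "7" = 1L, "9" = 1L), 3), 0L)
  expect_equal(classify_category(c("3" = 5L, "8" = 5L, "9" = 1L), 3), 1L)
  p <- c("2" = 9L, "5" = 3L, "6" = 1L, "7" = 1L, "8" = 1L)
  expect_equal(classify_category(p, 5), 2L)   # 3 < 9 and 3 > median 1
  expect_equal(classify_category(p, 6), 4L)   # single raw read
  expect_equal(classify_category(c("4" = 2L, "9" = 6L, "12" = 2L, "15" = 2L), 4),
               3L)                            # 2 <= median 2
  expect_error(classify_category(p, 3), "no reads")
})

test_that("classifier agrees with a literal restatement on exhaustive profiles", {
  # spot sample of profiles over up to 5 covered positions with counts
  # 1..4 (the full enumeration runs in the acceptance suite)
  set.seed(123)
  got <- integer(0)
  want <- integer(0)
  for (i in 1:500) {
    p <- sample(1:5, 1)
    profile <- stats::setNames(sample(1:4, p, replace = TRUE),
                               as.character(seq_len(p) * 3L))
    for (q in seq_len(p)) {
      pos <- q * 3L
      got[[length(got) + 1L]] <- classify_category(profile, pos)
      want[[length(want) + 1L]] <- oracle_category(profile, pos)
    }
  }
  expect_identical(got, want)
})

test_that("category 0/1 sit at the maximum and category 4 has one read", {
  set.seed(77)
  for (i in 1:200) {
    p <- sample(1:5, 1)
    profile <- stats::setNames(sample(1:9, p, replace = TRUE),
                               sample(200, p))
    q <- sample(p, 1)
    cat <- classify_category(profile, as.integer(names(profile)[[q]]))
    n <- profile[[q]]
    if (cat %in% c(0L, 1L)) expect_equal(n, max(profile))
    if (cat == 4L) expect_equal(n, 1L)
    if (cat == 0L) expect_equal(sum(profile == max(profile)), 1L)
  }
})

test_that("validation picks the coincident site with the stronger signal", {
  site <- paste(rev(COMP[strsplit("TGACAGAAGAGAGTGAGCACA", "")[[1]]]),
                collapse = "")
  set.seed(41)
  tx <- data.frame(id = "tx", seq = paste0(random_seq(100), site,
                                           random_seq(100)),
                   alphabet = "DNA", stringsAsFactors = FALSE)
  al <- scan_transcript("TGACAGAAGAGAGTGAGCACA", tx$seq, mirna_id = "mir",
                        transcript_id = "tx")
  hit <- al[al$penalty == 0, ]
  fake_profiles <- function(counts) {
    structure(list(profiles = list(tx = counts), n_unmapped = 0L,
                   n_discarded = 0L), class = "degradome_profiles")
  }
  # signal only at site10
  ev <- validate_targets(hit, fake_profiles(stats::setNames(8L, hit$site10)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$coincident_nt, 10L)
  expect_equal(ev$site, hit$site10)
  expect_equal(ev$category, 0L)
  # signal 5 at site10 and 8 at site11: the stronger wins
  prof <- stats::setNames(c(5L, 8L), c(hit$site10, hit$site11))
  ev <- validate_targets(hit, fake_profiles(prof))
  expect_equal(ev$site, hit$site11)
  expect_equal(ev$coincident_nt, 11L)
  expect_equal(ev$abundance, 8L)
  # tie goes to nucleotide 10
  prof <- stats::setNames(c(6L, 6L), c(hit$site10, hit$site11))
  ev <- validate_targets(hit, fake_profiles(prof))
  expect_equal(ev$coincident_nt, 10L)
  # no signal at either candidate: alignment dropped
  ev <- validate_targets(hit, fake_profiles(stats::setNames(9L, hit$site10 - 5L)))
  expect_equal(nrow(ev), 0L)
  # unknown transcript is a hard error
  bad <- hit
  bad$transcript_id <- "nope"
  expect_error(validate_targets(bad, fake_profiles(stats::setNames(1L, 5L))),
               "unknown transcript")
})

test_that("t-plot tables flag validated sites and reconstruct the profile", {
  prof <- c("7" = 3L)
  ev <- data.frame(transcript_id = "tx", site = 7L, stringsAsFactors = FALSE)
  tab <- tplot_table(prof, ev, "tx")
  expect_equal(tab, data.frame(position = 7L, count = 3L,
                               is_validated_site = TRUE))
  set.seed(55)
  prof <- stats::setNames(sample(1:20, 5), sort(sample(300, 5)))
  tab <- tplot_table(prof, ev["site"], NULL)
  expect_equal(nrow(tab), 5L)
  expect_equal(sum(tab$is_validated_site), 0L)
  # reconstruction
  expect_equal(stats::setNames(as.integer(tab$count),
                               as.character(tab$position)),
               prof[order(as.integer(names(prof)))])
})

test_that("the category census counts events, sites, genes and miRNAs", {
  expect_equal(category_census(NULL)$events, rep(0L, 5))
  ev <- data.frame(mirna_id = c("m1", "m2", "m1"),
                   transcript_id = c("t1", "t2", "t3"),
                   site = c(5L, 9L, 2L), category = c(0L, 0L, 4L),
                   stringsAsFactors = FALSE)
  cen <- category_census(ev)
  expect_equal(cen$events[cen$category == 0L], 2L)
  expect_equal(cen$events[cen$category == 4L], 1L)
  expect_equal(cen$genes[cen$category == 0L], 2L)
  expect_equal(cen$mirnas[cen$category == 0L], 2L)
  # two miRNAs validating the same site: 2 events but 1 site
  ev2 <- data.frame(mirna_id = c("m1", "m2"), transcript_id = "t1",
                    site = 5L, category = 2L, stringsAsFactors = FALSE)
  cen2 <- category_census(ev2)
  expect_equal(cen2$events[cen2$category == 2L], 2L)
  expect_equal(cen2$sites[cen2$category == 2L], 1L)
})

test_that("a planted category mix is realised and recovered by the census", {
  txg <- generate_transcriptome(10, c(300, 500), 0.5, seed = 61)
  mirs <- generate_mirnas(10, seed = 62)
  pt <- data.frame(mirna_id = mirs$id, transcript_id = txg$id,
                   penalty = rep(c(0, 0.5, 1), length.out = 10))
  pl <- plant_sites(txg, mirs, pt, seed = 63)
  truth <- pl$truth
  truth$category <- rep(c(0L, 4L), each = 5L)
  dg <- simulate_degradome(pl$transcripts, truth, depth = 40,
                           noise_fraction = 0.1, seed = 64)
  al <- scan_targets(mirs, pl$transcripts)
  ev <- validate_targets(al, map_signatures(dg$reads, pl$transcripts))
  planted <- merge(ev, truth[, c("mirna_id", "transcript_id", "category")],
                   by = c("mirna_id", "transcript_id"),
                   suffixes = c("", "_planted"))
  planted <- planted[planted$site == ifelse(planted$coincident_nt == 10,
                                            planted$site, planted$site), ]
  recovered <- planted[planted$category == planted$category_planted, ]
  expect_gte(nrow(recovered), 9L)
  cen <- category_census(recovered)
  expect_equal(cen$events[cen$category == 0L], sum(recovered$category == 0L))
})
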