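test_that("merge_pair reconstructs an amplicon from overlapping reads", {
  withr::local_seed(31)
  amp <- random_dna(300)
  r1 <- substr(amp, 1, 180)
  r2 <- reverse_complement(substr(amp, 121, 300))
  q <- strrep("I", 180)
  m <- merge_pair(r1, q, r2, q)
  expect_identical(m$seq, amp)
  expect_equal(m$overlap, 60L)
  expect_equal(m$mismatches, 0L)

  # overlap disagreement resolves toward the higher-quality base
  r1_bad <- r1
  substr(r1_bad, 150, 150) <- if (substr(amp, 150, 150) == "A") "C" else "A"
  q_low <- q; substr(q_low, 150, 150) <- "5"  # Q20
  m2 <- merge_pair(r1_bad, q_low, r2, q)     # r2 base Q40 wins
  expect_identical(m2$seq, amp)
  expect_equal(m2$mismatches, 1L)
  m3 <- merge_pair(r1_bad, q, r2, q_low)     # r1 base wins now
  expect_identical(substr(m3$seq, 150, 150), substr(r1_bad, 150, 150))
  # merged quality is the per-base max
  expect_identical(substr(m2$qual, 150, 150), "I")

  # no acceptable overlap -> reject, not error
  expect_null(merge_pair(random_dna(100), strrep("I", 100),
                         random_dna(100), strrep("I", 100)))
})

test_that("quality_filter implements the all-bases-at-Q30 default", {
  expect_true(quality_filter(strrep("?", 449)))            # all exactly Q30
  q <- paste0(strrep("?", 448), ">")                       # one base Q29
  expect_false(quality_filter(q))
  q2 <- paste0(strrep("#", 5), strrep("I", 95))            # 5% at Q2
  expect_true(quality_filter(q2, min_q = 30, min_fraction = 0.9))
  expect_false(quality_filter(q2))
})

test_that("match_and_trim_flanks enforces cutadapt-style error rates", {
  withr::local_seed(37)
  flank5 <- random_dna(50)
  flank3 <- random_dna(50)
  insert <- random_dna(350)
  amp <- paste0(flank5, insert, flank3)
  res <- match_and_trim_flanks(amp, flank5, flank3)
  expect_true(res$accepted)
  expect_equal(c(res$start5, res$end5, res$start3, res$end3),
               c(1L, 50L, 401L, 450L))
  expect_identical(res$trimmed, amp)

  mutate_n <- function(s, n) {
    pos <- sample(nchar(s), n)
    for (p in pos) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    s
  }
  # 5 substitutions in a 50-nt flank (rate 0.1) accepted; 6 rejected
  amp5 <- paste0(mutate_n(flank5, 5), insert, flank3)
  amp6 <- paste0(mutate_n(flank5, 6), insert, flank3)
  res56 <- match_and_trim_flanks(c(amp5, amp6), flank5, flank3)
  expect_identical(res56$accepted, c(TRUE, FALSE))
  expect_equal(res56$edits5[1], 5L)
  # edit distances agree with an independent pairwiseAlignment oracle
  expect_equal(res56$edits5[1], oracle_semiglobal_edits(flank5, amp5))
  expect_equal(res56$edits5[2], oracle_semiglobal_edits(flank5, amp6))
  # missing 3' flank -> rejected
  res_no3 <- match_and_trim_flanks(paste0(flank5, insert), flank5, flank3)
  expect_false(res_no3$accepted)
})

test_that("semi-global locator agrees with the alignment oracle on indel reads", {
  withr::local_seed(41)
  flank <- random_dna(50)
  for (i in 1:10) {
    text <- paste0(random_dna(30), flank, random_dna(40))
    # plant 1-3 random edits inside the flank region
    n_ed <- sample(1:3, 1)
    mutated <- text
    for (k in seq_len(n_ed)) {
      p <- sample(31:70, 1)
      op <- sample(c("sub", "del", "ins"), 1)
      mutated <- switch(op,
        sub = { s <- mutated
                substr(s, p, p) <- sample(setdiff(c("A","C","G","T"),
                                                  substr(s, p, p)), 1); s },
        del = paste0(substr(mutated, 1, p - 1), substring(mutated, p + 1)),
        ins = paste0(substr(mutated, 1, p), "A", substring(mutated, p + 1)))
    }
    got <- choanoedit:::cpp_semiglobal_locate(flank, mutated)[1, "edits"]
    expect_equal(unname(got), oracle_semiglobal_edits(flank, mutated))
  }
})

test_that("extract_umi takes the leading k bases and rejects short reads", {
  out <- extract_umi(c("ACGTACGGGTTT", "ACGTA"), k = 6)
  expect_identical(out$ok, c(TRUE, FALSE))
  expect_identical(out$umi[1], "ACGTAC")
  expect_identical(out$seq[1], "GGGTTT")
  expect_equal(umi_space(6), 4096)
})

test_that("deduplicate collapses identical (umi, seq) pairs with counts", {
  umi <- c("AAAAAA", "AAAAAA", "AAAAAA", "CCCCCC", "AAAAAA")
  seq <- c("S1", "S1", "S1", "S1", "S2")
  seq <- chartr("S12", "GAT", seq)  # make them DNA-ish but distinct
  u <- deduplicate(umi, seq)
  expect_equal(nrow(u), 3L)
  expect_equal(sort(u$duplicate_count, decreasing = TRUE), c(3L, 1L, 1L))
  expect_equal(sum(u$duplicate_count), 5L)
  # all-distinct input is the identity
  u2 <- deduplicate(c("A", "C", "G"), c("TT", "TT", "TT"))
  expect_equal(nrow(u2), 3L)
  expect_true(all(u2$duplicate_count == 1L))
})

test_that("classify_amplicon applies the published precedence rules", {
  withr::local_seed(43)
  ref <- random_dna(200)
  cut <- 100L
  pts <- pts_sequence()
  with_pts <- paste0(substr(ref, 1, cut), pts, substring(ref, cut + 1))
  del4 <- paste0(substr(ref, 1, cut), substring(ref, cut + 5))
  snp1 <- ref; substr(snp1, 57, 57) <- if (substr(ref, 57, 57) == "A") "G" else "A"
  ins1 <- paste0(substr(ref, 1, cut), "A", substring(ref, cut + 1))
  cls <- classify_amplicon(c(ref, with_pts, del4, snp1, ins1), ref)
  expect_identical(as.character(cls),
                   c("EXACT_REF", "TEMPLATED_PTS", "INDEL", "SNP", "AMBIGUOUS_1BP"))
  # PTS precedence: a templated read with a 2-nt extra deletion is templated
  pts_del <- paste0(substr(with_pts, 1, 30), substring(with_pts, 33))
  expect_identical(as.character(classify_amplicon(pts_del, ref)), "TEMPLATED_PTS")
  # PTS with one internal mutation is still templated at tolerance 2...
  pts_mut <- with_pts
  substr(pts_mut, cut + 9L, cut + 9L) <- "G"
  expect_identical(as.character(classify_amplicon(pts_mut, ref)), "TEMPLATED_PTS")
  # ...but with tolerance 0 the strict substring rule applies (INDEL: +18 nt)
  expect_identical(as.character(classify_amplicon(pts_mut, ref,
                                                  pts_max_mismatch = 0L)), "INDEL")
  # strict mode agrees with a brute-force substring search
  reads <- c(ref, with_pts, del4, snp1, ins1, pts_mut, pts_del)
  strict <- classify_amplicon(reads, ref, pts_max_mismatch = 0L)
  expect_identical(strict == "TEMPLATED_PTS", grepl(pts, reads, fixed = TRUE))
})

test_that("summarize_editing computes unique-read percentages and the LOD", {
  cls <- factor(rep(c("TEMPLATED_PTS", "INDEL", "SNP", "EXACT_REF"),
                    c(15, 1, 4, 980)),
                levels = levels(classify_amplicon("ACGT", "ACGT")))
  s <- summarize_editing(cls)
  expect_equal(s$total, 1000)
  expect_equal(s$templated_pct, 1.5)
  expect_equal(s$indel_pct, 0.1)
  expect_equal(s$snp_pct, 0.4)
  expect_equal(s$limit_of_detection_pct, 100 / 4^6)
  expect_equal(sum(s$counts), s$total)
  # single exact read: all mutation frequencies zero
  s2 <- summarize_editing(factor("EXACT_REF",
                                 levels = levels(cls)))
  expect_equal(s2$templated_pct + s2$indel_pct + s2$snp_pct, 0)
  expect_error(summarize_editing(factor(character(), levels = levels(cls))),
               "no unique amplicons")
})

test_that("detection_limit is 100/4^k and monotone decreasing", {
  expect_equal(detection_limit(6), 0.0244140625)
  expect_equal(round(detection_limit(6), 2), 0.02)
  expect_equal(detection_limit(1), 25)
  k <- 1:10
  expect_true(all(diff(detection_limit(k)) < 0))
  expect_error(detection_limit(0), "umi_len")
})
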