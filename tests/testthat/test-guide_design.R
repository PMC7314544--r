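test_that("scan_protospacers finds a constructed single-PAM candidate", {
  # 24-nt locus: 20-nt spacer, then PAM AGG, then context base
  locus <- paste0(strrep("A", 16), "CTGA", "AGG", "A")
  cand <- scan_protospacers(locus, compute_dg = FALSE)
  plus <- cand[cand$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_identical(plus$spacer, paste0(strrep("A", 16), "CTGA"))
  expect_identical(plus$pam, "AGG")
  expect_equal(plus$pam_start, 21L)
  expect_equal(plus$motif_mismatches, 1L)  # PAM AGG violates S at motif pos 6

  expect_message(out <- scan_protospacers(strrep("A", 20)), "shorter")
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(scan_protospacers(strrep("A", 30), compute_dg = FALSE)), 0L)
})

test_that("scan_protospacers agrees with a brute-force count on random loci", {
  withr::local_seed(101)
  for (rep in 1:3) {
    locus <- random_dna(1000)
    cand <- scan_protospacers(locus, compute_dg = FALSE)
    expect_equal(nrow(cand), oracle_scan_count(locus))
    expect_true(all(vapply(cand$pam, function(p) iupac_match("NGG", p), logical(1))))
  }
})

test_that("scanning the reverse complement mirrors the candidate set", {
  withr::local_seed(55)
  locus <- random_dna(600)
  n <- nchar(locus)
  a <- scan_protospacers(locus, compute_dg = FALSE)
  b <- scan_protospacers(reverse_complement(locus), compute_dg = FALSE)
  expect_equal(nrow(a), nrow(b))
  # map b's candidates back into a's reference frame: strands swap and the
  # cut coordinate reflects (insertion point x on the rc is n - x here)
  key_a <- sort(paste(a$spacer, a$pam, a$strand, a$cleavage_pos))
  key_b <- sort(paste(b$spacer, b$pam, ifelse(b$strand == "+", "-", "+"),
                      n - b$cleavage_pos))
  expect_identical(key_a, key_b)
})

test_that("motif_mismatch_count matches hand-derived cases and the IUPAC oracle", {
  expect_equal(motif_mismatch_count("ACTGAGGGA"), 0L)
  expect_equal(motif_mismatch_count("GCTGAGGGA"), 1L)
  withr::local_seed(3)
  ctx <- vapply(1:500, function(i) random_dna(9), character(1))
  expect_equal(motif_mismatch_count(ctx), oracle_motif_mismatches(ctx))
})

test_that("cleavage_site applies the 3-bp rule on both strands", {
  expect_equal(cleavage_site(120, "+"), 117L)
  expect_equal(cleavage_site(102, "-"), 106L)  # PAM [100,103), spacer [103,123)
  expect_error(cleavage_site(2, "+"), "underflow")
})

test_that("bundled folding DP equals the exhaustive hairpin oracle", {
  expect_equal(predict_fold_dg(strrep("A", 20)), 0)
  expect_lt(predict_fold_dg("GGGGGGGGAAAACCCCCCCC"), -1.5)
  withr::local_seed(13)
  seqs <- c("GGGGGGGGAAAACCCCCCCC", "GCGCAAAGCGC",
            vapply(1:25, function(i) random_dna(20), character(1)),
            vapply(1:10, function(i) random_dna(20, gc = 0.8), character(1)))
  dg <- predict_fold_dg(seqs)
  expect_true(all(dg <= 0))
  for (k in seq_along(seqs)) {
    expect_equal(dg[k], oracle_hairpin_mfe(seqs[k]), tolerance = 1e-9,
                 label = sprintf("MFE of %s", seqs[k]))
  }
  # pluggable backend is used verbatim
  expect_equal(predict_fold_dg("ACGTACGTACGTACGTACGT",
                               backend = function(s) -9.9), -9.9)
})

test_that("verify_genomic_contiguity detects exon-junction guides", {
  withr::local_seed(21)
  exon1 <- random_dna(80)
  intron <- random_dna(40)
  exon2 <- random_dna(80)
  genome <- c(chr1 = paste0(exon1, intron, exon2))
  ann <- data.frame(contig = "chr1",
                    start = c(1L, 121L), end = c(80L, 200L))
  # guide taken verbatim from exon 1 interior
  g_ok <- substr(exon1, 10, 32)
  expect_true(verify_genomic_contiguity(g_ok, genome))
  expect_true(verify_genomic_contiguity(g_ok, genome, ann))
  expect_true(verify_genomic_contiguity(reverse_complement(g_ok), genome, ann))
  # junction guide: last 12 nt of exon 1 + first 11 nt of exon 2 (cDNA only)
  g_junc <- paste0(substr(exon1, 69, 80), substr(exon2, 1, 11))
  expect_false(verify_genomic_contiguity(g_junc, genome))
  # a guide spanning exon/intron exists genomically but not within one exon
  g_span <- substr(genome[[1]], 70, 92)
  expect_true(verify_genomic_contiguity(g_span, genome))
  expect_false(verify_genomic_contiguity(g_span, genome, ann))
})

test_that("filter_guides applies thresholds and a total deterministic ranking", {
  cand <- data.frame(
    guide_id = paste0("g", 1:4), contig = "c", strand = "+",
    spacer = strrep("A", 20), pam = "AGG",
    pam_start = c(30L, 50L, 70L, 90L), cleavage_pos = c(27L, 47L, 67L, 87L),
    spacer_start = c(10L, 30L, 50L, 70L), context = "ACTGAGGGA",
    motif_mismatches = c(0L, 0L, 0L, 1L),
    delta_g = c(0.0, -2.0, 0.0, -0.5), passes_filter = NA,
    stringsAsFactors = FALSE)
  out <- filter_guides(cand)
  expect_identical(out$guide_id, c("g1", "g3"))   # dG -2.0 excluded; tie by coord
  expect_true(all(out$passes_filter))
  out2 <- filter_guides(cand, max_motif_mismatches = 1L)
  expect_identical(out2$guide_id, c("g1", "g3", "g4"))
  expect_true(all(out2$guide_id %in% cand$guide_id))
})
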