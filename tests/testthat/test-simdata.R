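test_that("simulate_locus plants a motif-perfect, unstructured guide", {
  loc <- simulate_locus(300, seed = 1)
  expect_equal(nchar(loc$seq), 300L)
  cand <- scan_protospacers(loc$seq)
  planted <- cand[cand$strand == "+" & cand$pam_start == loc$guide$pam_start, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$motif_mismatches, 0L)
  expect_equal(planted$delta_g, 0)
  expect_equal(planted$cleavage_pos, loc$guide$cleavage_pos)
  # determinism and seed sensitivity
  expect_identical(simulate_locus(300, seed = 1)$seq, loc$seq)
  expect_false(identical(simulate_locus(300, seed = 2)$seq, loc$seq))
  # degenerate GC still plants the (AT-rich) guide, as documented
  gc1 <- simulate_locus(300, gc = 1, seed = 3)
  expect_true(grepl(gc1$guide$spacer, gc1$seq, fixed = TRUE))
  expect_error(simulate_locus(100), ">= 150")
})

test_that("amplicon_sim_spec validates its stated world", {
  spec <- amplicon_sim_spec(seed = 5)
  expect_equal(nchar(spec$reference), 450L)
  expect_equal(spec$umi_len, 6L)
  expect_equal(spec$read_len, 300L)
  expect_equal(spec$templated_frac, 0.015)
  expect_equal(spec$indel_frac, 0.001)
  expect_error(amplicon_sim_spec(templated_frac = 0.9, indel_frac = 0.2))
  expect_error(amplicon_sim_spec(indel_sizes = 1:5))
})

test_that("truth-table class fractions track the spec frequencies", {
  run <- simulate_amplicon_run(amplicon_sim_spec(
    n_molecules = 2000, templated_frac = 0.05, indel_frac = 0.01, seed = 6))
  phat <- mean(run$truth$true_class == "TEMPLATED")
  sigma <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(phat - 0.05), 3 * sigma)
  # law of large numbers: the deviation shrinks with n
  run_big <- simulate_amplicon_run(amplicon_sim_spec(
    n_molecules = 20000, templated_frac = 0.05, indel_frac = 0.01, seed = 6))
  phat_big <- mean(run_big$truth$true_class == "TEMPLATED")
  expect_lt(abs(phat_big - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
})

test_that("error-free single-copy runs are recovered exactly, bin for bin", {
  run <- simulate_amplicon_run(amplicon_sim_spec(
    n_molecules = 300, templated_frac = 0.05, indel_frac = 0.02,
    dup_mean = 1, inject_errors = FALSE, seed = 8))
  expect_true(all(run$truth$n_reads == 1L))
  q <- quantify_run(run$r1, run$r2, reference = run$spec$reference,
                    pts_max_mismatch = 0L)
  expect_true(all(q$dispositions$disposition == "binned"))
  expected <- oracle_collapse_truth(run$truth)
  got <- q$unique[order(q$unique$umi, q$unique$seq), , drop = FALSE]
  expect_equal(nrow(got), nrow(expected))
  expect_identical(got$umi, expected$umi)
  expect_identical(got$seq, expected$seq)
  expect_identical(got$duplicate_count, expected$duplicate_count)
  expect_identical(as.character(got$class),
                   unname(map_truth_class(expected$true_class)))
})

test_that("PCR duplicates collapse back to the truth-table bins", {
  run <- simulate_amplicon_run(amplicon_sim_spec(
    n_molecules = 150, templated_frac = 0.05, dup_mean = 4,
    inject_errors = FALSE, seed = 9))
  expect_gt(nrow(run$r1), 150)
  q <- quantify_run(run$r1, run$r2, reference = run$spec$reference)
  expected <- oracle_collapse_truth(run$truth)
  expect_equal(nrow(q$unique), nrow(expected))
  expect_equal(sum(q$unique$duplicate_count), nrow(run$r1))
})

test_that("simulated runs are byte-identical under a fixed seed", {
  s <- amplicon_sim_spec(n_molecules = 120, seed = 10)
  a <- simulate_amplicon_run(s)
  b <- simulate_amplicon_run(s)
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  expect_identical(a$truth, b$truth)
  # and FASTQ output round-trips through seqio
  pre <- file.path(withr::local_tempdir(), "sim")
  paths <- write_amplicon_run(a, pre, gzip = FALSE)
  back <- read_fastq_pairs(paths[["r1"]], paths[["r2"]])
  expect_identical(back$r1$seq, a$r1$seq)
  expect_identical(back$r2$qual, a$r2$qual)
})

test_that("simulate_growth_series is exact at zero noise and deterministic", {
  df <- simulate_growth_series(K = 1e7, P0 = 1e4, T_const = 12, noise_cv = 0,
                               replicates = 3, seed = 4)
  expect_equal(nrow(df), 39L)  # 13 timepoints x 3 replicates
  one <- df[df$replicate == 1, ]
  expect_equal(one$density_cells_per_ml,
               logistic_density(one$time_h, 1e7, 1e4, 12))
  noisy1 <- simulate_growth_series(noise_cv = 0.2, seed = 12)
  noisy2 <- simulate_growth_series(noise_cv = 0.2, seed = 12)
  expect_identical(noisy1, noisy2)
})
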