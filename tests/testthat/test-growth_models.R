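test_that("logistic_density matches the closed form and its limits", {
  expect_equal(logistic_density(0, K = 2, P0 = 1, T_const = 1), 1)
  expect_equal(logistic_density(log(3), K = 2, P0 = 1, T_const = 1), 1.5)
  expect_equal(logistic_density(50 * 12, K = 1e7, P0 = 1e4, T_const = 12), 1e7,
               tolerance = 1e-6)
  expect_error(logistic_density(1, K = -1, P0 = 1, T_const = 1), "parameters")
  # strictly increasing when K > P0, strictly decreasing when K < P0
  t <- seq(0, 100, by = 5)
  expect_true(all(diff(logistic_density(t, 1e6, 1e3, 10)) > 0))
  expect_true(all(diff(logistic_density(t, 1e3, 1e6, 10)) < 0))
})

test_that("LAD logistic fit recovers noiseless parameters within 1%", {
  truth <- c(K = 1e7, P0 = 1e4, T = 12)
  t <- seq(0, 144, by = 12)  # 13 points over 6 days
  P <- logistic_density(t, truth["K"], truth["P0"], truth["T"])
  fit <- fit_logistic_lad(t, P, seed = 1)
  expect_lt(abs(fit$K - truth[["K"]]) / truth[["K"]], 0.01)
  expect_lt(abs(fit$P0 - truth[["P0"]]) / truth[["P0"]], 0.01)
  expect_lt(abs(fit$T - truth[["T"]]) / truth[["T"]], 0.01)
  # monotone improvement over the heuristic init
  expect_lte(fit$l1_residual, fit$init_objective)
  # deterministic given the seed
  fit2 <- fit_logistic_lad(t, P, seed = 1)
  expect_identical(fit[c("K", "P0", "T", "l1_residual")],
                   fit2[c("K", "P0", "T", "l1_residual")])
})

test_that("LAD fit recovers T within 15% under 20% multiplicative noise", {
  df <- simulate_growth_series(K = 1e7, P0 = 1e4, T_const = 12,
                               noise_cv = 0.2, replicates = 3, seed = 29)
  for (r in unique(df$replicate)) {
    d <- df[df$replicate == r, ]
    fit <- fit_logistic_lad(d$time_h, d$density_cells_per_ml, seed = 2)
    expect_lt(abs(fit$T - 12) / 12, 0.15, label = sprintf("replicate %d T", r))
  }
})

test_that("degenerate growth series warns and fits K ~ P0", {
  fit <- fit_logistic_lad(c(0, 12, 24, 36), rep(5e5, 4), seed = 3)
  expect_true(any(grepl("degenerate", fit$warnings)))
  expect_error(fit_logistic_lad(c(0, 12), c(1, 2)), "at least 4")
})

test_that("dose-inhibition fit recovers Hill parameters on noiseless data", {
  conc <- c(0.1, 0.5, 1, 2, 5, 10, 20, 50)
  truth <- list(top = 1e6, ic50 = 5, hill = 2)
  dens <- truth$top / (1 + (conc / truth$ic50)^truth$hill)
  fit <- fit_dose_inhibition(conc, dens)
  expect_equal(fit$top, truth$top, tolerance = 1e-3)
  expect_equal(fit$ic50, truth$ic50, tolerance = 1e-3)
  expect_equal(fit$hill, truth$hill, tolerance = 1e-3)
  # density at c = IC50 is top/2 by construction
  expect_equal(truth$top / (1 + (truth$ic50 / fit$ic50)^fit$hill),
               truth$top / 2, tolerance = 1e-3 * truth$top)
  flat <- fit_dose_inhibition(conc, rep(1e6, length(conc)))
  expect_true(any(grepl("flat", flat$warnings)))
})

test_that("limiting-dilution occupancy and single-founder probabilities", {
  expect_equal(mean_occupancy(3, 0.1), 0.3)
  expect_equal(mean_occupancy(10, 0.05), 0.5)
  expect_warning(z <- mean_occupancy(3, 0), "zero")
  expect_equal(z, 0)

  p <- single_founder_probability(0.3)
  expect_equal(round(p$p_single_given_occupied, 4), 0.8575)
  expect_equal(p$p_ge_2, 1 - exp(-0.3) * 1.3, tolerance = 1e-12)
  expect_equal(round(p$p_ge_2, 4), 0.0369)
  expect_equal(p$p_le_1 + p$p_ge_2, 1)
  # strictly decreasing in lambda, limit 1 as lambda -> 0+
  lam <- c(1e-6, 0.1, 0.3, 1, 3)
  ps <- vapply(lam, function(l) single_founder_probability(l)$p_single_given_occupied,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps < 1))
  expect_equal(ps[1], 1, tolerance = 1e-5)
  expect_error(single_founder_probability(0), "positive")
})

test_that("growth TSV round-trips through the reader", {
  df <- simulate_growth_series(noise_cv = 0, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_growth_tsv(f)
  expect_equal(back$density_cells_per_ml, df$density_cells_per_ml)
  expect_error(read_growth_tsv({
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write.table(data.frame(a = 1), f2, sep = "\t", row.names = FALSE)
    f2
  }), "columns")
})
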