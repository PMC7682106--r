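make_long <- function(mat, times = seq_len(ncol(mat) / 3), reps = 3) {
  # mat: features x (time*rep) with samples ordered rep-within-time
  grid <- expand.grid(replicate = seq_len(reps), time = times)
  do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    data.frame(feature = rownames(mat)[i], time = grid$time,
               replicate = grid$replicate, value = mat[i, ])
  }))
}

test_that("size factors are unit for identical samples and recover scaling", {
  m <- matrix(rpois(60, 50) + 1, nrow = 10)
  m <- m[, rep(1, 6)]
  rownames(m) <- paste0("g", 1:10)
  sf <- size_factor_normalize(make_long(m, times = 1:2))$size_factors
  expect_equal(unname(sf), rep(1, 6))

  m2 <- m
  m2[, 4] <- m2[, 4] * 2
  res <- size_factor_normalize(make_long(m2, times = 1:2))
  sf2 <- res$size_factors
  expect_equal(unname(sf2[4] / sf2[1]), 2)
  # normalized matrix equals the baseline up to one common scale
  norm_mat <- tapply(res$values$value,
                     list(res$values$feature,
                          paste(res$values$time, res$values$replicate)),
                     mean)
  expect_lt(max(apply(norm_mat, 1, function(r) diff(range(r)))), 1e-9)
})

test_that("size factors have unit geometric mean and match the independent
           median-of-ratios implementation", {
  set.seed(7)
  m <- matrix(rnbinom(200 * 12, mu = 100, size = 5) + 1, nrow = 200)
  rownames(m) <- paste0("g", 1:200)
  long <- make_long(m, times = 1:4)
  sf <- size_factor_normalize(long)$size_factors
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(sf), unname(ref), tolerance = 1e-9)
})

test_that("all-zero samples and all-zero features are rejected", {
  m <- matrix(0, 5, 6, dimnames = list(paste0("g", 1:5), NULL))
  expect_error(size_factor_normalize(make_long(m, times = 1:2)), "all-zero")
})

test_that("M-values follow the pooled-reference definition", {
  # constant feature -> M = 0 everywhere
  long <- data.frame(feature = "g1", time = rep(1:4, each = 2),
                     replicate = rep(1:2, 4), value = 6)
  expect_equal(compute_m_values(long)$M, rep(0, 4))

  # two-time toy: values 2 and 8, reference 5
  toy <- data.frame(feature = "g1", time = c(1, 2), replicate = 1,
                    value = c(2, 8))
  expect_equal(compute_m_values(toy)$M, c(log2(0.4), log2(1.6)))

  # algebraic identity: mean over time of 2^M is exactly 1
  set.seed(3)
  long <- make_long(matrix(rlnorm(50 * 21, 5, 1), nrow = 50,
                           dimnames = list(paste0("g", 1:50), NULL)),
                    times = 1:7)
  m <- compute_m_values(long)
  backs <- tapply(2^m$M, m$feature, mean)
  expect_lt(max(abs(backs - 1)), 1e-12)
})

test_that("zero-reference features are flagged with undefined M", {
  long <- data.frame(feature = "dead", time = 1:3, replicate = 1, value = 0)
  m <- compute_m_values(long)
  expect_true(all(is.na(m$M)))
  expect_equal(attr(m, "undefined_reference"), "dead")
})

test_that("identical replicate values yield no significant calls", {
  long <- make_long(matrix(5, 10, 12, dimnames = list(paste0("g", 1:10), NULL)),
                    times = 1:4)
  res <- test_significance(long)
  expect_false(any(res$significant))
})

test_that("fewer than two replicates gives NA p and no call", {
  long <- data.frame(feature = "g1", time = rep(1:4, each = 2),
                     replicate = rep(1:2, 4), value = rnorm(8, 10))
  long <- long[!(long$time == 2 & long$replicate == 2), ]
  res <- test_significance(long)
  expect_true(is.na(res$p[res$time == 2]))
  expect_false(res$significant[res$time == 2])
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.5)
  expect_equal(bh_oracle(p), c(0.05, 0.05, 0.05, 0.05, 0.5))
  expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
  expect_equal(stats::p.adjust(0.037, "BH"), 0.037)  # single test: p_adj = p
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("dynamic filter keeps any-significant features and drops boundary 0.05", {
  p_adj <- stats::p.adjust(c(0.01, 0.02, 0.03, 0.04, 0.5), "BH")
  records <- data.frame(feature = rep(c("a", "b"), c(4, 1)),
                        time = c(1:4, 1),
                        p_adj = p_adj,
                        significant = p_adj < 0.05)
  # BH here produces exactly 0.05: strictly-less-than rules those out
  expect_equal(records$p_adj[1], 0.05)
  expect_equal(filter_dynamic(records), character(0))

  records$significant[1] <- TRUE
  expect_equal(filter_dynamic(records), "a")
})

test_that("flat (null) genes are almost all ruled out at nominal FDR", {
  cfg <- sim_config(seed = 21, n_genes = 200,
                    archetype_probs = c(lag_peak = 0, monotone_decrease = 0,
                                        growth_peak = 0, transition_peak = 0,
                                        stationary_rise = 0, flat = 1))
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(sim$truth, cfg)
  norm <- size_factor_normalize(expr$counts)
  res <- test_significance(norm$values)
  retained <- filter_dynamic(res)
  expect_lte(length(retained) / cfg$n_genes, 0.05)
})

test_that("overview percentages use half-away-from-zero rounding to one decimal", {
  expect_equal(summarize_significance(1421, 8364), 17.0)
  expect_equal(summarize_significance(699, 878), 79.6)
  expect_equal(summarize_significance(0, 10), 0.0)
  expect_equal(summarize_significance(1, 16), 6.3)   # 6.25 rounds away from zero
  expect_equal(summarize_significance(49, 50), 98.0)
  expect_error(summarize_significance(1, 0), "positive")
  expect_error(summarize_significance(5, 4), "n <= denominator")
})

test_that("the significance overview counts up/down calls per time point", {
  records <- data.frame(
    feature = rep(c("a", "b", "c"), each = 2),
    time = rep(1:2, 3),
    M = c(1, -1, 2, 2, -3, 0.5),
    significant = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  ov <- significance_overview(records)
  # t1: a up, c down; t2: b up (M > 0), a down (M < 0), c not significant
  expect_equal(ov$n_up, c(1, 1))
  expect_equal(ov$n_down, c(1, 1))
  expect_equal(ov$denominator, c(3, 3))
  expect_equal(ov$pct_up, c(33.3, 33.3))
})
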