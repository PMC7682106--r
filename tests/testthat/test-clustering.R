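test_that("profile preparation drops sparse features and imputes neighbours", {
  m <- matrix(NA_real_, 3, 7,
              dimnames = list(c("sparse", "interior", "boundary"), 1:7))
  m["sparse", 1:4] <- 1                       # 4 of 7 observed: dropped
  m["interior", ] <- c(1, NA, 3, 4, 5, 6, 7)  # interior gap
  m["boundary", ] <- c(NA, 2, 3, 4, 5, 6, 7)  # first point missing
  out <- prepare_profiles(m)
  expect_equal(attr(out, "dropped"), "sparse")
  expect_equal(unname(out["interior", 2]), 2)   # mean of 1 and 3
  expect_equal(unname(out["boundary", 1]), 2)   # single available neighbour
  expect_false(anyNA(out))
})

test_that("two adjacent gaps impute from the nearest observed values", {
  m <- matrix(c(0, NA, NA, 6, 8, 10, 12), 1, 7,
              dimnames = list("g", 1:7))
  out <- prepare_profiles(m)
  expect_equal(unname(out[1, 2]), 3)  # mean of 0 and 6
  expect_equal(unname(out[1, 3]), 3)  # nearest observed are still 0 and 6
})

test_that("Ward clustering separates far apart groups and handles ties at zero", {
  x <- rbind(matrix(rnorm(9, 0, 0.01), 3), matrix(rnorm(9, 100, 0.01), 3))
  rownames(x) <- paste0("p", 1:6)
  sol <- ward_cluster(x, 2)
  expect_true(same_partition(sol$assignments, rep(1:2, each = 3)))

  same <- matrix(1, 5, 3, dimnames = list(paste0("p", 1:5), NULL))
  expect_equal(ward_cluster(same, 2)$heights, rep(0, 4))
  expect_error(ward_cluster(same, 9), "exceeds")
})

test_that("Ward agrees with the exhaustive greedy SSE oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    x <- matrix(runif(n * 3), n)
    rownames(x) <- paste0("p", seq_len(n))
    oracle <- greedy_ward_oracle(x)
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    for (k in 2:(n - 1)) {
      expect_true(same_partition(stats::cutree(hc, k), oracle[[k]]))
    }
  }
})

test_that("within-cluster dispersion equals the brute-force double sum", {
  expect_equal(within_dispersion(matrix(c(0, 2), 2, 1), c(1, 1)), 2)
  expect_equal(within_dispersion(matrix(rnorm(10), 5, 2), 1:5), 0)

  set.seed(5)
  x <- matrix(rnorm(60), 20, 3)
  a <- sample(1:4, 20, replace = TRUE)
  brute <- 0
  for (cl in unique(a)) {
    idx <- which(a == cl)
    ctr <- colMeans(x[idx, , drop = FALSE])
    for (i in idx) brute <- brute + sum((x[i, ] - ctr)^2)
  }
  expect_equal(within_dispersion(x, a), brute, tolerance = 1e-9)
})

test_that("the KL index finds two well-separated blobs", {
  set.seed(41)
  x <- rbind(matrix(rnorm(250 * 7, 0, 0.5), 250),
             matrix(rnorm(250 * 7, 5, 0.5), 250))
  rownames(x) <- paste0("f", 1:500)
  sol <- cluster_dynamics(x, k_max = 10)
  expect_equal(sol$k_opt, 2L)
})

test_that("KL formula matches direct evaluation and flags structureless traces", {
  W <- 0.7^(1:11)
  p <- 7
  expect_warning(res <- kl_optimal_k(W, p, k_max = 10), "low contrast")
  for (k in 2:9) {
    DIFFk <- (k - 1)^(2 / p) * W[k - 1] - k^(2 / p) * W[k]
    DIFFk1 <- k^(2 / p) * W[k] - (k + 1)^(2 / p) * W[k + 1]
    expect_equal(res$KL[k], abs(DIFFk) / abs(DIFFk1))
  }
  expect_true(res$low_contrast)

  flat <- kl_optimal_k(rep(0, 11), p = 7, k_max = 10)
  expect_true(flat$flat)
  expect_true(is.na(flat$k_opt))
})

test_that("scaling profiles scales W by c^2 and leaves KL and k_opt unchanged", {
  set.seed(43)
  x <- rbind(matrix(rnorm(90 * 7, 0, 0.4), 90),
             matrix(rnorm(90 * 7, 3, 0.4), 90),
             matrix(rnorm(90 * 7, -3, 0.4), 90))
  rownames(x) <- paste0("f", 1:270)
  a <- suppressWarnings(cluster_dynamics(x, k_max = 8))
  b <- suppressWarnings(cluster_dynamics(x * 5, k_max = 8))
  expect_equal(b$W, a$W * 25)
  expect_equal(b$KL, a$KL)
  expect_equal(b$k_opt, a$k_opt)
  expect_equal(a$k_opt, 3L)
  # dispersion trace is monotone non-increasing
  expect_true(all(diff(a$W) <= 1e-9))
})

test_that("clustering is invariant to feature order permutation", {
  set.seed(47)
  x <- rbind(matrix(rnorm(40 * 7, 0, 0.3), 40),
             matrix(rnorm(40 * 7, 4, 0.3), 40))
  rownames(x) <- paste0("f", 1:80)
  perm <- sample(80)
  a <- suppressWarnings(cluster_dynamics(x, k_max = 6))
  b <- suppressWarnings(cluster_dynamics(x[perm, ], k_max = 6))
  expect_equal(b$k_opt, a$k_opt)
  expect_true(same_partition(a$assignments[rownames(x)[perm]], b$assignments))
})

test_that("cluster mean profiles average members and recover archetype shapes", {
  x <- rbind(a = rep(0, 4), b = rep(2, 4), c = c(9, 9, 9, 9))
  sol <- list(assignments = c(a = 1, b = 1, c = 2))
  cp <- cluster_profiles(sol, x)
  expect_equal(unname(cp$means[1, ]), rep(1, 4))
  expect_equal(unname(cp$means[2, ]), rep(9, 4))  # singleton keeps its profile
  expect_equal(cp$sizes, c(2L, 1L))

  arch <- do.call(rbind, default_archetypes(7)[c("lag_peak", "growth_peak",
                                                 "stationary_rise")])
  set.seed(53)
  lab <- sample(1:3, 300, replace = TRUE)
  prof <- arch[lab, ] + matrix(rnorm(300 * 7, 0, 0.2), 300)
  rownames(prof) <- paste0("f", 1:300)
  sol2 <- suppressWarnings(cluster_dynamics(prof, k_max = 8))
  expect_equal(sol2$k_opt, 3L)
  cp2 <- cluster_profiles(sol2, prof)
  best_cor <- apply(cp2$means, 1, function(m) max(cor(m, t(arch))))
  expect_true(all(best_cor >= 0.95))
})

test_that("five planted expression archetypes are recovered end to end", {
  cfg <- sim_config(seed = 3, n_genes = 500, nb_dispersion = 0.02,
                    archetype_probs = c(lag_peak = 0.2,
                                        monotone_decrease = 0.2,
                                        growth_peak = 0.2,
                                        transition_peak = 0.2,
                                        stationary_rise = 0.2, flat = 0))
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(sim$truth, cfg)
  prof <- prepare_profiles(
    compute_m_values(size_factor_normalize(expr$counts)$values))
  sol <- suppressWarnings(cluster_dynamics(prof, k_max = 20))
  expect_equal(sol$k_opt, 5L)
  lab <- sim$truth$genes$archetype[match(rownames(prof),
                                         sim$truth$genes$gene)]
  expect_gte(mclust::adjustedRandIndex(sol$assignments, lab), 0.9)
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  # one cluster holding all and only the 5 category-N features of 20
  labels <- setNames(rep(c("N", "O"), c(5, 15)), paste0("f", 1:20))
  sol <- list(assignments = setNames(rep(c(1, 2), c(5, 15)), paste0("f", 1:20)))
  enr <- category_enrichment(sol, labels)
  row <- enr[enr$cluster == 1 & enr$category == "N", ]
  expect_equal(row$p, choose(5, 5) * choose(15, 0) / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(row$p, 6.45e-5, tolerance = 1e-2)
  expect_true(row$enriched)
})

test_that("shuffled labels stay near the nominal enrichment rate", {
  set.seed(61)
  n <- 400
  frac <- replicate(20, {
    labels <- setNames(sample(LETTERS[1:8], n, replace = TRUE),
                       paste0("f", 1:n))
    sol <- list(assignments = setNames(sample(1:6, n, replace = TRUE),
                                       paste0("f", 1:n)))
    mean(category_enrichment(sol, labels)$enriched)
  })
  expect_lte(mean(frac), 0.05 + 3 * sqrt(0.05 * 0.95 / (20 * 48)))
})
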