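# windows with a planted hexamer over a background alphabet, used to check
# EM recovery with known offsets
planted_windows <- function(n_with, n_without, offsets, width = 50,
                            motif = "TAGCAT", bg = c("C", "G"), seed = 1) {
  set.seed(seed)
  mk_bg <- function() paste(sample(bg, width, replace = TRUE), collapse = "")
  wins <- character(n_with + n_without)
  offs <- integer(n_with)
  for (i in seq_len(n_with)) {
    w <- mk_bg()
    o <- sample(offsets, 1)
    substr(w, o, o + nchar(motif) - 1) <- motif
    wins[i] <- w
    offs[i] <- o
  }
  for (i in seq_len(n_without)) wins[n_with + i] <- mk_bg()
  list(windows = wins, offsets = offs)
}

test_that("EM recovers a planted motif, its offsets and the hit fraction", {
  pw <- planted_windows(120, 15, offsets = 38:42, seed = 3)
  model <- em_motif_search(pw$windows, n_restarts = 5, seed = 1)
  expect_equal(model$consensus, "TAGCAT")
  expect_gte(mean(model$hit[1:120]), 0.95)
  expect_lte(mean(model$hit[121:135]), 0.2)
  found <- model$offsets[1:120]
  expect_gte(mean(found == pw$offsets, na.rm = TRUE), 0.95)
})

test_that("the EM objective is non-decreasing over iterations", {
  pw <- planted_windows(60, 10, offsets = 30:40, seed = 5)
  model <- em_motif_search(pw$windows, n_restarts = 3, seed = 2)
  expect_true(all(diff(model$loglik) >= -1e-8))
})

test_that("identical windows drive the PFM to the pseudocount-smoothed fixed point", {
  w <- paste0(strrep("CG", 10), "TAGCAT", strrep("GC", 12))
  wins <- rep(w, 30)
  model <- em_motif_search(wins, n_restarts = 2, seed = 1)
  expect_equal(model$consensus, "TAGCAT")
  # informative columns are (n + 0.25) / (n + 1)-smoothed indicators
  expect_true(all(apply(model$pfm, 2, max) > 0.9))
})

test_that("single-letter degenerate input is flagged", {
  wins <- rep(strrep("A", 30), 12)
  model <- em_motif_search(wins, n_restarts = 2, seed = 1)
  expect_true(model$degenerate)
})

test_that("motif frequency columns always sum to one", {
  pw <- planted_windows(40, 40, offsets = 10:30, bg = c("A", "C", "G", "T"),
                        seed = 7)
  model <- em_motif_search(pw$windows, n_restarts = 3, seed = 3)
  expect_equal(unname(colSums(model$pfm)), rep(1, 6), tolerance = 1e-12)
})

test_that("consensus rendering matches the reported promoter frequencies", {
  pfm10 <- matrix(c(
    # A     C     G     T  (columns = positions)
    0.12, 0.12, 0.14, 0.636,
    0.908, 0.03, 0.03, 0.032,
    0.30, 0.25, 0.25, 0.20,
    0.25, 0.30, 0.25, 0.20,
    0.20, 0.30, 0.30, 0.20,
    0.05, 0.05, 0.043, 0.857), nrow = 4,
    dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(consensus_string(pfm10), "TAnnnT")

  pfm35 <- matrix(c(
    0.25, 0.25, 0.25, 0.25,
    0.15, 0.09, 0.08, 0.679,
    0.05, 0.06, 0.837, 0.053,
    0.530, 0.17, 0.15, 0.15,
    0.09, 0.820, 0.05, 0.04,
    0.25, 0.25, 0.25, 0.25), nrow = 4,
    dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(consensus_string(pfm35), "nTGACn")

  uniform <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(consensus_string(uniform), "nnnnnn")
})

test_that("spacer statistics reproduce closed-form moments", {
  s <- spacer_stats(rep(6, 40))
  expect_equal(s$mean, 6)
  expect_equal(s$sd, 0)

  set.seed(11)
  u <- sample(5:7, 3000, replace = TRUE)
  su <- spacer_stats(u)
  expect_equal(su$mean, 6, tolerance = 0.05)
  expect_equal(su$sd, sqrt(2 / 3), tolerance = 0.03)  # uniform on {5,6,7}
  expect_equal(sum(su$histogram), 3000)

  empty <- spacer_stats(integer(0))
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
})

test_that("promoter search on planted windows recovers both elements and spacers", {
  # plant: -35 NTGACN ... spacer 17 ... -10 TAGCAT ... spacer s10 ... TSS(end)
  set.seed(13)
  wins <- vapply(1:80, function(i) {
    s10 <- sample(5:7, 1)
    left <- 50 - 6 - s10 - 17 - 6
    paste0(paste(sample(c("C", "G"), left, TRUE), collapse = ""),
           "GTGACC", strrep("G", 17), "TAGCAT",
           paste(rep("C", s10), collapse = ""))
  }, "")
  pm <- promoter_motifs(wins, seed = 2, n_restarts = 5)
  expect_equal(pm$minus10$consensus, "TAGCAT")
  expect_gte(pm$minus10$fraction_with_hit, 0.9)
  expect_equal(pm$spacer10$mean, 6, tolerance = 0.25)
  # EM alignment of the -35 may shift by one column; the spacer scale holds
  expect_equal(pm$spacer3510$mean, 17, tolerance = 1.5)
  # windows lacking a -35 hit are excluded from the -35/-10 spacing
  expect_lte(pm$spacer3510$n, pm$spacer10$n)
})

test_that("RBS search and TSS base statistics work on constructed inputs", {
  # genes on + strand, UTR 30 nt with GGAGG ending 8 nt upstream of the TLS
  set.seed(17)
  L <- 12000
  chars <- sample(c("C", "G"), L, replace = TRUE)
  tss_rows <- list()
  for (i in 1:15) {
    tls <- 500 + i * 700
    chars[(tls - 12):(tls - 8)] <- c("G", "G", "A", "G", "G")
    chars[tls - 30] <- "G"
    tss_rows[[i]] <- data.frame(tss_id = paste0("t", i), pos = tls - 30,
                                strand = "+", gene = paste0("g", i),
                                read_start_count = 50, utr_length = 30L,
                                leaderless = FALSE, start_nucleotide = "G")
  }
  genome <- Biostrings::DNAString(paste(chars, collapse = ""))
  tss <- do.call(rbind, tss_rows)
  res <- rbs_and_start_stats(tss, genome, seed = 3, n_restarts = 5)
  expect_gte(res$rbs_fraction, 0.9)
  expect_equal(res$purine_fraction, 1.0)
  expect_equal(unname(res$tss_base_distribution), c(0, 0, 1, 0))
})

test_that("simulated promoters yield the planted -10 consensus and spacer scale", {
  env <- local_sim()
  cand <- detect_tss(env$tracks$five_prime)
  tss <- assign_primary_tss(cand, env$sim$annotation, env$sim$genome)
  wins <- extract_upstream_windows(tss, env$sim$genome)
  pm <- promoter_motifs(wins, seed = 4, n_restarts = 5)
  expect_equal(pm$minus10$consensus, "TAnnnT")
  expect_gte(pm$minus10$fraction_with_hit, 0.9)
  expect_equal(pm$spacer10$mean, 6, tolerance = 1.5)
})
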