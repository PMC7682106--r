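test_that("flat tracks give no candidates; an isolated spike gives one", {
  flat <- list(`+` = rep(2, 500), `-` = rep(2, 500))
  expect_equal(nrow(detect_tss(flat)), 0L)

  spike <- list(`+` = rep(0, 500), `-` = rep(0, 500))
  spike$`+`[250] <- 100
  cand <- detect_tss(spike)
  expect_equal(cand$pos, 250L)
  expect_equal(cand$read_start_count, 100)
})

test_that("detection respects both the absolute and the fold threshold", {
  tr <- list(`+` = rep(0, 200), `-` = rep(0, 200))
  tr$`+`[50:99] <- 9.5  # local background below min_starts
  tr$`+`[100] <- 45     # >= min_starts but < 5 x background (47.5)
  expect_equal(nrow(detect_tss(tr)), 0L)
  tr$`+`[100] <- 48
  expect_equal(detect_tss(tr)$pos, 100L)
})

test_that("UTR length, leaderless boundary and argmax assignment are correct", {
  ann <- data.frame(id = c("g1", "g2"), type = "CDS",
                    start = c(1000, 3000), end = c(1900, 3900),
                    strand = "+")
  cand <- data.frame(pos = c(1000, 2997, 2996, 2950, 2800),
                     strand = "+",
                     read_start_count = c(30, 40, 20, 50, 10))
  tss <- assign_primary_tss(cand, ann)
  g1 <- tss[tss$gene == "g1", ]
  expect_equal(g1$utr_length, 0L)
  expect_true(g1$leaderless)           # distance 0

  g2 <- tss[tss$gene == "g2", ]
  expect_equal(g2$pos, 2950L)          # count 50 beats 40, 20, 10
  expect_equal(g2$utr_length, 50L)
  expect_false(g2$leaderless)

  # boundary: distance 3 leaderless, 4 leadered
  c3 <- data.frame(pos = 2997, strand = "+", read_start_count = 10)
  expect_true(assign_primary_tss(c3, ann)$leaderless)
  c4 <- data.frame(pos = 2996, strand = "+", read_start_count = 10)
  expect_false(assign_primary_tss(c4, ann)$leaderless)
})

test_that("count ties break towards the TLS-proximal candidate", {
  ann <- data.frame(id = "g1", type = "CDS", start = 1000, end = 1900,
                    strand = "+")
  cand <- data.frame(pos = c(900, 950), strand = "+",
                     read_start_count = c(25, 25))
  expect_equal(assign_primary_tss(cand, ann)$pos, 950L)
})

test_that("candidates go to the nearest downstream TLS", {
  ann <- data.frame(id = c("g1", "g2"), type = "CDS",
                    start = c(1000, 1200), end = c(1150, 1900),
                    strand = "+")
  cand <- data.frame(pos = 1190, strand = "+", read_start_count = 99)
  tss <- assign_primary_tss(cand, ann)
  expect_equal(tss$gene, "g2")
})

test_that("minus-strand assignment mirrors the plus strand", {
  ann <- data.frame(id = "g1", type = "CDS", start = 1000, end = 1900,
                    strand = "-")
  cand <- data.frame(pos = c(1903, 1960), strand = "-",
                     read_start_count = c(10, 60))
  tss <- assign_primary_tss(cand, ann)
  expect_equal(tss$pos, 1960L)
  expect_equal(tss$utr_length, 60L)
})

test_that("upstream windows are strand-aware and truncated at edges", {
  genome <- Biostrings::DNAString(paste(rep("ACGT", 50), collapse = ""))
  tss <- data.frame(tss_id = "t1", pos = 51, strand = "+")
  w <- extract_upstream_windows(tss, genome, length = 50)
  expect_equal(unname(w), as.character(Biostrings::subseq(genome, 1, 50)))

  tssm <- data.frame(tss_id = "t2", pos = 150, strand = "-")
  wm <- extract_upstream_windows(tssm, genome, length = 50)
  expect_equal(unname(wm), as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome, 151, 200))))

  short <- data.frame(tss_id = "t3", pos = 10, strand = "+")
  expect_warning(ws <- extract_upstream_windows(short, genome, length = 50),
                 "truncated")
  expect_equal(nchar(unname(ws)), 9L)
})

test_that("simulated TSS are recovered with high recall and precision
           and leaderless/leadered partition the assignments", {
  env <- local_sim()
  cand <- detect_tss(env$tracks$five_prime)
  planted <- env$sim$truth$tss_list
  key <- function(d) paste(d$pos, d$strand)
  recall <- mean(key(planted) %in% key(cand))
  precision <- mean(key(cand) %in% key(planted))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.9)

  tss <- assign_primary_tss(cand, env$sim$annotation, env$sim$genome)
  expect_equal(sum(tss$leaderless) + sum(!tss$leaderless), nrow(tss))
  # assigned UTR lengths agree with the planted ones
  m <- merge(tss, planted, by = "gene")
  expect_true(all(m$utr_length.x == m$utr_length.y))
  expect_equal(m$leaderless.x, m$leaderless.y)
  # planted start nucleotide is read back strand-aware
  expect_equal(m$start_nucleotide, m$start_base)
})

test_that("strand symmetry: a reverse-complemented genome gives mirrored TSS", {
  env <- local_sim()
  L <- length(env$sim$genome)
  ann <- env$sim$annotation
  ann_rc <- data.frame(id = ann$id, type = ann$type,
                       start = L - ann$end + 1L, end = L - ann$start + 1L,
                       strand = ifelse(ann$strand == "+", "-", "+"))
  fp <- env$tracks$five_prime
  fp_rc <- list(`+` = rev(fp$`-`), `-` = rev(fp$`+`))
  genome_rc <- Biostrings::reverseComplement(env$sim$genome)

  tss <- assign_primary_tss(detect_tss(fp), ann, env$sim$genome)
  tss_rc <- assign_primary_tss(detect_tss(fp_rc), ann_rc, genome_rc)
  m <- merge(tss, tss_rc, by = "gene")
  expect_equal(nrow(m), nrow(tss))
  expect_equal(m$pos.y, L - m$pos.x + 1L)
  expect_equal(m$utr_length.x, m$utr_length.y)
  expect_equal(m$start_nucleotide.x, m$start_nucleotide.y)
})
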