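#' Detect TSS candidates from 5'-read-start tracks
#'
#' A position is a candidate transcription start site when its read-start
#' count reaches `min_starts` and exceeds `fold_bg` times the mean read-start
#' count over the preceding `bg_window` nt on the same strand (upstream in
#' transcription direction: lower coordinates on `+`, higher on `-`).
#'
#' @param five_prime list of per-position read-start vectors named `"+"` and
#'   `"-"`.
#' @param min_starts minimum read-start count at the candidate position.
#' @param fold_bg required fold enrichment over the local background.
#' @param bg_window background window length (nt).
#' @return data.frame (`pos`, `strand`, `read_start_count`) sorted by
#'   position within strand.
#' @export
detect_tss <- function(five_prime, min_starts = 10, fold_bg = 5,
                       bg_window = 50) {
  out <- list()
  for (strand in c("+", "-")) {
    track <- five_prime[[strand]]
    if (is.null(track)) next
    L <- length(track)
    cs <- c(0, cumsum(track))
    idx <- seq_len(L)
    if (strand == "+") {
      lo <- pmax(idx - bg_window, 1L)
      n_bg <- idx - lo
      bg_sum <- cs[idx] - cs[lo]
    } else {
      hi <- pmin(idx + bg_window, L)
      n_bg <- hi - idx
      bg_sum <- cs[hi + 1L] - cs[idx + 1L]
    }
    bg <- ifelse(n_bg > 0, bg_sum / n_bg, 0)
    hit <- track >= min_starts & track >= fold_bg * bg
    if (any(hit)) {
      out[[strand]] <- data.frame(pos = idx[hit], strand = strand,
                                  read_start_count = track[hit])
    }
  }
  if (length(out) == 0) {
    return(data.frame(pos = integer(), strand = character(),
                      read_start_count = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign primary TSS to coding sequences
#'
#' Each candidate is first assigned to its nearest downstream translation
#' start site (TLS; gene `start` on `+`, gene `end` on `-`) within
#' `max_upstream` nt, which resolves candidates upstream of several genes.
#' Per gene the primary TSS is then the assigned candidate with the highest
#' read-start count (ties broken towards the TSS closer to the TLS). The
#' 5'-UTR length is the TSS-to-TLS distance (0 = TSS at the first base of the
#' start codon); transcripts with a distance of at most 3 nt are classified
#' leaderless.
#'
#' @param candidates data.frame from [detect_tss()].
#' @param annotation feature data.frame (`id`, `start`, `end`, `strand`).
#' @param genome optional [Biostrings::DNAString] to annotate the TSS base
#'   (strand-aware).
#' @param max_upstream maximal TSS-to-TLS distance considered (nt).
#' @return data.frame (`tss_id`, `pos`, `strand`, `gene`,
#'   `read_start_count`, `utr_length`, `leaderless`, `start_nucleotide`), one
#'   row per gene with at least one assigned candidate.
#' @export
assign_primary_tss <- function(candidates, annotation, genome = NULL,
                               max_upstream = 500) {
  res <- list()
  for (strand in c("+", "-")) {
    cand <- candidates[candidates$strand == strand, , drop = FALSE]
    genes <- annotation[annotation$strand == strand, , drop = FALSE]
    if (nrow(cand) == 0 || nrow(genes) == 0) next
    if (strand == "+") {
      tls <- sort(genes$start)
      gene_of_tls <- genes$id[order(genes$start)]
      # nearest TLS at or after the candidate position
      k <- findInterval(cand$pos - 0.5, tls) + 1L
      ok <- k <= length(tls)
      dist <- ifelse(ok, tls[pmin(k, length(tls))] - cand$pos, NA_real_)
    } else {
      tls <- sort(genes$end)
      gene_of_tls <- genes$id[order(genes$end)]
      # nearest TLS at or before the candidate position
      k <- findInterval(cand$pos + 0.5, tls)
      ok <- k >= 1
      dist <- ifelse(ok, cand$pos - tls[pmax(k, 1L)], NA_real_)
    }
    keep <- ok & !is.na(dist) & dist >= 0 & dist <= max_upstream
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    cand$gene <- gene_of_tls[k[keep]]
    cand$utr_length <- as.integer(dist[keep])
    res[[strand]] <- cand
  }
  if (length(res) == 0) {
    return(data.frame(tss_id = character(), pos = integer(),
                      strand = character(), gene = character(),
                      read_start_count = numeric(), utr_length = integer(),
                      leaderless = logical(), start_nucleotide = character()))
  }
  assigned <- do.call(rbind, res)
  # primary TSS per gene: highest count, ties towards the TLS-proximal one
  assigned <- assigned[order(assigned$gene, -assigned$read_start_count,
                             assigned$utr_length), ]
  primary <- assigned[!duplicated(assigned$gene), , drop = FALSE]
  primary$leaderless <- primary$utr_length <= 3L
  primary$tss_id <- sprintf("tss_%s_%d", ifelse(primary$strand == "+", "p", "m"),
                            primary$pos)
  primary$start_nucleotide <- NA_character_
  if (!is.null(genome)) {
    base <- substring(as.character(genome), primary$pos, primary$pos)
    primary$start_nucleotide <- ifelse(primary$strand == "+", base,
                                       comp_base(base))
  }
  rownames(primary) <- NULL
  primary[, c("tss_id", "pos", "strand", "gene", "read_start_count",
              "utr_length", "leaderless", "start_nucleotide")]
}

#' Extract strand-aware upstream sequence windows
#'
#' Returns the `length` nt immediately upstream of each TSS (excluding the
#' TSS base itself), reverse-complemented for minus-strand TSS so all windows
#' read 5' to 3' towards the TSS. Windows are truncated at contig edges with
#' a warning.
#'
#' @param tss data.frame with `pos` and `strand` (and optionally `tss_id`
#'   used as names).
#' @param genome [Biostrings::DNAString].
#' @param length window length (nt).
#' @return named character vector of windows.
#' @export
extract_upstream_windows <- function(tss, genome, length = 50) {
  L <- base::length(genome)
  gseq <- as.character(genome)
  n_trunc <- 0L
  win <- character(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    if (tss$strand[i] == "+") {
      lo <- tss$pos[i] - length
      hi <- tss$pos[i] - 1L
      if (lo < 1) { lo <- 1L; n_trunc <- n_trunc + 1L }
      win[i] <- if (hi >= lo) substring(gseq, lo, hi) else ""
    } else {
      lo <- tss$pos[i] + 1L
      hi <- tss$pos[i] + length
      if (hi > L) { hi <- L; n_trunc <- n_trunc + 1L }
      win[i] <- if (hi >= lo) revcomp_string(substring(gseq, lo, hi)) else ""
    }
  }
  if (n_trunc > 0) warnf("%d window(s) truncated at contig edge", n_trunc)
  names(win) <- tss$tss_id %||% NULL
  win
}
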