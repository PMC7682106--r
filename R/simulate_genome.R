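#' Simulate a GC-rich bacterial genome with planted transcriptional architecture
#'
#' Generates a genome sequence, a CDS annotation and a ground-truth record of
#' the planted transcriptional architecture. Genes are organised into
#' transcription units (TUs) whose sizes follow `operon_size_probs`; a fraction
#' `tss_prob` of TUs receives a planted primary TSS with a -10/-35 promoter
#' (these are the "validated" units; the rest emulate purely predicted
#' operons), and posterior operon genes receive internal TSS with probability
#' `internal_tss_prob` (the source of sub-operons). Leaderless transcripts
#' (5'-UTR <= 3 nt) are planted at rate `leaderless_prob`; leadered UTR
#' lengths follow a truncated geometric distribution within
#' `utr_length_range`. Each gene is assigned an expression archetype, a
#' baseline abundance, a protein-detection flag and a transcript-to-protein
#' lag flag, which downstream simulators ([simulate_tracks()],
#' [simulate_expression()]) consume.
#'
#' @param config a [sim_config()] object.
#' @return list with elements
#'   \describe{
#'     \item{genome}{[Biostrings::DNAString] genome sequence.}
#'     \item{annotation}{data.frame of features (`id`, `type`, `start`, `end`,
#'       `strand`), 1-based inclusive coordinates, non-overlapping per strand.}
#'     \item{truth}{ground truth: `operon_map` (gene to TU), `tss_list`
#'       (planted TSS with class, UTR length, leaderless flag, start base),
#'       `genes` (archetype label, baseline expression, protein detection and
#'       lag flags), and the effective `config`.}
#'   }
#' @export
simulate_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  n_genes <- cfg$n_genes

  ## --- transcription unit layout -------------------------------------------
  tu_sizes <- integer(0)
  while (sum(tu_sizes) < n_genes) {
    s <- sample(1:5, 1, prob = cfg$operon_size_probs)
    tu_sizes <- c(tu_sizes, s)
  }
  tu_sizes[length(tu_sizes)] <- tu_sizes[length(tu_sizes)] -
    (sum(tu_sizes) - n_genes)
  tu_sizes <- tu_sizes[tu_sizes > 0]
  n_tu <- length(tu_sizes)

  margin <- 600L
  cursor <- margin
  ann <- vector("list", n_genes)
  tu_of_gene <- integer(n_genes)
  tu_strand <- sample(c("+", "-"), n_tu, replace = TRUE)
  gi <- 0L
  tu_gene_ids <- vector("list", n_tu)
  for (tu in seq_len(n_tu)) {
    ids <- character(tu_sizes[tu])
    for (k in seq_len(tu_sizes[tu])) {
      gi <- gi + 1L
      len <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1)
      start <- cursor + 1L
      end <- start + len - 1L
      id <- sprintf("gene_%04d", gi)
      ann[[gi]] <- data.frame(id = id, type = "CDS", start = start, end = end,
                              strand = tu_strand[tu])
      ids[k] <- id
      tu_of_gene[gi] <- tu
      cursor <- end
      if (k < tu_sizes[tu]) {
        cursor <- cursor + sample(cfg$intra_gap_range[1]:cfg$intra_gap_range[2], 1)
      }
    }
    tu_gene_ids[[tu]] <- ids
    cursor <- cursor + sample(cfg$inter_gap_range[1]:cfg$inter_gap_range[2], 1)
  }
  annotation <- do.call(rbind, ann)
  total_len <- cursor + margin
  if (!is.null(cfg$genome_length)) {
    if (cfg$genome_length < total_len) {
      stopf("genome_length %d too short for %d genes (need >= %d nt)",
            cfg$genome_length, n_genes, total_len)
    }
    total_len <- cfg$genome_length
  }

  ## --- background sequence --------------------------------------------------
  gc <- cfg$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq_chars <- sample(DNA_BASES, total_len, replace = TRUE, prob = base_probs)

  plant <- function(pos, strand, motif_chars) {
    # plant `motif_chars` (given in transcript orientation, 5'->3') so that its
    # first transcribed base sits at genomic `pos` for '+' and at `pos` going
    # leftwards for '-'
    w <- length(motif_chars)
    if (strand == "+") {
      idx <- pos:(pos + w - 1L)
      if (idx[1] < 1 || idx[w] > total_len) return(invisible(NULL))
      seq_chars[idx] <<- motif_chars
    } else {
      idx <- (pos - w + 1L):pos
      if (idx[1] < 1 || idx[w] > total_len) return(invisible(NULL))
      seq_chars[idx] <<- revcomp_chars(motif_chars)
    }
    invisible(NULL)
  }

  sample_motif <- function(pwm) {
    vapply(seq_len(ncol(pwm)),
           function(i) sample(DNA_BASES, 1, prob = pwm[, i]), "")
  }

  draw_utr <- function(max_utr = cfg$utr_length_range[2]) {
    if (stats::runif(1) < cfg$leaderless_prob) {
      list(utr = sample(0:3, 1), leaderless = TRUE)
    } else {
      lo <- cfg$utr_length_range[1]
      u <- lo + stats::rgeom(1, 1 / (cfg$utr_mean - lo + 1))
      list(utr = min(u, max_utr), leaderless = FALSE)
    }
  }

  ## --- plant TSS + promoters ------------------------------------------------
  tss_rows <- list()
  tss_id <- 0L
  plant_tss <- function(gene_row, tu, klass, max_utr) {
    tss_id <<- tss_id + 1L
    u <- draw_utr(max_utr)
    strand <- gene_row$strand
    tls <- if (strand == "+") gene_row$start else gene_row$end
    pos <- if (strand == "+") tls - u$utr else tls + u$utr
    start_base <- sample(names(cfg$tss_base_probs), 1, prob = cfg$tss_base_probs)
    plant(pos, strand, start_base)
    # -10 element: 3' end separated from the TSS by an exclusive spacer gap
    s10 <- sample(cfg$spacer10_range[1]:cfg$spacer10_range[2], 1)
    m10 <- sample_motif(cfg$minus10_pwm)
    m10_start <- if (strand == "+") pos - s10 - 6L else pos + s10 + 6L
    plant(m10_start, strand, m10)
    # -35 element upstream of the -10
    s3510 <- max(10L, round(stats::rnorm(1, cfg$spacer_35_10_mean_sd[1],
                                         cfg$spacer_35_10_mean_sd[2])))
    m35 <- sample_motif(cfg$minus35_pwm)
    m35_start <- if (strand == "+") m10_start - s3510 - 6L else m10_start + s3510 + 6L
    plant(m35_start, strand, m35)
    # Shine-Dalgarno core for leadered transcripts, ending 8 nt upstream of TLS
    if (!u$leaderless && u$utr >= 13 && stats::runif(1) < cfg$rbs_prob) {
      rbs_start <- if (strand == "+") tls - 12L else tls + 12L
      plant(rbs_start, strand, strsplit("GGAGG", "")[[1]])
    }
    tss_rows[[tss_id]] <<- data.frame(
      tss_id = sprintf("tss_%04d", tss_id), pos = pos, strand = strand,
      gene = gene_row$id, tu = tu, class = klass,
      utr_length = u$utr, leaderless = u$leaderless,
      start_base = start_base, spacer10 = s10, spacer3510 = s3510
    )
  }

  for (tu in seq_len(n_tu)) {
    ids <- tu_gene_ids[[tu]]
    # transcription order: genomic order on '+', reversed on '-'
    if (tu_strand[tu] == "-") ids <- rev(ids)
    if (stats::runif(1) < cfg$tss_prob) {
      gene_row <- annotation[annotation$id == ids[1], ]
      plant_tss(gene_row, tu, "primary", cfg$utr_length_range[2])
    }
    if (length(ids) > 1) {
      for (j in 2:length(ids)) {
        if (stats::runif(1) < cfg$internal_tss_prob) {
          gene_row <- annotation[annotation$id == ids[j], ]
          # keep internal UTRs short so the TSS stays closer to its own TLS
          # than to any upstream gene's TLS
          plant_tss(gene_row, tu, "internal", 250L)
        }
      }
    }
  }
  tss_list <- if (tss_id > 0) do.call(rbind, tss_rows) else
    data.frame(tss_id = character(), pos = integer(), strand = character(),
               gene = character(), tu = integer(), class = character(),
               utr_length = integer(), leaderless = logical(),
               start_base = character(), spacer10 = integer(),
               spacer3510 = integer())

  ## --- expression ground truth ---------------------------------------------
  archetypes <- names(cfg$archetype_set)
  genes <- data.frame(
    gene = annotation$id,
    archetype = sample(archetypes, n_genes, replace = TRUE,
                       prob = cfg$archetype_probs[archetypes]),
    base_expr = stats::rlnorm(n_genes, cfg$base_expr_meanlog, cfg$base_expr_sdlog),
    detected_protein = stats::runif(n_genes) < cfg$protein_detect_rate
  )
  genes$lagged <- genes$detected_protein &
    stats::runif(n_genes) < cfg$protein_lag_fraction

  operon_map <- data.frame(gene = annotation$id, tu = tu_of_gene,
                           tu_size = tu_sizes[tu_of_gene])

  truth <- list(operon_map = operon_map, tss_list = tss_list, genes = genes,
                config = cfg)
  list(genome = Biostrings::DNAString(paste(seq_chars, collapse = "")),
       annotation = annotation, truth = truth)
}
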