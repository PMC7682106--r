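#' Call primary operons from annotation and combined coverage
#'
#' Joins consecutive same-strand genes into primary operons when the
#' intergenic distance is at most `d_max` nt and the minimum combined coverage
#' over the intergenic span is at least `f_min` times the lower of the two
#' flanking genes' mean coverages (evidence of a spanning transcript).
#' Coverage should be the combination (sum) of all time points, which raises
#' the read support in weakly covered regions. Maximal joined runs of two or
#' more genes become primary operons (gene lists in transcription order:
#' left-to-right on `+`, right-to-left on `-`); the remaining genes are
#' monocistronic.
#'
#' @param annotation data.frame (`id`, `type`, `start`, `end`, `strand`),
#'   1-based inclusive.
#' @param coverage list with per-strand numeric coverage vectors named `"+"`
#'   and `"-"`, or a list of such lists (summed).
#' @param d_max maximum intergenic distance joined (nt).
#' @param f_min minimum intergenic coverage as a fraction of the lower
#'   flanking gene mean coverage.
#' @param include_rna include rRNA/tRNA features in operon calling.
#' @return list with `operons` (list of operon records: `id`, `genes` in
#'   transcription order, `strand`, `klass = "primary"`, `validated`,
#'   `anchor_tss`) and `monocistronic` (character vector of gene ids).
#' @export
call_primary_operons <- function(annotation, coverage, d_max = 500,
                                 f_min = 0.5, include_rna = TRUE) {
  if (is.list(coverage) && is.list(coverage[[1]])) {
    coverage <- Reduce(function(a, b) list(`+` = a$`+` + b$`+`,
                                           `-` = a$`-` + b$`-`), coverage)
  }
  if (!all(c("+", "-") %in% names(coverage))) {
    stopf("coverage must provide '+' and '-' strand tracks")
  }
  ann <- annotation
  if (!include_rna) ann <- ann[ann$type == "CDS", , drop = FALSE]
  if (max(ann$end) > length(coverage$`+`)) {
    stopf("coverage track shorter than annotated features")
  }
  operons <- list()
  mono <- character(0)
  oid <- 0L
  for (strand in c("+", "-")) {
    genes <- ann[ann$strand == strand, , drop = FALSE]
    if (nrow(genes) == 0) next
    genes <- genes[order(genes$start), ]
    cov <- coverage[[strand]]
    gene_mean <- vapply(seq_len(nrow(genes)),
                        function(i) mean(cov[genes$start[i]:genes$end[i]]), 0)
    joined <- logical(max(nrow(genes) - 1, 0))
    for (i in seq_len(nrow(genes) - 1)) {
      gap_len <- genes$start[i + 1] - genes$end[i] - 1L
      if (gap_len > d_max) next
      gap_cov <- if (gap_len <= 0) Inf else
        min(cov[(genes$end[i] + 1L):(genes$start[i + 1] - 1L)])
      joined[i] <- gap_cov >= f_min * min(gene_mean[i], gene_mean[i + 1])
    }
    run_id <- cumsum(c(1L, !joined))
    for (r in unique(run_id)) {
      ids <- genes$id[run_id == r]
      if (length(ids) < 2) {
        mono <- c(mono, ids)
      } else {
        oid <- oid + 1L
        if (strand == "-") ids <- rev(ids)  # transcription order
        operons[[oid]] <- list(id = sprintf("operon_%04d", oid), genes = ids,
                               strand = strand, klass = "primary",
                               validated = NA, anchor_tss = NA_character_)
      }
    }
  }
  list(operons = operons, monocistronic = mono)
}

#' Validate operons by an assigned TSS at the first gene
#'
#' A primary operon is experimentally validated when a TSS has been assigned
#' to its first gene (in transcription order); the anchoring TSS id is
#' recorded. Operons without such a TSS remain predicted.
#'
#' @param operons list of operon records from [call_primary_operons()].
#' @param tss data.frame of assigned TSS (from [assign_primary_tss()]) with
#'   columns `tss_id` and `gene`.
#' @return the operon list with `validated` and `anchor_tss` filled in.
#' @export
validate_operons <- function(operons, tss) {
  lapply(operons, function(op) {
    hit <- match(op$genes[1], tss$gene)
    op$validated <- !is.na(hit)
    op$anchor_tss <- if (!is.na(hit)) tss$tss_id[hit] else NA_character_
    op
  })
}

#' Derive sub-operons from internal TSS
#'
#' For every TSS assigned to a posterior gene (position j > 1 in transcription
#' order) of a primary operon, the suffix `genes[j..n]` becomes a sub-operon;
#' an internal TSS at the last gene yields a single-gene sub-operon.
#' Duplicate suffixes are collapsed.
#'
#' @inheritParams validate_operons
#' @return list of sub-operon records (`klass = "sub"`, `parent` set to the
#'   primary operon id, `anchor_tss` the internal TSS).
#' @export
derive_sub_operons <- function(operons, tss) {
  subs <- list()
  sid <- 0L
  for (op in operons) {
    n <- length(op$genes)
    internal <- which(op$genes %in% tss$gene)
    internal <- internal[internal > 1]
    for (j in unique(internal)) {
      sid <- sid + 1L
      hit <- match(op$genes[j], tss$gene)
      subs[[sid]] <- list(id = sprintf("sub_%04d", sid),
                          genes = op$genes[j:n], strand = op$strand,
                          klass = "sub", validated = TRUE,
                          anchor_tss = tss$tss_id[hit], parent = op$id)
    }
  }
  subs
}

#' Summarize the operon landscape
#'
#' Size-binned counts (1, 2, 3, 4, >= 5 genes per transcript) of primary
#' operons, sub-operons and monocistronic genes, plus the validated-primary
#' percentage and the fraction of monocistronic genes with an assigned TSS
#' (percentages via [summarize_significance()]).
#'
#' @param operons validated primary operon list.
#' @param sub_operons sub-operon list.
#' @param monocistronic character vector of monocistronic gene ids.
#' @param tss assigned TSS table.
#' @return list with `by_size` (data.frame), `totals` and percentage fields.
#' @export
summarize_operons <- function(operons, sub_operons, monocistronic, tss) {
  size_bin <- function(ops) {
    s <- vapply(ops, function(op) length(op$genes), 0L)
    bins <- cut(s, c(0, 1, 2, 3, 4, Inf), labels = c("1", "2", "3", "4", ">=5"))
    table(factor(bins, levels = c("1", "2", "3", "4", ">=5")))
  }
  by_size <- data.frame(
    genes_per_transcript = c("1", "2", "3", "4", ">=5"),
    primary_operons = as.integer(size_bin(operons)),
    sub_operons = as.integer(size_bin(sub_operons)),
    monocistronic = c(length(monocistronic), 0L, 0L, 0L, 0L)
  )
  n_primary <- length(operons)
  n_validated <- sum(vapply(operons, function(op) isTRUE(op$validated), TRUE))
  n_mono_tss <- sum(monocistronic %in% tss$gene)
  list(
    by_size = by_size,
    totals = c(primary = n_primary, sub = length(sub_operons),
               monocistronic = length(monocistronic)),
    genes_in_primary = sum(vapply(operons, function(op) length(op$genes), 0L)),
    n_validated = n_validated,
    pct_validated = if (n_primary > 0)
      summarize_significance(n_validated, n_primary) else NA_real_,
    n_mono_with_tss = n_mono_tss,
    pct_mono_with_tss = if (length(monocistronic) > 0)
      summarize_significance(n_mono_tss, length(monocistronic)) else NA_real_
  )
}

#' Tidy operon table
#'
#' Flattens an operon list into a data.frame suitable for TSV export.
#'
#' @param operons list of operon records.
#' @return data.frame (`id`, `klass`, `strand`, `validated`, `anchor_tss`,
#'   `n_genes`, `genes` comma-collapsed in transcription order).
#' @export
as_operon_table <- function(operons) {
  do.call(rbind, lapply(operons, function(op) {
    data.frame(id = op$id, klass = op$klass, strand = op$strand,
               validated = op$validated, anchor_tss = op$anchor_tss,
               n_genes = length(op$genes),
               genes = paste(op$genes, collapse = ","))
  }))
}
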