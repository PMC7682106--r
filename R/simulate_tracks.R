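#' Simulate strand-specific coverage and 5'-read-start tracks
#'
#' Builds the two evidence tracks the architecture-inference modules consume:
#' a combined (all-time-point) whole-transcriptome coverage track per strand
#' and a 5'-enriched read-start track per strand. Gene bodies are covered at a
#' depth proportional to their baseline expression; intergenic positions
#' inside a planted operon carry spanning coverage at `spanning_frac` of the
#' lower flanking gene depth, while inter-operon gaps are coverage-free.
#' Coverage is reported as expected depth (the combined evidence of all
#' libraries); read-start counts are Poisson: planted TSS positions pile up at
#' mean `tss_strength`, and expressed gene bodies receive background starts at
#' `bg_start_rate` per nt. A gene with zero baseline expression yields zero
#' coverage and no background starts over its span.
#'
#' @param sim result of [simulate_genome()].
#' @param config a [sim_config()]; defaults to the one stored in `sim`.
#' @return list with `coverage` and `five_prime`, each a list of numeric
#'   per-position vectors named `"+"` and `"-"` (1-based genomic positions).
#' @export
simulate_tracks <- function(sim, config = sim$truth$config) {
  validate_sim_config(config)
  with_seed(config$seed + 1L, simulate_tracks_impl(sim, config))
}

simulate_tracks_impl <- function(sim, cfg) {
  L <- length(sim$genome)
  ann <- sim$annotation
  truth <- sim$truth
  level <- cfg$coverage_depth * truth$genes$base_expr / exp(cfg$base_expr_meanlog)
  names(level) <- truth$genes$gene

  cov <- list(`+` = numeric(L), `-` = numeric(L))
  fp <- list(`+` = numeric(L), `-` = numeric(L))

  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    cov[[g$strand]][g$start:g$end] <- level[g$id]
  }
  # spanning coverage over intra-operon gaps
  om <- truth$operon_map
  for (tu in unique(om$tu[om$tu_size > 1])) {
    ids <- om$gene[om$tu == tu]
    rows <- ann[match(ids, ann$id), ]
    rows <- rows[order(rows$start), ]
    for (j in seq_len(nrow(rows) - 1)) {
      gap <- seq.int(rows$end[j] + 1L, rows$start[j + 1] - 1L)
      if (length(gap) == 0) next
      cov[[rows$strand[1]]][gap] <- cfg$spanning_frac *
        min(level[rows$id[j]], level[rows$id[j + 1]])
    }
  }
  # background read starts within expressed gene bodies
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    if (level[g$id] <= 0) next
    span <- g$start:g$end
    fp[[g$strand]][span] <- fp[[g$strand]][span] +
      stats::rpois(length(span), cfg$bg_start_rate)
  }
  # planted TSS pile-ups
  tss <- truth$tss_list
  if (nrow(tss) > 0) {
    counts <- stats::rpois(nrow(tss), cfg$tss_strength)
    for (i in seq_len(nrow(tss))) {
      fp[[tss$strand[i]]][tss$pos[i]] <- fp[[tss$strand[i]]][tss$pos[i]] + counts[i]
    }
  }
  list(coverage = cov, five_prime = fp)
}
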