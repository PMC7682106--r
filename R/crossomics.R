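#' Pair features present in both omics layers
#'
#' Intersects the feature sets of a transcript and a protein M-value profile
#' matrix: only genes with both a transcript and a protein profile enter the
#' combined analyses. Exclusion counts are reported.
#'
#' @param transcript,protein profile matrices (features x time points, same
#'   time axis) as produced by [prepare_profiles()], or M-value tables
#'   accepted by it.
#' @return list of class `paired_features`: `features`, `transcript`,
#'   `protein` (row-aligned matrices), `n_transcript_only`,
#'   `n_protein_only`.
#' @export
pair_features <- function(transcript, protein) {
  tm <- if (is.matrix(transcript)) transcript else prepare_profiles(transcript)
  pm <- if (is.matrix(protein)) protein else prepare_profiles(protein)
  if (ncol(tm) != ncol(pm)) stopf("layers have different time axes")
  common <- intersect(rownames(tm), rownames(pm))
  if (length(common) == 0) {
    stopf("no shared features: %d transcript-only, %d protein-only",
          nrow(tm), nrow(pm))
  }
  structure(list(features = common,
                 transcript = tm[common, , drop = FALSE],
                 protein = pm[common, , drop = FALSE],
                 n_transcript_only = nrow(tm) - length(common),
                 n_protein_only = nrow(pm) - length(common)),
            class = "paired_features")
}

#' Cluster both layers of a paired feature set
#'
#' Clusters the transcript and the protein profiles of the paired feature set
#' independently (Ward/Euclidean, Krzanowski-Lai selected k, `k_max` cut) via
#' [cluster_dynamics()].
#'
#' @param paired a `paired_features` object.
#' @param k_max maximal cluster number per layer.
#' @return list with `transcript` and `protein` `cluster_solution`s.
#' @export
combined_clustering <- function(paired, k_max = 50) {
  if (length(paired$features) < 3) stopf("need at least 3 paired features")
  list(transcript = cluster_dynamics(paired$transcript, k_max = k_max),
       protein = cluster_dynamics(paired$protein, k_max = k_max))
}

#' Cross-omics cluster co-occurrence matrix
#'
#' `C[i, j]` is the percentage of transcriptome cluster i's members that fall
#' into proteome cluster j; every row sums to 100 before rounding. Identical
#' partitions therefore give a permutation matrix times 100.
#'
#' @param t_solution,p_solution `cluster_solution`s over the same features.
#' @param digits rounding for the `rounded` copy (raw values kept alongside).
#' @param order_by_size order rows/columns by cluster size, largest first.
#' @return list: `C` (raw percentages), `rounded`, `row_sizes`, `col_sizes`.
#' @export
co_occurrence <- function(t_solution, p_solution, digits = 1,
                          order_by_size = FALSE) {
  ta <- t_solution$assignments
  pa <- p_solution$assignments
  feats <- intersect(names(ta), names(pa))
  if (length(feats) == 0 || length(ta) != length(pa)) {
    stopf("solutions must cover the same feature set")
  }
  tab <- table(transcript = ta[feats], protein = pa[feats])
  row_sizes <- rowSums(tab)
  if (any(row_sizes == 0)) stopf("empty transcriptome cluster")
  C <- sweep(unclass(tab), 1, row_sizes, "/") * 100
  if (order_by_size) {
    ro <- order(row_sizes, decreasing = TRUE)
    co <- order(colSums(tab), decreasing = TRUE)
    C <- C[ro, co, drop = FALSE]
    tab <- tab[ro, co, drop = FALSE]
    row_sizes <- row_sizes[ro]
  }
  list(C = C, rounded = round_half_away(C, digits),
       row_sizes = row_sizes, col_sizes = colSums(tab))
}

#' Lagged transcript-protein Pearson correlation
#'
#' For every valid time-point pair (t, t + lag) the Pearson correlation across
#' paired features between the transcript M-value at t and the protein
#' M-value at t + lag. A lag of 1 compares the transcriptome at time X to the
#' proteome at time X + 1, capturing a one-sampling-interval transcription-to-
#' translation offset. Features missing either value are excluded pairwise; a
#' time pair with fewer than 3 complete pairs or zero variance yields `NA`.
#'
#' @param paired a `paired_features` object.
#' @param lag non-negative integer time-point offset (< number of time
#'   points).
#' @param per_feature also compute per-feature correlations across time
#'   (transcript t vs protein t + lag within each gene).
#' @return data.frame (`lag`, `t_transcript`, `t_protein`, `r`, `n`); with
#'   `per_feature = TRUE`, a list also holding `feature_r`.
#' @export
lagged_pearson <- function(paired, lag = 0, per_feature = FALSE) {
  nt <- ncol(paired$transcript)
  if (lag < 0 || lag >= nt) stopf("lag must be in [0, n_timepoints - 1]")
  times_t <- colnames(paired$transcript)
  rows <- lapply(seq_len(nt - lag), function(t) {
    x <- paired$transcript[, t]
    y <- paired$protein[, t + lag]
    ok <- !is.na(x) & !is.na(y)
    r <- if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      stats::cor(x[ok], y[ok])
    } else {
      NA_real_
    }
    data.frame(lag = lag, t_transcript = times_t[t],
               t_protein = times_t[t + lag], r = r, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  if (!per_feature) return(out)
  fr <- vapply(seq_along(paired$features), function(i) {
    x <- paired$transcript[i, seq_len(nt - lag)]
    y <- paired$protein[i, seq_len(nt - lag) + lag]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      stats::cor(x[ok], y[ok])
    } else {
      NA_real_
    }
  }, 0)
  names(fr) <- paired$features
  list(by_time = out, feature_r = fr)
}
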