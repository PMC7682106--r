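# Expression data move through the package as long-format data.frames with
# columns feature, time, replicate, value (one layer per table: transcript
# counts or protein LFQ). Helpers below pivot them to matrices.

# feature x sample matrix (sample = time:replicate)
expr_matrix <- function(long) {
  sample_id <- paste(long$time, long$replicate, sep = ":")
  feats <- unique(long$feature)
  samps <- unique(sample_id)
  m <- matrix(NA_real_, length(feats), length(samps),
              dimnames = list(feats, samps))
  m[cbind(match(long$feature, feats), match(sample_id, samps))] <- long$value
  m
}

# feature x time matrix of replicate means (NA-aware)
replicate_mean_matrix <- function(long) {
  feats <- unique(long$feature)
  times <- sort(unique(long$time))
  m <- matrix(NA_real_, length(feats), length(times),
              dimnames = list(feats, as.character(times)))
  agg <- stats::aggregate(value ~ feature + time, data = long, FUN = mean,
                          na.action = stats::na.omit)
  m[cbind(match(agg$feature, feats), match(as.character(agg$time), times))] <-
    agg$value
  m
}

#' Median-of-ratios size-factor normalization
#'
#' Computes one size factor per sample (time x replicate library) as the
#' median across features of the ratio of the sample's count to the feature's
#' geometric mean count over all samples (features with a zero anywhere are
#' excluded from the reference). Factors are rescaled to geometric mean 1 and
#' each sample's values are divided by its factor, so count tables that differ
#' only by per-library sequencing depth become comparable.
#'
#' @param counts long-format count table (`feature`, `time`, `replicate`,
#'   `value`).
#' @return list with `values` (normalized long table) and `size_factors`
#'   (named per-sample vector, geometric mean 1).
#' @export
size_factor_normalize <- function(counts) {
  m <- expr_matrix(counts)
  if (any(colSums(m, na.rm = TRUE) == 0)) {
    stopf("sample with all-zero counts; size factors undefined")
  }
  pos <- rowSums(is.na(m) | m <= 0) == 0
  if (!any(pos)) stopf("no feature with nonzero counts in every sample")
  logm <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(stats::median(col - ref)))
  sf <- sf / exp(mean(log(sf)))
  sample_id <- paste(counts$time, counts$replicate, sep = ":")
  out <- counts
  out$value <- counts$value / sf[sample_id]
  attr(out, "layer") <- attr(counts, "layer")
  list(values = out, size_factors = sf)
}

#' Pooled-reference M-values
#'
#' For each feature the replicate-mean abundance per time point is compared to
#' the pooled reference, the mean of those replicate-mean abundances over all
#' time points (the in-silico analogue of an equimolar pooled-RNA reference
#' library): `M[f,t] = log2(mean_reps(value[f,t]) / reference[f])`. By
#' construction the mean of `2^M` over time is exactly 1 for every feature.
#'
#' @param long normalized long-format table; values must be non-negative and
#'   the per-feature time-mean positive for M to be defined.
#' @return data.frame (`feature`, `time`, `M`); features with a zero or
#'   missing reference get `NA` M-values and are listed in the
#'   `"undefined_reference"` attribute.
#' @export
compute_m_values <- function(long) {
  A <- replicate_mean_matrix(long)
  ref <- rowMeans(A, na.rm = TRUE)
  bad <- !is.finite(ref) | ref <= 0
  M <- log2(sweep(A, 1, ref, "/"))
  M[bad, ] <- NA_real_
  out <- data.frame(
    feature = rep(rownames(A), times = ncol(A)),
    time = rep(as.numeric(colnames(A)), each = nrow(A)),
    M = as.vector(M)
  )
  out <- out[order(match(out$feature, rownames(A)), out$time), ]
  rownames(out) <- NULL
  attr(out, "undefined_reference") <- rownames(A)[bad]
  out
}

#' Per-time-point significance against the pooled rest
#'
#' For every (feature, time point) a Welch two-sample t-test compares the time
#' point's replicate values against the pooled replicate values of all other
#' time points, on the log scale. Raw p-values are Benjamini-Hochberg adjusted
#' across all tests of the layer and calls use a strict `p_adj < 0.05`
#' threshold. Cells with fewer than two replicate values get `NA` p-values and
#' are never called significant.
#'
#' @param long long-format table of one layer.
#' @param log_transform apply `log2(value + 1)` before testing (use for raw
#'   counts; z-normalized LFQ tables should pass `FALSE`).
#' @param alpha adjusted-p significance threshold.
#' @return data.frame (`feature`, `time`, `p`, `p_adj`, `significant`).
#' @export
test_significance <- function(long, log_transform = TRUE, alpha = 0.05) {
  x <- long
  if (log_transform) x$value <- log2(x$value + 1)
  feats <- unique(x$feature)
  times <- sort(unique(x$time))
  res <- expand.grid(time = times, feature = feats,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- res[, c("feature", "time")]
  res$p <- NA_real_
  by_feat <- split(x[c("time", "value")], x$feature)
  k <- 0L
  for (f in feats) {
    d <- by_feat[[f]]
    for (t in times) {
      k <- k + 1L
      a <- d$value[d$time == t & !is.na(d$value)]
      b <- d$value[d$time != t & !is.na(d$value)]
      if (length(a) >= 2 && length(b) >= 2 &&
          (stats::sd(c(a, b)) > 0)) {
        res$p[k] <- tryCatch(stats::t.test(a, b)$p.value,
                             error = function(e) NA_real_)
      }
    }
  }
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Combined M-value and significance table
#'
#' Convenience wrapper producing one abundance record per (feature, time):
#' M-value, raw and BH-adjusted p-value and the significance flag.
#'
#' @inheritParams test_significance
#' @param m_input optional separate long table to compute M-values from (e.g.
#'   size-factor-normalized counts when testing is done on the same values).
#' @return data.frame (`feature`, `time`, `M`, `p`, `p_adj`, `significant`).
#' @export
abundance_records <- function(long, log_transform = TRUE, alpha = 0.05,
                              m_input = long) {
  m <- compute_m_values(m_input)
  s <- test_significance(long, log_transform = log_transform, alpha = alpha)
  merge(m, s, by = c("feature", "time"), sort = FALSE)
}

#' Retain features with dynamic expression
#'
#' A feature is kept iff it is significant (`p_adj < 0.05`) at one or more
#' time points; features whose abundance never differs from the pooled
#' reference are ruled out.
#'
#' @param records output of [abundance_records()] or [test_significance()].
#' @return character vector of retained feature ids.
#' @export
filter_dynamic <- function(records) {
  keep <- tapply(records$significant, records$feature, any)
  names(keep)[!is.na(keep) & keep]
}

#' Percentage with the reporting convention
#'
#' `100 * n / denominator`, rounded half away from zero to one decimal — the
#' convention used for all reported overview percentages (e.g. 1421 of 8364
#' genes gives 17.0).
#'
#' @param n count of interest.
#' @param denominator reference count (> 0).
#' @return numeric percentage with one decimal.
#' @export
summarize_significance <- function(n, denominator) {
  if (denominator <= 0) stopf("denominator must be positive")
  if (any(n < 0 | n > denominator)) stopf("need 0 <= n <= denominator")
  round_half_away(100 * n / denominator, 1)
}

#' Per-time-point overview of significant changes
#'
#' Counts features with significantly increased (`M > 0`) and decreased
#' (`M < 0`) abundance per time point, with percentages of the tested feature
#' set.
#'
#' @param records output of [abundance_records()].
#' @return data.frame (`time`, `n_up`, `n_down`, `denominator`, `pct_up`,
#'   `pct_down`).
#' @export
significance_overview <- function(records) {
  denominator <- length(unique(records$feature))
  out <- do.call(rbind, lapply(split(records, records$time), function(d) {
    n_up <- sum(d$significant & !is.na(d$M) & d$M > 0)
    n_down <- sum(d$significant & !is.na(d$M) & d$M < 0)
    data.frame(time = d$time[1], n_up = n_up, n_down = n_down,
               denominator = denominator,
               pct_up = summarize_significance(n_up, denominator),
               pct_down = summarize_significance(n_down, denominator))
  }))
  rownames(out) <- NULL
  out[order(out$time), ]
}
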