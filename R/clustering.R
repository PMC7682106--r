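#' Prepare time-course profiles for clustering
#'
#' Converts an M-value table into a complete feature x time matrix: features
#' observed at fewer than two thirds of the time points (ceiling) are
#' dropped; remaining interior gaps are imputed with the mean of the nearest
#' observed earlier and later time points, and missing boundary values take
#' the single nearest observed neighbour.
#'
#' @param m_table data.frame (`feature`, `time`, `M`) or a feature x time
#'   matrix with `NA` for missing.
#' @return numeric matrix (features x time points) without missing values;
#'   dropped features are recorded in the `"dropped"` attribute.
#' @export
prepare_profiles <- function(m_table) {
  m <- if (is.matrix(m_table)) m_table else {
    feats <- unique(m_table$feature)
    times <- sort(unique(m_table$time))
    mm <- matrix(NA_real_, length(feats), length(times),
                 dimnames = list(feats, as.character(times)))
    mm[cbind(match(m_table$feature, feats),
             match(as.character(m_table$time), as.character(times)))] <- m_table$M
    mm
  }
  nt <- ncol(m)
  need <- ceiling(2 * nt / 3)
  ok <- rowSums(!is.na(m)) >= need
  dropped <- rownames(m)[!ok]
  m <- m[ok, , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    obs <- which(!is.na(m[i, ]))   # originally observed values only
    miss <- which(is.na(m[i, ]))
    for (t in miss) {
      before <- obs[obs < t]
      after <- obs[obs > t]
      if (length(before) > 0 && length(after) > 0) {
        m[i, t] <- (m[i, max(before)] + m[i, min(after)]) / 2
      } else if (length(after) > 0) {
        m[i, t] <- m[i, min(after)]
      } else {
        m[i, t] <- m[i, max(before)]
      }
    }
  }
  attr(m, "dropped") <- dropped
  m
}

#' Ward hierarchical clustering of profiles
#'
#' Agglomerative clustering that merges, at each step, the pair of clusters
#' minimizing the increase in total within-cluster sum of squares (Ward's
#' criterion on Euclidean distances; `stats::hclust(method = "ward.D2")`).
#'
#' @param profiles complete numeric matrix (features x time points).
#' @param k number of clusters to cut the dendrogram into.
#' @return list of class `cluster_solution`: `assignments` (named integer
#'   vector), `k`, `hclust` (the dendrogram), `heights`.
#' @export
ward_cluster <- function(profiles, k) {
  if (k > nrow(profiles)) stopf("k = %d exceeds number of features (%d)",
                                k, nrow(profiles))
  hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
  structure(list(assignments = stats::cutree(hc, k = k), k = k,
                 hclust = hc, heights = hc$height),
            class = "cluster_solution")
}

#' Within-cluster dispersion
#'
#' `W = sum over clusters of the squared Euclidean distances of members to
#' their cluster centroid` — the quantity traced over `k` by the
#' Krzanowski-Lai index.
#'
#' @param profiles numeric matrix (features x dims).
#' @param assignments integer cluster id per row.
#' @return numeric scalar `W`.
#' @export
within_dispersion <- function(profiles, assignments) {
  if (length(assignments) != nrow(profiles)) stopf("assignment length mismatch")
  W <- 0
  for (cl in unique(assignments)) {
    x <- profiles[assignments == cl, , drop = FALSE]
    ctr <- colMeans(x)
    W <- W + sum(sweep(x, 2, ctr)^2)
  }
  W
}

#' Krzanowski-Lai optimal cluster number
#'
#' From the within-dispersion trace `W_k` (k = 1..k_max+1) and the profile
#' dimension `p`, computes `DIFF(k) = (k-1)^(2/p) W_{k-1} - k^(2/p) W_k` and
#' `KL(k) = |DIFF(k)| / |DIFF(k+1)|`; the optimal cluster number is the
#' maximizer of KL over k from 2 to k_max, skipping k with `DIFF(k+1) = 0` and
#' breaking ties towards smaller k. When all DIFF vanish the structure is
#' flat and no optimum exists. Candidates whose numerator `|DIFF(k)|` is
#' negligible (`<= tol_rel * max |DIFF|`) are excluded from the argmax: in
#' the structureless tail of the trace DIFF fluctuates around zero, and a
#' chance near-zero denominator under a similarly tiny numerator would
#' otherwise produce an arbitrarily large spurious KL maximum at a
#' meaningless k. A genuine optimum keeps a large numerator, so it is never
#' excluded.
#'
#' @param W numeric vector `W_1 .. W_{k_max+1}`.
#' @param p profile dimension (number of time points).
#' @param k_max largest candidate cluster number (defaults to
#'   `length(W) - 1`).
#' @param tol_rel relative tolerance below which a DIFF numerator is treated
#'   as noise.
#' @return list: `KL` (index trace, `NA` at undefined k), `DIFF`, `k_opt`,
#'   `flat` flag, and `low_contrast` (`TRUE`, with a warning, when the KL
#'   maximum barely exceeds the trace median, as for dispersion traces
#'   without cluster structure, e.g. geometric `W_k`).
#' @export
kl_optimal_k <- function(W, p, k_max = length(W) - 1, tol_rel = 1e-3) {
  if (p < 1) stopf("p must be >= 1")
  if (length(W) < k_max + 1) stopf("W must cover k = 1 .. k_max + 1")
  if (k_max < 2) {
    return(list(KL = rep(NA_real_, k_max + 1), DIFF = rep(NA_real_, k_max + 1),
                k_opt = NA_integer_, flat = TRUE))
  }
  ks <- seq_len(k_max + 1)
  DIFF <- c(NA_real_,
            (ks[-1] - 1)^(2 / p) * W[ks[-1] - 1] - ks[-1]^(2 / p) * W[ks[-1]])
  KL <- rep(NA_real_, k_max + 1)
  for (k in 2:k_max) {
    if (!is.na(DIFF[k + 1]) && DIFF[k + 1] != 0) {
      KL[k] <- abs(DIFF[k]) / abs(DIFF[k + 1])
    }
  }
  if (all(is.na(KL)) || all(DIFF[-1] == 0, na.rm = TRUE)) {
    return(list(KL = KL, DIFF = DIFF, k_opt = NA_integer_, flat = TRUE,
                low_contrast = TRUE))
  }
  num_floor <- tol_rel * max(abs(DIFF), na.rm = TRUE)
  eligible <- KL
  eligible[abs(DIFF[seq_along(KL)]) <= num_floor] <- NA_real_
  if (all(is.na(eligible))) eligible <- KL
  k_opt <- which.max(eligible)  # first maximum: ties go to smaller k
  contrast <- max(eligible, na.rm = TRUE) / stats::median(KL, na.rm = TRUE)
  low_contrast <- is.finite(contrast) && contrast < 2
  if (low_contrast) {
    warnf("KL index has low contrast (max/median = %.2f); k_opt = %d is weakly supported",
          contrast, k_opt)
  }
  list(KL = KL, DIFF = DIFF, k_opt = as.integer(k_opt), flat = FALSE,
       low_contrast = low_contrast)
}

#' Cluster a profile matrix with KL-selected k
#'
#' Runs Ward clustering once, traces the within-cluster dispersion for
#' k = 1..k_max+1 dendrogram cuts, selects the optimal k by the
#' Krzanowski-Lai index and returns the full solution.
#'
#' @param profiles complete numeric matrix (features x time points).
#' @param k_max maximal cluster number considered.
#' @return `cluster_solution` with `assignments` at `k_opt`, the `W` and `KL`
#'   traces, `k_opt`, `flat` flag and the dendrogram.
#' @export
cluster_dynamics <- function(profiles, k_max = 50) {
  n <- nrow(profiles)
  k_hi <- min(k_max + 1, n)
  hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
  cuts <- stats::cutree(hc, k = seq_len(k_hi))
  W <- vapply(seq_len(k_hi), function(k) within_dispersion(profiles, cuts[, k]), 0)
  kl <- kl_optimal_k(W, p = ncol(profiles), k_max = k_hi - 1)
  k_opt <- if (is.na(kl$k_opt)) 1L else kl$k_opt
  structure(list(assignments = cuts[, k_opt], k = k_opt, k_opt = kl$k_opt,
                 W = W, KL = kl$KL, DIFF = kl$DIFF, flat = kl$flat,
                 hclust = hc, heights = hc$height),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Ward/Euclidean cluster solution: %d features, k = %d\n",
              length(x$assignments), x$k))
  if (!is.null(x$flat) && isTRUE(x$flat)) cat("flat structure: KL undefined\n")
  invisible(x)
}

#' Per-cluster mean profiles and sizes
#'
#' @param solution a `cluster_solution`.
#' @param profiles the clustered matrix.
#' @return list with `means` (cluster x time matrix) and `sizes`.
#' @export
cluster_profiles <- function(solution, profiles) {
  a <- solution$assignments
  cls <- sort(unique(a))
  means <- t(vapply(cls, function(cl) {
    colMeans(profiles[a == cl, , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(means) <- cls
  list(means = means, sizes = as.integer(table(factor(a, levels = cls))))
}

#' Functional category enrichment per cluster
#'
#' Hypergeometric upper-tail test of each (cluster, category) pair — is the
#' category overrepresented among the cluster's members relative to the
#' clustered population — with Benjamini-Hochberg adjustment across all
#' pairs; enriched at `p_adj < 0.05`.
#'
#' @param solution a `cluster_solution`.
#' @param labels named character vector of category labels (COG/KEGG class)
#'   per feature.
#' @return data.frame (`cluster`, `category`, `overlap`, `cluster_size`,
#'   `category_size`, `p`, `p_adj`, `enriched`).
#' @export
category_enrichment <- function(solution, labels) {
  a <- solution$assignments
  feats <- names(a)
  labels <- labels[feats]
  N <- length(feats)
  rows <- list()
  for (cl in sort(unique(a))) {
    members <- feats[a == cl]
    n <- length(members)
    for (cat in sort(unique(labels[!is.na(labels)]))) {
      K <- sum(labels == cat, na.rm = TRUE)
      x <- sum(labels[members] == cat, na.rm = TRUE)
      p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, category = cat, overlap = x, cluster_size = n,
        category_size = K, p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$p_adj < 0.05
  out
}
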