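#' Simulate time-course transcript counts and protein LFQ intensities
#'
#' Draws a gene x time x replicate count table and a protein x time x
#' replicate label-free quantification (LFQ) table around the planted
#' archetype mean profiles. Counts follow a gamma-Poisson (negative binomial)
#' model with shared dispersion around `baseline * 2^archetype(t) * library
#' factor`; with `nb_dispersion = 0` and `library_size_cv = 0` the noiseless
#' limit is returned (values equal their means). LFQ intensities are
#' log-normal around the same archetype shape; proteins flagged as lagged
#' follow the transcript archetype delayed by one time point (the first
#' protein time point copies the first transcript time point). Missing-at-
#' random dropout at `missing_rate` is applied to LFQ cells only. Per-protein
#' metadata (unique peptide counts, localization prediction, fraction
#' detection, COG class) is drawn alongside.
#'
#' @param truth ground truth from [simulate_genome()] (`sim$truth`).
#' @param config a [sim_config()]; defaults to the one stored in `truth`.
#' @return list with long-format data.frames `counts` and `lfq`
#'   (`feature`, `time`, `replicate`, `value`; LFQ may contain `NA`) and
#'   `meta` (per-feature metadata: `unique_peptides`, `localization`,
#'   `fraction`, `cog`).
#' @export
simulate_expression <- function(truth, config = truth$config) {
  validate_sim_config(config)
  if (is.null(truth$genes$archetype)) stopf("truth lacks archetype labels")
  missing_arch <- setdiff(unique(truth$genes$archetype), names(config$archetype_set))
  if (length(missing_arch) > 0) {
    stopf("unknown archetype name(s): %s", paste(missing_arch, collapse = ", "))
  }
  with_seed(config$seed + 2L, simulate_expression_impl(truth, config))
}

simulate_expression_impl <- function(truth, cfg) {
  genes <- truth$genes
  nt <- cfg$n_timepoints
  nr <- cfg$n_replicates
  times <- cfg$timepoints

  profiles <- do.call(rbind, cfg$archetype_set[genes$archetype])  # gene x time

  # per-sample library size factors (log-normal, unit mean scale)
  sf <- if (cfg$library_size_cv > 0) {
    sdl <- sqrt(log(1 + cfg$library_size_cv^2))
    stats::rlnorm(nt * nr, -sdl^2 / 2, sdl)
  } else {
    rep(1, nt * nr)
  }
  sf <- matrix(sf, nrow = nt, ncol = nr)

  grid <- expand.grid(replicate = seq_len(nr), time_idx = seq_len(nt),
                      gene_idx = seq_len(nrow(genes)))
  mu <- genes$base_expr[grid$gene_idx] *
    2^profiles[cbind(grid$gene_idx, grid$time_idx)] *
    sf[cbind(grid$time_idx, grid$replicate)]
  value <- if (cfg$nb_dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  } else {
    mu
  }
  counts <- data.frame(feature = genes$gene[grid$gene_idx],
                       time = times[grid$time_idx],
                       replicate = grid$replicate,
                       value = value)
  attr(counts, "layer") <- "transcript_counts"

  # proteins: archetype shape, optionally delayed by one time point
  det <- which(genes$detected_protein)
  lfq <- NULL
  if (length(det) > 0) {
    pprof <- profiles[det, , drop = FALSE]
    lagged <- genes$lagged[det]
    pprof[lagged, ] <- cbind(pprof[lagged, 1, drop = FALSE],
                             pprof[lagged, -nt, drop = FALSE])
    base_p <- stats::rlnorm(length(det), log(1e7), 1)
    pg <- expand.grid(replicate = seq_len(nr), time_idx = seq_len(nt),
                      p_idx = seq_along(det))
    logv <- log2(base_p[pg$p_idx]) + pprof[cbind(pg$p_idx, pg$time_idx)] +
      stats::rnorm(nrow(pg), 0, cfg$lfq_sigma)
    val <- 2^logv
    val[stats::runif(nrow(pg)) < cfg$missing_rate] <- NA_real_
    lfq <- data.frame(feature = genes$gene[det][pg$p_idx],
                      time = times[pg$time_idx],
                      replicate = pg$replicate,
                      value = val)
  } else {
    lfq <- data.frame(feature = character(), time = numeric(),
                      replicate = integer(), value = numeric())
  }
  attr(lfq, "layer") <- "protein_lfq"

  loc <- sample(c("cytosolic", "membrane", "extracellular"),
                nrow(genes), replace = TRUE, prob = c(0.7, 0.2, 0.1))
  in_extra <- genes$detected_protein &
    (stats::runif(nrow(genes)) < ifelse(loc == "extracellular", 0.8, 0.2))
  meta <- data.frame(
    feature = genes$gene,
    unique_peptides = ifelse(stats::runif(nrow(genes)) < 0.1, 1L,
                             2L + stats::rpois(nrow(genes), 6)),
    localization = loc,
    fraction = ifelse(in_extra, "both", "cellular"),
    cog = sample(LETTERS[1:20], nrow(genes), replace = TRUE)
  )
  list(counts = counts, lfq = lfq, meta = meta)
}
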