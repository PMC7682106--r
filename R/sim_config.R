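#' Default time-course expression archetypes
#'
#' Mean log2 profile shapes (relative to the pooled all-time-point reference)
#' used to plant cluster structure in simulated time courses. The six shapes
#' mirror the qualitative cluster families seen in growth-phase expression
#' studies of filamentous actinomycetes: an inoculation/lag peak, a monotone
#' shut-down, a peak during filamentous growth, a transition-phase peak, a
#' stationary-phase rise, and a flat (non-dynamic) profile.
#'
#' @param n_timepoints number of sampling times (profiles are interpolated to
#'   this length; the canonical shapes are defined on 7 points).
#' @return named list of numeric vectors of length `n_timepoints`.
#' @export
default_archetypes <- function(n_timepoints = 7) {
  base <- list(
    lag_peak          = c( 2.0,  1.0,  0.0, -0.5, -1.0, -1.0, -0.5),
    monotone_decrease = c( 1.5,  1.0,  0.5,  0.0, -0.5, -1.0, -1.5),
    growth_peak       = c(-1.0,  0.5,  1.5,  1.0,  0.0, -1.0, -1.0),
    transition_peak   = c(-1.5, -1.0,  0.0,  0.5,  1.5,  1.0, -0.5),
    stationary_rise   = c(-1.5, -1.0, -0.5,  0.0,  0.5,  1.0,  1.5),
    flat              = rep(0, 7)
  )
  if (n_timepoints == 7L) return(base)
  lapply(base, function(p) {
    stats::approx(seq_along(p), p, n = n_timepoints)$y
  })
}

# Position frequency matrix from a consensus string with a given weight on the
# consensus base at informative positions; 'n' positions are uniform.
pwm_from_consensus <- function(consensus, weight = 0.85) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  w <- length(chars)
  m <- matrix(0.25, nrow = 4, ncol = w, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(w)) {
    b <- chars[i]
    if (b %in% DNA_BASES) {
      ww <- if (length(weight) == w) weight[i] else weight[1]
      m[, i] <- (1 - ww) / 3
      m[b, i] <- ww
    }
  }
  m
}

#' Simulation configuration
#'
#' Builds the configuration object consumed by [simulate_genome()],
#' [simulate_tracks()], [simulate_expression()] and [simulate_growth()].
#' Defaults emulate the statistical structure of a growth-phase multi-omics
#' study of *Actinoplanes* sp. SE50/110: a GC-rich genome (realized GC close
#' to 0.71), operonic gene organisation, a 14% leaderless-transcript rate,
#' 5'-UTR lengths within 4-494 nt, -10/-35 promoter elements (TAnnnT /
#' nTGACn consensus) with a 5-7 nt -10-to-TSS spacer and a ~17.6 +/- 2.5 nt
#' -35-to--10 spacer, seven sampling times in three biological replicates,
#' negative-binomial transcript counts, log-normal protein LFQ intensities
#' with missingness, a one-time-point transcript-to-protein lag for a
#' configurable fraction of coupled genes, and logistic growth with
#' growth-coupled product formation.
#'
#' @param seed integer seed; all simulator randomness derives from it.
#' @param n_genes number of annotated CDS features.
#' @param genome_length optional genome size (nt). `NULL` sizes the genome to
#'   fit the gene layout; a stated length too short for `n_genes` is an error
#'   at simulation time.
#' @param gc_content target genomic G+C fraction.
#' @param gene_length_range CDS length range (nt).
#' @param operon_size_probs probabilities of 1,2,3,4,>=5 genes per
#'   transcription unit (must sum to 1).
#' @param intra_gap_range,inter_gap_range intergenic distances (nt) within and
#'   between transcription units.
#' @param tss_prob fraction of transcription units receiving a planted TSS and
#'   promoter (the remainder emulate "predicted", non-validated operons).
#' @param internal_tss_prob per posterior operon gene, probability of an
#'   internal TSS (source of sub-operons).
#' @param leaderless_prob probability that a planted TSS is leaderless
#'   (5'-UTR <= 3 nt).
#' @param utr_length_range admissible leadered 5'-UTR lengths (nt).
#' @param utr_mean mean of the geometric leadered UTR length distribution.
#' @param minus10_pwm,minus35_pwm base-frequency matrices used to sample
#'   planted promoter hexamers.
#' @param spacer10_range -10 3' end to TSS gap (nt, sampled uniformly).
#' @param spacer_35_10_mean_sd mean and sd of the -35 3' end to -10 5' start
#'   gap (nt, rounded normal).
#' @param rbs_prob probability that a leadered gene (UTR > 10 nt) carries a
#'   planted GGAGG ribosome binding site.
#' @param tss_base_probs base distribution at the TSS position (A,C,G,T).
#' @param n_timepoints,n_replicates time-course design.
#' @param timepoints sampling times in hours.
#' @param archetype_set named list of mean log2 profile shapes.
#' @param archetype_probs sampling weights over the archetypes.
#' @param base_expr_meanlog,base_expr_sdlog log-normal baseline transcript
#'   abundance parameters.
#' @param nb_dispersion negative-binomial dispersion (gamma-Poisson); 0 gives
#'   the noiseless Poisson-free limit (counts equal their means, rounded).
#' @param library_size_cv coefficient of variation of per-sample library size
#'   factors.
#' @param protein_detect_rate fraction of genes with a detected protein.
#' @param protein_lag_fraction fraction of detected proteins whose profile
#'   follows the transcript archetype delayed by one time point (the first
#'   protein time point copies the first transcript time point).
#' @param lfq_sigma log2-scale sd of LFQ noise.
#' @param missing_rate missing-at-random rate applied to LFQ cells only.
#' @param coverage_depth mean combined coverage of an average-expression gene.
#' @param spanning_frac intra-operon intergenic coverage as a fraction of the
#'   lower flanking gene coverage.
#' @param tss_strength expected read-start count at a planted TSS.
#' @param bg_start_rate per-nt Poisson rate of background read starts within
#'   transcribed regions.
#' @param growth_params list: `mu` (1/h logistic rate), `X0`, `Xmax` (g/L CDW),
#'   `q_max` (g/g/h peak specific production), `t_peak` (h, time of peak
#'   specific production; 0 disables production).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 300L,
                       genome_length = NULL,
                       gc_content = 0.71,
                       gene_length_range = c(300L, 1500L),
                       operon_size_probs = c(`1` = 0.60, `2` = 0.18, `3` = 0.10,
                                             `4` = 0.07, `5` = 0.05),
                       intra_gap_range = c(20L, 120L),
                       inter_gap_range = c(700L, 1500L),
                       tss_prob = 0.7,
                       internal_tss_prob = 0.4,
                       leaderless_prob = 0.14,
                       utr_length_range = c(4L, 494L),
                       utr_mean = 80,
                       minus10_pwm = pwm_from_consensus("TAnnnT",
                                                        c(0.85, 0.9, 0, 0, 0, 0.85)),
                       minus35_pwm = pwm_from_consensus("nTGACn",
                                                        c(0, 0.7, 0.85, 0.55, 0.8, 0)),
                       spacer10_range = c(5L, 7L),
                       spacer_35_10_mean_sd = c(17.6, 2.5),
                       rbs_prob = 0.932,
                       tss_base_probs = c(A = 0.242, C = 0.117, G = 0.512, T = 0.129),
                       n_timepoints = 7L,
                       n_replicates = 3L,
                       timepoints = c(24.0, 47.8, 72.3, 96.5, 120.0, 144.3, 168.0),
                       archetype_set = default_archetypes(n_timepoints),
                       archetype_probs = NULL,
                       base_expr_meanlog = log(200),
                       base_expr_sdlog = 1,
                       nb_dispersion = 0.05,
                       library_size_cv = 0.1,
                       protein_detect_rate = 0.5,
                       protein_lag_fraction = 0.3,
                       lfq_sigma = 0.2,
                       missing_rate = 0.1,
                       coverage_depth = 200,
                       spanning_frac = 0.8,
                       tss_strength = 100,
                       bg_start_rate = 0.05,
                       growth_params = list(mu = 0.06, X0 = 0.4, Xmax = 20,
                                            q_max = 2e-3, t_peak = 36)) {
  cfg <- as.list(environment())
  if (is.null(cfg$archetype_probs)) {
    cfg$archetype_probs <- stats::setNames(
      rep(1 / length(cfg$archetype_set), length(cfg$archetype_set)),
      names(cfg$archetype_set)
    )
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$tss_prob, cfg$internal_tss_prob, cfg$leaderless_prob,
             cfg$rbs_prob, cfg$protein_detect_rate, cfg$protein_lag_fraction,
             cfg$missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stopf("all probability parameters must lie in [0, 1]")
  }
  if (abs(sum(cfg$operon_size_probs) - 1) > 1e-8) {
    stopf("operon_size_probs must sum to 1")
  }
  if (abs(sum(cfg$tss_base_probs) - 1) > 1e-8) {
    stopf("tss_base_probs must sum to 1")
  }
  if (cfg$utr_length_range[1] < 4 || cfg$utr_length_range[2] > 494) {
    stopf("utr_length_range must lie within [4, 494] nt")
  }
  if (cfg$n_timepoints < 3) stopf("n_timepoints must be >= 3")
  if (length(cfg$timepoints) != cfg$n_timepoints) {
    stopf("timepoints must have length n_timepoints")
  }
  if (is.unsorted(cfg$timepoints, strictly = TRUE)) {
    stopf("timepoints must be strictly increasing")
  }
  if (cfg$nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  if (!all(vapply(cfg$archetype_set, length, 1L) == cfg$n_timepoints)) {
    stopf("each archetype profile must have n_timepoints values")
  }
  gp <- cfg$growth_params
  if (gp$mu <= 0 || gp$X0 <= 0 || gp$Xmax <= gp$X0) {
    stopf("growth_params require mu > 0 and Xmax > X0 > 0")
  }
  invisible(cfg)
}
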