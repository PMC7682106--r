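#' Run the full synthetic growth-phase multi-omics pipeline
#'
#' End-to-end driver: simulates a genome with planted transcriptional
#' architecture, evidence tracks, expression time courses and a growth
#' series, then runs every analysis stage — specific product formation and
#' phase labels; size-factor normalization, pooled-reference M-values,
#' per-time-point significance and the dynamic-feature filter for the
#' transcriptome; the proteome filter cascade with z-scores and protein
#' M-values; operon calling, TSS assignment and validation, sub-operon
#' derivation and the operon summary; promoter -10/-35 motif discovery with
#' spacer statistics and RBS/TSS-base statistics; Ward/Krzanowski-Lai
#' clustering of both layers; and the cross-omics co-occurrence matrix and
#' lagged correlations. With an output directory, all result tables are
#' written as TSV along with a YAML run manifest (seed, package version,
#' effective parameters); identical seeds give byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory (created if missing).
#' @param d_max,f_min operon joining parameters (see
#'   [call_primary_operons()]).
#' @param min_starts,fold_bg,bg_window TSS detection parameters (see
#'   [detect_tss()]).
#' @param k_max maximal cluster number.
#' @param n_restarts EM restarts for motif discovery.
#' @param write_tracks also export genome FASTA, GFF3 and bedGraph tracks
#'   (larger files; off by default).
#' @return a named list with every stage's results (invisible when
#'   `out_dir` is given).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         d_max = 500, f_min = 0.5,
                         min_starts = 10, fold_bg = 5, bg_window = 50,
                         k_max = 50, n_restarts = 20, write_tracks = FALSE) {
  stage <- "simulate"
  res <- tryCatch({
    sim <- simulate_genome(config)
    tracks <- simulate_tracks(sim, config)
    expr <- simulate_expression(sim$truth, config)

    stage <- "growth"
    growth <- simulate_growth(config)
    q_table <- specific_product_formation(growth)
    phases <- annotate_phases(config$timepoints)

    stage <- "transcriptome"
    norm <- size_factor_normalize(expr$counts)
    t_records <- abundance_records(norm$values, log_transform = TRUE)
    t_overview <- significance_overview(t_records)
    t_dynamic <- filter_dynamic(t_records)

    stage <- "proteome"
    casc <- proteome_filter_cascade(expr$lfq, expr$meta,
                                    n_replicates = config$n_replicates)
    p_m <- compute_m_values(expr$lfq[expr$lfq$feature %in%
                                       unique(casc$values$feature), ])
    p_sig <- test_significance(casc$values, log_transform = FALSE)
    p_records <- merge(p_m, p_sig, by = c("feature", "time"), sort = FALSE)
    p_overview <- significance_overview(p_records)

    stage <- "operons"
    operon_call <- call_primary_operons(sim$annotation, tracks$coverage,
                                        d_max = d_max, f_min = f_min)
    candidates <- detect_tss(tracks$five_prime, min_starts = min_starts,
                             fold_bg = fold_bg, bg_window = bg_window)
    tss <- assign_primary_tss(candidates, sim$annotation, sim$genome)
    operons <- validate_operons(operon_call$operons, tss)
    subs <- derive_sub_operons(operons, tss)
    operon_summary <- summarize_operons(operons, subs,
                                        operon_call$monocistronic, tss)

    stage <- "motifs"
    windows <- extract_upstream_windows(tss, sim$genome, length = 50)
    promoters <- promoter_motifs(windows, seed = config$seed,
                                 n_restarts = n_restarts)
    rbs <- rbs_and_start_stats(tss, sim$genome, seed = config$seed,
                               n_restarts = n_restarts)

    stage <- "clustering"
    t_profiles <- prepare_profiles(
      t_records[t_records$feature %in% t_dynamic, c("feature", "time", "M")])
    t_clusters <- cluster_dynamics(t_profiles, k_max = k_max)

    stage <- "crossomics"
    p_profiles <- prepare_profiles(p_records[, c("feature", "time", "M")])
    all_t_profiles <- prepare_profiles(t_records[, c("feature", "time", "M")])
    paired <- pair_features(all_t_profiles, p_profiles)
    both <- combined_clustering(paired, k_max = k_max)
    cooc <- co_occurrence(both$transcript, both$protein)
    lag_tables <- do.call(rbind, lapply(0:1, function(l) {
      lagged_pearson(paired, lag = l)
    }))

    list(sim = sim, tracks = tracks, expr = expr, growth = growth,
         q_table = q_table, phases = phases,
         size_factors = norm$size_factors,
         transcript_records = t_records, transcript_overview = t_overview,
         dynamic_features = t_dynamic,
         proteome = casc, protein_records = p_records,
         protein_overview = p_overview,
         operons = operons, sub_operons = subs,
         monocistronic = operon_call$monocistronic, tss = tss,
         operon_summary = operon_summary,
         promoters = promoters, rbs = rbs,
         transcript_clusters = t_clusters, paired = paired,
         cross_clusters = both, co_occurrence = cooc,
         lag_correlations = lag_tables)
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_tsv(res$q_table, p("specific_product_formation.tsv"))
    write_tsv(data.frame(time = config$timepoints, phase = res$phases),
              p("growth_phases.tsv"))
    write_tsv(res$transcript_records, p("transcript_abundance.tsv"))
    write_tsv(res$transcript_overview, p("transcript_overview.tsv"))
    write_tsv(res$protein_records, p("protein_abundance.tsv"))
    write_tsv(res$protein_overview, p("protein_overview.tsv"))
    write_tsv(as_operon_table(c(res$operons, res$sub_operons)),
              p("operons.tsv"))
    write_tsv(res$operon_summary$by_size, p("operon_summary.tsv"))
    write_tsv(res$tss, p("tss.tsv"))
    pfm10 <- as.data.frame(res$promoters$minus10$pfm)
    pfm10 <- cbind(base = rownames(pfm10), pfm10)
    write_tsv(pfm10, p("minus10_pfm.tsv"))
    if (!is.null(res$promoters$minus35)) {
      pfm35 <- as.data.frame(res$promoters$minus35$pfm)
      pfm35 <- cbind(base = rownames(pfm35), pfm35)
      write_tsv(pfm35, p("minus35_pfm.tsv"))
    }
    write_tsv(data.frame(feature = names(res$transcript_clusters$assignments),
                         cluster = res$transcript_clusters$assignments),
              p("transcript_clusters.tsv"))
    cooc_df <- as.data.frame(res$co_occurrence$rounded)
    write_tsv(cbind(transcript_cluster = rownames(cooc_df), cooc_df),
              p("co_occurrence.tsv"))
    write_tsv(res$lag_correlations, p("lag_correlations.tsv"))
    if (write_tracks) {
      write_genome(res$sim$genome, p("genome.fasta"))
      write_annotation(res$sim$annotation, p("annotation.gff3"))
      write_bedgraph(res$tracks$coverage$`+`, p("coverage_plus.bedgraph"))
      write_bedgraph(res$tracks$coverage$`-`, p("coverage_minus.bedgraph"))
      write_bedgraph(res$tracks$five_prime$`+`, p("five_prime_plus.bedgraph"))
      write_bedgraph(res$tracks$five_prime$`-`, p("five_prime_minus.bedgraph"))
    }
    manifest <- list(
      package = "phaseomics",
      version = as.character(utils::packageVersion("phaseomics")),
      seed = config$seed,
      n_genes = config$n_genes,
      n_timepoints = config$n_timepoints,
      n_replicates = config$n_replicates,
      parameters = list(d_max = d_max, f_min = f_min,
                        min_starts = min_starts, fold_bg = fold_bg,
                        bg_window = bg_window, k_max = k_max,
                        n_restarts = n_restarts),
      filters = res$proteome$report
    )
    yaml::write_yaml(manifest, p("manifest.yaml"))
    return(invisible(res))
  }
  res
}
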