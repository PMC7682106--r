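#' Proteome filter cascade
#'
#' Applies the quantification filters used for label-free proteome time
#' courses: (1) proteins identified with fewer than two unique peptides are
#' excluded; (2) every (protein, time point) cell in which the protein was not
#' quantified in all replicates is blanked; (3) the retained intensities are
#' log2-transformed and z-normalized per protein (mean 0, sd 1 over its
#' retained cells, replicate-wise). The filter report records the removal
#' counts per rule and how many retained proteins have data at >= 6 of 7 time
#' points. Rules 1 and 2 commute, so the final set does not depend on their
#' order.
#'
#' @param lfq long-format LFQ table (`feature`, `time`, `replicate`, `value`;
#'   `NA` marks a missed identification).
#' @param meta per-feature metadata with columns `feature` and
#'   `unique_peptides`.
#' @param n_replicates replicate completeness required per retained cell.
#' @return list with `values` (long table of per-protein z-scores; blanked
#'   cells are `NA`) and `report` (named list of counts).
#' @export
proteome_filter_cascade <- function(lfq, meta, n_replicates = 3L) {
  if (is.null(meta$unique_peptides)) stopf("meta lacks unique_peptides")
  up <- stats::setNames(meta$unique_peptides, meta$feature)
  feats0 <- unique(lfq$feature)
  low_pep <- feats0[up[feats0] < 2]
  x <- lfq[!(lfq$feature %in% low_pep), , drop = FALSE]

  # blank cells not quantified in all replicates
  obs <- stats::aggregate(value ~ feature + time, data = x,
                          FUN = function(v) sum(!is.na(v)),
                          na.action = stats::na.pass)
  names(obs)[3] <- "n_obs"
  x <- merge(x, obs, by = c("feature", "time"), sort = FALSE)
  blank <- x$n_obs < n_replicates
  cells_blanked <- nrow(unique(x[blank & x$n_obs > 0, c("feature", "time")]))
  x$value[blank] <- NA_real_
  x$n_obs <- NULL

  # per-protein z-normalization of log2 intensities over retained cells
  x$value <- log2(x$value)
  parts <- split(x, x$feature)
  x <- do.call(rbind, lapply(parts, function(d) {
    v <- d$value
    if (sum(!is.na(v)) >= 2 && stats::sd(v, na.rm = TRUE) > 0) {
      d$value <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    }
    d
  }))
  rownames(x) <- NULL
  x <- x[order(match(x$feature, feats0), x$time, x$replicate), ]

  times_per <- tapply(!is.na(x$value), list(x$feature, x$time), any)
  n_times <- rowSums(times_per, na.rm = TRUE)
  n_tp <- length(unique(lfq$time))
  report <- list(
    removed_low_peptides = length(low_pep),
    cells_blanked = cells_blanked,
    n_proteins_retained = length(unique(x$feature)),
    n_proteins_6of7 = sum(n_times >= max(n_tp - 1, 1))
  )
  attr(x, "layer") <- "protein_lfq"
  list(values = x, report = report)
}

#' Reconcile cellular and extracellular fraction assignments
#'
#' Proteins detected in both the cellular and the extracellular fraction that
#' are also predicted extracellular (signal peptide) are treated as genuine
#' extracellular proteins: they are removed from the cellular data set and
#' assigned `extracellular`. All other both-fraction proteins keep `both`;
#' single-fraction proteins keep their fraction.
#'
#' @param cellular character vector of protein ids detected in the cellular
#'   fraction.
#' @param extracellular character vector of protein ids detected in the
#'   extracellular fraction.
#' @param localization named character vector (`cytosolic`, `membrane`,
#'   `extracellular`) per protein; unknown labels are treated as cytosolic
#'   with a warning.
#' @return list with `assignment` (data.frame `feature`, `fraction`) and
#'   `counts` (per reconciliation class).
#' @export
fraction_reconciliation <- function(cellular, extracellular, localization) {
  ids <- union(cellular, extracellular)
  loc <- localization[ids]
  bad <- !is.na(loc) & !(loc %in% c("cytosolic", "membrane", "extracellular"))
  if (any(bad)) {
    warnf("unknown localization label(s) treated as cytosolic: %s",
          paste(unique(loc[bad]), collapse = ", "))
    loc[bad] <- "cytosolic"
  }
  loc[is.na(loc)] <- "cytosolic"
  in_c <- ids %in% cellular
  in_e <- ids %in% extracellular
  fraction <- ifelse(in_c & in_e,
                     ifelse(loc == "extracellular", "extracellular", "both"),
                     ifelse(in_e, "extracellular", "cellular"))
  counts <- list(
    both_reassigned_extracellular = sum(in_c & in_e & loc == "extracellular"),
    both_kept = sum(in_c & in_e & loc != "extracellular"),
    cellular_only = sum(in_c & !in_e),
    extracellular_only = sum(!in_c & in_e)
  )
  list(assignment = data.frame(feature = ids, fraction = fraction,
                               row.names = NULL),
       counts = counts)
}

PTM_TYPES <- c("oxidation", "acetylation", "phosphorylation", "pyro-Glu")

#' Summarize post-translational modification records
#'
#' Groups validated modification records by protein and modification type and
#' lists the time points at which each (protein, type) combination was
#' observed. With `exclude_oxidation = TRUE` (the overview-table view),
#' methionine oxidations are dropped before summarizing.
#'
#' @param records data.frame with columns `protein`, `type` (one of
#'   `oxidation`, `acetylation`, `phosphorylation`, `pyro-Glu`), optional
#'   `position`, and `time` (time-point label, e.g. `"T3"`).
#' @param exclude_oxidation drop oxidation records before summarizing.
#' @return data.frame (`protein`, `type`, `timepoints`) with time points
#'   sorted, unique and collapsed with `"; "`.
#' @export
ptm_summary <- function(records, exclude_oxidation = TRUE) {
  empty <- data.frame(protein = character(), type = character(),
                      timepoints = character())
  if (nrow(records) == 0) return(empty)
  unknown <- setdiff(unique(records$type), PTM_TYPES)
  if (length(unknown) > 0) {
    stopf("unknown modification type(s): %s", paste(unknown, collapse = ", "))
  }
  if (exclude_oxidation) records <- records[records$type != "oxidation", ]
  if (nrow(records) == 0) return(empty)
  out <- stats::aggregate(time ~ protein + type, data = records,
                          FUN = function(tp) paste(sort(unique(tp)),
                                                   collapse = "; "))
  names(out)[3] <- "timepoints"
  out[order(out$protein, out$type), c("protein", "type", "timepoints")]
}
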