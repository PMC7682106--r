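#' Motif discovery by ZOOPS expectation maximization
#'
#' Fits a zero-or-one-occurrence-per-sequence (ZOOPS) motif model of width
#' `width` to a set of sequence windows. The E-step computes, per window, a
#' posterior over all motif start offsets plus a no-site option under a fixed
#' 0-order background (the window base composition); the M-step re-estimates
#' the position frequency matrix with a pseudocount of 0.25 per base and the
#' site prior. The pseudocount makes this maximum-a-posteriori EM under a
#' Dirichlet(1.25) column prior, so the monotone objective reported in
#' `loglik` is the penalized log-likelihood (data log-likelihood plus
#' `0.25 * sum(log f)`); iteration stops when its gain drops below `tol` or
#' after `max_iter` iterations, and it is non-decreasing across iterations.
#' The best of `n_restarts` seeded restarts (each initialised from a randomly
#' chosen window subsequence) is returned. A window is a hit when its total
#' site posterior is at least 0.5.
#'
#' @param windows character vector of A/C/G/T windows (unequal lengths
#'   allowed; windows shorter than `width` can never be hits).
#' @param width motif width (nt).
#' @param n_restarts number of EM restarts.
#' @param seed base seed for the restarts.
#' @param max_iter,tol EM stopping rule.
#' @param offset_decay optional geometric offset prior: the prior weight of a
#'   site starting at offset `o` is proportional to
#'   `offset_decay^(m_s - o)` (favouring 3'-proximal placements, as
#'   location-weighted promoter motif samplers do). `NULL` gives a uniform
#'   offset prior.
#' @return object of class `motif_model`: `width`, `pfm` (4 x width base
#'   frequency matrix, columns sum to 1), `offsets` (per-window best-hit
#'   1-based start, `NA` when no hit), `hit` (logical per window),
#'   `fraction_with_hit`, `site_prior`, `loglik` (per-iteration trace of the
#'   winning restart), `consensus`, `degenerate` flag.
#' @export
em_motif_search <- function(windows, width = 6, n_restarts = 20, seed = 1,
                            max_iter = 500, tol = 1e-6, offset_decay = NULL) {
  if (length(windows) < 10) stopf("need at least 10 windows")
  enc <- lapply(strsplit(toupper(windows), ""), function(ch) {
    match(ch, DNA_BASES)
  })
  lens <- lengths(enc)
  if (max(lens) < width) stopf("width exceeds every window length")
  n <- length(enc)
  Lmax <- max(lens)
  X <- matrix(NA_integer_, n, Lmax)
  for (i in seq_len(n)) if (lens[i] > 0) X[i, seq_len(lens[i])] <- enc[[i]]
  m_s <- pmax(lens - width + 1L, 0L)  # offsets per window
  max_m <- max(m_s)

  # fixed 0-order background from overall base composition
  tab <- tabulate(X[!is.na(X)], nbins = 4)
  degenerate <- sum(tab > 0) <= 1
  bg <- pmax(tab / sum(tab), 1e-6)
  bg <- bg / sum(bg)
  log_bg <- log(bg)

  # per-window offset prior (rows sum to 1 over valid offsets)
  P <- matrix(0, n, max_m)
  for (i in seq_len(n)) {
    if (m_s[i] > 0) {
      w_o <- if (is.null(offset_decay)) rep(1, m_s[i]) else
        offset_decay^(m_s[i] - seq_len(m_s[i]))
      P[i, seq_len(m_s[i])] <- w_o / sum(w_o)
    }
  }

  fit_once <- function(f0) {
    f <- f0
    gamma <- 0.5
    ll_trace <- numeric(0)
    ll_old <- -Inf
    z <- NULL
    for (iter in seq_len(max_iter)) {
      logdiff <- log(f) - log_bg           # 4 x width
      # S[s, o]: log-likelihood ratio of a site at offset o vs background
      S <- matrix(-Inf, n, max_m)
      for (o in seq_len(max_m)) {
        seg <- X[, o:(o + width - 1L), drop = FALSE]
        v <- matrix(logdiff[cbind(as.vector(seg),
                                  rep(seq_len(width), each = n))], n, width)
        sc <- rowSums(v)
        sc[m_s < o] <- -Inf
        S[, o] <- sc
      }
      R <- exp(S)
      R[P == 0] <- 0
      denom_site <- gamma * rowSums(P * R, na.rm = TRUE)
      denom <- (1 - gamma) + denom_site
      # penalized (MAP) objective: data log-likelihood ratio + Dirichlet term
      ll <- sum(log(denom)) + 0.25 * sum(log(f))
      ll_trace <- c(ll_trace, ll)
      z <- (gamma * P * R) / denom
      z[!is.finite(z)] <- 0
      # M-step
      counts <- matrix(0.25, 4, width)
      for (o in seq_len(max_m)) {
        w_o <- z[, o]
        if (all(w_o == 0)) next
        for (i in seq_len(width)) {
          b <- X[, o + i - 1L]
          ok <- !is.na(b) & w_o > 0
          if (any(ok)) {
            counts[, i] <- counts[, i] +
              vapply(1:4, function(k) sum(w_o[ok][b[ok] == k]), 0)
          }
        }
      }
      f <- sweep(counts, 2, colSums(counts), "/")
      gamma <- min(max(mean(rowSums(z)), 1e-4), 1 - 1e-4)
      if (ll - ll_old < tol && iter > 1) break
      ll_old <- ll
    }
    site_post <- rowSums(z)
    hit <- site_post >= 0.5
    offsets <- rep(NA_integer_, n)
    if (any(hit)) {
      offsets[hit] <- apply(z[hit, , drop = FALSE], 1, which.max)
    }
    list(f = f, gamma = gamma, ll = ll_trace, hit = hit, offsets = offsets)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(as.integer(seed) + r, {
      eligible <- which(m_s > 0)
      i <- eligible[sample.int(length(eligible), 1)]
      o <- sample(m_s[i], 1)
      f0 <- matrix((1 - 0.7) / 3, 4, width)
      sub <- X[i, o:(o + width - 1L)]
      for (j in seq_len(width)) {
        if (!is.na(sub[j])) f0[sub[j], j] <- 0.7 else f0[, j] <- 0.25
      }
      fit_once(f0)
    })
    if (is.null(best) || max(fit$ll) > max(best$ll)) best <- fit
  }

  pfm <- best$f
  dimnames(pfm) <- list(DNA_BASES, NULL)
  model <- structure(list(
    width = width, pfm = pfm, offsets = best$offsets, hit = best$hit,
    fraction_with_hit = mean(best$hit), site_prior = best$gamma,
    loglik = best$ll, degenerate = degenerate,
    window_lengths = lens
  ), class = "motif_model")
  model$consensus <- consensus_string(model)
  model
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("ZOOPS motif model, width %d, consensus %s\n", x$width,
              x$consensus))
  cat(sprintf("hits in %.1f%% of %d windows (site prior %.2f)\n",
              100 * x$fraction_with_hit, length(x$hit), x$site_prior))
  invisible(x)
}

#' Consensus string of a motif model
#'
#' Renders each position as its most frequent base when that base's frequency
#' reaches `threshold`, and as `n` otherwise (e.g. the canonical -10 and -35
#' promoter consensus strings TAnnnT and nTGACn).
#'
#' @param model a `motif_model` or a 4 x width base frequency matrix with
#'   rows A, C, G, T.
#' @param threshold minimal frequency for a position to be rendered as a
#'   base.
#' @return character scalar over `{A, C, G, T, n}`.
#' @export
consensus_string <- function(model, threshold = 0.5) {
  f <- if (inherits(model, "motif_model")) model$pfm else model
  stopifnot(nrow(f) == 4)
  paste(vapply(seq_len(ncol(f)), function(i) {
    b <- which.max(f[, i])
    if (f[b, i] >= threshold) DNA_BASES[b] else "n"
  }, ""), collapse = "")
}

#' Promoter -10 and -35 motif discovery with spacer statistics
#'
#' Runs [em_motif_search()] on the upstream windows for the -10 element, then
#' on the sub-windows upstream of each -10 hit for the -35 element, and
#' derives the two spacer distributions: the exclusive gap between the -10
#' 3' end and the TSS (windows end at the base immediately before the TSS)
#' and the gap between the -35 3' end and the -10 5' start (windows with both
#' hits only).
#'
#' @param windows upstream windows from [extract_upstream_windows()].
#' @param width motif width.
#' @param seed,n_restarts EM settings.
#' @param offset_decay10 geometric proximity prior for the -10 search (the
#'   -10 element sits close to the TSS); `NULL` for a uniform offset prior.
#' @return list: `minus10`, `minus35` (motif models; -35 offsets are in
#'   original window coordinates), `spacer10`, `spacer3510` (spacer stats,
#'   see [spacer_stats()]).
#' @export
promoter_motifs <- function(windows, width = 6, seed = 1, n_restarts = 20,
                            offset_decay10 = 0.9) {
  m10 <- em_motif_search(windows, width = width, seed = seed,
                         n_restarts = n_restarts, offset_decay = offset_decay10)
  lens <- nchar(windows)
  sp10 <- spacer_stats(lens[m10$hit] - (m10$offsets[m10$hit] + width - 1L),
                       type = "minus10_to_TSS")
  # -35 search upstream of the -10 hit
  idx10 <- which(m10$hit)
  prefix <- substr(windows[idx10], 1L, pmax(m10$offsets[idx10] - 1L, 0L))
  m35 <- NULL
  sp3510 <- spacer_stats(integer(0), type = "minus35_to_minus10")
  if (sum(nchar(prefix) >= width) >= 10) {
    m35 <- em_motif_search(prefix, width = width, seed = seed + 1000,
                           n_restarts = n_restarts)
    # map hits back to original windows
    offsets <- rep(NA_integer_, length(windows))
    hit <- logical(length(windows))
    offsets[idx10] <- m35$offsets
    hit[idx10] <- m35$hit
    m35$offsets <- offsets
    m35$hit <- hit
    m35$fraction_with_hit <- sum(hit) / length(windows)
    both <- which(hit & m10$hit)
    sp3510 <- spacer_stats(m10$offsets[both] - (m35$offsets[both] + width),
                           type = "minus35_to_minus10")
  }
  list(minus10 = m10, minus35 = m35, spacer10 = sp10, spacer3510 = sp3510)
}

#' Spacer length statistics
#'
#' Mean, population standard deviation and histogram of a vector of spacer
#' lengths (nt).
#'
#' @param values integer spacer lengths.
#' @param type label (`minus10_to_TSS` or `minus35_to_minus10`).
#' @return list (`type`, `n`, `mean`, `sd`, `histogram`); empty input gives
#'   `n = 0` with `NA` moments.
#' @export
spacer_stats <- function(values, type = "minus10_to_TSS") {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(list(type = type, n = 0L, mean = NA_real_, sd = NA_real_,
                histogram = table(integer(0))))
  }
  list(type = type, n = length(values), mean = mean(values),
       sd = sqrt(mean((values - mean(values))^2)),
       histogram = table(values))
}

#' Ribosome-binding-site fraction and TSS base statistics
#'
#' Searches the 5'-UTRs of leadered transcripts with UTR length greater than
#' `utr_min` nt for a ribosome binding site (Shine-Dalgarno, consensus
#' nGGAGn) by EM, restricted to the `search_len` nt immediately upstream of
#' the translation start. Also reports the base distribution at the TSS
#' positions and the purine fraction.
#'
#' @param tss assigned TSS table from [assign_primary_tss()] (needs
#'   `start_nucleotide`).
#' @param genome [Biostrings::DNAString].
#' @param utr_min minimal UTR length for the RBS search (nt).
#' @param search_len UTR suffix searched (nt upstream of the TLS).
#' @param width,seed,n_restarts EM settings.
#' @return list: `rbs_model` (or `NULL` when too few leadered transcripts),
#'   `rbs_fraction`, `n_searched`, `tss_base_distribution` (A/C/G/T
#'   fractions), `purine_fraction`.
#' @export
rbs_and_start_stats <- function(tss, genome, utr_min = 10, search_len = 20,
                                width = 6, seed = 1, n_restarts = 20) {
  base_tab <- table(factor(tss$start_nucleotide, levels = DNA_BASES))
  base_dist <- if (sum(base_tab) > 0) as.numeric(base_tab) / sum(base_tab)
               else rep(NA_real_, 4)
  names(base_dist) <- DNA_BASES
  purine <- unname(base_dist["A"] + base_dist["G"])

  lead <- tss[!tss$leaderless & tss$utr_length > utr_min, , drop = FALSE]
  if (nrow(lead) < 10) {
    return(list(rbs_model = NULL, rbs_fraction = NA_real_, n_searched = 0L,
                tss_base_distribution = base_dist, purine_fraction = purine))
  }
  gseq <- as.character(genome)
  win <- character(nrow(lead))
  for (i in seq_len(nrow(lead))) {
    u <- lead$utr_length[i]
    span <- min(search_len, u)
    if (lead$strand[i] == "+") {
      tls <- lead$pos[i] + u
      win[i] <- substring(gseq, tls - span, tls - 1L)
    } else {
      tls <- lead$pos[i] - u
      win[i] <- revcomp_string(substring(gseq, tls + 1L, tls + span))
    }
  }
  model <- em_motif_search(win, width = width, seed = seed,
                           n_restarts = n_restarts)
  list(rbs_model = model, rbs_fraction = model$fraction_with_hit,
       n_searched = nrow(lead), tss_base_distribution = base_dist,
       purine_fraction = purine)
}
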