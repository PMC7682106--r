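#' Simulate a batch-cultivation growth series with product formation
#'
#' Cell dry weight (CDW) follows a logistic curve
#' `X(t) = Xmax / (1 + ((Xmax - X0)/X0) exp(-mu t))`. The specific product
#' formation rate is modelled as a single-peak gamma-type pulse
#' `q(t) = q_max (t/t_peak) exp(1 - t/t_peak)` (g product per g CDW per h),
#' which rises over the lag/early-growth phase, peaks at `t_peak` and decays
#' towards zero in stationary phase; the product concentration is the
#' integral of `q(t) X(t)`, hence non-decreasing. Replicates receive
#' multiplicative measurement noise.
#'
#' @param config a [sim_config()]; `growth_params` supplies `mu`, `X0`,
#'   `Xmax`, `q_max`, `t_peak`. `q_max = 0` (or `t_peak = 0`) disables
#'   production and yields a flat zero product curve.
#' @param noise_cv multiplicative replicate noise (coefficient of variation);
#'   0 for noiseless curves.
#' @return data.frame (`t`, `X`, `P`, `replicate`): hours, CDW g/L, product
#'   g/L, one row per sampling time and replicate.
#' @export
simulate_growth <- function(config = sim_config(), noise_cv = 0.02) {
  validate_sim_config(config)
  gp <- config$growth_params
  if ((gp$q_max %||% 0) < 0) stopf("growth_params$q_max must be >= 0")
  with_seed(config$seed + 3L, {
    t_obs <- config$timepoints
    fine <- seq(0, max(t_obs), by = 0.25)
    X_fine <- logistic_cdw(fine, gp)
    q_fine <- if ((gp$q_max %||% 0) > 0 && (gp$t_peak %||% 0) > 0) {
      gp$q_max * (fine / gp$t_peak) * exp(1 - fine / gp$t_peak)
    } else {
      numeric(length(fine))
    }
    # cumulative trapezoidal integral of q(t) X(t)
    integrand <- q_fine * X_fine
    dP <- diff(fine) * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2
    P_fine <- c(0, cumsum(dP))
    X_obs <- stats::approx(fine, X_fine, t_obs)$y
    P_obs <- stats::approx(fine, P_fine, t_obs)$y
    out <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      noise_X <- if (noise_cv > 0) stats::rnorm(length(t_obs), 1, noise_cv) else 1
      noise_P <- if (noise_cv > 0) stats::rnorm(length(t_obs), 1, noise_cv) else 1
      data.frame(t = t_obs, X = pmax(X_obs * noise_X, 1e-6),
                 P = pmax(P_obs * noise_P, 0), replicate = r)
    }))
    rownames(out) <- NULL
    out
  })
}

logistic_cdw <- function(t, gp) {
  gp$Xmax / (1 + ((gp$Xmax - gp$X0) / gp$X0) * exp(-gp$mu * t))
}

#' Specific product formation rate per sampling interval
#'
#' For each pair of consecutive sampling times the specific product formation
#' rate is the product increment normalized to the mean cell dry weight of the
#' interval endpoints and to the interval length:
#' `q_i = (P_i - P_{i-1}) / (((X_i + X_{i-1})/2) * (t_i - t_{i-1}))`,
#' in g(product) g(CDW)^-1 h^-1. Replicates, when present, are averaged per
#' time point before the rate is computed (set `per_replicate = TRUE` for
#' per-replicate rates).
#'
#' @param series data.frame with columns `t` (h, strictly increasing per
#'   replicate), `X` (CDW g/L, > 0), `P` (product g/L) and optionally
#'   `replicate`.
#' @param per_replicate compute rates separately per replicate instead of on
#'   the replicate-mean series.
#' @return data.frame (`t_start`, `t_end`, `q`) with one row per consecutive
#'   time interval (plus `replicate` if `per_replicate`).
#' @export
specific_product_formation <- function(series, per_replicate = FALSE) {
  stopifnot(all(c("t", "X", "P") %in% names(series)))
  if (per_replicate && !is.null(series$replicate)) {
    parts <- split(series, series$replicate)
    out <- do.call(rbind, lapply(names(parts), function(r) {
      cbind(q_intervals(parts[[r]]), replicate = r)
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (!is.null(series$replicate) && length(unique(series$replicate)) > 1) {
    agg <- stats::aggregate(series[c("X", "P")], by = list(t = series$t), mean)
    series <- agg[order(agg$t), ]
  }
  q_intervals(series)
}

q_intervals <- function(s) {
  s <- s[order(s$t), ]
  if (nrow(s) < 2) stopf("need at least two time points")
  if (any(diff(s$t) <= 0)) stopf("time points must be strictly increasing")
  mean_X <- (s$X[-1] + s$X[-nrow(s)]) / 2
  if (any(mean_X <= 0)) stopf("mean CDW is zero on an interval; rate undefined")
  data.frame(t_start = s$t[-nrow(s)], t_end = s$t[-1],
             q = diff(s$P) / (mean_X * diff(s$t)))
}

#' Label sampling times with growth phases
#'
#' Assigns each time point one of `lag`, `growth`, `transition`, `stationary`
#' using three ordered phase boundaries: `t <= lag_end` is lag,
#' `lag_end < t < growth_end` is growth, `growth_end <= t <= transition_end`
#' is transition, and later times are stationary. With the default boundaries
#' the canonical sampling grid 24.0, 47.8, 72.3, 96.5, 120.0, 144.3, 168.0 h
#' is labelled lag / growth x3 / transition x2 / stationary.
#'
#' @param t numeric sampling times (h), strictly increasing.
#' @param boundaries named numeric vector with `lag_end`, `growth_end`,
#'   `transition_end` (ordered increasing).
#' @return character vector of phase labels, one per time point.
#' @export
annotate_phases <- function(t, boundaries = c(lag_end = 24, growth_end = 120,
                                              transition_end = 144.3)) {
  if (is.unsorted(t, strictly = TRUE)) {
    stopf("time points must be strictly increasing")
  }
  b <- boundaries[c("lag_end", "growth_end", "transition_end")]
  if (anyNA(b) || is.unsorted(as.numeric(b))) {
    stopf("boundaries must supply ordered lag_end < growth_end < transition_end")
  }
  if (any(t < 0) || any(t > b["transition_end"] * 10)) {
    warnf("time points far outside the configured phase range; using nearest phase")
  }
  unname(ifelse(t <= b["lag_end"], "lag",
                ifelse(t < b["growth_end"], "growth",
                       ifelse(t <= b["transition_end"], "transition",
                              "stationary"))))
}
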