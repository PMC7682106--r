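# Independent oracles used across the suite. They re-derive expected values by
# direct enumeration / closed form, never by calling the code paths they check.

# Benjamini-Hochberg step-up by brute force: sort, scale by m/rank, enforce
# monotonicity from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Greedy Ward by exhaustive search: at every step evaluate the SSE increase of
# every possible pair merge directly and take the minimum. Returns the
# partition (assignment vector) for every k from n down to 1.
greedy_ward_oracle <- function(x) {
  n <- nrow(x)
  sse <- function(idx) {
    xm <- x[idx, , drop = FALSE]
    sum(sweep(xm, 2, colMeans(xm))^2)
  }
  clusters <- as.list(seq_len(n))
  assign_of <- function(cl) {
    a <- integer(n)
    for (i in seq_along(cl)) a[cl[[i]]] <- i
    a
  }
  parts <- vector("list", n)
  parts[[n]] <- assign_of(clusters)
  while (length(clusters) > 1) {
    best <- NULL
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- sse(c(clusters[[i]], clusters[[j]])) -
          sse(clusters[[i]]) - sse(clusters[[j]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    parts[[length(clusters)]] <- assign_of(clusters)
  }
  parts
}

# TRUE iff two assignment vectors describe the same partition (labels may
# differ).
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# gene-pair co-membership sets and their Jaccard index
co_membership_pairs <- function(groups) {
  unlist(lapply(groups, function(g) {
    g <- sort(g)
    if (length(g) < 2) return(character(0))
    apply(utils::combn(g, 2), 2, paste, collapse = "|")
  }))
}

pair_jaccard <- function(groups_a, groups_b) {
  pa <- co_membership_pairs(groups_a)
  pb <- co_membership_pairs(groups_b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# small default simulation shared by several tests (cached per session)
local_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, n_genes = 150)
      sim <- simulate_genome(cfg)
      cache <<- list(cfg = cfg, sim = sim,
                     tracks = simulate_tracks(sim, cfg),
                     expr = simulate_expression(sim$truth, cfg))
    }
    cache
  }
})
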