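# Independent brute-force reference implementations. These deliberately use
# a different code path from the package (stats::cor, plain loops, no shared
# helpers) so they can serve as oracles for the C++-backed search.

oracle_score <- function(x, y, metric) {
  if (metric == "euclidean") return(sqrt(sum((x - y)^2)))
  if (metric == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

oracle_better <- function(metric, a, b) {
  if (metric == "euclidean") a < b else a > b
}

oracle_window <- function(z, start, w, rev = FALSE) {
  v <- z[(start + 1):(start + w)]
  if (rev) rev(v) else v
}

# all placements of z against profile p; first-encountered wins ties
# (un-reversed before reversed, ascending start)
oracle_best_vs_profile <- function(p, z, w, metric, allow_rev = FALSE) {
  S <- length(z) - w
  best <- NULL
  for (rv in c(FALSE, TRUE)[seq_len(1 + allow_rev)]) {
    for (s in 0:(S - 1)) {
      sc <- oracle_score(oracle_window(z, s, w, rv), p, metric)
      if (is.null(best) || oracle_better(metric, sc, best$score)) {
        best <- list(start = s, rev = rv, score = sc)
      }
    }
  }
  best
}

oracle_best_pair <- function(a, b, w, metric, allow_rev = FALSE) {
  S <- length(a) - w
  sa <- S %/% 2
  hit <- oracle_best_vs_profile(oracle_window(a, sa, w), b, w, metric,
                                allow_rev)
  list(start_a = sa, start_b = hit$start, reversed_b = hit$rev,
       score = hit$score)
}

# global best pair over all unordered (i, j), anchor i centered
oracle_global_best_pair <- function(Z, w, metric, allow_rev = FALSE) {
  n <- nrow(Z)
  best <- NULL
  n_cand <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      hit <- oracle_best_pair(Z[i, ], Z[j, ], w, metric, allow_rev)
      n_cand <- n_cand + (ncol(Z) - w) * (1 + allow_rev)
      if (is.null(best) || oracle_better(metric, hit$score, best$score)) {
        best <- c(list(i = i, j = j), hit)
      }
    }
  }
  best$n_candidates <- n_cand
  best
}

# straight-line progressive greedy alignment from a seed placement
oracle_greedy <- function(Z, i, j, w, metric, allow_rev = FALSE,
                          seed = NULL) {
  n <- nrow(Z)
  if (is.null(seed)) seed <- oracle_best_pair(Z[i, ], Z[j, ], w, metric,
                                              allow_rev)
  start <- rep(NA_integer_, n)
  revd <- rep(FALSE, n)
  start[i] <- seed$start_a
  start[j] <- seed$start_b
  revd[j] <- isTRUE(seed$reversed_b)
  P <- (oracle_window(Z[i, ], start[i], w, revd[i]) +
          oracle_window(Z[j, ], start[j], w, revd[j])) / 2
  order <- c(i, j)
  remaining <- setdiff(1:n, c(i, j))
  while (length(remaining) > 0) {
    best <- NULL
    for (r in remaining) {
      hit <- oracle_best_vs_profile(P, Z[r, ], w, metric, allow_rev)
      if (is.null(best) || oracle_better(metric, hit$score, best$score)) {
        best <- c(list(region = r), hit)
      }
    }
    r <- best$region
    start[r] <- best$start
    revd[r] <- best$rev
    k <- length(order) + 1
    P <- (P * (k - 1) + oracle_window(Z[r, ], best$start, w, best$rev)) / k
    order <- c(order, r)
    remaining <- setdiff(remaining, r)
  }
  list(start = start, rev = revd, order = order, consensus = P)
}

oracle_quality <- function(W, metric) {
  n <- nrow(W)
  tot <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    tot <- tot + oracle_score(W[a, ], W[b, ], metric)
  }
  tot / (n * (n - 1) / 2)
}

oracle_windows <- function(Z, start, rev, w) {
  t(sapply(seq_len(nrow(Z)), function(r) {
    oracle_window(Z[r, ], start[r], w, rev[r])
  }))
}

# full seed-sampling procedure: one forced-seed alignment per region, keep
# the best quality (ties to the lowest seed index)
oracle_seed_sampling <- function(Z, w, metric, allow_rev = FALSE) {
  n <- nrow(Z)
  best <- NULL
  qualities <- numeric(n)
  for (i in 1:n) {
    part <- NULL
    for (j in setdiff(1:n, i)) {
      hit <- oracle_best_pair(Z[i, ], Z[j, ], w, metric, allow_rev)
      if (is.null(part) || oracle_better(metric, hit$score, part$score)) {
        part <- c(list(j = j), hit)
      }
    }
    al <- oracle_greedy(Z, i, part$j, w, metric, allow_rev, seed = part)
    q <- oracle_quality(oracle_windows(Z, al$start, al$rev, w), metric)
    qualities[i] <- q
    if (is.null(best) || oracle_better(metric, q, best$quality)) {
      best <- c(al, list(quality = q, seed = c(i, part$j)))
    }
  }
  c(best, list(qualities = qualities))
}

# per-base tag-extension coverage by direct accumulation
oracle_coverage <- function(tags, ext, genome_sizes) {
  out <- lapply(genome_sizes, function(L) numeric(L))
  for (t in seq_len(nrow(tags))) {
    L <- genome_sizes[[tags$chrom[t]]]
    bases <- if (tags$strand[t] == "+") {
      tags$start[t] + 0:(ext - 1)
    } else {
      (tags$end[t] - 1) - 0:(ext - 1)
    }
    bases <- bases[bases >= 0 & bases < L]
    for (b in bases) out[[tags$chrom[t]]][b + 1] <-
        out[[tags$chrom[t]]][b + 1] + 1
  }
  out
}
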