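new_alignment <- function(rm, res, frame_bins, metric, allow_reversal,
                          seed, seed_score, quality = NA_real_,
                          n_seed_candidates = NA_real_) {
  structure(list(
    region_id = rownames(rm$signal),
    start_bin = as.integer(res$start),
    reversed = as.logical(res$rev),
    score = as.numeric(res$score),
    order = as.integer(res$order),
    consensus = as.numeric(res$consensus),
    frame_bins = as.integer(frame_bins),
    n_bins = ncol(rm$signal),
    bin_size = rm$bin_size,
    metric = metric,
    allow_reversal = allow_reversal,
    seed = as.integer(seed),
    seed_score = seed_score,
    quality = quality,
    n_seed_candidates = n_seed_candidates), class = "chrom_alignment")
}

#' @export
print.chrom_alignment <- function(x, ...) {
  cat(sprintf(paste0(
    "<chrom_alignment> %d regions, frame %d bins (%d bp), metric %s%s\n",
    "  seed regions: %d, %d (seed score %.4f)\n",
    "  quality: %s\n"),
    length(x$start_bin), x$frame_bins, x$frame_bins * x$bin_size, x$metric,
    if (x$allow_reversal) ", reversals enabled" else "",
    x$seed[1], x$seed[2], x$seed_score,
    if (is.na(x$quality)) "unset" else sprintf("%.4f", x$quality)))
  invisible(x)
}

check_alignable <- function(rm, frame_bins) {
  assert_that(inherits(rm, "region_matrix"), "need a region_matrix")
  assert_that(nrow(rm$signal) >= 2, "alignment needs at least 2 regions")
  frame_starts(ncol(rm$signal), frame_bins)
}

#' Progressive greedy alignment from a chosen seed
#'
#' The consensus is initialized as the mean of the two orientation-resolved
#' seed windows; then, repeatedly, the single (region, placement) pair with
#' the best score against the running consensus `P` is committed and folded
#' in by the running mean `P <- (P * (i - 1) + window) / i`, where `i` is
#' the number of committed regions, until all regions are placed. The final
#' consensus therefore equals the unweighted mean of all aligned windows.
#'
#' @param rm A `region_matrix`.
#' @param seed Either a length-2 vector of region indices (their mutual
#'   best window placement is computed with the first as anchor), or a list
#'   with `i`, `j`, `start_i`, `start_j`, `reversed_j` (and optionally
#'   `score`) giving explicit seed placements.
#' @param frame_bins Alignment frame length in bins.
#' @inheritParams best_window_pair
#' @return A `chrom_alignment` with per-region `start_bin` (0-based),
#'   `reversed`, greedy `score`, commit `order`, `consensus`, and `quality`
#'   (mean pairwise score of the aligned windows).
#' @export
chosen_seed_alignment <- function(rm, seed, frame_bins, metric = "pearson",
                                  allow_reversal = FALSE) {
  check_alignable(rm, frame_bins)
  n <- nrow(rm$signal)
  zt <- t(rm$signal)
  code <- metric_code(metric)
  if (!is.list(seed)) {
    assert_that(length(seed) == 2 && all(seed %in% seq_len(n)) &&
                  seed[1] != seed[2],
                "seed must name two distinct region indices")
    hit <- cpp_best_pair(zt, as.integer(seed[1]), as.integer(seed[2]),
                         as.integer(frame_bins), code,
                         isTRUE(allow_reversal))
    seed <- list(i = seed[1], j = seed[2], start_i = hit$anchor_start,
                 start_j = hit$start, reversed_j = hit$rev,
                 score = hit$score)
  }
  res <- cpp_greedy_from_seed(zt, as.integer(seed$i), as.integer(seed$j),
                              as.integer(seed$start_i),
                              as.integer(seed$start_j),
                              isTRUE(seed$reversed_i %||% FALSE),
                              isTRUE(seed$reversed_j),
                              as.numeric(seed$score %||% NA_real_),
                              as.integer(frame_bins), code,
                              isTRUE(allow_reversal))
  a <- new_alignment(rm, res, frame_bins, metric, allow_reversal,
                     seed = c(seed$i, seed$j),
                     seed_score = seed$score %||% NA_real_)
  a$quality <- quality_assessment(a, rm)
  a
}

global_best_pair <- function(rm, frame_bins, metric, allow_reversal) {
  n <- nrow(rm$signal)
  zt <- t(rm$signal)
  code <- metric_code(metric)
  best <- NULL
  n_cand <- 0
  for (i in seq_len(n - 1)) {
    hit <- cpp_best_pair(zt, i, (i + 1):n, as.integer(frame_bins), code,
                         isTRUE(allow_reversal))
    n_cand <- n_cand + hit$n_candidates
    if (is.null(best) || better_score(metric, hit$score, best$score)) {
      best <- list(i = i, j = hit$region, start_i = hit$anchor_start,
                   start_j = hit$start, reversed_j = hit$rev,
                   score = hit$score)
    }
  }
  best$n_candidates <- n_cand
  best
}

#' Single-best-pair alignment
#'
#' Finds the globally most similar region pair over all unordered pairs
#' (anchor-and-slide: `S` candidate placements per pair, `2S` with
#' reversal) and uses it to seed the progressive greedy alignment.
#'
#' @inheritParams chosen_seed_alignment
#' @return A `chrom_alignment`; `n_seed_candidates` records how many
#'   candidate pairs were enumerated.
#' @export
single_best_pair_alignment <- function(rm, frame_bins, metric = "pearson",
                                       allow_reversal = FALSE) {
  check_alignable(rm, frame_bins)
  seed <- global_best_pair(rm, frame_bins, metric, allow_reversal)
  a <- chosen_seed_alignment(rm, seed, frame_bins, metric, allow_reversal)
  a$n_seed_candidates <- seed$n_candidates
  a
}

#' Seed-sampling alignment
#'
#' Every region is tried as a seed: for region `i`, its best partner `j`
#' (over all placements, `j != i`) forms a forced seed, and a full
#' chosen-seed alignment is built. The alignment with the best
#' post-alignment quality is returned (ties break to the lowest seed
#' index), together with all `n` quality values.
#'
#' @inheritParams chosen_seed_alignment
#' @param verbose Report progress (one line per seed) to stderr?
#' @return List with `alignment` (a `chrom_alignment`) and `qualities`
#'   (numeric vector of the `n` seed qualities, in region order).
#' @export
seed_sampling_alignment <- function(rm, frame_bins, metric = "pearson",
                                    allow_reversal = FALSE,
                                    verbose = FALSE) {
  check_alignable(rm, frame_bins)
  n <- nrow(rm$signal)
  zt <- t(rm$signal)
  code <- metric_code(metric)
  qualities <- numeric(n)
  best <- NULL
  for (i in seq_len(n)) {
    hit <- cpp_best_pair(zt, i, setdiff(seq_len(n), i),
                         as.integer(frame_bins), code,
                         isTRUE(allow_reversal))
    seed <- list(i = i, j = hit$region, start_i = hit$anchor_start,
                 start_j = hit$start, reversed_j = hit$rev,
                 score = hit$score)
    res <- cpp_greedy_from_seed(zt, seed$i, seed$j, seed$start_i,
                                seed$start_j, FALSE, seed$reversed_j,
                                seed$score, as.integer(frame_bins), code,
                                isTRUE(allow_reversal))
    a <- new_alignment(rm, res, frame_bins, metric, allow_reversal,
                       seed = c(seed$i, seed$j), seed_score = seed$score)
    qualities[i] <- a$quality <- quality_assessment(a, rm)
    if (is.null(best) ||
          better_score(metric, qualities[i], best$quality)) {
      best <- a
    }
    if (verbose) {
      message(sprintf("seed %d/%d: partner %d, quality %.5f", i, n,
                      seed$j, qualities[i]))
    }
  }
  list(alignment = best, qualities = qualities)
}

#' Orientation-resolved aligned windows
#'
#' @param a A `chrom_alignment`.
#' @param rm The `region_matrix` it was built from.
#' @return Numeric matrix, regions x `frame_bins`; reversed regions appear
#'   in reversed bin order, so rows are directly comparable.
#' @export
aligned_windows <- function(a, rm) {
  assert_that(inherits(a, "chrom_alignment"), "need a chrom_alignment")
  assert_that(identical(rownames(rm$signal), a$region_id),
              "alignment does not match this region_matrix")
  t(cpp_aligned_windows(t(rm$signal), a$start_bin, a$reversed,
                        a$frame_bins))
}

#' Post-alignment quality assessment
#'
#' The mean pairwise score over all `choose(n, 2)` unordered pairs of
#' aligned, orientation-resolved windows (denominator `n * (n - 1) / 2`).
#' Under the Euclidean metric lower is better, and alignment selection uses
#' the metric's orientation.
#'
#' @inheritParams aligned_windows
#' @param metric Metric for the pairwise scores; defaults to the metric the
#'   alignment was built with.
#' @return A single numeric quality.
#' @export
quality_assessment <- function(a, rm, metric = a$metric) {
  w <- aligned_windows(a, rm)
  assert_that(nrow(w) >= 2, "quality needs at least 2 regions")
  cpp_quality(t(w), metric_code(metric))
}

#' Write alignment results as TSV
#'
#' One row per region: id, chromosome, genomic start/end of the aligned
#' frame (when the matrix carries coordinates; otherwise the bp offset
#' within the region), orientation, commit order and the greedy score at
#' commit time.
#'
#' @inheritParams aligned_windows
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(a, rm, path) {
  assert_that(inherits(a, "chrom_alignment"), "need a chrom_alignment")
  off_bp <- a$start_bin * a$bin_size
  has_coords <- !all(is.na(rm$regions$start))
  fs <- if (has_coords) rm$regions$start + off_bp else off_bp
  df <- data.frame(
    region_id = a$region_id,
    chrom = rm$regions$chrom,
    aligned_frame_start = fs,
    aligned_frame_end = fs + a$frame_bins * a$bin_size,
    orientation = ifelse(a$reversed, "-", "+"),
    commit_order = match(seq_along(a$region_id), a$order),
    score = a$score,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the consensus profile as two-column TSV (bin offset bp, value)
#'
#' @param a A `chrom_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_tsv <- function(a, path) {
  assert_that(inherits(a, "chrom_alignment"), "need a chrom_alignment")
  df <- data.frame(
    bin_offset_bp = (seq_along(a$consensus) - 1L) * a$bin_size,
    value = a$consensus)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
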