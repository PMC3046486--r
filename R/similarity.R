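METRICS <- c("pearson", "spearman", "euclidean")

metric_code <- function(metric) {
  metric <- match.arg(metric, METRICS)
  match(metric, METRICS) - 1L
}

#' Compare two scores under a metric's orientation
#'
#' Correlation metrics are "higher is more similar"; Euclidean distance is
#' "lower is more similar". All arg-max language in the package means
#' arg-best under this predicate.
#'
#' @param metric `"pearson"`, `"spearman"` or `"euclidean"`.
#' @param a,b Scores.
#' @return `TRUE` when `a` is strictly better than `b`.
#' @export
better_score <- function(metric, a, b) {
  if (match.arg(metric, METRICS) == "euclidean") a < b else a > b
}

#' Score two equal-length signal windows
#'
#' Pearson is the sample correlation; Spearman is Pearson on mid-ranks
#' (average ranks for ties); Euclidean is the root of the summed squared
#' differences. A window with zero variance under a correlation metric
#' yields the defined degenerate score 0 (uninformative), with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @inheritParams better_score
#' @return A single numeric score.
#' @export
profile_score <- function(x, y, metric = "pearson") {
  code <- metric_code(metric)
  assert_that(length(x) == length(y), "x and y must have the same length")
  assert_that(length(x) >= 2, "windows must have length >= 2")
  if (code != 2L && (var(x) == 0 || var(y) == 0)) {
    warning("constant window under a correlation metric; score set to 0",
            call. = FALSE)
    return(0)
  }
  cpp_score(as.numeric(x), as.numeric(y), code)
}

#' Extract an (optionally reversed) window from a profile
#'
#' @param profile Numeric vector of bin values.
#' @param start_bin 0-based offset of the window within the profile.
#' @param frame_bins Window length in bins.
#' @param reversed Read the window in reversed bin order?
#' @return Numeric vector of length `frame_bins`.
#' @export
extract_window <- function(profile, start_bin, frame_bins,
                           reversed = FALSE) {
  assert_that(is_count(frame_bins), "frame_bins must be >= 1")
  assert_that(length(start_bin) == 1 && start_bin == round(start_bin) &&
                start_bin >= 0 &&
                start_bin + frame_bins <= length(profile),
              "window placement out of range")
  w <- profile[(start_bin + 1):(start_bin + frame_bins)]
  if (reversed) rev(w) else w
}

frame_starts <- function(m, frame_bins) {
  s <- m - frame_bins
  assert_that(s > 0, "frame_bins must be smaller than the region length")
  s
}

#' Best mutual window placement between two region profiles
#'
#' Anchor-and-slide search: `a`'s frame is fixed at the centered placement
#' (`start_bin = S %/% 2` with `S = m - frame_bins` start positions), and
#' `b`'s frame is evaluated at every start in `[0, S)`, un-reversed and
#' (when `allow_reversal`) reversed: exactly `S` candidates without
#' reversal, `2S` with. Ties break to the first-enumerated candidate
#' (un-reversed before reversed, ascending start).
#'
#' @param a,b Numeric profiles of equal length.
#' @param frame_bins Alignment frame length in bins (< profile length).
#' @inheritParams better_score
#' @param allow_reversal Also evaluate reversed placements of `b`?
#' @return List with `start_a`, `start_b` (0-based), `reversed_b`, `score`,
#'   `n_candidates`.
#' @export
best_window_pair <- function(a, b, frame_bins, metric = "pearson",
                             allow_reversal = FALSE) {
  assert_that(length(a) == length(b), "profiles must have equal length")
  frame_starts(length(a), frame_bins)
  hit <- cpp_best_pair(cbind(as.numeric(a), as.numeric(b)), 1L, 2L,
                       as.integer(frame_bins), metric_code(metric),
                       isTRUE(allow_reversal))
  list(start_a = hit$anchor_start, start_b = hit$start,
       reversed_b = hit$rev, score = hit$score,
       n_candidates = hit$n_candidates)
}

#' Best window placement of a region against a consensus profile
#'
#' Evaluates the region's frame at every start in `[0, S)` (and reversed
#' copies when allowed) against the fixed consensus `p` and returns the
#' arg-best placement.
#'
#' @param p Consensus vector of length `frame_bins`.
#' @param z Region profile (length > `frame_bins`).
#' @inheritParams best_window_pair
#' @return List with `start_bin`, `reversed`, `score`, `n_candidates`.
#' @export
best_window_vs_profile <- function(p, z, frame_bins, metric = "pearson",
                                   allow_reversal = FALSE) {
  assert_that(length(p) == frame_bins,
              "consensus length must equal frame_bins")
  frame_starts(length(z), frame_bins)
  hit <- cpp_best_vs_profile(matrix(as.numeric(z), ncol = 1),
                             as.numeric(p), 1L, as.integer(frame_bins),
                             metric_code(metric), isTRUE(allow_reversal))
  list(start_bin = hit$start, reversed = hit$rev, score = hit$score,
       n_candidates = hit$n_candidates)
}

#' Number of candidate comparisons in the pairwise seed search
#'
#' With `n` regions of `region_bins` bins and a frame of `frame_bins` bins
#' there are `S = region_bins - frame_bins` start positions for the sliding
#' region of each unordered pair, doubled when reversals are enabled:
#' `choose(n, 2) * S * (2 if allow_reversal else 1)`.
#'
#' @param n Number of regions (>= 2).
#' @param region_bins Region length in bins.
#' @param frame_bins Frame length in bins (< `region_bins`).
#' @param allow_reversal Are reversed placements enumerated?
#' @return The candidate count (numeric scalar).
#' @export
count_candidate_pairs <- function(n, region_bins, frame_bins,
                                  allow_reversal = FALSE) {
  assert_that(is_count(n, min = 2), "need n >= 2 regions")
  assert_that(is_count(region_bins) && is_count(frame_bins) &&
                frame_bins < region_bins,
              "need 1 <= frame_bins < region_bins")
  choose(n, 2) * (region_bins - frame_bins) *
    (if (isTRUE(allow_reversal)) 2 else 1)
}
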