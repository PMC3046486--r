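#' Randomize region coordinates
#'
#' Shifts each region by an offset drawn uniformly from the integers
#' `[-max_shift, +max_shift]` (0 included), recording the drawn offsets —
#' the ground truth a subsequent alignment must recover.
#'
#' @param regions data.frame with `id`, `chrom`, `start`, `end`.
#' @param max_shift Maximum shift in bp (> 0).
#' @param seed Optional integer seed (the caller's RNG state is preserved);
#'   `NULL` draws from the current RNG state.
#' @return List with `regions` (shifted) and `offsets` (bp, per region).
#' @export
randomize_coordinates <- function(regions, max_shift, seed = NULL) {
  assert_that(is_count(max_shift), "max_shift must be a positive integer")
  n <- nrow(regions)
  delta <- with_seed(seed,
                     sample.int(2L * max_shift + 1L, n, replace = TRUE) -
                       (max_shift + 1L))
  shifted <- regions
  shifted$start <- regions$start + delta
  shifted$end <- regions$end + delta
  list(regions = shifted, offsets = delta)
}

# Mode of integer residuals; ties break to the smaller absolute offset
# (then to the smaller signed value).
mode_offset <- function(x) {
  tb <- table(x)
  cand <- as.integer(names(tb)[tb == max(tb)])
  cand[order(abs(cand), cand)][1]
}

# Residual of each region's placement against truth, in bp. The alignment
# frame is coordinate-free, so residuals are meaningful only up to a global
# constant (and the formula accounts for planted orientation: a region
# whose content was mirrored maps its start through S - start).
placement_residuals <- function(a, true_offsets_bp, true_reversed = NULL) {
  s <- a$n_bins - a$frame_bins
  eff <- a$start_bin
  if (!is.null(true_reversed)) {
    eff <- ifelse(true_reversed, s - a$start_bin, a$start_bin)
  }
  eff * a$bin_size + true_offsets_bp
}

#' Alignment accuracy against known true offsets
#'
#' A region counts as accurately aligned when its placement residual,
#' after removing the single global registration offset (the mode of the
#' residuals in bin units; the alignment frame is coordinate-free, so only
#' relative placement is meaningful), is within `threshold` bp of zero.
#' Accuracy is invariant to the alignment's arbitrary global offset and to
#' a global orientation flip.
#'
#' @param a A `chrom_alignment`.
#' @param true_offsets_bp Per-region true shifts in bp (the offsets the
#'   randomization or the synthetic generator applied), in region order.
#' @param threshold Accuracy threshold in bp (default 40).
#' @param true_reversed Optional logical vector of planted orientations
#'   (needed when the generator mirrored regions).
#' @param register `"mode"` (default) removes the global registration
#'   offset before thresholding; `"none"` compares raw residuals to zero.
#' @return Percentage (0-100) of accurately placed regions.
#' @export
alignment_accuracy <- function(a, true_offsets_bp, threshold = 40,
                               true_reversed = NULL,
                               register = c("mode", "none")) {
  register <- match.arg(register)
  assert_that(inherits(a, "chrom_alignment"), "need a chrom_alignment")
  assert_that(length(true_offsets_bp) == length(a$start_bin),
              "true_offsets_bp must cover the aligned regions")
  resid <- placement_residuals(a, true_offsets_bp, true_reversed)
  if (register == "mode") {
    off <- mode_offset(round(resid / a$bin_size)) * a$bin_size
    resid <- resid - off
  }
  100 * mean(abs(resid) <= threshold)
}

#' Per-region placement errors in bp (after global registration)
#'
#' @inheritParams alignment_accuracy
#' @return Numeric vector of signed errors in bp.
#' @export
placement_errors <- function(a, true_offsets_bp, true_reversed = NULL) {
  resid <- placement_residuals(a, true_offsets_bp, true_reversed)
  resid - mode_offset(round(resid / a$bin_size)) * a$bin_size
}

#' Orientation agreement with planted truth
#'
#' The global orientation of an alignment is arbitrary (flipping every
#' region gives an equivalent alignment), so agreement is reported up to a
#' global flip.
#'
#' @inheritParams alignment_accuracy
#' @param true_reversed Logical vector of planted orientations.
#' @return Percentage (50-100) of regions whose recovered orientation
#'   matches the planted one, maximized over the global flip.
#' @export
orientation_agreement <- function(a, true_reversed) {
  assert_that(length(true_reversed) == length(a$reversed),
              "true_reversed must cover the aligned regions")
  f <- mean(a$reversed == true_reversed)
  100 * max(f, 1 - f)
}

#' Alignment variability
#'
#' For each region, the root of the summed squared deviations of its
#' aligned window from the consensus profile; variability of the whole
#' alignment is the mean of these per-region values.
#'
#' @inheritParams aligned_windows
#' @return A single non-negative numeric.
#' @export
alignment_variability <- function(a, rm) {
  w <- aligned_windows(a, rm)
  assert_that(nrow(w) >= 1, "variability needs at least 1 region")
  mean(sqrt(rowSums(sweep(w, 2, a$consensus)^2)))
}

#' Coordinate-randomization validation
#'
#' For every cell of a `max_shifts x replicates` grid, region coordinates
#' are randomized, profiles are re-extracted at the randomized positions,
#' the alignment strategy is run, and accuracy (within `threshold` bp of
#' truth, after global registration) and variability are recorded. This is
#' the table behind accuracy/variability-versus-randomization curves.
#'
#' @param track A genome-scale `signal_track`.
#' @param regions Truth regions data.frame (`id`, `chrom`, `start`, `end`),
#'   all the same length.
#' @param max_shifts Vector of maximum randomization distances in bp.
#' @param replicates Randomized datasets per `max_shift`.
#' @param strategy `"seed_sampling"` or `"single_best_pair"`.
#' @param frame_bp Alignment frame in bp (multiple of `bin_size`).
#' @param bin_size Extraction resolution in bp.
#' @inheritParams best_window_pair
#' @param threshold Accuracy threshold in bp.
#' @param seed Master seed; every cell derives its own sub-seed from it.
#' @param verbose Report one line per cell to stderr?
#' @return data.frame with columns `max_shift`, `replicate`, `accuracy_pct`,
#'   `variability`, `n_regions`, `seed`.
#' @export
run_validation <- function(track, regions,
                           max_shifts = seq(50, 250, by = 25),
                           replicates = 10,
                           strategy = c("seed_sampling",
                                        "single_best_pair"),
                           frame_bp, bin_size = 10, metric = "pearson",
                           allow_reversal = FALSE, threshold = 40,
                           seed = 1L, verbose = FALSE) {
  strategy <- match.arg(strategy)
  assert_that(all(max_shifts > 0) && is_count(replicates),
              "invalid randomization grid")
  assert_that(is_count(frame_bp) && frame_bp %% bin_size == 0,
              "frame_bp must be a positive multiple of bin_size")
  frame_bins <- as.integer(frame_bp / bin_size)
  grid <- expand.grid(replicate = seq_len(replicates),
                      max_shift = max_shifts)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    ms <- grid$max_shift[k]
    rnd <- randomize_coordinates(regions, ms, seed = seeds[k])
    rm <- extract_region_matrix(track, rnd$regions, bin_size)
    kept <- match(rm$regions$id, rnd$regions$id)
    a <- switch(strategy,
                seed_sampling = seed_sampling_alignment(
                  rm, frame_bins, metric, allow_reversal)$alignment,
                single_best_pair = single_best_pair_alignment(
                  rm, frame_bins, metric, allow_reversal))
    acc <- alignment_accuracy(a, rnd$offsets[kept], threshold = threshold)
    vr <- alignment_variability(a, rm)
    rows[[k]] <- data.frame(max_shift = ms, replicate = grid$replicate[k],
                            accuracy_pct = acc, variability = vr,
                            n_regions = nrow(rm$signal), seed = seeds[k])
    if (verbose) {
      message(sprintf("max_shift %d, replicate %d: accuracy %.1f%%, %s",
                      ms, grid$replicate[k], acc,
                      sprintf("variability %.3f", vr)))
    }
  }
  do.call(rbind, rows)
}

#' Summarize a validation table
#'
#' @param tbl Output of [run_validation()].
#' @return data.frame with mean and standard error of accuracy and
#'   variability per `max_shift`.
#' @export
summarize_validation <- function(tbl) {
  se <- function(x) sd(x) / sqrt(length(x))
  agg <- aggregate(cbind(accuracy_pct, variability) ~ max_shift, tbl, mean)
  ses <- aggregate(cbind(accuracy_pct, variability) ~ max_shift, tbl, se)
  data.frame(max_shift = agg$max_shift,
             accuracy_mean = agg$accuracy_pct,
             accuracy_se = ses$accuracy_pct,
             variability_mean = agg$variability,
             variability_se = ses$variability)
}
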