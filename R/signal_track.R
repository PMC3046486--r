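#' Construct a signal track
#'
#' A `signal_track` holds one numeric vector per chromosome at a fixed
#' resolution: element `i` of a chromosome's vector is the value over bases
#' `[(i-1)*resolution, i*resolution)` (0-based, half-open coordinates are
#' used throughout the package). `NA` marks missing data and is distinct
#' from a value of 0.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param resolution Base pairs per stored value (>= 1).
#' @param kind `"coverage"` for raw tag coverage, `"log2"` for log2
#'   occupancy ratios.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, resolution = 1L,
                         kind = c("coverage", "log2")) {
  kind <- match.arg(kind)
  assert_that(is.list(values) && length(values) > 0 &&
                !is.null(names(values)) && all(nzchar(names(values))),
              "values must be a non-empty named list of numeric vectors")
  assert_that(all(vapply(values, is.numeric, logical(1))),
              "track values must be numeric")
  assert_that(is_count(resolution), "resolution must be a positive integer")
  structure(list(values = values, resolution = as.integer(resolution),
                 kind = kind),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s, resolution %d bp, %d chromosome(s)\n",
              x$kind, x$resolution, length(x$values)))
  for (ch in names(x$values)) {
    v <- x$values[[ch]]
    cat(sprintf("  %s: %d values (%d bp), %d missing\n", ch, length(v),
                length(v) * x$resolution, sum(is.na(v))))
  }
  invisible(x)
}

#' Tag-extension coverage
#'
#' Converts mapped sequencing tags to a per-base coverage track. Each tag is
#' extended from its 5' end in the direction of its strand to
#' `extension_len` bases (the expected fragment length), clipped at
#' chromosome ends, and contributes 1 to every base it covers.
#'
#' @param tags data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand` (`"+"` or `"-"`).
#' @param extension_len Fragment extension length in bp (> 0).
#' @param genome_sizes Named numeric vector, chromosome -> length in bp.
#' @return A `signal_track` of kind `"coverage"` at 1-bp resolution.
#' @export
tag_extension_coverage <- function(tags, extension_len, genome_sizes) {
  assert_that(is.data.frame(tags) &&
                all(c("chrom", "start", "end", "strand") %in% names(tags)),
              "tags must have columns chrom, start, end, strand")
  assert_that(is_count(extension_len), "extension_len must be > 0")
  assert_that(!is.null(names(genome_sizes)),
              "genome_sizes must be a named vector")
  bad_chrom <- setdiff(unique(tags$chrom), names(genome_sizes))
  if (length(bad_chrom) > 0) {
    stop("unknown chromosome(s): ", paste(bad_chrom, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tags$strand %in% c("+", "-"))) {
    stop("every tag needs strand '+' or '-'", call. = FALSE)
  }
  sizes <- genome_sizes[tags$chrom]
  assert_that(all(tags$start >= 0) && all(tags$end <= sizes) &&
                all(tags$end > tags$start),
              "every tag must lie within its chromosome bounds")

  # extended interval [from, to) per tag, anchored at the 5' end
  from <- ifelse(tags$strand == "+", tags$start, tags$end - extension_len)
  to <- ifelse(tags$strand == "+", tags$start + extension_len, tags$end)
  from <- pmax(from, 0)
  to <- pmin(to, sizes)

  values <- lapply(names(genome_sizes), function(ch) {
    L <- as.integer(genome_sizes[[ch]])
    d <- numeric(L + 1L)
    sel <- tags$chrom == ch & to > from
    if (any(sel)) {
      add <- tapply(rep(1, sum(sel)), from[sel], sum)
      sub <- tapply(rep(1, sum(sel)), to[sel], sum)
      d[as.integer(names(add)) + 1L] <- d[as.integer(names(add)) + 1L] + add
      d[as.integer(names(sub)) + 1L] <- d[as.integer(names(sub)) + 1L] - sub
    }
    cumsum(d)[seq_len(L)]
  })
  names(values) <- names(genome_sizes)
  signal_track(values, resolution = 1L, kind = "coverage")
}

#' Log2 occupancy from coverage
#'
#' Transforms a raw coverage track into a log2 ratio of coverage at each
#' position to the average coverage per position across the genome (the mean
#' is taken over all positions with defined coverage). A pseudocount is
#' added to numerator and denominator so positions with zero coverage stay
#' finite.
#'
#' @param coverage A `signal_track` of kind `"coverage"`.
#' @param pseudocount Non-negative pseudocount, default 0.25 tags.
#' @return A `signal_track` of kind `"log2"`.
#' @export
log2_occupancy <- function(coverage, pseudocount = 0.25) {
  assert_that(inherits(coverage, "signal_track"), "need a signal_track")
  assert_that(coverage$kind == "coverage",
              "log2_occupancy needs a raw coverage track")
  assert_that(length(pseudocount) == 1 && pseudocount >= 0,
              "pseudocount must be a single non-negative number")
  all_vals <- unlist(coverage$values, use.names = FALSE)
  mean_cov <- mean(all_vals, na.rm = TRUE)
  if (!is.finite(mean_cov) || mean_cov <= 0) {
    stop("genome-wide mean coverage must be positive", call. = FALSE)
  }
  values <- lapply(coverage$values, function(v) {
    log2((v + pseudocount) / (mean_cov + pseudocount))
  })
  signal_track(values, resolution = coverage$resolution, kind = "log2")
}

#' Construct a region matrix
#'
#' A `region_matrix` holds one binned signal profile per region: a numeric
#' matrix with one row per region (row names are region ids) and one column
#' per bin, plus the bin size and the region table.
#'
#' @param signal Numeric matrix, regions x bins, with row names.
#' @param bin_size Bin width in bp.
#' @param regions Optional data.frame with columns `id`, `chrom`, `start`,
#'   `end` matching the matrix rows.
#' @param dropped Optional data.frame of regions excluded by gap filtering.
#' @return An object of class `region_matrix`.
#' @export
region_matrix <- function(signal, bin_size, regions = NULL, dropped = NULL) {
  assert_that(is.matrix(signal) && is.numeric(signal),
              "signal must be a numeric matrix")
  assert_that(!is.null(rownames(signal)) &&
                !anyDuplicated(rownames(signal)),
              "signal must have unique row names (region ids)")
  assert_that(is_count(bin_size), "bin_size must be a positive integer")
  if (is.null(regions)) {
    regions <- data.frame(id = rownames(signal), chrom = NA_character_,
                          start = NA_real_, end = NA_real_,
                          stringsAsFactors = FALSE)
  }
  assert_that(nrow(regions) == nrow(signal) &&
                identical(regions$id, rownames(signal)),
              "regions table must match matrix rows")
  structure(list(signal = signal, bin_size = as.integer(bin_size),
                 regions = regions,
                 dropped = dropped %||%
                   regions[0, , drop = FALSE]),
            class = "region_matrix")
}

#' @export
print.region_matrix <- function(x, ...) {
  cat(sprintf(
    "<region_matrix> %d regions x %d bins (%d bp at %d bp/bin), %d dropped\n",
    nrow(x$signal), ncol(x$signal), ncol(x$signal) * x$bin_size,
    x$bin_size, nrow(x$dropped)))
  invisible(x)
}

#' @export
dim.region_matrix <- function(x) dim(x$signal)

#' Extract a binned region x bin matrix from a signal track
#'
#' Each region is cut into consecutive bins of `bin_size` bp; a bin's value
#' is the arithmetic mean of the track values covering it. Regions
#' containing any missing base (a gap in the track, or bases outside the
#' stored track) are excluded and reported in the `dropped` component, so
#' the retained matrix has no missing bins.
#'
#' @param track A `signal_track`.
#' @param regions data.frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open); all regions must have the same length, divisible
#'   by `bin_size`.
#' @param bin_size Bin width in bp; must be a multiple of the track
#'   resolution.
#' @return A `region_matrix`; excluded regions are in its `dropped` field.
#' @export
extract_region_matrix <- function(track, regions, bin_size = 10L) {
  assert_that(inherits(track, "signal_track"), "need a signal_track")
  assert_that(is.data.frame(regions) &&
                all(c("id", "chrom", "start", "end") %in% names(regions)),
              "regions must have columns id, chrom, start, end")
  assert_that(!anyDuplicated(regions$id), "region ids must be unique")
  assert_that(all(regions$end > regions$start), "regions need end > start")
  len <- unique(regions$end - regions$start)
  assert_that(length(len) == 1, "all regions must have the same length")
  assert_that(is_count(bin_size) && len %% bin_size == 0,
              "region length must be divisible by bin_size")
  res <- track$resolution
  assert_that(bin_size %% res == 0,
              "bin_size must be a multiple of the track resolution")
  if (res > 1) {
    assert_that(all(regions$start %% res == 0),
                "region starts must align to the track resolution")
  }
  m <- as.integer(len / bin_size)
  per_bin <- as.integer(bin_size / res)

  rows <- vector("list", nrow(regions))
  keep <- logical(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    ch <- regions$chrom[r]
    v <- track$values[[ch]]
    if (is.null(v)) {
      keep[r] <- FALSE
      next
    }
    i0 <- regions$start[r] / res
    idx <- (i0 + 1L):(i0 + m * per_bin)
    if (i0 < 0 || max(idx) > length(v)) {
      keep[r] <- FALSE
      next
    }
    vals <- v[idx]
    if (anyNA(vals)) {
      keep[r] <- FALSE
      next
    }
    rows[[r]] <- colMeans(matrix(vals, nrow = per_bin, ncol = m))
    keep[r] <- TRUE
  }
  if (!any(keep)) stop("no region survived gap filtering", call. = FALSE)
  sig <- do.call(rbind, rows[keep])
  rownames(sig) <- regions$id[keep]
  region_matrix(sig, bin_size,
                regions = regions[keep, , drop = FALSE],
                dropped = regions[!keep, , drop = FALSE])
}
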