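#' Read regions or tags from a BED file
#'
#' Accepts BED3-BED6; the `name` column (when present) supplies region ids,
#' otherwise ids default to `chrom:start-end`. `#`, `track` and `browser`
#' lines are ignored.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open; strand is `"*"` when absent).
#' @export
read_regions_bed <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based closed
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm))) {
    nm <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  }
  nm <- make.unique(as.character(nm))
  cbind(data.frame(id = nm, stringsAsFactors = FALSE), df)
}

#' @rdname read_regions_bed
#' @export
read_tags_bed <- function(path) {
  df <- read_regions_bed(path)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("tag BED must carry '+'/'-' strands for every tag", call. = FALSE)
  }
  df
}

granges_to_track <- function(gr, genome_sizes, kind) {
  values <- lapply(names(genome_sizes), function(ch) {
    rep(NA_real_, as.integer(genome_sizes[[ch]]))
  })
  names(values) <- names(genome_sizes)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(chroms), names(genome_sizes))
  if (length(bad) > 0) {
    stop("track contains unknown chromosome(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  sc <- gr$score
  for (ch in unique(chroms)) {
    sel <- which(chroms == ch)
    v <- values[[ch]]
    for (i in sel) {
      v[st[i]:min(en[i], length(v))] <- sc[i]
    }
    values[[ch]] <- v
  }
  signal_track(values, resolution = 1L, kind = kind)
}

#' Read a signal track from bedGraph or fixed-step wiggle
#'
#' Imports the file with rtracklayer and expands it to a per-base
#' `signal_track`; bases not covered by any record are missing (`NA`).
#'
#' @param path Path to a bedGraph (`.bedgraph`/`.bg`) or wiggle (`.wig`)
#'   file.
#' @param genome_sizes Named vector, chromosome -> length in bp.
#' @param kind Value semantics of the track (`"log2"` or `"coverage"`).
#' @param format Override format detection (`"bedGraph"` or `"wig"`).
#' @return A `signal_track` at 1-bp resolution.
#' @export
read_signal_track <- function(path, genome_sizes, kind = "log2",
                              format = NULL) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (is.null(format)) {
    format <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE)) {
      "wig"
    } else {
      "bedGraph"
    }
  }
  gr <- rtracklayer::import(path, format = format)
  granges_to_track(gr, genome_sizes, kind = kind)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal values are merged; missing (`NA`) stretches are omitted,
#' which is how bedGraph represents gaps.
#'
#' @param track A `signal_track` (any resolution).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  assert_that(inherits(track, "signal_track"), "need a signal_track")
  con <- file(path, open = "wt")
  on.exit(close(con))
  res <- track$resolution
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    r <- rle(ifelse(is.na(v), "NA", format(v, digits = 10, trim = TRUE,
                                           scientific = FALSE)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != "NA"
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep] * res,
                       ends[keep] * res, r$values[keep]), con)
  }
  invisible(path)
}

#' Write / read a region matrix as TSV
#'
#' The header row is `region_id` followed by the bp offset of each bin
#' start within the region; one row per region. '#' comment lines are
#' ignored on input.
#'
#' @param rm A `region_matrix`.
#' @param path File path.
#' @return `write_region_matrix_tsv` returns `path` invisibly;
#'   `read_region_matrix_tsv` returns a `region_matrix` (with genomic
#'   coordinates when a matching sidecar is absent, region coordinates are
#'   `NA`).
#' @export
write_region_matrix_tsv <- function(rm, path) {
  assert_that(inherits(rm, "region_matrix"), "need a region_matrix")
  m <- ncol(rm$signal)
  header <- c("region_id", format((seq_len(m) - 1L) * rm$bin_size,
                                  trim = TRUE, scientific = FALSE))
  df <- data.frame(rownames(rm$signal), rm$signal, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_region_matrix_tsv
#' @export
read_region_matrix_tsv <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 3, "matrix TSV needs an id column and >= 2 bins")
  offsets <- suppressWarnings(as.numeric(names(df)[-1]))
  assert_that(!anyNA(offsets), "header must carry numeric bin offsets")
  bin_size <- if (length(offsets) > 1) diff(offsets)[1] else 1
  assert_that(all(abs(diff(offsets) - bin_size) < 1e-9),
              "bin offsets must be evenly spaced")
  sig <- as.matrix(df[, -1, drop = FALSE])
  mode(sig) <- "numeric"
  rownames(sig) <- as.character(df[[1]])
  colnames(sig) <- NULL
  region_matrix(sig, bin_size = as.integer(bin_size))
}

#' Read a two-column genome sizes file (chrom, length)
#'
#' @param path Tab-separated file, no header.
#' @return Named numeric vector.
#' @export
read_genome_sizes <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  sizes <- as.numeric(df[[2]])
  names(sizes) <- as.character(df[[1]])
  sizes
}
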