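TEMPLATE_KINDS <- c("tss_like", "origin_like", "asymmetric_ctcf_like",
                    "null")

default_template_params <- function(kind) {
  # Log2-occupancy units, bin units of 10 bp unless rescaled by the caller.
  # period 17 bins ~ 170 bp nucleosome repeat; NDR ~ 120 bp wide, ~ 70 bp
  # upstream of the anchor for promoter-like architecture.
  p <- list(period = 17, peak_sd = 2.5, peak_amp = 0.8, decay = 0.9,
            n_nucs = 6, ndr_width = 12, ndr_depth = 1.2, ndr_offset = 0,
            left_amp = 1, right_amp = 1)
  adj <- switch(kind,
                tss_like = list(ndr_offset = -7, left_amp = 0.55,
                                right_amp = 1),
                origin_like = list(),
                asymmetric_ctcf_like = list(left_amp = 1, right_amp = 0),
                null = list())
  modifyList(p, adj)
}

#' Build a deterministic chromatin-architecture template
#'
#' Templates are sums of Gaussian nucleosome peaks phased at a fixed
#' period around a negative nucleosome-depleted-region (NDR) trough, in
#' log2-occupancy units per bin:
#' * `tss_like` — NDR slightly upstream of the anchor with phased arrays on
#'   both sides, the downstream array stronger (the well-positioned +1
#'   nucleosome side), so the template is directional;
#' * `origin_like` — symmetric NDR with equal arrays on both sides;
#' * `asymmetric_ctcf_like` — phased array on the left of the NDR only;
#' * `null` — the all-zero vector (no deterministic architecture).
#'
#' @param kind Template kind.
#' @param length_bins Template length in bins.
#' @param params Named list overriding the defaults: `period`, `peak_sd`,
#'   `peak_amp`, `decay` (amplitude ratio between successive nucleosomes),
#'   `n_nucs` (array length per side), `ndr_width`, `ndr_depth`,
#'   `ndr_offset` (bins, relative to the template center), `left_amp`,
#'   `right_amp` (side-specific array scaling). All positions/widths in
#'   bins, amplitudes in log2 units.
#' @return A `chrom_template` object (fields `values`, `kind`,
#'   `length_bins`, `params`).
#' @export
make_template <- function(kind = "tss_like", length_bins = 200,
                          params = list()) {
  kind <- match.arg(kind, TEMPLATE_KINDS)
  assert_that(is_count(length_bins, min = 2),
              "length_bins must be an integer >= 2")
  p <- modifyList(default_template_params(kind), params)
  assert_that(all(vapply(p, function(x) is.numeric(x) && is.finite(x),
                         logical(1))), "template parameters must be finite")
  x <- seq_len(length_bins)
  v <- numeric(length_bins)
  if (kind != "null") {
    center <- (length_bins + 1) / 2 + p$ndr_offset
    v <- v - p$ndr_depth *
      exp(-(x - center)^2 / (2 * (p$ndr_width / 2.355)^2))
    d0 <- p$ndr_width / 2 + p$period / 2
    for (k in seq_len(p$n_nucs) - 1) {
      amp <- p$peak_amp * p$decay^k
      for (side in c(-1, 1)) {
        side_amp <- if (side < 0) p$left_amp else p$right_amp
        if (side_amp == 0) next
        mu <- center + side * (d0 + k * p$period)
        v <- v + amp * side_amp * exp(-(x - mu)^2 / (2 * p$peak_sd^2))
      }
    }
  }
  structure(list(values = v, kind = kind,
                 length_bins = as.integer(length_bins), params = p),
            class = "chrom_template")
}

#' @export
print.chrom_template <- function(x, ...) {
  cat(sprintf("<chrom_template> %s, %d bins, amplitude %.2f log2 units\n",
              x$kind, x$length_bins, diff(range(x$values))))
  invisible(x)
}

pad_template <- function(template, pad) {
  if (inherits(template, "chrom_template")) {
    # regenerate at the padded length so the architecture (anchored at the
    # template center) extends naturally into the flanks
    make_template(template$kind, template$length_bins + 2L * pad,
                  template$params)$values
  } else {
    c(numeric(pad), as.numeric(template), numeric(pad))
  }
}

#' Generate a synthetic region set with planted truth
#'
#' Each region is the template observed through a random integer bin shift
#' (cropped from a padded template, so nothing wraps around), an optional
#' mirror flip, and additive i.i.d. Gaussian noise on the log2 scale. The
#' planted shift and orientation of every region are returned so an
#' alignment can be scored against ground truth. Fully reproducible from
#' `seed`.
#'
#' @param template A `chrom_template` (or plain numeric vector, which is
#'   zero-padded for shifting).
#' @param n Number of regions (>= 2).
#' @param max_shift_bins Maximum planted |shift| in bins.
#' @param reversal_prob Probability a region is mirror-flipped.
#' @param noise_sd Additive Gaussian noise sd per bin (log2 units).
#' @param bin_size Nominal resolution in bp (bookkeeping only).
#' @param seed Master seed.
#' @return List with `matrix` (a `region_matrix`), `truth` (data.frame
#'   `id`, `shift_bins`, `reversed`) and `params`.
#' @export
generate_dataset <- function(template, n = 200, max_shift_bins = 15,
                             reversal_prob = 0, noise_sd = 0.1,
                             bin_size = 10L, seed = 1L) {
  assert_that(is_count(n, min = 2), "need n >= 2 regions")
  assert_that(is_count(max_shift_bins, min = 0) ||
                max_shift_bins == 0, "max_shift_bins must be >= 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(reversal_prob >= 0 && reversal_prob <= 1,
              "reversal_prob must be in [0, 1]")
  m <- if (inherits(template, "chrom_template")) {
    template$length_bins
  } else {
    length(template)
  }
  pad <- as.integer(max_shift_bins)
  tpl <- pad_template(template, pad)
  with_seed(seed, {
    shifts <- if (pad > 0) {
      sample.int(2L * pad + 1L, n, replace = TRUE) - (pad + 1L)
    } else {
      integer(n)
    }
    reversed <- runif(n) < reversal_prob
    sig <- matrix(NA_real_, n, m)
    for (r in seq_len(n)) {
      row <- tpl[(pad + shifts[r] + 1L):(pad + shifts[r] + m)]
      if (reversed[r]) row <- rev(row)
      sig[r, ] <- row
    }
    if (noise_sd > 0) sig <- sig + rnorm(n * m, sd = noise_sd)
    ids <- sprintf("synth_%03d", seq_len(n))
    rownames(sig) <- ids
    step <- m * bin_size + 1000L
    regions <- data.frame(id = ids, chrom = "synth",
                          start = (seq_len(n) - 1L) * step,
                          end = (seq_len(n) - 1L) * step + m * bin_size,
                          stringsAsFactors = FALSE)
    list(matrix = region_matrix(sig, bin_size, regions = regions),
         truth = data.frame(id = ids, shift_bins = shifts,
                            reversed = reversed,
                            stringsAsFactors = FALSE),
         params = list(n = n, max_shift_bins = max_shift_bins,
                       reversal_prob = reversal_prob, noise_sd = noise_sd,
                       bin_size = bin_size, seed = seed,
                       kind = if (inherits(template, "chrom_template"))
                         template$kind else "custom"))
  })
}

#' Simulate a genome-scale track with the template planted at known sites
#'
#' Builds one synthetic chromosome at 1-bp resolution: the template
#' (expanded to base pairs) is added at `n_sites` regularly spaced centers,
#' on top of i.i.d. Gaussian base-level noise whose sd is scaled so that
#' `bin_size`-bp bin means have standard deviation `noise_sd`. This is the
#' substrate for [run_validation()]: the truth regions it returns can be
#' coordinate-randomized and re-extracted at any offset.
#'
#' @param template A `chrom_template`.
#' @param n_sites Number of planted sites.
#' @param gap_bp Gap between consecutive regions in bp.
#' @param bin_size Bin width the noise sd refers to.
#' @param noise_sd Noise sd per `bin_size`-bp bin (log2 units).
#' @param margin_bp Noise-only margin at the chromosome ends (must exceed
#'   the largest randomization shift).
#' @param seed Master seed.
#' @return List with `track` (a `signal_track`), `regions` (truth regions,
#'   one per site, template-length, centered on the planted architecture)
#'   and `centers` (bp).
#' @export
simulate_genome_track <- function(template, n_sites = 100, gap_bp = 1000,
                                  bin_size = 10L, noise_sd = 0.6,
                                  margin_bp = 400L, seed = 1L) {
  assert_that(inherits(template, "chrom_template"), "need a chrom_template")
  assert_that(is_count(n_sites, min = 2), "need n_sites >= 2")
  len_bp <- template$length_bins * bin_size
  step <- len_bp + gap_bp
  total <- 2L * margin_bp + n_sites * step
  block <- rep(template$values, each = bin_size)
  with_seed(seed, {
    v <- rnorm(total, sd = noise_sd * sqrt(bin_size))
    starts <- margin_bp + (seq_len(n_sites) - 1L) * step + gap_bp %/% 2L
    for (s in starts) v[(s + 1L):(s + len_bp)] <-
        v[(s + 1L):(s + len_bp)] + block
    ids <- sprintf("site_%03d", seq_len(n_sites))
    regions <- data.frame(id = ids, chrom = "synth",
                          start = starts, end = starts + len_bp,
                          stringsAsFactors = FALSE)
    list(track = signal_track(list(synth = v), resolution = 1L,
                              kind = "log2"),
         regions = regions, centers = starts + len_bp / 2)
  })
}

#' Write a synthetic dataset to disk (matrix TSV, truth TSV, params JSON)
#'
#' @param ds Output of [generate_dataset()].
#' @param prefix Output path prefix; files `<prefix>.matrix.tsv`,
#'   `<prefix>.truth.tsv` and `<prefix>.params.json` are written.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, prefix) {
  paths <- c(matrix = paste0(prefix, ".matrix.tsv"),
             truth = paste0(prefix, ".truth.tsv"),
             params = paste0(prefix, ".params.json"))
  write_region_matrix_tsv(ds$matrix, paths["matrix"])
  write.table(ds$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(ds$params, paths["params"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
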