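test_that("tag extension covers the 5'-anchored interval", {
  sizes <- c(chrI = 1000)
  tags <- data.frame(chrom = "chrI", start = 0, end = 36, strand = "+")
  cov <- tag_extension_coverage(tags, 120, sizes)
  expect_s3_class(cov, "signal_track")
  expect_equal(cov$kind, "coverage")
  expect_equal(cov$values$chrI, c(rep(1, 120), rep(0, 880)))

  # two identical tags double the coverage everywhere
  cov2 <- tag_extension_coverage(rbind(tags, tags), 120, sizes)
  expect_equal(cov2$values$chrI, 2 * cov$values$chrI)
})

test_that("tag extension matches the per-base brute-force oracle", {
  sizes <- c(chrI = 1000)
  tags <- data.frame(chrom = "chrI", start = c(100, 115),
                     end = c(136, 151), strand = c("+", "-"))
  cov <- tag_extension_coverage(tags, 120, sizes)
  expect_equal(cov$values$chrI, oracle_coverage(tags, 120, sizes)$chrI)

  # random tags on two chromosomes, including ends that force clipping
  set.seed(11)
  rnd <- data.frame(chrom = sample(c("chrI", "chrII"), 40, replace = TRUE),
                    start = sample(0:960, 40, replace = TRUE),
                    strand = sample(c("+", "-"), 40, replace = TRUE))
  rnd$end <- rnd$start + 36
  sizes2 <- c(chrI = 1000, chrII = 800)
  rnd <- rnd[rnd$end <= sizes2[rnd$chrom], ]
  cov <- tag_extension_coverage(rnd, 75, sizes2)
  orc <- oracle_coverage(rnd, 75, sizes2)
  expect_equal(cov$values$chrI, orc$chrI)
  expect_equal(cov$values$chrII, orc$chrII)
})

test_that("tag extension rejects bad input", {
  sizes <- c(chrI = 100)
  tag <- data.frame(chrom = "chrX", start = 0, end = 30, strand = "+")
  expect_error(tag_extension_coverage(tag, 50, sizes), "chrX")
  tag <- data.frame(chrom = "chrI", start = 0, end = 30, strand = ".")
  expect_error(tag_extension_coverage(tag, 50, sizes), "strand")
  tag <- data.frame(chrom = "chrI", start = 90, end = 120, strand = "+")
  expect_error(tag_extension_coverage(tag, 50, sizes), "bounds")
})

test_that("log2 occupancy follows the log2(cov/mean) formula", {
  # uniform coverage -> 0 everywhere, any pseudocount
  tr <- signal_track(list(c1 = rep(3, 50)), kind = "coverage")
  expect_equal(log2_occupancy(tr, 0.25)$values$c1, rep(0, 50))

  # coverage 2x the mean, pseudocount 0 -> exactly 1
  tr <- signal_track(list(c1 = c(rep(1, 8), 4, 3)), kind = "coverage")
  lg <- log2_occupancy(tr, 0)
  expect_equal(lg$values$c1[9], log2(4 / mean(tr$values$c1)))
  expect_equal(lg$kind, "log2")
  tr2 <- signal_track(list(c1 = c(4, 2, 2, 0)), kind = "coverage")  # mean 2
  expect_equal(log2_occupancy(tr2, 0)$values$c1[1], 1)

  # small toy track with pseudocount 0.25 against a looped oracle
  v <- c(0, 1, 2, 5, 0, 3, 1, 0, 2, 6)
  tr <- signal_track(list(c1 = v), kind = "coverage")
  got <- log2_occupancy(tr, 0.25)$values$c1
  want <- vapply(v, function(b) log2((b + 0.25) / (mean(v) + 0.25)),
                 numeric(1))
  expect_equal(got, want)

  expect_error(log2_occupancy(signal_track(list(c1 = rep(0, 10)),
                                           kind = "coverage")),
               "mean coverage")
  expect_error(log2_occupancy(log2_occupancy(signal_track(
    list(c1 = rep(2, 10)), kind = "coverage"))), "raw coverage")
})

test_that("extract_region_matrix bins, drops gapped regions, keeps order", {
  set.seed(3)
  v <- rnorm(6000)
  track <- signal_track(list(c1 = v), kind = "log2")
  regions <- data.frame(id = c("a", "b", "c"), chrom = "c1",
                        start = c(0, 2000, 4000),
                        end = c(2000, 4000, 6000))
  rm <- extract_region_matrix(track, regions, 10)
  expect_equal(dim(rm), c(3L, 200L))
  expect_equal(nrow(rm$dropped), 0)
  expect_equal(unname(rm$signal["b", 1]), mean(v[2001:2010]))
  expect_equal(unname(rm$signal["c", 200]), mean(v[5991:6000]))

  # a single missing base anywhere in a region drops the whole region
  v2 <- v
  v2[2500] <- NA
  rm2 <- extract_region_matrix(signal_track(list(c1 = v2), kind = "log2"),
                               regions, 10)
  expect_equal(rownames(rm2$signal), c("a", "c"))
  expect_equal(rm2$dropped$id, "b")

  # constant track -> every entry is that constant
  rm3 <- extract_region_matrix(signal_track(list(c1 = rep(1.5, 6000)),
                                            kind = "log2"), regions, 10)
  expect_true(all(rm3$signal == 1.5))

  # all regions gapped -> error
  expect_error(extract_region_matrix(
    signal_track(list(c1 = rep(NA_real_, 6000)), kind = "log2"),
    regions, 10), "gap filtering")
})

test_that("extraction is translation-consistent on a periodic track", {
  v <- rep(sin(2 * pi * (1:40) / 40), 50)  # period 40 bp
  track <- signal_track(list(c1 = v), kind = "log2")
  r1 <- data.frame(id = "a", chrom = "c1", start = 200, end = 600)
  r2 <- data.frame(id = "a", chrom = "c1", start = 240, end = 640)
  p1 <- extract_region_matrix(track, r1, 10)$signal[1, ]
  p2 <- extract_region_matrix(track, r2, 10)$signal[1, ]
  # shifting the region by 4 bins on a 4-bin-periodic track changes nothing
  expect_equal(p1, p2)
  r3 <- data.frame(id = "a", chrom = "c1", start = 210, end = 610)
  p3 <- extract_region_matrix(track, r3, 10)$signal[1, ]
  expect_equal(p1[-1], p3[-length(p3)])
})

test_that("tags -> log2 -> matrix equals the brute-force per-base pipeline", {
  sizes <- c(chrI = 8000)
  set.seed(23)
  tags <- data.frame(chrom = "chrI",
                     start = sample(0:7900, 300, replace = TRUE),
                     strand = sample(c("+", "-"), 300, replace = TRUE))
  tags$end <- tags$start + 40
  track <- log2_occupancy(tag_extension_coverage(tags, 100, sizes), 0.25)
  regions <- data.frame(id = c("a", "b"), chrom = "chrI",
                        start = c(1000, 4000), end = c(3000, 6000))
  rm <- extract_region_matrix(track, regions, 10)

  cov <- oracle_coverage(tags, 100, sizes)$chrI
  lg <- log2((cov + 0.25) / (mean(cov) + 0.25))
  for (r in 1:2) {
    want <- colMeans(matrix(lg[(regions$start[r] + 1):regions$end[r]],
                            nrow = 10))
    expect_equal(unname(rm$signal[r, ]), want)
  }
})
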