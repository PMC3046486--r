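test_that("identical regions align trivially with quality 1", {
  sig <- t(replicate(6, make_template("tss_like", 50)$values))
  rownames(sig) <- sprintf("r%d", 1:6)
  rm <- region_matrix(sig, 10L)
  a <- chosen_seed_alignment(rm, c(1, 2), frame_bins = 30)
  expect_equal(a$start_bin, rep(10L, 6))  # S = 20, centered start 10
  expect_equal(a$score, rep(1, 6), tolerance = 1e-9)
  expect_equal(a$quality, 1, tolerance = 1e-9)
  expect_equal(a$consensus, sig[1, 11:40], ignore_attr = TRUE)

  res <- seed_sampling_alignment(rm, 30)
  expect_equal(res$qualities, rep(1, 6), tolerance = 1e-9)
  expect_equal(res$alignment$seed[1], 1)  # tie broken to the lowest seed
})

test_that("noise-free planted shifts are recovered exactly", {
  # |shift| kept well inside S/2 = 12 so every relative placement is
  # feasible whichever seed anchors the frame
  shifts <- c(0, 3, -5, 5, -2, 4, -4, 1, 2, -3)
  rm <- planted_matrix(shifts, m = 60, w = 36)
  for (build in list(
    function() single_best_pair_alignment(rm, 36),
    function() seed_sampling_alignment(rm, 36)$alignment)) {
    a <- build()
    # relative placement: start + shift constant across regions
    expect_equal(length(unique(a$start_bin + shifts)), 1)
    expect_false(any(a$reversed))
    expect_equal(alignment_accuracy(a, shifts * 10, threshold = 0), 100)
  }
})

test_that("consensus equals the mean of aligned windows (identity)", {
  set.seed(12)
  for (k in 1:5) {
    rm <- random_matrix(n = sample(4:8, 1), m = 30, seed = 40 + k)
    rv <- k %% 2 == 0
    a <- single_best_pair_alignment(rm, 20, allow_reversal = rv)
    w <- aligned_windows(a, rm)
    expect_equal(a$consensus, unname(colMeans(w)), tolerance = 1e-9)
    expect_true(all(sort(a$order) == seq_len(nrow(rm$signal))))
  }
})

test_that("chosen-seed greedy matches the straight-line oracle stepwise", {
  set.seed(13)
  for (k in 1:10) {
    n <- sample(4:6, 1)
    m <- sample(16:20, 1)
    w <- m - 8
    metric <- sample(c("pearson", "euclidean"), 1)
    rv <- sample(c(TRUE, FALSE), 1)
    rm <- random_matrix(n, m, seed = 60 + k)
    a <- chosen_seed_alignment(rm, c(1, 2), w, metric, rv)
    orc <- oracle_greedy(rm$signal, 1, 2, w, metric, rv)
    expect_equal(a$start_bin, orc$start)
    expect_equal(a$reversed, orc$rev)
    expect_equal(a$order, orc$order)
    expect_equal(a$consensus, orc$consensus, tolerance = 1e-10)
  }
})

test_that("single best pair matches exhaustive pair enumeration", {
  set.seed(14)
  for (k in 1:8) {
    rm <- random_matrix(5, 18, seed = 80 + k)
    rv <- k %% 2 == 0
    a <- single_best_pair_alignment(rm, 8, allow_reversal = rv)
    orc <- oracle_global_best_pair(rm$signal, 8, "pearson", rv)
    expect_equal(a$seed, c(orc$i, orc$j))
    expect_equal(a$seed_score, orc$score, tolerance = 1e-10)
  }

  # planted exact copies become the seed with score 1
  rm <- random_matrix(8, 30, seed = 99)
  rm$signal[7, ] <- rm$signal[3, ]
  a <- single_best_pair_alignment(rm, 20)
  expect_equal(a$seed, c(3, 7))
  expect_equal(a$seed_score, 1, tolerance = 1e-9)
})

test_that("seed sampling reproduces the full brute-force procedure", {
  set.seed(15)
  for (k in 1:4) {
    n <- 6
    m <- 16
    w <- 8
    rv <- k %% 2 == 0
    rm <- random_matrix(n, m, seed = 120 + k)
    res <- seed_sampling_alignment(rm, w, allow_reversal = rv)
    orc <- oracle_seed_sampling(rm$signal, w, "pearson", rv)
    expect_equal(res$qualities, orc$qualities, tolerance = 1e-10)
    expect_equal(res$alignment$seed, orc$seed)
    expect_equal(res$alignment$start_bin, orc$start)
    expect_equal(res$alignment$quality, orc$quality, tolerance = 1e-10)
  }
})

test_that("seed sampling dominates any individual forced seed", {
  shifts <- c(0, 2, -3, 5, -1, 4, 12, -6)
  rm <- planted_matrix(shifts, m = 60, w = 40, seed = 2, noise_sd = 0.3)
  res <- seed_sampling_alignment(rm, 40)
  expect_equal(res$alignment$quality, max(res$qualities), tolerance = 1e-12)
  sbp <- single_best_pair_alignment(rm, 40)
  expect_true(res$alignment$quality >= sbp$quality - 1e-12)
})

test_that("quality assessment is the mean pairwise score", {
  # n = 2: exactly the pairwise score of the two windows
  rm <- random_matrix(2, 20, seed = 31)
  a <- chosen_seed_alignment(rm, c(1, 2), 12)
  w <- aligned_windows(a, rm)
  expect_equal(a$quality, oracle_score(w[1, ], w[2, ], "pearson"),
               tolerance = 1e-10)

  # n = 5 random alignments against the double-loop oracle, all metrics
  for (metric in c("pearson", "spearman", "euclidean")) {
    rm <- random_matrix(5, 25, seed = 32)
    a <- chosen_seed_alignment(rm, c(1, 2), 15, metric = metric)
    w <- aligned_windows(a, rm)
    expect_equal(quality_assessment(a, rm),
                 oracle_quality(w, metric), tolerance = 1e-10)
  }
})

test_that("mirrored regions are recovered by reversal", {
  shifts <- c(0, 3, -5, 5, -2, 1, 4, -3)
  revd <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  rm <- planted_matrix(shifts, m = 60, w = 36, reversed = revd)
  a <- seed_sampling_alignment(rm, 36, allow_reversal = TRUE)$alignment
  # orientations match planted truth up to a global flip
  agree <- mean(a$reversed == revd)
  expect_true(agree %in% c(0, 1))
  expect_equal(alignment_accuracy(a, shifts * 10, threshold = 0,
                                  true_reversed = revd), 100)
})

test_that("null regions yield a flat consensus relative to planted data", {
  tpl <- make_template("tss_like", 80)
  nul <- make_template("null", 80)
  expect_equal(nul$values, rep(0, 80))
  ds_t <- generate_dataset(tpl, n = 40, max_shift_bins = 8, noise_sd = 0.1,
                           seed = 5)
  ds_n <- generate_dataset(nul, n = 40, max_shift_bins = 8, noise_sd = 0.1,
                           seed = 5)
  a_t <- single_best_pair_alignment(ds_t$matrix, 50)
  a_n <- single_best_pair_alignment(ds_n$matrix, 50)
  expect_lt(diff(range(a_n$consensus)), diff(range(a_t$consensus)))
})

test_that("degenerate inputs error out", {
  rm <- random_matrix(4, 20, seed = 50)
  expect_error(chosen_seed_alignment(rm, c(2, 2), 10), "distinct")
  expect_error(single_best_pair_alignment(rm, 20), "smaller")
  one <- region_matrix(rm$signal[1, , drop = FALSE], 10L)
  expect_error(single_best_pair_alignment(one, 10), "at least 2")
})
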