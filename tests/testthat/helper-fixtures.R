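random_matrix <- function(n, m, seed, bin_size = 10L) {
  set.seed(seed)
  sig <- matrix(rnorm(n * m), n, m)
  rownames(sig) <- sprintf("r%02d", seq_len(n))
  region_matrix(sig, bin_size)
}

# noise-free copies of one template at known bin shifts (no wraparound)
planted_matrix <- function(shifts, m = 60, w = 40, seed = 1,
                           reversed = NULL, noise_sd = 0) {
  tpl <- make_template("tss_like", m)
  ds_pad <- max(abs(shifts))
  tplv <- make_template("tss_like", m + 2 * ds_pad)$values
  n <- length(shifts)
  if (is.null(reversed)) reversed <- rep(FALSE, n)
  set.seed(seed)
  sig <- t(sapply(seq_len(n), function(r) {
    row <- tplv[(ds_pad + shifts[r] + 1):(ds_pad + shifts[r] + m)]
    if (reversed[r]) row <- rev(row)
    row + rnorm(m, sd = noise_sd)
  }))
  rownames(sig) <- sprintf("p%02d", seq_len(n))
  region_matrix(sig, 10L)
}
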