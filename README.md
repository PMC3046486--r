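# chromalign

Coordinate-free alignment of chromatin architecture profiles.

## What it does, and for whom

Chromatin maps such as MNase-seq nucleosome occupancy show stereotyped
architectures around functional elements — a nucleosome-depleted region
(NDR) flanked by a phased nucleosome array at promoters, symmetric arrays
at replication origins, directional arrays at insulators. Averaging
profiles anchored at annotated coordinates blurs these architectures
whenever the annotation is offset from the structural landmark or the
architecture occurs in either orientation. `chromalign` is for
epigenomics analysts who want the architecture itself, not the
annotation, to define the registration.

Given an n × m matrix Z of binned log₂-occupancy profiles (one row per
region), the package finds per-region frame offsets sᵣ ∈ [0, S) and
orientation flags vᵣ (S = m − w, with w the alignment-frame length in
bins) so that the windows Wᵣ = Zᵣ[sᵣ, sᵣ+w) — reversed when vᵣ — are
maximally similar under a Pearson, Spearman, or Euclidean score.
Alignment is progressive and greedy: a seed pair initializes the
consensus P = (Wₓ + Wᵧ)/2, and remaining regions are committed one at a
time by best score against P, which is updated by the running mean
P ← (P·(i−1) + W)/i. Two seeding strategies are provided:

* **single-best-pair** — seed with the globally most similar pair over
  all `choose(n,2) · S` candidate placements (`· 2S` with reversals);
* **seed sampling** — force every region to act as seed, build n full
  alignments, and keep the one with the best *post-alignment quality*,
  the mean pairwise score over all `choose(n,2)` aligned windows.

A coordinate-randomization validation harness, a synthetic
chromatin-architecture generator (so everything is testable without
external data), standard readers/writers (BED, bedGraph, fixed-step
wiggle, TSV matrices) and a CLI round out the package. The search and
greedy loops are C++ (Rcpp); a 200-region seed-sampling run with a
100-bin frame takes tens of seconds on one core.

## Worked example

Plant a promoter-like architecture (NDR + phased array) in 50 synthetic
regions at random offsets up to ±15 bins, half of them mirrored, with
additive noise, then recover the registration without using the truth:

```r
library(chromalign)

tpl <- make_template("tss_like", length_bins = 200)   # 2-kb region, 10 bp/bin
ds  <- generate_dataset(tpl, n = 50, max_shift_bins = 15,
                        reversal_prob = 0.5, noise_sd = 0.1, seed = 42)

res <- seed_sampling_alignment(ds$matrix, frame_bins = 100,
                               metric = "pearson", allow_reversal = TRUE)
res$alignment
#> <chrom_alignment> 50 regions, frame 100 bins (1000 bp), metric pearson, reversals enabled
#>   seed regions: 8, 30 (seed score 0.9672)
#>   quality: 0.9558

err <- placement_errors(res$alignment, ds$truth$shift_bins * 10,
                        ds$truth$reversed)
100 * mean(abs(err) <= 10)                                  # within ±1 bin
#> [1] 100
orientation_agreement(res$alignment, ds$truth$reversed)
#> [1] 100
diff(range(res$alignment$consensus))
#> [1] 1.966
```

Reading the numbers: the post-alignment quality 0.9558 is the mean
pairwise Pearson correlation of the 50 aligned windows; every region was
placed within one 10-bp bin of its planted offset and every orientation
matched the planted one (up to the arbitrary global flip); the consensus
spans ~2 log₂ units from NDR trough to the +1-nucleosome peak — the
planted architecture recovered at full sharpness.

The validation harness reproduces randomization curves
(`run_validation()`, `summarize_validation()`), and the CLI drives the
same machinery from the shell:

```sh
Rscript inst/cli/chromalign simulate --n 200 --out-prefix sim
Rscript inst/cli/chromalign align --matrix sim.matrix.tsv --frame 1000 \
    --strategy seed_sampling --reversal --out-prefix aln
Rscript inst/cli/chromalign validate --n 100 --replicates 3 --out-prefix val
```

## Known red test

One assertion in `tests/testthat/test-acceptance.R` fails by design: in
the synthetic world (additive i.i.d. noise), single-best-pair seeding
shows no accuracy loss at large coordinate randomization, because an
i.i.d.-noise world lacks the structured region-to-region heterogeneity
that degrades seed quality on real data. The assertion is kept at its
specified strength rather than weakened; see the "Known limitations"
section of the methods vignette (`vignettes/chromalign-methods.Rmd`).
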