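---
title: "hicforge: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hicforge: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hicforge is a self-contained Hi-C processing pipeline: raw paired-end reads
are pre-truncated at ligation junctions, aligned mates are filtered into
valid contacts, per-chromosome contact matrices are normalized with an
explicit-factor correction model, and topologically-associated domains
(TADs) are called from the directionality index with a hidden Markov model.
This vignette explains the models behind each stage, the tunable parameters
and their defaults, and the design decisions taken where several defensible
choices existed.

## Restriction digestion and FEND annotation

A Hi-C library is built by cutting chromatin with a restriction enzyme,
ligating spatially proximal fragment ends, and sequencing the chimeric
products. The unit of bias correction is therefore the **fragment end
(FEND)**: each restriction fragment contributes its left and right end,
and each FEND carries three features known to modulate ligation
efficiency — fragment length, local GC content, and local mappability.

`digest_sequence()` scans the top strand for exact occurrences of the
recognition site and cuts after `cut_offset` bases. Only palindromic,
unambiguous (ACGT) sites are accepted, which makes top-strand scanning
exact; the four built-in cutters (HindIII `A^AGCTT`, NcoI `C^CATGG`,
DpnII/MboI `^GATC`) all satisfy this. Coordinates are 0-based half-open
everywhere, including the FEND BED output; 1-based numbers appear only on
plot axes.

The feature windows are not dictated by the pipeline definition itself, so
they are explicit, overridable defaults chosen to follow the established
fragment-level correction convention:

* **GC content** — fraction of G/C among non-N bases in the 200 bp interior
  to the fragment from the FEND coordinate, truncated at the fragment
  boundary. An all-N window yields the sentinel `-1`, and such FENDs are
  excluded from correction learning.
* **Mappability** — fraction of 50-mers starting in the 500 bp interior
  window that occur exactly once in the genome, counting both strands
  (a palindromic k-mer counts once per locus; k-mers containing N count as
  non-unique). This is an exact-uniqueness proxy for alignability; it does
  not model mismatches, which a read aligner would tolerate.

## Read pre-truncation

A read that runs through its fragment's restriction site into the ligated
partner contains the reconstructed **ligation junction**: the 5' overhang
is filled in and the blunt ends ligated, giving
`site[1..L-cut] + site[cut+1..L]` (HindIII: `AAGCTAGCTT`; MboI:
`GATCGATC`). `truncate_read()` keeps the 5' prefix through the first
`L - cut_offset` bases of the first junction occurrence — the portion that
belongs to the read's own fragment — and truncates the quality string
alongside (required for valid FASTQ). The search is exact and
case-insensitive, and truncation is idempotent. Reads truncated below the
20 bp floor are kept and counted rather than dropped: the MAPQ filter
after alignment is the appropriate place to discard them, and keeping them
preserves record-count conservation between input and output. Mate files
are processed independently, mirroring independent single-end alignment of
the two mates.

## Pair filtering

Each mate file is aligned separately, so pairing happens here: mates are
matched by read id after dropping unmapped reads and reads with MAPQ < 30
(the conventional threshold; MAPQ 30 itself is kept). Fragment assignment
uses the mate's **5' position** — `pos` for + strand, `pos + aligned_ref_width - 1`
for − strand — because the 5' end is the ligation-proximal end; the FEND
assigned is the fragment end the read points toward (right end for +,
left end for −).

Non-informative products are classified with the standard artifact
taxonomy: same fragment with convergent strands (+ mate 5' of the − mate)
is a **dangling end** (unligated fragment); same fragment otherwise is a
**self-circle**; adjacent fragments are **re-ligation** products (removed
by default, configurable). PCR duplicates are pairs sharing both mates'
(chromosome, 5' position, strand) after canonically ordering the two
mates, so mates swapped between files still collide; the first occurrence
survives. Inter-chromosomal valid pairs are written to the pairs table but
ignored by the (intra-chromosomal) matrix builder.

## Normalization

### Observed matrix and distance decay

`bin_pairs()` counts pairs into fixed-size bins (default 40 kb, the
standard resolution for TAD analysis). Contact frequency decays
monotonically with genomic distance; hicforge estimates this at two
levels:

* `estimate_distance_decay()` — cell level: mean `O[i,j]` per bin distance,
  for reporting and as the monotone reference profile.
* `fend_distance_profile()` — FEND level: observed pair count divided by
  the number of FEND pairs at each distance. This is the distance term of
  the correction model, because summing a per-FEND-pair rate over the FEND
  pairs of a cell gives that cell's expected count; a cell-level mean
  would over-count by the FEND-pair density.

Both are smoothed with a weighted pool-adjacent-violators fit constrained
non-increasing for d ≥ 1 (d = 0 is left raw: the diagonal mixes
self-ligation artifacts and genuine short-range contacts and should not
constrain the tail). Distances with no data are imputed from the nearest
positive smoothed neighbor so the profile is strictly positive wherever
the data support it.

### Explicit-factor correction model

The correction model predicts the weight of a FEND pair (p, q) as

```
w(p,q) = s * decay(d_pq) * C_len[g(p),g(q)] * C_gc[g(p),g(q)] * C_map[g(p),g(q)]
```

where each feature partitions FENDs into quantile groups (default 20 per
feature; left-closed right-open intervals break ties) and `C_f` is a
symmetric per-feature table of multiplicative corrections. Learning is by
cyclic moment-matching: for each feature and group pair, the table entry
is multiplied by the ratio of observed pair counts to predicted weight
summed over **all** eligible FEND pairs in that group combination —
the denominator must run over all pairs, not only observed ones, or
unbiased data would not converge to `C = 1`. After each sweep the tables
are renormalized to mean-zero log over occupied group pairs (the
identifiability constraint) with the global scale `s` absorbing the
remainder; iteration stops when the largest absolute log change falls
below `tol = 1e-4` or after `max_iter = 100` sweeps. This is an iterative
proportional-fitting style optimizer: simpler than a full likelihood
machinery, and validated by planted-bias recovery (a planted 4:1
two-group fend effect is recovered within 10% at 50,000 pairs) rather
than by numeric identity with any particular external implementation.

Only FEND pairs separated by more than `min_distance = 500 kb` enter the
fit. This single exclusion is also how biological confounders
(transcription start sites, CTCF-bound sites, and the local chromatin
conformation around them) are kept out of the technical correction — no
annotation files are consumed.

### The two readings of E

The correction matrix E admits two constructions, and hicforge implements
both:

* **Observed-pair sum** (default): `E[i,j]` sums the correction product
  over the observed read pairs in the cell. E then shares its support with
  O exactly (`E = 0` iff `O = 0`), and with a unit model `E` equals `O`
  entrywise, so `N = O/E` is exactly 1 on the support. This N is the
  per-cell inverse mean bias — a diagnostic of bias structure, stripped of
  count structure.
* **All-pair sum** (`correction_matrix(..., all_pairs = TRUE)`): `E[i,j]`
  sums the correction product over every FEND pair mapping to the cell.
  `N = O/E` then preserves the count and distance structure while removing
  the learned bias — the map one would visualize — and it is the variant
  under which normalization demonstrably increases correlation with
  bias-free truth on synthetic data.

The **observed/expected** matrix uses the full model: the expected count
sums `s * decay(d) * prod C_f` over all FEND pairs of the cell, and the
entry is `log2(O / expected)`. Cells with no expected mass (bins without
FENDs) carry the `na_expected` sentinel; cells with expected but no
observed contacts carry `na_observed`. On decay-only synthetic data the
mean of `2^(O/E log2)` per distance is 1 within Monte-Carlo error, which
the test suite checks at ±0.1.

## TAD calling

The **directionality index** contrasts upstream and downstream contact
sums per bin within a window (default 2 Mb, the standard choice at 40 kb
resolution): with `A` the upstream sum, `B` the downstream sum and
`E = (A+B)/2`,

```
DI = sign(B - A) * ((A-E)^2/E + (B-E)^2/E)
```

Bins at a domain start contact preferentially downstream (DI > 0), bins at
a domain end upstream (DI < 0). Bins with `A + B = 0` (unmappable
regions) are masked: they are excluded from model fitting, decode to a
sentinel, and break domain runs.

The "true DI" is decoded with a 3-state hidden Markov model (downstream
bias / no bias / upstream bias) with univariate Gaussian emissions —
deliberately simpler than a mixture emission; the acceptance standard is
boundary recovery, not replication of any specific caller. Fitting is
Baum-Welch on the finite DI values with 5 seeded random restarts (best
log-likelihood wins; the per-iteration log-likelihood is non-decreasing,
and degenerate variances are floored at 1e-8 with a warning). States are
relabeled by descending emission mean, making the labeling deterministic.
Decoding uses the Viterbi path — "state shifts" semantics require one
coherent path, which posterior marginals do not give — run per contiguous
unmasked segment. Models are fit per chromosome by default; a median
filter of width 3 on DI is available but off by default.

Domains are read off the state track: a TAD opens at the first bin of a
maximal downstream (+1) run and closes at the end of the first following
upstream (−1) run; a new downstream run, a masked bin, or the track end
closes an open domain at the preceding bin (or at the run end). A no-bias
gap between a domain's +1 and −1 runs stays inside the domain; a no-bias
gap after a closed domain is TAD-free. This treatment of unbiased gaps is
a design decision — merging them into domains would be equally
implementable but would bias domain sizes upward. Coordinates are bin
multiples, half-open, sorted, non-overlapping; a contiguous run of k TADs
has k+1 distinct boundaries.

## Storage format

Contact matrices are symmetric and sparse, so files store only the upper
triangle (diagonal included) in row-major order, with each maximal run of
k zeros collapsed to the single token `-k`. Zero-run tokens are bare
negative integers; because log2 O/E matrices legitimately contain negative
values, negative floats are always serialized with a decimal point, which
keeps the stream unambiguous. O/E sentinels are written as the reserved
tokens `na_expected` / `na_observed`. Floats use 6 significant digits
(configurable); observed matrices are written as integers and round-trip
exactly. A one-line header `#hicforge triangular n=... bin=... chrom=...
role=...` makes files self-describing; `headerless = TRUE` writes bare
streams. On matrices with ≥ 80% zeros the encoded stream is at most 40% of
the dense triangle, and in practice much less at realistic sparsity. TADs
are one `start<TAB>end` line per domain; DI and state tracks are one value
per line with `nan` for masked bins.

## The synthetic-data generator

Every pipeline stage is validated against `simulate_*()` generators whose
ground truth is recorded, all driven by one seed:

* `simulate_genome()` — random chromosomes with restriction sites planted
  at recorded positions and guaranteed absent elsewhere (spontaneous site
  and junction occurrences are scrubbed by point mutation). Planted
  fragments are ≥ 300 bp with a 1 kb mean, a desk-scale compression of a
  4-cutter digest.
* `simulate_pairs()` — FEND pairs drawn with probability proportional to
  `(1+d)^(-alpha) * enrichment^[same TAD block] * bias_p * bias_q`
  (alpha defaults to 1, the canonical contact-decay exponent). Mate
  positions sit just inside their FENDs with a per-draw jitter so that
  distinct read pairs never share coordinates — accidental collisions
  would masquerade as PCR duplicates and break exact truth accounting.
* `simulate_fastq()` — junctions inserted into exactly
  `round(rate * n)` mate-1 reads at recorded offsets (default rate 0.15,
  the typical magnitude for in situ Hi-C libraries).
* `simulate_sam()` — minimal single-end SAM records with planted
  duplicates (5%), low-MAPQ mates (15%), self-circles, dangling ends and
  re-ligations (2% each), with exact category counts recorded.
* `simulate_tad_matrix()` — Poisson contact matrices with power-law decay,
  5-fold block-diagonal enrichment and 10-30 bin blocks.

What the generator does **not** emulate: sequencing errors and quality
variation, chimeric reads, copy-number variation, inter-chromosomal
contacts, nested or hierarchical domain structure, and realistic
mappability structure (features are drawn independently unless a test
plants spatial autocorrelation). Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
end-to-end performance on real libraries.

## Problem sizes and numerical choices

The test and acceptance workloads run at desk scale, chosen so the whole
suite completes in minutes on one core: 0.2-2 Mb chromosomes, 10,000 to
60,000 read pairs, 150-bin TAD matrices, three seeds where variability
matters. Numerical details worth knowing: symmetric matrices are checked
at 1e-9 relative asymmetry; quantile group edges use type-7 quantiles with
left-closed intervals; the correction updates guard empty group
combinations (left unchanged) and the EM variance floor is 1e-8; heatmap
percentile cutoffs are computed over all upper-triangle entries including
zeros.

## Limitations

Matrix balancing (ICE/Knight-Ruiz), inter-chromosomal expected models,
loop calling, compartment analysis and nested TADs are out of scope. The
mappability feature is exact k-mer uniqueness, stricter than
aligner-based mappability. The moment-matching optimizer matches the
correction model's moments rather than maximizing an explicit likelihood;
on strongly confounded features (e.g., GC correlated with length) the
factorized tables share the credit, which is inherent to the model class.
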