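# Shared fixtures and independent oracles for the test suite.

# Synthetic FEND table without a genome: fragment boundaries at least
# 400 bp apart, random GC and mappability features. Fast stand-in for
# build_fend_table() where only the table's geometry/features matter.
make_test_fends <- function(n_frags_per_chrom = 250L, chroms = c("chr1", "chr2"),
                            chrom_length = 1e6, seed = 42L) {
  set.seed(seed)
  per <- lapply(chroms, function(cn) {
    cuts <- sort(sample(seq(400L, chrom_length - 400L, by = 400L),
                        n_frags_per_chrom - 1L))
    bounds <- c(0L, cuts, as.integer(chrom_length))
    n <- length(bounds) - 1L
    data.frame(
      chrom = cn,
      coord = as.integer(c(rbind(bounds[-(n + 1L)], bounds[-1L]))),
      side = rep(c("L", "R"), n),
      fragment_index = rep(0:(n - 1L), each = 2L),
      fragment_length = rep(diff(bounds), each = 2L),
      gc = rep(stats::runif(n, 0.3, 0.7), each = 2L),
      mappability = rep(stats::runif(n, 0.6, 1), each = 2L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per)
  out$fend_id <- seq_len(nrow(out))
  out
}

# Correction model with all tables identically 1 (zero learning sweeps).
uniform_model <- function(pairs, fends, bin_size = 40000L,
                          min_distance = 1e5) {
  decay <- fend_distance_profile(pairs, fends, bin_size)
  binning <- suppressWarnings(partition_fend_features(fends, 2L))
  learn_corrections(pairs, fends, binning, decay,
                    min_distance = min_distance, max_iter = 0L)
}

# Brute-force digestion oracle: regex scan for site occurrences, cuts at
# site_start + offset, fragments from sorted interior cuts.
oracle_digest <- function(seq, site, cut_offset) {
  seq <- toupper(seq)
  starts <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(site, substr(seq, from, nchar(seq)), fixed = TRUE)
    if (hit < 0L) break
    starts <- c(starts, from + hit - 2L)  # 0-based
    from <- from + hit  # allow overlapping occurrences
  }
  cuts <- starts + cut_offset
  cuts <- sort(unique(cuts[cuts > 0L & cuts < nchar(seq)]))
  bounds <- c(0L, cuts, nchar(seq))
  cbind(start = bounds[-length(bounds)], end = bounds[-1L])
}

# Brute-force pair classification oracle: literal rule table.
oracle_classify <- function(chrom1, pos1, strand1, frag1,
                            chrom2, pos2, strand2, frag2) {
  n <- length(chrom1)
  out <- character(n)
  for (i in seq_len(n)) {
    if (chrom1[i] == chrom2[i] && frag1[i] == frag2[i]) {
      if (strand1[i] != strand2[i]) {
        pp <- if (strand1[i] == "+") pos1[i] else pos2[i]
        mp <- if (strand1[i] == "+") pos2[i] else pos1[i]
        out[i] <- if (pp <= mp) "dangling_end" else "self_circle"
      } else {
        out[i] <- "self_circle"
      }
    } else if (chrom1[i] == chrom2[i] && abs(frag1[i] - frag2[i]) == 1L) {
      out[i] <- "re_ligation"
    } else {
      out[i] <- "valid"
    }
  }
  out
}

# Exhaustive most-probable-path oracle: scores every 3^L state sequence.
oracle_viterbi <- function(model, x) {
  K <- length(model$means)
  L <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  score <- function(p) {
    s <- log(model$init[p[1L]]) +
      stats::dnorm(x[1L], model$means[p[1L]], sqrt(model$vars[p[1L]]), log = TRUE)
    if (L > 1L) {
      for (t in 2:L) {
        s <- s + log(model$trans[p[t - 1L], p[t]]) +
          stats::dnorm(x[t], model$means[p[t]], sqrt(model$vars[p[t]]), log = TRUE)
      }
    }
    s
  }
  best <- which.max(apply(paths, 1L, score))
  unname(paths[best, ])
}

# Random symmetric sparse matrix (integer counts).
random_sparse_symmetric <- function(n, zero_frac = 0.85, integer_counts = TRUE) {
  M <- matrix(0, n, n)
  up <- which(upper.tri(M, diag = TRUE))
  nz <- sample(up, round((1 - zero_frac) * length(up)))
  M[nz] <- if (integer_counts) stats::rpois(length(nz), 4) + 1
           else stats::rexp(length(nz)) + 0.1
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

# Write a tiny FASTQ from parallel vectors.
write_test_fastq <- function(ids, seqs, path, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
}
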