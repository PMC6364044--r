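#' Configuration for the synthetic Hi-C data generator
#'
#' Bundles every knob of the simulator with defaults chosen to emulate a
#' desk-scale Hi-C experiment: MboI-digested multi-chromosome genome with
#' ~1 kb fragments, contact probability decaying with genomic distance as
#' a power law, ~15% of reads carrying a ligation junction and ~15% of
#' mates mapping below MAPQ 30 (the typical magnitudes for in situ Hi-C
#' libraries), plus small planted fractions of PCR duplicates and
#' self-circle/dangling-end/re-ligation artifacts.
#'
#' @param seed Master seed; every generator is a pure function of it.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param enzyme Enzyme name or `restriction_enzyme`.
#' @param frag_mean Mean planted fragment length in bp (min 300).
#' @param junction_rate Fraction of mate-1 reads carrying a junction.
#' @param dup_rate,low_mapq_rate,self_circle_rate,dangling_rate,religation_rate
#'   Planted artifact fractions (relative to `n_pairs`).
#' @param n_pairs Number of valid read pairs to draw.
#' @param decay_exponent Power-law exponent alpha of the contact decay.
#' @param tad_blocks List of `c(start_bin, end_bin)` intervals (1-based,
#'   inclusive) enriched `tad_enrichment`-fold; applied to each chromosome.
#' @param tad_enrichment Within-block contact multiplier.
#' @param fend_bias Per-FEND multiplicative bias spec: a list
#'   `list(feature=, n_groups=, effects=)`; NULL for unbiased data.
#' @param read_length Read length in bp.
#' @param bin_size Bin size in bp.
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 0L, n_chroms = 2L, chrom_length = 2e6,
                       enzyme = "MboI", frag_mean = 1000,
                       junction_rate = 0.15, dup_rate = 0.05,
                       low_mapq_rate = 0.15, self_circle_rate = 0.02,
                       dangling_rate = 0.02, religation_rate = 0.02,
                       n_pairs = 10000L, decay_exponent = 1,
                       tad_blocks = NULL, tad_enrichment = 1,
                       fend_bias = NULL, read_length = 50L,
                       bin_size = 40000L) {
  rates <- c(junction_rate, dup_rate, low_mapq_rate, self_circle_rate,
             dangling_rate, religation_rate)
  stopifnot(all(rates >= 0 & rates <= 1), decay_exponent >= 0,
            tad_enrichment > 0, frag_mean >= 300)
  structure(as.list(environment()), class = "sim_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All start positions (0-based) of `pat` in `s`.
.occ0 <- function(s, pat) {
  Biostrings::start(Biostrings::matchPattern(pat, Biostrings::DNAString(s))) - 1L
}

#' Simulate a genome with planted restriction sites
#'
#' Random sequence per chromosome in which the enzyme's recognition site
#' occurs exactly at the recorded planted positions and nowhere else, and
#' the ligation junction occurs nowhere: spontaneous occurrences are
#' scrubbed by point mutation. Deterministic for a given config seed.
#'
#' @param config `sim_config`.
#' @return List with `genome` (named character vector) and `truth`
#'   (per-chrom data.frame of planted `site_pos` and `cut_pos`).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  enzyme <- get_enzyme(config$enzyme)
  site <- enzyme$site
  junction <- make_ligation_junction(enzyme)
  site_len <- nchar(site)
  genome <- character(config$n_chroms)
  names(genome) <- paste0("chr", seq_len(config$n_chroms))
  truth <- list()
  site_chars <- strsplit(site, "", fixed = TRUE)[[1L]]
  for (cn in names(genome)) {
    L <- as.integer(config$chrom_length)
    # work on a base vector: per-base mutation on a multi-Mb string would
    # copy the whole string each time
    b <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    gaps <- 300 + stats::rgeom(ceiling(L / 100), 1 / (config$frag_mean - 300))
    pos <- cumsum(gaps + site_len)
    pos <- pos[pos + site_len <= L - 300L]
    for (p in pos) b[(p + 1L):(p + site_len)] <- site_chars
    planted <- sort(pos)
    protected <- logical(L)
    for (p in planted) protected[(p + 1L):(p + site_len)] <- TRUE
    guard <- 0L
    repeat {
      s <- paste(b, collapse = "")
      bad_site <- setdiff(.occ0(s, site), planted)
      bad_junc <- .occ0(s, junction)
      bad <- sort(unique(c(bad_site, bad_junc)))
      if (length(bad) == 0L) break
      guard <- guard + 1L
      if (guard > 50L) stop("could not scrub spurious sites")
      for (p0 in bad) {
        span_len <- if (p0 %in% bad_junc && !(p0 %in% bad_site))
          nchar(junction) else site_len
        free <- ((p0 + 1L):(p0 + span_len))
        free <- free[!protected[free]]
        if (length(free) == 0L) next
        i <- free[ceiling(length(free) / 2)]
        b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
      }
    }
    genome[[cn]] <- s
    truth[[cn]] <- data.frame(site_pos = planted,
                              cut_pos = planted + enzyme$cut_offset)
  }
  list(genome = genome, truth = truth)
}

# Per-fend multiplicative bias from the config's fend_bias spec; groups
# are assigned by quantile rank of the named feature.
.fend_bias_values <- function(config, fends) {
  bias <- rep(1, nrow(fends))
  group <- rep(1L, nrow(fends))
  spec <- config$fend_bias
  if (!is.null(spec)) {
    x <- .fend_feature(fends, spec$feature)
    qs <- stats::quantile(x, probs = seq(0, 1, length.out = spec$n_groups + 1),
                          names = FALSE)
    internal <- unique(qs[2:spec$n_groups])
    group <- findInterval(x, internal) + 1L
    group <- pmin(group, length(spec$effects))
    bias <- spec$effects[group]
  }
  list(bias = bias, group = group)
}

.bin_of <- function(coord, bin_size) coord %/% bin_size + 1L  # 1-based bin

#' Simulate valid read pairs from a planted contact model
#'
#' Draws `n_pairs` FEND pairs (intra-chromosomal, skipping same- and
#' adjacent-fragment pairs, which would be filtered as artifacts) with
#' probability proportional to
#' `(1 + d_bins)^(-alpha) * enrichment^[same TAD block] * bias_p * bias_q`,
#' then places each mate's 5' end just inside its FEND (pointing at the
#' cut site), so the filtering pipeline recovers the FEND assignment
#' exactly.
#'
#' @param config `sim_config`.
#' @param fends FEND table for the simulated genome.
#' @return List with `pairs` (valid-pairs table plus `read_id`) and
#'   `truth` (eligible fend pairs with sampling weights and per-pair draw
#'   counts, per-FEND `bias`/`group`).
#' @export
simulate_pairs <- function(config, fends) {
  set.seed(config$seed + 1L)
  rl <- config$read_length
  bias <- .fend_bias_values(config, fends)
  elig <- .all_fend_pairs(fends, config$bin_size)
  frag_by_id <- stats::setNames(fends$fragment_index, fends$fend_id)
  chrom_by_id <- stats::setNames(fends$chrom, fends$fend_id)
  coord_by_id <- stats::setNames(fends$coord, fends$fend_id)
  side_by_id <- stats::setNames(fends$side, fends$fend_id)
  keep <- abs(frag_by_id[as.character(elig$p)] -
              frag_by_id[as.character(elig$q)]) > 1L
  elig <- elig[keep, , drop = FALSE]

  w <- (1 + elig$dbin)^(-config$decay_exponent)
  if (!is.null(config$tad_blocks) && config$tad_enrichment != 1) {
    bi <- .bin_of(coord_by_id[as.character(elig$p)], config$bin_size)
    bj <- .bin_of(coord_by_id[as.character(elig$q)], config$bin_size)
    same_block <- rep(FALSE, nrow(elig))
    for (blk in config$tad_blocks) {
      same_block <- same_block |
        (bi >= blk[1L] & bi <= blk[2L] & bj >= blk[1L] & bj <= blk[2L])
    }
    w <- w * ifelse(same_block, config$tad_enrichment, 1)
  }
  bias_by_id <- stats::setNames(bias$bias, fends$fend_id)
  w <- w * bias_by_id[as.character(elig$p)] * bias_by_id[as.character(elig$q)]

  draw <- sample.int(nrow(elig), config$n_pairs, replace = TRUE,
                     prob = w / sum(w))
  elig$count <- tabulate(draw, nbins = nrow(elig))

  # the k-th draw of the same fend pair gets jitter k-1, so every read
  # pair has unique coordinates (planted fragments are >= 300 bp apart,
  # well above the jitter range; true duplicates are planted separately)
  jit <- stats::ave(draw, draw, FUN = seq_along) - 1L
  if (any(jit >= 200L)) jit <- jit %% 200L
  pos5_of <- function(id, jit) {
    coord <- coord_by_id[as.character(id)]
    ifelse(side_by_id[as.character(id)] == "R",
           coord - rl - jit, coord + rl + jit)
  }
  strand_of <- function(id) {
    ifelse(side_by_id[as.character(id)] == "R", "+", "-")
  }
  p <- elig$p[draw]; q <- elig$q[draw]
  pairs <- data.frame(
    read_id = sprintf("sim%07d", seq_along(draw)),
    chrom1 = unname(chrom_by_id[as.character(p)]),
    pos1 = unname(as.integer(pos5_of(p, jit))), strand1 = unname(strand_of(p)),
    fend1 = p,
    chrom2 = unname(chrom_by_id[as.character(q)]),
    pos2 = unname(as.integer(pos5_of(q, jit))), strand2 = unname(strand_of(q)),
    fend2 = q,
    stringsAsFactors = FALSE
  )
  list(pairs = pairs,
       truth = list(eligible = elig, weight = w,
                    bias = bias$bias, group = bias$group))
}

# Extract read sequence (read-strand orientation) from the genome.
.read_seq <- function(genome, chrom, pos5, strand, len) {
  s <- genome[[chrom]]
  if (strand == "+") {
    substr(s, pos5 + 1L, pos5 + len)
  } else {
    frag <- substr(s, pos5 - len + 2L, pos5 + 1L)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  }
}

#' Simulate FASTQ mates with planted ligation junctions
#'
#' Writes one FASTQ per mate. Exactly `round(junction_rate * n)` mate-1
#' reads get the junction inserted at a recorded offset (the bases beyond
#' it come from an unrelated locus, emulating read-through into the
#' ligation partner); the simulated genome is junction-free, so no read
#' carries a spurious junction.
#'
#' @param pairs Pair table from [simulate_pairs()].
#' @param config `sim_config`.
#' @param genome Simulated genome (named character vector).
#' @param fq1,fq2 Output FASTQ paths.
#' @return Truth data.frame: `read_id`, `truncated`, `offset`,
#'   `post_trunc_len`.
#' @export
simulate_fastq <- function(pairs, config, genome, fq1, fq2) {
  set.seed(config$seed + 2L)
  enzyme <- get_enzyme(config$enzyme)
  junction <- make_ligation_junction(enzyme)
  jl <- nchar(junction)
  rl <- config$read_length
  keep_extra <- nchar(enzyme$site) - enzyme$cut_offset
  n <- nrow(pairs)
  n_trunc <- round(config$junction_rate * n)
  which_trunc <- sort(sample.int(n, n_trunc))
  offsets <- rep(NA_integer_, n)
  if (n_trunc > 0L) {
    offsets[which_trunc] <- sample(5:(rl - jl - 2L), n_trunc, replace = TRUE)
  }
  seq1 <- character(n); seq2 <- character(n)
  for (i in seq_len(n)) {
    s1 <- .read_seq(genome, pairs$chrom1[i], pairs$pos1[i], pairs$strand1[i], rl)
    if (!is.na(offsets[i])) {
      p <- offsets[i]
      filler_len <- rl - p - jl
      s1 <- paste0(substr(s1, 1L, p), junction,
                   if (filler_len > 0L) .rand_dna(filler_len) else "")
      # the genome is site-free away from cuts, but verify the junction
      # occurs first at the planted offset; redraw the filler if not
      guard <- 0L
      while (.occ0(s1, junction)[1L] != p) {
        guard <- guard + 1L
        if (guard > 20L) stop("could not place junction cleanly")
        s1 <- paste0(substr(s1, 1L, p), junction,
                     if (filler_len > 0L) .rand_dna(filler_len) else "")
      }
    }
    seq1[i] <- s1
    seq2[i] <- .read_seq(genome, pairs$chrom2[i], pairs$pos2[i],
                         pairs$strand2[i], rl)
  }
  qual <- strrep("I", rl)
  write_fq <- function(ids, seqs, path) {
    con <- .open_maybe_gz(path, "wt")
    on.exit(close(con))
    writeLines(as.vector(rbind(paste0("@", ids), seqs,
                               rep("+", length(ids)),
                               rep(qual, length(ids)))), con)
  }
  write_fq(pairs$read_id, seq1, fq1)
  write_fq(pairs$read_id, seq2, fq2)
  data.frame(read_id = pairs$read_id,
             truncated = !is.na(offsets),
             offset = offsets,
             post_trunc_len = ifelse(is.na(offsets), rl, offsets + keep_extra),
             stringsAsFactors = FALSE)
}

.sam_header <- function(genome) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
}

.sam_record <- function(id, chrom, pos5, strand, mapq, len) {
  flag <- if (strand == "-") 16L else 0L
  leftmost <- if (strand == "-") pos5 - len + 1L else pos5
  sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
          id, flag, chrom, leftmost + 1L, mapq, len,
          strrep("A", len), strrep("I", len))
}

#' Simulate aligned mate SAM files with planted artifacts
#'
#' Writes two single-end SAM files (minimal mandatory fields) containing
#' the valid pairs plus planted PCR duplicates, low-MAPQ mates,
#' self-circles, dangling ends, and re-ligation pairs at the configured
#' rates, with the exact planted category counts recorded so
#' [run_pair_filter()]'s report can be checked against truth.
#'
#' @param pairs Pair table from [simulate_pairs()].
#' @param config `sim_config`.
#' @param genome Simulated genome.
#' @param fends FEND table.
#' @param sam1,sam2 Output SAM paths.
#' @return Truth list with planted counts per category.
#' @export
simulate_sam <- function(pairs, config, genome, fends, sam1, sam2) {
  set.seed(config$seed + 3L)
  rl <- config$read_length
  n <- nrow(pairs)
  frag_tabs <- .fragments_from_fends(fends)

  rec1 <- list(); rec2 <- list()
  add_pair <- function(id, c1, p1, s1, c2, p2, s2, mapq1 = 44L, mapq2 = 44L) {
    rec1[[length(rec1) + 1L]] <<- .sam_record(id, c1, p1, s1, mapq1, rl)
    rec2[[length(rec2) + 1L]] <<- .sam_record(id, c2, p2, s2, mapq2, rl)
  }
  for (i in seq_len(n)) {
    add_pair(pairs$read_id[i], pairs$chrom1[i], pairs$pos1[i],
             pairs$strand1[i], pairs$chrom2[i], pairs$pos2[i],
             pairs$strand2[i])
  }

  n_dup <- round(config$dup_rate * n)
  if (n_dup > 0L) {
    src <- sample.int(n, n_dup, replace = FALSE)
    for (k in seq_len(n_dup)) {
      i <- src[k]
      # mates swapped between files half the time: still duplicates
      if (k %% 2L == 0L) {
        add_pair(sprintf("dup%05d", k), pairs$chrom2[i], pairs$pos2[i],
                 pairs$strand2[i], pairs$chrom1[i], pairs$pos1[i],
                 pairs$strand1[i])
      } else {
        add_pair(sprintf("dup%05d", k), pairs$chrom1[i], pairs$pos1[i],
                 pairs$strand1[i], pairs$chrom2[i], pairs$pos2[i],
                 pairs$strand2[i])
      }
    }
  }

  # roomy fragments for within-fragment artifact placement; sampled
  # without replacement so planted artifacts never collide into
  # accidental duplicates
  all_frags <- do.call(rbind, lapply(frag_tabs, function(f) f))
  used <- rep(FALSE, nrow(all_frags))
  pick_frag <- function(k, min_len, unique_frags = TRUE) {
    ok <- which(!used & all_frags$end - all_frags$start >= min_len)
    if (!unique_frags) {
      return(all_frags[sample(ok, k, replace = TRUE), , drop = FALSE])
    }
    if (length(ok) < k) stop("not enough roomy fragments for artifacts")
    sel <- sample(ok, k)
    used[sel] <<- TRUE
    all_frags[sel, , drop = FALSE]
  }
  n_sc <- round(config$self_circle_rate * n)
  if (n_sc > 0L) {
    fr <- pick_frag(n_sc, 2L * rl + 10L)
    for (k in seq_len(n_sc)) {
      add_pair(sprintf("sc%05d", k),
               fr$chrom[k], fr$start[k] + rl, "-",
               fr$chrom[k], fr$end[k] - rl - 1L, "+")
    }
  }
  n_de <- round(config$dangling_rate * n)
  if (n_de > 0L) {
    fr <- pick_frag(n_de, 2L * rl + 10L)
    for (k in seq_len(n_de)) {
      add_pair(sprintf("de%05d", k),
               fr$chrom[k], fr$start[k] + 2L, "+",
               fr$chrom[k], fr$end[k] - 3L, "-")
    }
  }
  n_rl <- round(config$religation_rate * n)
  if (n_rl > 0L) {
    adj <- do.call(rbind, lapply(names(frag_tabs), function(cn) {
      f <- frag_tabs[[cn]]
      if (nrow(f) < 2L) return(NULL)
      j <- seq_len(nrow(f) - 1L)
      ok <- f$end[j] - f$start[j] >= rl + 4L &
        f$end[j + 1L] - f$start[j + 1L] >= rl + 4L
      data.frame(chrom = cn, e1 = f$end[j][ok], s2 = f$start[j + 1L][ok])
    }))
    if (nrow(adj) < n_rl) stop("not enough adjacent fragments for re-ligations")
    sel <- adj[sample.int(nrow(adj), n_rl), , drop = FALSE]
    for (k in seq_len(n_rl)) {
      add_pair(sprintf("rl%05d", k),
               sel$chrom[k], sel$e1[k] - rl - 2L, "+",
               sel$chrom[k], sel$s2[k] + rl + 1L, "-")
    }
  }
  n_lm <- round(config$low_mapq_rate * n)
  if (n_lm > 0L) {
    # low-MAPQ pairs never reach duplicate removal, so fragments may repeat
    fr <- pick_frag(n_lm, 2L * rl + 10L, unique_frags = FALSE)
    fr2 <- pick_frag(n_lm, 2L * rl + 10L, unique_frags = FALSE)
    for (k in seq_len(n_lm)) {
      add_pair(sprintf("lm%05d", k),
               fr$chrom[k], fr$start[k] + rl, "-",
               fr2$chrom[k], fr2$start[k] + rl, "-",
               mapq1 = 10L)
    }
  }

  header <- .sam_header(genome)
  ord <- sample.int(length(rec1))  # shuffle record order
  writeLines(c(header, unlist(rec1)[ord]), sam1)
  writeLines(c(header, unlist(rec2)[ord]), sam2)
  list(valid = n, duplicate = n_dup, self_circle = n_sc,
       dangling_end = n_de, re_ligation = n_rl, low_mapq = n_lm)
}

#' Simulate an observed contact matrix with planted TAD blocks
#'
#' Poisson counts with cell mean
#' `depth * (1 + |i-j|)^(-alpha) * enrichment^[i,j in same block]`, the
#' standard power-law contact decay with block-diagonal domain enrichment.
#' Blocks default to a random tiling of the chromosome with 10-30 bin
#' domains.
#'
#' @param n_bins Number of bins.
#' @param blocks List of `c(start_bin, end_bin)` (1-based inclusive);
#'   NULL to tile randomly with sizes in `block_range`.
#' @param enrichment Within-block multiplier (default 5).
#' @param depth Mean count at distance 0 outside blocks (default 100).
#' @param alpha Decay exponent (default 1).
#' @param bin_size Bin size in bp (default 40000).
#' @param block_range Domain size range in bins.
#' @param seed Seed.
#' @param chrom Chromosome name.
#' @return List with `matrix` (`contact_matrix`, observed), `blocks`, and
#'   `boundaries` (bin indices, 1-based, of planted domain edges).
#' @export
simulate_tad_matrix <- function(n_bins = 150L, blocks = NULL, enrichment = 5,
                                depth = 100, alpha = 1, bin_size = 40000L,
                                block_range = c(10L, 30L), seed = 0L,
                                chrom = "chrSim") {
  set.seed(seed)
  if (is.null(blocks)) {
    blocks <- list()
    at <- 1L
    while (at <= n_bins - block_range[1L]) {
      len <- sample(block_range[1L]:block_range[2L], 1L)
      end <- min(at + len - 1L, n_bins)
      blocks[[length(blocks) + 1L]] <- c(at, end)
      at <- end + 1L
    }
  }
  lam <- depth * (1 + abs(outer(seq_len(n_bins), seq_len(n_bins), "-")))^(-alpha)
  for (blk in blocks) {
    sel <- blk[1L]:blk[2L]
    lam[sel, sel] <- lam[sel, sel] * enrichment
  }
  O <- matrix(0, n_bins, n_bins)
  up <- upper.tri(O, diag = TRUE)
  O[up] <- stats::rpois(sum(up), lam[up])
  O <- O + t(O) - diag(diag(O))
  bounds <- sort(unique(unlist(lapply(blocks, function(b) c(b[1L], b[2L] + 1L)))))
  list(matrix = contact_matrix(O, chrom, bin_size, "observed"),
       blocks = blocks, boundaries = bounds[bounds <= n_bins])
}
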