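#' In-silico restriction digestion of one chromosome
#'
#' Scans the top strand for exact, case-insensitive occurrences of the
#' enzyme's recognition site and cuts after `cut_offset` bases of each
#' occurrence. Because only palindromic sites are admitted, top-strand
#' scanning finds every cut. Fragments tile `[0, nchar(seq))` exactly; a
#' sequence with no site yields a single fragment.
#'
#' @param seq DNA sequence (character or `DNAString`).
#' @param enzyme Enzyme name or `restriction_enzyme`.
#' @param chrom Chromosome name to record.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `index` (0-based ordinal within the chromosome).
#' @examples
#' digest_sequence("TTTAAGCTTGGGAAGCTTCC", "HindIII", "toy")
#' @export
digest_sequence <- function(seq, enzyme, chrom = "chr1") {
  enzyme <- get_enzyme(enzyme)
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("empty sequence for chromosome ", chrom)
  L <- nchar(seq)
  m <- Biostrings::matchPattern(enzyme$site, Biostrings::DNAString(seq))
  cuts <- sort(unique(Biostrings::start(m) - 1L + enzyme$cut_offset))
  cuts <- cuts[cuts > 0L & cuts < L]
  bounds <- c(0L, cuts, L)
  data.frame(
    chrom = chrom,
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    index = seq_len(length(bounds) - 1L) - 1L,
    stringsAsFactors = FALSE
  )
}

# Window of sequence interior to the fragment, starting at the FEND
# coordinate and truncated at the fragment boundary. `fend` needs fields
# coord, side ("L"/"R") and fragment_length. Returns 1-based [from, to]
# (possibly empty) on the chromosome.
.fend_window <- function(fend, window) {
  len <- fend$fragment_length
  w <- min(window, len)
  if (identical(fend$side, "L")) {
    c(fend$coord + 1L, fend$coord + w)
  } else {
    c(fend$coord - w + 1L, fend$coord)
  }
}

#' GC content of the fragment interior adjoining a FEND
#'
#' Fraction of G/C among non-N bases in the `window` bases running from the
#' FEND coordinate into its fragment, truncated at the fragment boundary.
#' Returns the sentinel -1 when every base in the window is N (such FENDs
#' are excluded from correction learning).
#'
#' @param seq Chromosome sequence (character or `DNAString`).
#' @param fend List or one-row data.frame with `coord`, `side` ("L" or "R")
#'   and `fragment_length`.
#' @param window Window size in bp (> 0).
#' @return GC fraction in `[0, 1]`, or -1 for an all-N window.
#' @export
compute_gc <- function(seq, fend, window = 200L) {
  stopifnot(window > 0L)
  seq <- toupper(as.character(seq))
  rng <- .fend_window(fend, window)
  if (rng[2L] < rng[1L]) return(-1)
  bases <- strsplit(substr(seq, rng[1L], rng[2L]), "", fixed = TRUE)[[1L]]
  informative <- bases != "N"
  if (!any(informative)) return(-1)
  sum(bases %in% c("G", "C")) / sum(informative)
}

# Multiset counts of all k-mers on the forward strand of every chromosome,
# keyed for fast joins.
.genome_kmer_counts <- function(genome, k) {
  kmers <- unlist(lapply(genome, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  dt <- data.table::data.table(kmer = kmers)
  out <- dt[, list(n = .N), by = "kmer"]
  data.table::setkeyv(out, "kmer")
  out
}

# Occurrence count on both strands for query k-mers, given forward-strand
# counts. A palindromic k-mer is counted once per locus.
.kmer_both_strand_counts <- function(queries, counts) {
  fwd <- counts[data.table::data.table(kmer = queries), on = "kmer"]$n
  fwd[is.na(fwd)] <- 0L
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(queries)))
  rev <- counts[data.table::data.table(kmer = rc), on = "kmer"]$n
  rev[is.na(rev)] <- 0L
  rev[rc == queries] <- 0L
  fwd + rev
}

#' Mappability of the fragment interior adjoining a FEND
#'
#' Fraction of the k-mers whose start lies in the `window` bases interior to
#' the fragment (from the FEND coordinate, truncated at the fragment
#' boundary) that occur exactly once in the whole genome, counting both
#' strands. K-mers containing N, and k-mers running past the chromosome end,
#' count as non-unique. A window admitting no k-mer start yields 0.
#'
#' @param genome Named character vector or `DNAStringSet` of chromosomes.
#' @param fend As in [compute_gc()], plus `chrom`.
#' @param k K-mer length (`k <= window`).
#' @param window Window size in bp.
#' @return Unique-k-mer fraction in `[0, 1]`.
#' @export
compute_mappability <- function(genome, fend, k = 50L, window = 500L) {
  stopifnot(k <= window)
  genome <- .as_genome(genome)
  counts <- .genome_kmer_counts(genome, k)
  .fend_mappability(genome, fend, k, window, counts)
}

.fend_mappability <- function(genome, fend, k, window, counts) {
  seq <- genome[[fend$chrom]]
  rng <- .fend_window(fend, window)
  if (rng[2L] < rng[1L]) return(0)
  starts <- rng[1L]:rng[2L]
  n_total <- length(starts)
  starts <- starts[starts + k - 1L <= nchar(seq)]
  if (length(starts) == 0L) return(0)
  q <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", q, fixed = TRUE)
  uniq <- logical(length(q))
  if (any(ok)) uniq[ok] <- .kmer_both_strand_counts(q[ok], counts) == 1L
  sum(uniq) / n_total
}

# Vectorised GC over all FENDs of one chromosome (same contract as
# compute_gc).
.batch_gc <- function(seq, fends, window) {
  w <- pmin(window, fends$fragment_length)
  from <- ifelse(fends$side == "L", fends$coord + 1L, fends$coord - w + 1L)
  to <- ifelse(fends$side == "L", fends$coord + w, fends$coord)
  win <- substring(seq, from, to)
  n_gc <- nchar(gsub("[^GC]", "", win))
  n_inf <- nchar(gsub("N", "", win))
  ifelse(n_inf == 0L, -1, n_gc / pmax(n_inf, 1L))
}

# Vectorised k-mer-uniqueness mappability over all FENDs of one chromosome.
.batch_mappability <- function(seq, fends, k, window, counts) {
  L <- nchar(seq)
  w <- pmin(window, fends$fragment_length)
  from <- ifelse(fends$side == "L", fends$coord + 1L, fends$coord - w + 1L)
  to <- ifelse(fends$side == "L", fends$coord + w, fends$coord)
  n_total <- pmax(to - from + 1L, 0L)
  starts <- unlist(lapply(seq_len(nrow(fends)), function(i) {
    if (n_total[i] == 0L) return(integer(0))
    s <- from[i]:to[i]
    s[s + k - 1L <= L]
  }))
  owner <- rep.int(seq_len(nrow(fends)),
                   vapply(seq_len(nrow(fends)), function(i) {
                     if (n_total[i] == 0L) return(0L)
                     sum(from[i]:to[i] + k - 1L <= L)
                   }, integer(1L)))
  if (length(starts) == 0L) return(rep(0, nrow(fends)))
  q <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", q, fixed = TRUE)
  uniq <- logical(length(q))
  if (any(ok)) uniq[ok] <- .kmer_both_strand_counts(q[ok], counts) == 1L
  agg <- rowsum(as.numeric(uniq), owner)
  res <- rep(0, nrow(fends))
  res[as.integer(rownames(agg))] <- agg[, 1L]
  ifelse(n_total > 0L, res / pmax(n_total, 1L), 0)
}

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet") || inherits(genome, "XStringSet")) {
    genome <- as.character(genome)
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome chromosomes must be named")
  }
  # keep only the first word of FASTA headers
  names(genome) <- sub("\\s.*$", "", names(genome))
  vapply(genome, function(s) toupper(as.character(s)), character(1L))
}

#' Build the annotated fragment-end (FEND) table for a genome
#'
#' Digests every chromosome and emits two FENDs per fragment (its left and
#' right ends), annotated with fragment length, interior GC content and
#' interior k-mer mappability. These are the per-FEND features the
#' explicit-factor correction model is learned from. Chromosomes are
#' normalized to name order, so the result is independent of input order.
#'
#' @param genome Named character vector, `DNAStringSet`, or path to a FASTA
#'   file.
#' @param enzyme Enzyme name or `restriction_enzyme`.
#' @param gc_window GC window in bp (default 200).
#' @param map_k Mappability k-mer length (default 50).
#' @param map_window Mappability window in bp (default 500).
#' @return `data.frame` with columns `chrom`, `coord`, `side` ("L"/"R"),
#'   `fragment_index`, `fragment_length`, `gc`, `mappability`, `fend_id`
#'   (1-based, in chrom/coord order).
#' @export
build_fend_table <- function(genome, enzyme, gc_window = 200L,
                             map_k = 50L, map_window = 500L) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
      file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  genome <- .as_genome(genome)
  if (length(genome) == 0L) stop("empty genome")
  genome <- genome[order(names(genome))]
  enzyme <- get_enzyme(enzyme)

  counts <- .genome_kmer_counts(genome, map_k)
  per_chrom <- lapply(names(genome), function(cn) {
    frags <- digest_sequence(genome[[cn]], enzyme, cn)
    n <- nrow(frags)
    fends <- data.frame(
      chrom = cn,
      coord = as.integer(c(rbind(frags$start, frags$end))),
      side = rep(c("L", "R"), n),
      fragment_index = rep(frags$index, each = 2L),
      fragment_length = rep(frags$end - frags$start, each = 2L),
      stringsAsFactors = FALSE
    )
    fends$gc <- .batch_gc(genome[[cn]], fends, gc_window)
    fends$mappability <- .batch_mappability(genome[[cn]], fends, map_k,
                                            map_window, counts)
    fends[order(fends$coord, fends$fragment_index), ]
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  out$fend_id <- seq_len(nrow(out))
  out
}

.fend_bed_cols <- c("chrom", "start", "end", "fend_id", "fragment_length",
                    "gc", "mappability", "side", "fragment_index")

#' Write / read the FEND table as BED-style text
#'
#' 0-based half-open coordinates; one line per FEND with columns chrom,
#' start, end, fend_id, fragment_length, gc, mappability, side,
#' fragment_index. `read_fend_bed(write_fend_bed(x))` returns `x`.
#'
#' @param fends FEND table from [build_fend_table()].
#' @param path Output file.
#' @return `write_fend_bed` returns `path` invisibly; `read_fend_bed`
#'   returns the FEND table.
#' @export
write_fend_bed <- function(fends, path) {
  lines <- paste0("#", paste(.fend_bed_cols, collapse = "\t"))
  if (nrow(fends) > 0L) {
    body <- paste(fends$chrom, fends$coord, fends$coord + 1L, fends$fend_id,
                  fends$fragment_length, as.character(fends$gc),
                  as.character(fends$mappability), fends$side,
                  fends$fragment_index, sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fend_bed
#' @export
read_fend_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  body <- lines[!startsWith(lines, "#")]
  empty <- data.frame(chrom = character(0), coord = integer(0),
                      side = character(0), fragment_index = integer(0),
                      fragment_length = integer(0), gc = numeric(0),
                      mappability = numeric(0), fend_id = integer(0),
                      stringsAsFactors = FALSE)
  if (length(body) == 0L) return(empty)
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    lineno <- i + 1L  # header is line 1
    if (length(p) != length(.fend_bed_cols)) {
      stop("malformed FEND BED line ", lineno, ": expected ",
           length(.fend_bed_cols), " fields, got ", length(p))
    }
    nums <- suppressWarnings(as.numeric(p[c(2, 3, 4, 5, 6, 7, 9)]))
    if (anyNA(nums)) {
      stop("malformed FEND BED line ", lineno, ": non-numeric field")
    }
  }
  m <- do.call(rbind, parts)
  data.frame(
    chrom = m[, 1L],
    coord = as.integer(m[, 2L]),
    side = m[, 8L],
    fragment_index = as.integer(m[, 9L]),
    fragment_length = as.integer(m[, 5L]),
    gc = as.numeric(m[, 6L]),
    mappability = as.numeric(m[, 7L]),
    fend_id = as.integer(m[, 4L]),
    stringsAsFactors = FALSE
  )
}

# Reconstruct per-chromosome fragment tables from a FEND table.
.fragments_from_fends <- function(fends) {
  left <- fends[fends$side == "L", ]
  split(
    data.frame(chrom = left$chrom, start = left$coord,
               end = left$coord + left$fragment_length,
               index = left$fragment_index, stringsAsFactors = FALSE),
    left$chrom
  )
}
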