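#' Read independently aligned mates from SAM/BAM
#'
#' Loads one mate file (each Hi-C mate is aligned single-end, so each file
#' is independent) into a table of alignments. SAM input is converted to
#' BAM in a temporary file first. The 5' mapped position — the
#' ligation-proximal end used for fragment assignment — is `pos` for +
#' strand reads and `pos + reference_width - 1` for - strand reads.
#'
#' @param path SAM or BAM file.
#' @return `data.frame` with `read_id`, `chrom`, `pos` (0-based leftmost),
#'   `pos5` (0-based 5' end), `strand`, `mapq`, `mapped`.
#' @export
read_aligned_mates <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar")
  ))[[1L]]
  mapped <- !bitwAnd(res$flag, 4L) & !is.na(res$pos)
  width <- rep(NA_integer_, length(res$qname))
  if (any(mapped)) {
    width[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
      res$cigar[mapped])
  }
  pos0 <- res$pos - 1L
  strand <- as.character(res$strand)
  pos5 <- ifelse(strand == "-", pos0 + width - 1L, pos0)
  data.frame(
    read_id = res$qname,
    chrom = as.character(res$rname),
    pos = pos0,
    pos5 = as.integer(pos5),
    strand = strand,
    mapq = res$mapq,
    mapped = mapped,
    stringsAsFactors = FALSE
  )
}

#' Keep mapped mates with sufficient mapping quality
#'
#' Retains exactly the mates that are mapped and have `mapq >= threshold`
#' (the conventional threshold is 30, so MAPQ 30 is kept and MAPQ 29
#' dropped); order is preserved.
#'
#' @param mates Table from [read_aligned_mates()].
#' @param threshold Minimum MAPQ (default 30).
#' @return Filtered table.
#' @export
filter_mapq <- function(mates, threshold = 30L) {
  mates[mates$mapped & !is.na(mates$mapq) & mates$mapq >= threshold, ,
        drop = FALSE]
}

#' Pair mates by read identifier
#'
#' Emits one pair per read id present in both (already filtered) mate
#' tables; singletons are dropped and counted. A duplicate read id within
#' one file is an error.
#'
#' @param mates1,mates2 Filtered mate tables.
#' @return List with `pairs` (data.frame of `<col>1`/`<col>2` columns) and
#'   `n_singletons`.
#' @export
pair_mates <- function(mates1, mates2) {
  for (m in list(mates1, mates2)) {
    if (anyDuplicated(m$read_id)) {
      stop("duplicate read_id within one mate file: ",
           m$read_id[duplicated(m$read_id)][1L])
    }
  }
  common <- intersect(mates1$read_id, mates2$read_id)
  i1 <- match(common, mates1$read_id)
  i2 <- match(common, mates2$read_id)
  pairs <- data.frame(
    read_id = common,
    chrom1 = mates1$chrom[i1], pos1 = mates1$pos5[i1],
    strand1 = mates1$strand[i1],
    chrom2 = mates2$chrom[i2], pos2 = mates2$pos5[i2],
    strand2 = mates2$strand[i2],
    stringsAsFactors = FALSE
  )
  list(pairs = pairs,
       n_singletons = (nrow(mates1) - length(common)) +
                      (nrow(mates2) - length(common)))
}

#' Assign a mapped position to its restriction fragment and FEND
#'
#' Locates the fragment containing the 5' position (binary search over the
#' fragment tiling) and picks the fragment end the read points toward: the
#' downstream (right) end for + strand reads, the upstream (left) end for -
#' strand reads.
#'
#' @param pos 0-based 5' position(s).
#' @param strand "+" or "-" (recycled).
#' @param fragments Fragment table for one chromosome (from
#'   [digest_sequence()]).
#' @param fends FEND table rows for the same chromosome (optional; needed
#'   for `fend_id`).
#' @return `data.frame` with `fragment_index` and `fend_id` (NA if `fends`
#'   not given).
#' @export
assign_to_fragment <- function(pos, strand, fragments, fends = NULL) {
  chrom_len <- max(fragments$end)
  if (any(pos < 0L | pos >= chrom_len)) {
    stop("position beyond chromosome end (length ", chrom_len, ")")
  }
  idx <- findInterval(pos, fragments$start)
  frag <- fragments$index[idx]
  side <- ifelse(strand == "+", "R", "L")
  fend_id <- rep(NA_integer_, length(pos))
  if (!is.null(fends)) {
    key <- paste(frag, side)
    lut <- stats::setNames(fends$fend_id, paste(fends$fragment_index, fends$side))
    fend_id <- unname(lut[key])
  }
  data.frame(fragment_index = frag, fend_id = fend_id)
}

#' Classify a read pair as valid or as a ligation artifact
#'
#' Applies the standard Hi-C artifact taxonomy: mates in the same fragment
#' with convergent strands (+ mate 5' of the - mate) are dangling ends
#' (unligated fragments); same fragment with divergent or equal strands are
#' self-circles (circularized fragments); adjacent fragments on the same
#' chromosome are re-ligation products; everything else is a valid contact.
#'
#' @param chrom1,chrom2 Chromosomes.
#' @param pos1,pos2 0-based 5' positions.
#' @param strand1,strand2 Strands.
#' @param frag1,frag2 Fragment indices.
#' @return Character vector of categories: "valid", "self_circle",
#'   "dangling_end", "re_ligation".
#' @export
classify_pair <- function(chrom1, pos1, strand1, frag1,
                          chrom2, pos2, strand2, frag2) {
  same_chrom <- chrom1 == chrom2
  same_frag <- same_chrom & frag1 == frag2
  adjacent <- same_chrom & abs(frag1 - frag2) == 1L
  plus_pos <- ifelse(strand1 == "+", pos1, pos2)
  minus_pos <- ifelse(strand1 == "+", pos2, pos1)
  convergent <- strand1 != strand2 & plus_pos <= minus_pos
  out <- rep("valid", length(chrom1))
  out[adjacent] <- "re_ligation"
  out[same_frag & convergent] <- "dangling_end"
  out[same_frag & !convergent] <- "self_circle"
  out
}

# Canonical duplicate key: the two (chrom,pos,strand) triplets in sorted
# order, so mates swapped between files still collide.
.dup_key <- function(pairs) {
  a <- paste(pairs$chrom1, pairs$pos1, pairs$strand1, sep = ":")
  b <- paste(pairs$chrom2, pairs$pos2, pairs$strand2, sep = ":")
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Remove PCR duplicates among read pairs
#'
#' Pairs sharing both mate coordinates (chromosome, 5' position, strand),
#' after putting the two mates of each pair in canonical order, are
#' duplicates; the first encountered survives.
#'
#' @param pairs Pair table with `chrom/pos/strand` columns for both mates.
#' @return List with `pairs` (deduplicated) and `n_duplicates`.
#' @export
remove_duplicates <- function(pairs) {
  dup <- duplicated(.dup_key(pairs))
  list(pairs = pairs[!dup, , drop = FALSE], n_duplicates = sum(dup))
}

#' Filter two aligned mate files into a valid-pairs table
#'
#' Full filtering pipeline: MAPQ filter on each mate file, pairing by read
#' id, fragment/FEND assignment, PCR-duplicate removal, then artifact
#' classification. Self-circles and dangling ends are always removed;
#' re-ligation (adjacent-fragment) pairs are removed by default.
#' Inter-chromosomal valid pairs are kept in the table (the matrix builder
#' ignores them).
#'
#' @param bam1,bam2 SAM/BAM files for mate 1 and mate 2.
#' @param fends FEND table (or path to a FEND BED file).
#' @param mapq MAPQ threshold (default 30).
#' @param remove_religation Drop adjacent-fragment pairs (default TRUE).
#' @return List with `pairs` (valid-pair table: chrom1, pos1, strand1,
#'   fend1, chrom2, pos2, strand2, fend2) and `report` (a `filter_report`).
#' @export
run_pair_filter <- function(bam1, bam2, fends, mapq = 30L,
                            remove_religation = TRUE) {
  if (is.character(fends)) fends <- read_fend_bed(fends)
  mates1 <- read_aligned_mates(bam1)
  mates2 <- read_aligned_mates(bam2)
  f1 <- filter_mapq(mates1, mapq)
  f2 <- filter_mapq(mates2, mapq)
  paired <- pair_mates(f1, f2)
  pairs <- paired$pairs

  frag_tabs <- .fragments_from_fends(fends)
  fend_tabs <- split(fends, fends$chrom)
  missing <- setdiff(unique(c(pairs$chrom1, pairs$chrom2)), names(frag_tabs))
  if (length(missing) > 0L) {
    stop("chromosome(s) absent from FEND table: ", paste(missing, collapse = ", "))
  }
  assign_one <- function(chrom, pos, strand) {
    frag <- integer(length(pos)); fid <- integer(length(pos))
    for (cn in unique(chrom)) {
      sel <- chrom == cn
      a <- assign_to_fragment(pos[sel], strand[sel], frag_tabs[[cn]],
                              fend_tabs[[cn]])
      frag[sel] <- a$fragment_index
      fid[sel] <- a$fend_id
    }
    list(frag = frag, fend = fid)
  }
  if (nrow(pairs) > 0L) {
    a1 <- assign_one(pairs$chrom1, pairs$pos1, pairs$strand1)
    a2 <- assign_one(pairs$chrom2, pairs$pos2, pairs$strand2)
    pairs$frag1 <- a1$frag; pairs$fend1 <- a1$fend
    pairs$frag2 <- a2$frag; pairs$fend2 <- a2$fend
  } else {
    pairs$frag1 <- pairs$fend1 <- pairs$frag2 <- pairs$fend2 <- integer(0)
  }

  dd <- remove_duplicates(pairs)
  pairs <- dd$pairs
  category <- if (nrow(pairs) > 0L) {
    classify_pair(pairs$chrom1, pairs$pos1, pairs$strand1, pairs$frag1,
                  pairs$chrom2, pairs$pos2, pairs$strand2, pairs$frag2)
  } else character(0)
  keep <- category == "valid" |
    (!remove_religation & category == "re_ligation")
  valid <- pairs[keep, c("chrom1", "pos1", "strand1", "fend1",
                         "chrom2", "pos2", "strand2", "fend2"), drop = FALSE]
  rownames(valid) <- NULL

  report <- structure(list(
    total_mates1 = nrow(mates1), total_mates2 = nrow(mates2),
    mapq_pass1 = nrow(f1), mapq_pass2 = nrow(f2),
    paired = nrow(paired$pairs), singletons = paired$n_singletons,
    duplicate = dd$n_duplicates,
    self_circle = sum(category == "self_circle"),
    dangling_end = sum(category == "dangling_end"),
    re_ligation = sum(category == "re_ligation"),
    valid = sum(category == "valid")
  ), class = "filter_report")
  list(pairs = valid, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (f in names(x)) cat(sprintf("  %-14s %d\n", f, x[[f]]))
  invisible(x)
}

#' Write / read a valid-pairs table
#'
#' Tab-separated text (optionally gzip by extension) with a `#`-prefixed
#' header line; columns chrom1, pos1, strand1, fend1, chrom2, pos2,
#' strand2, fend2.
#'
#' @param pairs Valid-pairs table.
#' @param path Output file (`.gz` for gzip).
#' @export
write_pairs <- function(pairs, path) {
  con <- .open_maybe_gz(path, "wt")
  on.exit(close(con))
  cols <- c("chrom1", "pos1", "strand1", "fend1",
            "chrom2", "pos2", "strand2", "fend2")
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(pairs) > 0L) {
    writeLines(do.call(paste, c(unname(pairs[cols]), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  con <- .open_maybe_gz(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  body <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.frame(chrom1 = character(0), pos1 = integer(0),
                      strand1 = character(0), fend1 = integer(0),
                      chrom2 = character(0), pos2 = integer(0),
                      strand2 = character(0), fend2 = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  data.frame(
    chrom1 = m[, 1L], pos1 = as.integer(m[, 2L]), strand1 = m[, 3L],
    fend1 = as.integer(m[, 4L]),
    chrom2 = m[, 5L], pos2 = as.integer(m[, 6L]), strand2 = m[, 7L],
    fend2 = as.integer(m[, 8L]),
    stringsAsFactors = FALSE
  )
}
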