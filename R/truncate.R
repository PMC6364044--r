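#' Pre-truncate a read at a ligation junction
#'
#' If the reconstructed ligation junction occurs in the read, everything
#' from the partner fragment onwards is removed: the read keeps its 5'
#' prefix through the first `len(site) - cut_offset` bases of the junction,
#' i.e. the portion contributed by the read's own fragment's restriction
#' site. The search is exact-match, case-insensitive, first occurrence only;
#' the quality string is truncated alongside. Idempotent.
#'
#' @param read_seq Read sequence.
#' @param read_qual Quality string (same length).
#' @param enzyme Enzyme name or `restriction_enzyme`.
#' @return List with `seq`, `qual`, `was_truncated`.
#' @export
truncate_read <- function(read_seq, read_qual, enzyme) {
  if (nchar(read_seq) != nchar(read_qual)) {
    stop("sequence and quality lengths differ (", nchar(read_seq), " vs ",
         nchar(read_qual), ")")
  }
  enzyme <- get_enzyme(enzyme)
  junction <- make_ligation_junction(enzyme)
  p <- regexpr(junction, toupper(read_seq), fixed = TRUE)
  if (p < 0L) {
    return(list(seq = read_seq, qual = read_qual, was_truncated = FALSE))
  }
  keep <- (p - 1L) + (nchar(enzyme$site) - enzyme$cut_offset)
  list(seq = substr(read_seq, 1L, keep),
       qual = substr(read_qual, 1L, keep),
       was_truncated = TRUE)
}

# Vectorised core of truncate_read for a chunk of records.
.truncate_chunk <- function(seqs, quals, junction, keep_extra) {
  p <- regexpr(junction, toupper(seqs), fixed = TRUE)
  hit <- p > 0L
  keep <- ifelse(hit, (p - 1L) + keep_extra, nchar(seqs))
  list(seq = substr(seqs, 1L, keep), qual = substr(quals, 1L, keep),
       truncated = hit)
}

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Pre-truncate a FASTQ file at ligation junctions
#'
#' Streams the file in fixed-size record chunks (bounded memory), applying
#' [truncate_read()] to every record, and reports truncation statistics and
#' the post-truncation read-length histogram. Plain and gzip FASTQ are both
#' accepted; output compression follows the output extension. Mate files
#' are processed independently.
#'
#' @param in_path Input FASTQ (optionally .gz).
#' @param out_path Output FASTQ (optionally .gz).
#' @param enzyme Enzyme name or `restriction_enzyme`.
#' @param chunk_size Records per chunk.
#' @return A `truncation_report` list: `total_reads`, `truncated_reads`,
#'   `percent_truncated`, `length_histogram` (named count vector).
#' @export
pretruncate_fastq <- function(in_path, out_path, enzyme, chunk_size = 100000L) {
  enzyme <- get_enzyme(enzyme)
  junction <- make_ligation_junction(enzyme)
  keep_extra <- nchar(enzyme$site) - enzyme$cut_offset
  con_in <- .open_maybe_gz(in_path, "rt")
  on.exit(close(con_in), add = TRUE)
  con_out <- .open_maybe_gz(out_path, "wt")
  on.exit(close(con_out), add = TRUE)

  total <- 0L
  truncated <- 0L
  hist <- integer(0)
  repeat {
    lines <- readLines(con_in, n = 4L * chunk_size)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L) {
      stop("FASTQ ", in_path, " is truncated mid-record (", length(lines),
           " trailing lines)")
    }
    idx <- seq(1L, length(lines), by = 4L)
    heads <- lines[idx]
    seqs <- lines[idx + 1L]
    quals <- lines[idx + 3L]
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad) > 0L) {
      stop("FASTQ record ", total + bad[1L], " (", heads[bad[1L]],
           "): sequence and quality lengths differ")
    }
    res <- .truncate_chunk(seqs, quals, junction, keep_extra)
    out <- character(4L * length(idx))
    out[idx] <- heads
    out[idx + 1L] <- res$seq
    out[idx + 2L] <- lines[idx + 2L]
    out[idx + 3L] <- res$qual
    writeLines(out, con_out)

    total <- total + length(idx)
    truncated <- truncated + sum(res$truncated)
    h <- table(nchar(res$seq))
    lens <- union(names(hist), names(h))
    merged <- stats::setNames(integer(length(lens)), lens)
    merged[names(hist)] <- hist
    merged[names(h)] <- merged[names(h)] + as.integer(h)
    hist <- merged
  }
  hist <- hist[order(as.integer(names(hist)))]
  structure(list(
    total_reads = total,
    truncated_reads = truncated,
    percent_truncated = if (total > 0L) 100 * truncated / total else 0,
    length_histogram = hist
  ), class = "truncation_report")
}

#' @export
print.truncation_report <- function(x, ...) {
  cat(sprintf("<truncation_report> %d reads, %d truncated (%.2f%%)\n",
              x$total_reads, x$truncated_reads, x$percent_truncated))
  invisible(x)
}
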