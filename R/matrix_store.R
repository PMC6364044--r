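# Tokens reserved for O/E sentinels in stored streams.
.TOK_NA_EXPECTED <- "na_expected"
.TOK_NA_OBSERVED <- "na_observed"

# Upper triangle (diagonal included) in row-major order.
.upper_row_major <- function(m) {
  t(m)[lower.tri(m, diag = TRUE)]
}

#' Run-length encode a symmetric matrix's upper triangle
#'
#' A symmetric n x n matrix is reduced to its upper triangle (diagonal
#' included) read row-major — n(n+1)/2 values — and every maximal run of k
#' consecutive zeros is collapsed to the single integer -k. For sparse
#' contact matrices this combination of symmetry and zero-run compression
#' shrinks storage to a small fraction of the dense size. Sentinel entries
#' (NA values of an oe_log2 matrix) are preserved as reserved tokens and
#' never merged into zero runs.
#'
#' @param matrix A `contact_matrix` or plain symmetric numeric matrix.
#' @param precision Significant digits for non-integer values (default 6).
#' @return Character vector: the encoded stream, one token per element.
#' @export
encode_triangular <- function(matrix, precision = 6L) {
  sent <- NULL
  role <- "normalized"
  if (inherits(matrix, "contact_matrix")) {
    sent <- matrix$sentinel
    role <- matrix$role
    matrix <- matrix$values
  }
  .check_symmetric(matrix)
  vals <- .upper_row_major(matrix)
  tokens <- if (role == "observed") {
    format(as.integer(round(vals)), scientific = FALSE, trim = TRUE)
  } else {
    tok <- as.character(signif(vals, precision))
    # a negative value printed as a bare integer would collide with a
    # zero-run token; force a decimal point on those
    bare_neg <- !is.na(vals) & grepl("^-[0-9]+$", tok)
    tok[bare_neg] <- paste0(tok[bare_neg], ".0")
    tok
  }
  if (!is.null(sent)) {
    sv <- .upper_row_major(sent)
    tokens[sv == 1L] <- .TOK_NA_EXPECTED
    tokens[sv == 2L] <- .TOK_NA_OBSERVED
  } else if (anyNA(vals)) {
    stop("NA entries without a sentinel matrix; cannot encode")
  }
  is_zero <- !is.na(vals) & vals == 0 &
    !(tokens %in% c(.TOK_NA_EXPECTED, .TOK_NA_OBSERVED))
  r <- rle(is_zero)
  out <- character(0)
  pos <- 1L
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]
    if (r$values[k]) {
      out <- c(out, as.character(-len))
    } else {
      out <- c(out, tokens[pos:(pos + len - 1L)])
    }
    pos <- pos + len
  }
  out
}

#' Decode a triangular run-length stream back into a symmetric matrix
#'
#' Inverse of [encode_triangular()]. Negative integers -k expand to k
#' zeros; the expanded length must be a triangular number n(n+1)/2 (and
#' must match `expect_n` when given). Sentinel tokens decode to NA with
#' the corresponding sentinel code.
#'
#' @param stream Character (or numeric) token vector.
#' @param expect_n Optional expected matrix dimension.
#' @return List with `values` (symmetric matrix) and `sentinel` (integer
#'   matrix, NULL when no sentinel tokens occur).
#' @export
decode_triangular <- function(stream, expect_n = NULL) {
  stream <- as.character(stream)
  is_sent <- stream %in% c(.TOK_NA_EXPECTED, .TOK_NA_OBSERVED)
  num <- suppressWarnings(as.numeric(stream))
  if (any(is.na(num) & !is_sent)) {
    stop("malformed stream token: ", stream[which(is.na(num) & !is_sent)[1L]])
  }
  # zero-run tokens are bare negative integers; negative values carry a
  # decimal point or exponent
  is_run <- !is_sent & grepl("^-[0-9]+$", stream)
  if (any(is_run & num == 0)) stop("run token -0 is not allowed")
  reps <- rep(1, length(stream))
  reps[is_run] <- -num[is_run]
  vals <- num
  vals[is_run] <- 0
  expanded <- rep(vals, reps)
  codes <- rep(ifelse(stream == .TOK_NA_EXPECTED, 1L,
                      ifelse(stream == .TOK_NA_OBSERVED, 2L, 0L)), reps)
  L <- length(expanded)
  n <- (sqrt(8 * L + 1) - 1) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("expanded length ", L, " is not a triangular number")
  }
  n <- as.integer(round(n))
  if (!is.null(expect_n) && n != expect_n) {
    stop("decoded dimension ", n, " does not match expected ", expect_n)
  }
  tM <- matrix(0, n, n); tM[lower.tri(tM, diag = TRUE)] <- expanded
  M <- t(tM)
  tS <- matrix(0L, n, n); tS[lower.tri(tS, diag = TRUE)] <- codes
  S <- t(tS)
  # mirror upper triangle down
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  M[S != 0L] <- NA_real_
  list(values = M, sentinel = if (any(S != 0L)) S else NULL)
}

#' Write / read a contact matrix in compressed triangular text format
#'
#' One token per line, preceded by a self-describing header line
#' `#hicforge triangular n=<n> bin=<bp> chrom=<name> role=<role>`;
#' `headerless = TRUE` omits it (`read_matrix_txt` then needs the metadata
#' as arguments). A `.gz` extension gzips the file.
#'
#' @param matrix `contact_matrix`.
#' @param path Output file (`.gz` for gzip).
#' @param precision Significant digits for non-integer values.
#' @param headerless Omit the header line.
#' @export
write_matrix_txt <- function(matrix, path, precision = 6L,
                             headerless = FALSE) {
  stream <- encode_triangular(matrix, precision)
  con <- .open_maybe_gz(path, "wt")
  on.exit(close(con))
  if (!headerless) {
    writeLines(sprintf("#hicforge triangular n=%d bin=%d chrom=%s role=%s",
                       matrix$n_bins, matrix$bin_size, matrix$chrom,
                       matrix$role), con)
  }
  writeLines(stream, con)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @param chrom,bin_size,role Metadata for headerless files.
#' @export
read_matrix_txt <- function(path, chrom = NULL, bin_size = NULL, role = NULL) {
  con <- .open_maybe_gz(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- NULL
  if (length(lines) > 0L && startsWith(lines[1L], "#hicforge triangular")) {
    h <- lines[1L]
    pick <- function(key) sub(paste0(".* ", key, "=([^ ]+).*"), "\\1", h)
    n <- as.integer(pick("n"))
    bin_size <- as.integer(pick("bin"))
    chrom <- pick("chrom")
    role <- pick("role")
    lines <- lines[-1L]
  }
  if (is.null(bin_size) || is.null(chrom) || is.null(role)) {
    stop("headerless matrix file needs chrom, bin_size and role arguments")
  }
  dec <- decode_triangular(lines[nzchar(lines)], expect_n = n)
  contact_matrix(dec$values, chrom, bin_size, role, sentinel = dec$sentinel)
}

#' Write / read TAD coordinates
#'
#' One domain per line, tab-separated start and end in bp (0-based
#' half-open). Domains are sorted on write; overlapping domains are an
#' error.
#'
#' @param tads `data.frame` with `start`, `end` columns (bp).
#' @param path Output file.
#' @export
write_tads <- function(tads, path) {
  tads <- tads[order(tads$start), , drop = FALSE]
  if (nrow(tads) > 1L && any(tads$start[-1L] < tads$end[-nrow(tads)])) {
    stop("overlapping TADs cannot be written")
  }
  if (any(tads$start >= tads$end)) stop("TAD with start >= end")
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  writeLines(if (nrow(tads) > 0L) paste(fmt(tads$start), fmt(tads$end),
                                        sep = "\t")
             else character(0), path)
  invisible(path)
}

#' @rdname write_tads
#' @export
read_tads <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(start = as.numeric(m[, 1L]), end = as.numeric(m[, 2L]))
}

#' Write / read a per-bin track (DI values or HMM states)
#'
#' One value per line in bin order; NA/NaN sentinels are written as "nan"
#' and read back as NA. A non-numeric line is an error naming the line.
#'
#' @param values Numeric vector.
#' @param path Output file.
#' @param precision Significant digits.
#' @export
write_track <- function(values, path, precision = 6L) {
  out <- as.character(ifelse(is.na(values), "nan",
                             as.character(signif(values, precision))))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- rep(NA_real_, length(lines))
  is_nan <- tolower(lines) %in% c("nan", "na")
  num <- suppressWarnings(as.numeric(lines[!is_nan]))
  if (anyNA(num)) {
    bad <- which(!is_nan)[which(is.na(num))[1L]]
    stop("non-numeric track value at line ", bad, ": ", lines[bad])
  }
  out[!is_nan] <- num
  out
}
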