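#' Contact matrix container
#'
#' A square symmetric per-chromosome matrix of contact values at a fixed
#' bin size, tagged with its role in the pipeline: `observed` (integer
#' counts), `correction` (summed correction weights, E), `normalized`
#' (N = O/E) or `oe_log2` (log2 observed/expected). For `oe_log2`,
#' undefined entries are NA and a parallel integer `sentinel` matrix
#' distinguishes bins with no expected contacts (1, no FENDs) from bins
#' with expected but no observed contacts (2).
#'
#' @param values Square symmetric numeric matrix.
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param role One of "observed", "correction", "normalized", "oe_log2".
#' @param sentinel Optional integer matrix (0 = none, 1 = no expected,
#'   2 = no observed), only for role "oe_log2".
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(values, chrom, bin_size,
                           role = c("observed", "correction", "normalized",
                                    "oe_log2"),
                           sentinel = NULL) {
  role <- match.arg(role)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  .check_symmetric(values)
  if (role == "observed" && any(values[!is.na(values)] %% 1 != 0)) {
    stop("observed matrix entries must be integer counts")
  }
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 n_bins = nrow(values), values = values, role = role,
                 sentinel = sentinel),
            class = "contact_matrix")
}

.check_symmetric <- function(m, rtol = 1e-9) {
  v <- m[!is.na(m)]
  d <- abs(m - t(m))
  d <- d[!is.na(d)]
  scale <- max(abs(v), 1)
  if (length(d) > 0L && max(d) > rtol * scale) {
    stop("matrix is not symmetric (max asymmetry ", max(d), ")")
  }
  na_mismatch <- is.na(m) != t(is.na(m))
  if (any(na_mismatch)) stop("matrix is not symmetric (NA pattern)")
  invisible(TRUE)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s %s, %d bins of %d bp\n",
              x$role, x$chrom, x$n_bins, x$bin_size))
  invisible(x)
}

# Accumulate symmetric counts/weights into an n x n matrix from bin index
# pairs (0-based) and per-pair weights. Both [i,j] and [j,i] are filled;
# the diagonal is counted once.
.accumulate_sym <- function(i, j, w, n) {
  M <- matrix(0, n, n)
  if (length(i) == 0L) return(M)
  dt <- data.table::data.table(a = pmin(i, j), b = pmax(i, j), w = w)
  agg <- dt[, list(w = sum(w)), by = c("a", "b")]
  M[cbind(agg$a + 1L, agg$b + 1L)] <- agg$w
  off <- agg$a != agg$b
  M[cbind(agg$b[off] + 1L, agg$a[off] + 1L)] <- agg$w[off]
  M
}

#' Bin intra-chromosomal pairs into an observed contact matrix
#'
#' Each pair increments the entry for bins `floor(pos/bin_size)`; the
#' matrix is symmetrized (off-diagonal pairs appear at `[i,j]` and
#' `[j,i]`; same-bin pairs count once on the diagonal).
#'
#' @param pairs Valid-pairs table; only rows with both mates on `chrom`
#'   are used.
#' @param bin_size Bin size in bp.
#' @param chrom_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @return `contact_matrix` with role "observed".
#' @export
bin_pairs <- function(pairs, bin_size, chrom_length, chrom) {
  n <- ceiling(chrom_length / bin_size)
  sel <- pairs$chrom1 == chrom & pairs$chrom2 == chrom
  p <- pairs[sel, , drop = FALSE]
  if (nrow(p) > 0L && any(p$pos1 >= chrom_length | p$pos2 >= chrom_length)) {
    stop("pair position beyond chromosome end on ", chrom)
  }
  i <- p$pos1 %/% bin_size
  j <- p$pos2 %/% bin_size
  M <- .accumulate_sym(i, j, rep(1, nrow(p)), n)
  contact_matrix(M, chrom, bin_size, "observed")
}
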