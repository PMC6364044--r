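# Weighted pool-adjacent-violators for a non-increasing fit.
.pava_nonincreasing <- function(y, w) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  vals <- y; wts <- w; sizes <- rep(1L, n); k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    vals[k] <- y[i]; wts[k] <- w[i]; sizes[k] <- 1L
    while (k > 1L && vals[k - 1L] < vals[k]) {
      tw <- wts[k - 1L] + wts[k]
      vals[k - 1L] <- (vals[k - 1L] * wts[k - 1L] + vals[k] * wts[k]) / tw
      wts[k - 1L] <- tw
      sizes[k - 1L] <- sizes[k - 1L] + sizes[k]
      k <- k - 1L
    }
  }
  rep(vals[seq_len(k)], sizes[seq_len(k)])
}

# Shared smoothing: keep d=0 raw, isotonic non-increasing for d>=1,
# impute non-positive entries from the nearest positive smoothed neighbor.
.smooth_profile <- function(raw, weight) {
  smoothed <- raw
  if (length(raw) > 1L) {
    idx <- 2:length(raw)
    w <- weight[idx]
    w[w <= 0] <- 1e-12
    smoothed[idx] <- .pava_nonincreasing(raw[idx], w)
  }
  pos <- which(smoothed > 0)
  if (length(pos) > 0L) {
    bad <- which(smoothed <= 0)
    for (b in bad) smoothed[b] <- smoothed[pos[which.min(abs(pos - b))]]
  }
  smoothed
}

#' Estimate the distance-decay profile from observed matrices
#'
#' The average intra-chromosomal contact count decreases monotonically with
#' genomic distance. The raw profile at bin distance d is the mean of
#' `O[i,j]` over all cells with `j - i = d`, pooled across chromosomes; the
#' smoothed profile is its isotonic (non-increasing for d >= 1) regression,
#' with zero-count distances imputed from the nearest positive smoothed
#' neighbor, so the smoothed profile is strictly positive wherever any data
#' exist.
#'
#' @param matrices A `contact_matrix` (role "observed") or list of them.
#' @param bin_size Bin size; defaults to the matrices' bin size.
#' @return `expected_profile` object with `raw`, `smoothed` (length =
#'   max n_bins, indexed by distance d = 0..), `bin_size`, `level = "cell"`.
#' @export
estimate_distance_decay <- function(matrices, bin_size = NULL) {
  if (inherits(matrices, "contact_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  if (is.null(bin_size)) bin_size <- matrices[[1L]]$bin_size
  n_max <- max(vapply(matrices, function(m) m$n_bins, integer(1L)))
  tot <- numeric(n_max)   # summed counts per distance
  cnt <- numeric(n_max)   # number of cells per distance
  for (m in matrices) {
    n <- m$n_bins
    d <- abs(row(m$values) - col(m$values))
    up <- row(m$values) <= col(m$values)
    tot[1:n] <- tot[1:n] + as.numeric(rowsum(m$values[up], d[up])[, 1L])
    cnt[1:n] <- cnt[1:n] + tabulate(d[up] + 1L, nbins = n)
  }
  if (all(tot == 0)) stop("no contacts: all matrices are zero")
  raw <- ifelse(cnt > 0, tot / cnt, 0)
  structure(list(raw = raw, smoothed = .smooth_profile(raw, cnt),
                 bin_size = as.integer(bin_size), level = "cell"),
            class = "expected_profile")
}

# All unordered intra-chromosomal FEND pairs (p < q by fend_id), with
# bin-unit distances; optionally restricted to separation > min_distance.
.all_fend_pairs <- function(fends, bin_size, min_distance = 0) {
  per <- lapply(split(fends, fends$chrom), function(f) {
    n <- nrow(f)
    if (n < 2L) return(NULL)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    p <- idx[, 1L]; q <- idx[, 2L]
    sep <- abs(f$coord[q] - f$coord[p])
    keep <- sep > min_distance
    if (!any(keep)) return(NULL)
    data.frame(chrom = f$chrom[1L], p = f$fend_id[p[keep]],
               q = f$fend_id[q[keep]], sep = sep[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), p = integer(0), q = integer(0),
                      sep = numeric(0), stringsAsFactors = FALSE)
  }
  out$dbin <- pmin(out$sep %/% bin_size, .Machine$integer.max)
  rownames(out) <- NULL
  out
}

#' FEND-level distance profile
#'
#' Mean observed contact count per FEND pair at each bin-unit distance:
#' observed intra-chromosomal pair counts divided by the number of FEND
#' pairs at that distance, isotonically smoothed like
#' [estimate_distance_decay()]. This is the distance term of the
#' correction model — it is a per-FEND-pair contact rate, so summing it
#' over the FEND pairs of a matrix cell gives that cell's expected count.
#'
#' @param pairs Valid-pairs table.
#' @param fends FEND table.
#' @param bin_size Bin size in bp.
#' @return `expected_profile` with `level = "fend"`.
#' @export
fend_distance_profile <- function(pairs, fends, bin_size) {
  ap <- .all_fend_pairs(fends, bin_size)
  if (nrow(ap) == 0L) stop("need at least two FENDs on one chromosome")
  n_d <- max(ap$dbin) + 1L
  denom <- tabulate(ap$dbin + 1L, nbins = n_d)
  intra <- pairs[pairs$chrom1 == pairs$chrom2, , drop = FALSE]
  dbin_obs <- pmin(abs(intra$pos2 - intra$pos1) %/% bin_size, n_d - 1L)
  num <- tabulate(dbin_obs + 1L, nbins = n_d)
  raw <- ifelse(denom > 0, num / denom, 0)
  structure(list(raw = raw, smoothed = .smooth_profile(raw, denom),
                 bin_size = as.integer(bin_size), level = "fend"),
            class = "expected_profile")
}

.decay_at <- function(profile, dbin) {
  s <- profile$smoothed
  s[pmin(dbin, length(s) - 1L) + 1L]
}

#' @export
print.expected_profile <- function(x, ...) {
  cat(sprintf("<expected_profile> %s-level, %d distances, bin %d bp\n",
              x$level, length(x$raw), x$bin_size))
  invisible(x)
}

.features <- c("length", "gc", "mappability")

.fend_feature <- function(fends, feature) {
  switch(feature,
         length = as.numeric(fends$fragment_length),
         gc = fends$gc,
         mappability = fends$mappability)
}

#' Partition FENDs into quantile groups per feature
#'
#' For each of the three FEND features (fragment length, GC content,
#' mappability) the valid FENDs are split into `n_groups` quantile groups
#' with left-closed right-open intervals. FENDs carrying the all-N GC
#' sentinel (-1) are excluded (label NA) and take no part in correction
#' learning. Features with fewer distinct quantile edges than requested
#' collapse to fewer groups with a warning.
#'
#' @param fends FEND table.
#' @param n_groups Groups per feature, recycled to length 3 (default 20).
#' @return `feature_binning` object: per feature `edges`, `labels`
#'   (aligned with `fends` rows), `n_groups`.
#' @export
partition_fend_features <- function(fends, n_groups = 20L) {
  n_groups <- rep_len(as.integer(n_groups), 3L)
  names(n_groups) <- .features
  valid <- fends$gc >= 0
  if (sum(valid) < max(n_groups)) {
    stop("need at least ", max(n_groups), " FENDs with valid features")
  }
  out <- list()
  for (f in .features) {
    B <- n_groups[[f]]
    x <- .fend_feature(fends, f)
    edges <- unique(stats::quantile(x[valid], probs = seq(0, 1, length.out = B + 1),
                                    names = FALSE, type = 7))
    B_eff <- max(length(edges) - 1L, 1L)
    if (B_eff < B) {
      warning("feature '", f, "': only ", B_eff,
              " distinct quantile group(s) available (requested ", B, ")")
    }
    labels <- rep(NA_integer_, nrow(fends))
    if (B_eff == 1L) {
      labels[valid] <- 1L
    } else {
      internal <- edges[2:(length(edges) - 1L)]
      labels[valid] <- findInterval(x[valid], internal) + 1L
    }
    out[[f]] <- list(edges = edges, labels = labels, n_groups = B_eff)
  }
  structure(out, class = "feature_binning")
}

# Per-fend-id label lookup for one feature (NA for excluded fends).
.labels_by_id <- function(binning, fends, feature) {
  lab <- rep(NA_integer_, max(fends$fend_id))
  lab[fends$fend_id] <- binning[[feature]]$labels
  lab
}

#' Learn explicit-factor correction tables from FEND features
#'
#' Fits the multiplicative correction model
#' `w(p,q) = s * decay(d_pq) * prod_f C_f[g_f(p), g_f(q)]`
#' for features f in length, GC, mappability, by cyclic moment-matching
#' updates: for each feature and symmetric group pair (a,b), `C_f[a,b]` is
#' multiplied by the ratio of observed pair counts to model-predicted
#' weight summed over ALL eligible FEND pairs in that group combination.
#' Only FEND pairs separated by more than `min_distance` (default 500 kb)
#' enter the fit, which shields the technical corrections from
#' short-range biological structure (TSS/CTCF-driven local conformation).
#' After each sweep every table is renormalized to mean-zero log over
#' occupied group pairs (the global scale `s` absorbs the remainder);
#' iteration stops when the largest absolute log change drops below `tol`.
#'
#' @param pairs Valid-pairs table (with `fend1`/`fend2`).
#' @param fends FEND table.
#' @param binning `feature_binning` from [partition_fend_features()].
#' @param decay `expected_profile` (FEND-level, from
#'   [fend_distance_profile()]); NULL to compute it from `pairs`/`fends`.
#' @param min_distance Minimum pair separation in bp (default 500000).
#' @param max_iter Maximum sweeps (default 100).
#' @param tol Convergence threshold on max |log change| (default 1e-4).
#' @return `correction_model`: `tables` (named list of symmetric matrices),
#'   `binning`, `scale`, `decay`, `min_distance`, `iterations`, `delta`,
#'   `converged`.
#' @export
learn_corrections <- function(pairs, fends, binning, decay = NULL,
                              min_distance = 500000, max_iter = 100L,
                              tol = 1e-4) {
  if (is.null(decay)) {
    decay <- fend_distance_profile(pairs, fends,
                                   bin_size = .default_bin_for(fends))
  }
  bin_size <- decay$bin_size
  ap <- .all_fend_pairs(fends, bin_size, min_distance)
  if (nrow(ap) == 0L) {
    stop("no FEND pairs separated by more than ", min_distance,
         " bp; use a smaller min_distance for small genomes")
  }
  labs <- lapply(.features, function(f) .labels_by_id(binning, fends, f))
  names(labs) <- .features
  ok <- rep(TRUE, nrow(ap))
  for (f in .features) ok <- ok & !is.na(labs[[f]][ap$p]) & !is.na(labs[[f]][ap$q])
  ap <- ap[ok, , drop = FALSE]
  if (nrow(ap) == 0L) stop("no eligible FEND pairs with valid feature labels")

  # observed counts aggregated onto eligible fend pairs
  intra <- pairs[pairs$chrom1 == pairs$chrom2 &
                 abs(pairs$pos2 - pairs$pos1) > min_distance, , drop = FALSE]
  okey <- paste(pmin(intra$fend1, intra$fend2), pmax(intra$fend1, intra$fend2))
  ocnt <- table(okey)
  obs <- as.numeric(ocnt[paste(ap$p, ap$q)])
  obs[is.na(obs)] <- 0
  if (sum(obs) == 0) {
    stop("no observed pairs between eligible FENDs beyond ", min_distance,
         " bp; use a smaller min_distance for small genomes")
  }

  dval <- .decay_at(decay, ap$dbin)
  B <- vapply(.features, function(f) binning[[f]]$n_groups, integer(1L))
  Cf <- lapply(.features, function(f) matrix(1, B[[f]], B[[f]]))
  names(Cf) <- .features
  lin_idx <- combo <- obs_combo <- occupied <- list()
  for (f in .features) {
    a <- labs[[f]][ap$p]; b <- labs[[f]][ap$q]
    lo <- pmin(a, b); hi <- pmax(a, b)
    lin_idx[[f]] <- (b - 1L) * B[[f]] + a            # index into C_f
    combo[[f]] <- (hi - 1L) * B[[f]] + lo            # symmetric combo id
    obs_combo[[f]] <- rowsum(obs, combo[[f]])
    occupied[[f]] <- sort(unique(combo[[f]]))
  }

  s <- sum(obs) / sum(dval)
  iterations <- 0L; delta <- Inf
  for (it in seq_len(max_iter)) {
    old <- Cf
    for (f in .features) {
      w <- s * dval
      for (g in .features) w <- w * Cf[[g]][lin_idx[[g]]]
      exp_combo <- rowsum(w, combo[[f]])
      ratio <- as.numeric(obs_combo[[f]] / pmax(exp_combo, 1e-300))
      ratio[as.numeric(obs_combo[[f]]) == 0] <- 1  # empty combos: leave alone
      upd <- stats::setNames(ratio, rownames(exp_combo))
      cid <- occupied[[f]]
      lo <- (cid - 1L) %% B[[f]] + 1L
      hi <- (cid - 1L) %/% B[[f]] + 1L
      r <- upd[as.character(cid)]
      Cnew <- Cf[[f]]
      Cnew[cbind(lo, hi)] <- Cnew[cbind(lo, hi)] * r
      Cnew[cbind(hi, lo)] <- Cnew[cbind(lo, hi)]
      Cf[[f]] <- Cnew
    }
    # identifiability: mean log C over occupied combos = 0 per feature
    for (f in .features) {
      cid <- occupied[[f]]
      lo <- (cid - 1L) %% B[[f]] + 1L
      hi <- (cid - 1L) %/% B[[f]] + 1L
      lm <- mean(log(Cf[[f]][cbind(lo, hi)]))
      Cf[[f]] <- Cf[[f]] / exp(lm)
      s <- s * exp(lm)
    }
    w <- s * dval
    for (g in .features) w <- w * Cf[[g]][lin_idx[[g]]]
    s <- s * sum(obs) / sum(w)
    iterations <- it
    delta <- max(vapply(.features, function(f) {
      max(abs(log(Cf[[f]] / old[[f]])))
    }, numeric(1L)))
    if (delta < tol) break
  }
  structure(list(tables = Cf, binning = binning, scale = s, decay = decay,
                 min_distance = min_distance, iterations = iterations,
                 delta = delta, converged = delta < tol),
            class = "correction_model")
}

.default_bin_for <- function(fends) {
  span <- max(fends$coord)
  max(1L, as.integer(2^floor(log2(max(span %/% 50L, 1L)))))
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> %d sweep(s), delta %.2e (%s)\n",
              x$iterations, x$delta,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

# Product of per-feature corrections for fend id pairs (excluded labels
# contribute 1).
.pair_correction <- function(model, fends, p, q) {
  w <- rep(1, length(p))
  for (f in .features) {
    lab <- .labels_by_id(model$binning, fends, f)
    a <- lab[p]; b <- lab[q]
    ok <- !is.na(a) & !is.na(b)
    w[ok] <- w[ok] * model$tables[[f]][cbind(a[ok], b[ok])]
  }
  w
}

#' Correction matrix E
#'
#' By default each entry sums, over the observed read pairs assigned to
#' bins (i,j), the product of the learned per-feature corrections for the
#' pair's two FENDs; E is then symmetric and shares its support with the
#' observed matrix (`E[i,j] = 0` exactly where `O[i,j] = 0`). With
#' `all_pairs = TRUE` the sum instead runs over every intra-chromosomal
#' FEND pair mapping to the cell (corrections only, no distance term),
#' which makes `O/E` a bias-removed contact map that preserves the count
#' and distance structure. Pairs whose FENDs carry excluded feature labels
#' contribute a correction of 1.
#'
#' @param model `correction_model`.
#' @param pairs Valid-pairs table.
#' @param fends FEND table.
#' @param bin_size Bin size in bp.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param all_pairs Sum over all FEND pairs instead of observed read pairs.
#' @return `contact_matrix` with role "correction".
#' @export
correction_matrix <- function(model, pairs, fends, bin_size, chrom,
                              chrom_length, all_pairs = FALSE) {
  n <- ceiling(chrom_length / bin_size)
  if (all_pairs) {
    f <- fends[fends$chrom == chrom, , drop = FALSE]
    ap <- .all_fend_pairs(f, bin_size)
    coord_by_id <- stats::setNames(f$coord, f$fend_id)
    w <- .pair_correction(model, fends, ap$p, ap$q)
    bi <- pmin(coord_by_id[as.character(ap$p)] %/% bin_size, n - 1L)
    bj <- pmin(coord_by_id[as.character(ap$q)] %/% bin_size, n - 1L)
    M <- .accumulate_sym(as.integer(bi), as.integer(bj), w, n)
    return(contact_matrix(M, chrom, bin_size, "correction"))
  }
  sel <- pairs$chrom1 == chrom & pairs$chrom2 == chrom
  p <- pairs[sel, , drop = FALSE]
  w <- .pair_correction(model, fends, p$fend1, p$fend2)
  M <- .accumulate_sym(p$pos1 %/% bin_size, p$pos2 %/% bin_size, w, n)
  contact_matrix(M, chrom, bin_size, "correction")
}

#' Normalized contact matrix N = O / E
#'
#' Entrywise ratio of observed counts to summed corrections; entries where
#' both are zero are zero by convention. An entry with `E = 0` but `O > 0`
#' violates the construction contract of E and raises an error.
#'
#' @param O Observed `contact_matrix`.
#' @param E Correction `contact_matrix`.
#' @return `contact_matrix` with role "normalized".
#' @export
normalize_matrix <- function(O, E) {
  stopifnot(identical(dim(O$values), dim(E$values)))
  o <- O$values; e <- E$values
  if (any(e == 0 & o > 0)) {
    stop("E is zero where O is positive; E must share O's support")
  }
  N <- matrix(0, nrow(o), ncol(o))
  pos <- e > 0
  N[pos] <- o[pos] / e[pos]
  contact_matrix(N, O$chrom, O$bin_size, "normalized")
}

#' Observed-over-expected log2 matrix
#'
#' The expected count for bins (i,j) sums the model weight
#' `s * decay(d_pq) * prod_f C_f` over ALL FEND pairs (p,q) of the
#' chromosome mapping to that cell — not only observed pairs — so it
#' reflects both the learned corrections and the linear genomic distance.
#' Entries are `log2(O / expected)`; bins without any expected contact
#' (no FENDs) get the `na_expected` sentinel, cells with expected but no
#' observed contacts get `na_observed`.
#'
#' @param O Observed `contact_matrix`.
#' @param model `correction_model` (its FEND-level decay is used).
#' @param fends FEND table.
#' @return `contact_matrix` with role "oe_log2" (NA values + `sentinel`
#'   matrix: 1 = no expected, 2 = no observed).
#' @export
observed_over_expected <- function(O, model, fends) {
  chrom <- O$chrom
  bin_size <- O$bin_size
  n <- O$n_bins
  f <- fends[fends$chrom == chrom, , drop = FALSE]
  E_full <- matrix(0, n, n)
  if (nrow(f) >= 1L) {
    coord_by_id <- stats::setNames(f$coord, f$fend_id)
    ap <- .all_fend_pairs(f, bin_size)
    self <- data.frame(chrom = chrom, p = f$fend_id, q = f$fend_id,
                       sep = 0, dbin = 0L)   # same-fend diagonal mass
    ap <- rbind(ap, self)
    w <- model$scale * .decay_at(model$decay, ap$dbin) *
      .pair_correction(model, fends, ap$p, ap$q)
    bi <- pmin(coord_by_id[as.character(ap$p)] %/% bin_size, n - 1L)
    bj <- pmin(coord_by_id[as.character(ap$q)] %/% bin_size, n - 1L)
    E_full <- .accumulate_sym(as.integer(bi), as.integer(bj), w, n)
  }
  o <- O$values
  vals <- matrix(NA_real_, n, n)
  sent <- matrix(0L, n, n)
  sent[E_full == 0] <- 1L
  sent[E_full > 0 & o == 0] <- 2L
  ok <- E_full > 0 & o > 0
  vals[ok] <- log2(o[ok] / E_full[ok])
  contact_matrix(vals, chrom, bin_size, "oe_log2", sentinel = sent)
}

#' Serialize / restore a correction model as JSON
#'
#' @param model `correction_model`.
#' @param path JSON file path.
#' @export
write_correction_model <- function(model, path) {
  payload <- list(
    tables = lapply(model$tables, unclass),
    edges = lapply(model$binning, function(b) b$edges),
    scale = model$scale,
    decay = list(raw = model$decay$raw, smoothed = model$decay$smoothed,
                 bin_size = model$decay$bin_size, level = model$decay$level),
    min_distance = model$min_distance,
    iterations = model$iterations, delta = model$delta,
    converged = model$converged
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
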