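#' Directionality index of a normalized contact matrix
#'
#' For each bin i, contacts are summed upstream
#' (`A = sum_{j=i-w}^{i-1} N[i,j]`) and downstream
#' (`B = sum_{j=i+1}^{i+w} N[i,j]`) within a `window` of w bins (default
#' 2 Mb), clipped at the chromosome ends. With `E = (A+B)/2`, the DI is
#' `sign(B-A) * ((A-E)^2/E + (B-E)^2/E)`: a chi-square-like statistic
#' whose sign marks whether the bin preferentially contacts downstream
#' (positive, typical of domain starts) or upstream (negative, domain
#' ends). DI is 0 when A = B; bins with A + B = 0 (unmappable regions)
#' are masked.
#'
#' @param N `contact_matrix` (normalized, or observed for exploration).
#' @param window Window in bp (default 2e6); rounded down to a multiple of
#'   the bin size with a warning if needed.
#' @return `di_track`: `di`, `A`, `B`, `masked`, `window`, `bin_size`.
#' @export
directionality_index <- function(N, window = 2e6) {
  bin_size <- N$bin_size
  if (window < bin_size) stop("window must be at least one bin")
  if (window %% bin_size != 0) {
    window <- (window %/% bin_size) * bin_size
    warning("window rounded down to ", window, " bp (multiple of bin size)")
  }
  w <- window %/% bin_size
  m <- N$values
  n <- nrow(m)
  A <- B <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - w)
    hi <- min(n, i + w)
    if (i > 1L) A[i] <- sum(m[i, lo:(i - 1L)])
    if (i < n) B[i] <- sum(m[i, (i + 1L):hi])
  }
  E <- (A + B) / 2
  di <- numeric(n)
  nz <- E > 0 & A != B
  di[nz] <- sign(B[nz] - A[nz]) *
    ((A[nz] - E[nz])^2 / E[nz] + (B[nz] - E[nz])^2 / E[nz])
  structure(list(di = di, A = A, B = B, masked = (A + B) == 0,
                 window = window, bin_size = bin_size, chrom = N$chrom),
            class = "di_track")
}

#' @export
print.di_track <- function(x, ...) {
  cat(sprintf("<di_track> %s: %d bins (%d masked), window %g bp\n",
              x$chrom, length(x$di), sum(x$masked), x$window))
  invisible(x)
}

# --- three-state Gaussian HMM ------------------------------------------

.hmm_loglik_matrix <- function(x, means, vars) {
  outer(x, seq_along(means), function(xi, k) {
    stats::dnorm(xi, means[k], sqrt(vars[k]), log = TRUE)
  })
}

# Scaled forward-backward; returns log-likelihood and posteriors.
.hmm_forward_backward <- function(x, init, trans, means, vars) {
  Tn <- length(x); K <- length(init)
  B <- exp(.hmm_loglik_matrix(x, means, vars))
  alpha <- matrix(0, Tn, K); beta <- matrix(0, Tn, K); scale <- numeric(Tn)
  a <- init * B[1L, ]
  scale[1L] <- sum(a)
  alpha[1L, ] <- a / scale[1L]
  for (t in 2:Tn) {
    a <- (alpha[t - 1L, ] %*% trans)[1L, ] * B[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta[Tn, ] <- 1
  for (t in (Tn - 1L):1L) {
    beta[t, ] <- (trans %*% (B[t + 1L, ] * beta[t + 1L, ]))[, 1L] / scale[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  # expected transition counts
  xi <- matrix(0, K, K)
  for (t in seq_len(Tn - 1L)) {
    m <- (alpha[t, ] %o% (B[t + 1L, ] * beta[t + 1L, ])) * trans / scale[t + 1L]
    xi <- xi + m
  }
  list(loglik = sum(log(scale)), gamma = gamma, xi = xi, emis = B)
}

#' Fit a three-state Gaussian HMM to a DI track
#'
#' Baum-Welch EM over the finite (unmasked) DI values, with `n_restarts`
#' random initializations (best final log-likelihood wins) and states
#' relabeled by descending emission mean as downstream-bias, no-bias,
#' upstream-bias. The per-iteration log-likelihood is non-decreasing and
#' the fit is deterministic given `seed`.
#'
#' @param di `di_track` or numeric DI vector.
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 5).
#' @param max_iter EM iterations per restart (default 500).
#' @param tol Stop when the log-likelihood gain drops below `tol`.
#' @return `hmm_model`: `init`, `trans`, `means`, `vars` (states ordered
#'   downstream, no_bias, upstream), `loglik`, `loglik_trace`.
#' @export
fit_hmm <- function(di, seed = 0L, n_restarts = 5L, max_iter = 500L,
                    tol = 1e-4) {
  x <- if (inherits(di, "di_track")) di$di[!di$masked] else di[is.finite(di)]
  if (length(x) < 30L) stop("need at least 30 finite DI values to fit")
  K <- 3L
  best <- NULL
  set.seed(as.integer(seed))
  for (r in seq_len(n_restarts)) {
    qs <- stats::quantile(x, c(0.15, 0.5, 0.85), names = FALSE)
    means <- sort(qs + stats::rnorm(K, 0, stats::sd(x) * 0.2),
                  decreasing = TRUE)
    vars <- rep(stats::var(x) / 2, K)
    init <- rep(1 / K, K)
    trans <- matrix(0.1 / (K - 1), K, K); diag(trans) <- 0.9
    trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      fb <- .hmm_forward_backward(x, init, trans, means, vars)
      trace <- c(trace, fb$loglik)
      g <- fb$gamma
      init <- g[1L, ]
      trans <- fb$xi / pmax(rowSums(fb$xi), 1e-300)
      Ns <- colSums(g)
      means <- colSums(g * x) / Ns
      vars <- colSums(g * (outer(x, means, "-")^2)) / Ns
      low <- vars < 1e-8
      if (any(low)) {
        warning("degenerate emission variance floored at 1e-8")
        vars[low] <- 1e-8
      }
      if (fb$loglik - prev < tol && it > 1L) break
      prev <- fb$loglik
    }
    ll <- trace[length(trace)]
    if (is.null(best) || ll > best$loglik) {
      best <- list(init = init, trans = trans, means = means, vars = vars,
                   loglik = ll, loglik_trace = trace)
    }
  }
  ord <- order(best$means, decreasing = TRUE)  # downstream, no_bias, upstream
  structure(list(init = best$init[ord],
                 trans = best$trans[ord, ord, drop = FALSE],
                 means = best$means[ord], vars = best$vars[ord],
                 loglik = best$loglik, loglik_trace = best$loglik_trace),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf(
    "<hmm_model> 3-state Gaussian; means %.3g / %.3g / %.3g; loglik %.4g\n",
    x$means[1L], x$means[2L], x$means[3L], x$loglik))
  invisible(x)
}

#' Viterbi decoding of a Gaussian HMM
#'
#' Most probable state path for an observation vector (log-space dynamic
#' program).
#'
#' @param model `hmm_model`.
#' @param x Numeric observations.
#' @return Integer state indices (1 = downstream, 2 = no_bias,
#'   3 = upstream).
#' @export
viterbi_path <- function(model, x) {
  Tn <- length(x)
  if (Tn == 0L) return(integer(0))
  K <- length(model$means)
  logB <- .hmm_loglik_matrix(x, model$means, model$vars)
  logA <- log(pmax(model$trans, 1e-300))
  delta <- matrix(-Inf, Tn, K)
  psi <- matrix(0L, Tn, K)
  delta[1L, ] <- log(pmax(model$init, 1e-300)) + logB[1L, ]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      for (k in seq_len(K)) {
        cand <- delta[t - 1L, ] + logA[, k]
        psi[t, k] <- which.max(cand)
        delta[t, k] <- cand[psi[t, k]] + logB[t, k]
      }
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1L) for (t in (Tn - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Decode the "true DI" state track
#'
#' Runs Viterbi decoding over each contiguous stretch of unmasked bins
#' (masked, unmappable bins get the NA sentinel and break the path) and
#' renders the decoded states as +1 (downstream bias), 0 (no bias), -1
#' (upstream bias) — the "true DI" track.
#'
#' @param model `hmm_model`.
#' @param di `di_track`.
#' @return `state_track`: `states` (+1/0/-1, NA where masked), `chrom`,
#'   `bin_size`.
#' @export
decode_states <- function(model, di) {
  n <- length(di$di)
  states <- rep(NA_real_, n)
  rl <- rle(!di$masked)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  code <- c(1, 0, -1)  # state index -> rendered value
  for (k in seq_along(rl$values)) {
    if (!rl$values[k]) next
    seg <- starts[k]:ends[k]
    states[seg] <- code[viterbi_path(model, di$di[seg])]
  }
  structure(list(states = states, chrom = di$chrom, bin_size = di$bin_size),
            class = "state_track")
}

#' @export
print.state_track <- function(x, ...) {
  cat(sprintf("<state_track> %s: %d bins (%d masked)\n",
              x$chrom, length(x$states), sum(is.na(x$states))))
  invisible(x)
}

#' Call TAD coordinates from HMM state shifts
#'
#' A domain opens at the first bin of each maximal run of downstream (+1)
#' states and closes at the end of the first following maximal run of
#' upstream (-1) states. A domain still open when the next downstream run
#' starts closes at the bin preceding it; masked (sentinel) bins and the
#' track end also close an open domain. Coordinates are bin indices times
#' the bin size, 0-based half-open; the output is sorted and
#' non-overlapping.
#'
#' @param states `state_track` (or numeric vector of +1/0/-1/NA).
#' @param bin_size Bin size in bp (taken from the track if omitted).
#' @return `data.frame` with `start`, `end` in bp.
#' @export
call_tads <- function(states, bin_size = NULL) {
  if (inherits(states, "state_track")) {
    if (is.null(bin_size)) bin_size <- states$bin_size
    states <- states$states
  }
  if (is.null(bin_size)) stop("bin_size required")
  n <- length(states)
  coded <- ifelse(is.na(states), 99, states)  # rle cannot compare NA
  r <- rle(coded)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  d_start <- integer(0); d_end <- integer(0)
  open_at <- NA_integer_
  emit <- function(s, e) {
    if (e >= s) { d_start <<- c(d_start, s); d_end <<- c(d_end, e) }
  }
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v == 1) {           # downstream run: opens a domain
      if (!is.na(open_at)) emit(open_at, run_start[k] - 1L)
      open_at <- run_start[k]
    } else if (v == -1) {   # upstream run: closes the open domain at its end
      if (!is.na(open_at)) { emit(open_at, run_end[k]); open_at <- NA_integer_ }
    } else if (v == 99) {   # masked bins break domain runs
      if (!is.na(open_at)) { emit(open_at, run_start[k] - 1L); open_at <- NA_integer_ }
    }                        # no-bias runs leave the domain open
  }
  if (!is.na(open_at)) emit(open_at, n)
  data.frame(start = (d_start - 1L) * bin_size, end = d_end * bin_size)
}
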