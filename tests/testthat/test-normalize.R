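test_that("pair binning floors positions and symmetrizes counts", {
  p <- data.frame(chrom1 = "c", pos1 = 10000L, strand1 = "+", fend1 = 1L,
                  chrom2 = "c", pos2 = 50000L, strand2 = "-", fend2 = 2L,
                  stringsAsFactors = FALSE)
  O <- bin_pairs(p, 40000L, 200000L, "c")
  expect_equal(O$values[1, 2], 1)
  expect_equal(O$values[2, 1], 1)
  expect_equal(sum(O$values), 2)

  # both ends in one bin: diagonal counted once
  p$pos2 <- 12000L
  Od <- bin_pairs(p, 40000L, 200000L, "c")
  expect_equal(Od$values[1, 1], 1)
  expect_equal(sum(Od$values), 1)

  O0 <- bin_pairs(p[0, ], 40000L, 200000L, "c")
  expect_true(all(O0$values == 0))
  expect_equal(O0$n_bins, 5L)

  p$pos2 <- 300000L
  expect_error(bin_pairs(p, 40000L, 200000L, "c"), "beyond")

  # off-diagonal mass is twice the off-diagonal pair count
  set.seed(3)
  pr <- data.frame(chrom1 = "c", pos1 = sample(0:199999, 200), strand1 = "+",
                   fend1 = 1L, chrom2 = "c", pos2 = sample(0:199999, 200),
                   strand2 = "-", fend2 = 2L, stringsAsFactors = FALSE)
  Om <- bin_pairs(pr, 40000L, 200000L, "c")
  off <- sum(Om$values) - sum(diag(Om$values))
  n_off <- sum(pr$pos1 %/% 40000L != pr$pos2 %/% 40000L)
  expect_equal(off, 2 * n_off)
})

test_that("distance decay averages by diagonal and smooths monotonically", {
  cm <- function(v) contact_matrix(v, "c", 40000L, "normalized")
  const <- matrix(3, 6, 6)
  prof <- estimate_distance_decay(cm(const))
  expect_equal(prof$raw, rep(3, 6))
  expect_equal(prof$smoothed, rep(3, 6))

  n <- 8
  hyp <- 1 / (1 + abs(outer(1:n, 1:n, "-")))
  prof2 <- estimate_distance_decay(cm(hyp))
  expect_equal(prof2$raw, 1 / (1 + 0:(n - 1)))

  set.seed(4)
  R <- matrix(rpois(100, 5), 10, 10)
  R <- R + t(R)
  prof3 <- estimate_distance_decay(contact_matrix(R, "c", 40000L, "observed"))
  expect_true(all(diff(prof3$smoothed[-1]) <= 1e-12))
  expect_true(all(prof3$smoothed > 0))

  expect_error(estimate_distance_decay(cm(matrix(0, 4, 4))), "no contacts")
})

test_that("feature partitioning yields quantile groups and excludes sentinels", {
  fe <- make_test_fends(60, chroms = "chr1", chrom_length = 1e5, seed = 7)
  fe$fragment_length <- rep(1:60, each = 2)[seq_len(nrow(fe))]
  b <- suppressWarnings(partition_fend_features(fe, c(4L, 2L, 2L)))
  expect_equal(unname(table(b$length$labels)), rep(nrow(fe) / 4, 4),
               ignore_attr = TRUE)

  # constant gc collapses to one group with a warning
  fe2 <- fe; fe2$gc <- 0.5
  expect_warning(b2 <- partition_fend_features(fe2, 4L), "gc")
  expect_equal(b2$gc$n_groups, 1L)

  # sentinel gc=-1 fends get NA labels everywhere
  fe3 <- fe; fe3$gc[1:4] <- -1
  b3 <- suppressWarnings(partition_fend_features(fe3, 2L))
  expect_true(all(is.na(b3$gc$labels[1:4])))
  expect_true(all(is.na(b3$length$labels[1:4])))
})

test_that("correction learning satisfies identifiability and recovers planted bias", {
  fe <- make_test_fends(250, chrom_length = 1e6, seed = 8)

  # all fends in one group per feature: corrections are identically 1
  cfg0 <- sim_config(seed = 40, n_pairs = 5000L, decay_exponent = 1)
  sp0 <- simulate_pairs(cfg0, fe)
  decay0 <- fend_distance_profile(sp0$pairs, fe, 40000L)
  bn1 <- suppressWarnings(partition_fend_features(fe, 1L))
  mod1 <- learn_corrections(sp0$pairs, fe, bn1, decay0, min_distance = 1e5)
  for (f in c("length", "gc", "mappability")) {
    expect_equal(mod1$tables[[f]], matrix(1, 1, 1))
  }

  # planted 2-group GC bias with 4:1 fend-level effects
  cfg <- sim_config(seed = 41, n_pairs = 20000L,
                    fend_bias = list(feature = "gc", n_groups = 2,
                                     effects = c(1, 4)))
  sp <- simulate_pairs(cfg, fe)
  decay <- fend_distance_profile(sp$pairs, fe, 40000L)
  bn <- partition_fend_features(fe, 2L)
  mod <- learn_corrections(sp$pairs, fe, bn, decay, min_distance = 1e5)
  ratio <- sqrt(mod$tables$gc[2, 2] / mod$tables$gc[1, 1])
  expect_gt(ratio, 4 * 0.85)
  expect_lt(ratio, 4 * 1.15)
  # identifiability: mean log C over occupied combos ~ 0
  lc <- log(mod$tables$gc[upper.tri(mod$tables$gc, diag = TRUE)])
  expect_lt(abs(mean(lc)), 0.2)

  # unbiased data: corrections stay near 1
  mod_null <- learn_corrections(sp0$pairs, fe,
                                partition_fend_features(fe, 2L), decay0,
                                min_distance = 1e5)
  expect_lt(max(abs(log(unlist(mod_null$tables)))), 0.1)

  # no pairs beyond min_distance on a toy genome is a clear error
  expect_error(learn_corrections(sp0$pairs, fe, bn, decay0,
                                 min_distance = 1e9), "min_distance")
})

test_that("correction matrix sums per-pair corrections over observed support", {
  fe <- make_test_fends(100, chroms = "chr1", chrom_length = 4e5, seed = 9)
  cfg <- sim_config(seed = 42, n_chroms = 1, n_pairs = 3000L)
  sp <- simulate_pairs(cfg, fe)
  mod1 <- uniform_model(sp$pairs, fe, 40000L)
  O <- bin_pairs(sp$pairs, 40000L, 4e5, "chr1")
  E <- correction_matrix(mod1, sp$pairs, fe, 40000L, "chr1", 4e5)
  # model == 1: each pair contributes exactly 1, so E equals O
  expect_equal(E$values, O$values)
  expect_identical((E$values == 0), (O$values == 0))

  # a single pair with product of corrections 2.5 lands as E = 2.5
  one <- sp$pairs[1, ]
  b <- mod1$binning
  lab <- function(id) b$gc$labels[match(id, fe$fend_id)]
  mod25 <- mod1
  mod25$tables$gc[lab(one$fend1), lab(one$fend2)] <- 2.5
  mod25$tables$gc[lab(one$fend2), lab(one$fend1)] <- 2.5
  E1 <- correction_matrix(mod25, one, fe, 40000L, "chr1", 4e5)
  i <- one$pos1 %/% 40000L + 1L; j <- one$pos2 %/% 40000L + 1L
  expect_equal(E1$values[i, j], 2.5)
  expect_equal(sum(E1$values > 0), if (i == j) 1L else 2L)
})

test_that("N = O/E with the zero-support convention and contract errors", {
  O <- contact_matrix(matrix(c(4, 0, 0, 0), 2), "c", 1000L, "observed")
  E <- contact_matrix(matrix(c(2, 0, 0, 0), 2), "c", 1000L, "correction")
  N <- normalize_matrix(O, E)
  expect_equal(N$values[1, 1], 2)
  expect_equal(N$values[2, 2], 0)

  # E == O means N is 1 on the support
  NN <- normalize_matrix(O, contact_matrix(O$values, "c", 1000L, "correction"))
  expect_true(all(NN$values[O$values > 0] == 1))

  Ebad <- contact_matrix(matrix(0, 2, 2), "c", 1000L, "correction")
  expect_error(normalize_matrix(O, Ebad), "support")
})

test_that("O/E flags missing-expected and missing-observed bins", {
  # fends only in the first two of three bins
  fe <- data.frame(chrom = "c", coord = c(0L, 30000L, 30000L, 70000L),
                   side = c("L", "R", "L", "R"), fragment_index = c(0L, 0L, 1L, 1L),
                   fragment_length = c(30000L, 30000L, 40000L, 40000L),
                   gc = 0.5, mappability = 1, fend_id = 1:4,
                   stringsAsFactors = FALSE)
  p <- data.frame(chrom1 = "c", pos1 = 10000L, strand1 = "+", fend1 = 1L,
                  chrom2 = "c", pos2 = 60000L, strand2 = "-", fend2 = 4L,
                  stringsAsFactors = FALSE)
  mod <- uniform_model(p, fe, 40000L, min_distance = 10000L)
  O <- bin_pairs(p, 40000L, 120000L, "c")
  oe <- observed_over_expected(O, mod, fe)
  expect_equal(oe$role, "oe_log2")
  # bin 3 holds no fends: na_expected row/column
  expect_true(all(oe$sentinel[3, ] == 1L))
  # bin pair (1,1) has expected mass but no observed pair
  expect_equal(oe$sentinel[1, 1], 2L)
  # the observed cell carries a finite log2 ratio
  expect_true(is.finite(oe$values[1, 2]))
  expect_equal(oe$values, t(oe$values))
})

test_that("symmetry survives the whole normalization chain", {
  fe <- make_test_fends(120, chroms = "chr1", chrom_length = 5e5, seed = 10)
  cfg <- sim_config(seed = 43, n_chroms = 1, n_pairs = 4000L)
  sp <- simulate_pairs(cfg, fe)
  decay <- fend_distance_profile(sp$pairs, fe, 40000L)
  bn <- partition_fend_features(fe, 2L)
  mod <- learn_corrections(sp$pairs, fe, bn, decay, min_distance = 1e5)
  O <- bin_pairs(sp$pairs, 40000L, 5e5, "chr1")
  E <- correction_matrix(mod, sp$pairs, fe, 40000L, "chr1", 5e5)
  N <- normalize_matrix(O, E)
  oe <- observed_over_expected(O, mod, fe)
  for (m in list(O, E, N)) expect_equal(m$values, t(m$values))
  expect_identical(oe$sentinel, t(oe$sentinel))
})
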