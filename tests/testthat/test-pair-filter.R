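# Hand-built fragment/FEND tables for chrT: fragments [0,400), [400,900),
# [900,1400), [1400,2000).
toy_fends <- function() {
  bounds <- c(0L, 400L, 900L, 1400L, 2000L)
  n <- 4L
  data.frame(
    chrom = "chrT",
    coord = as.integer(c(rbind(bounds[-5], bounds[-1]))),
    side = rep(c("L", "R"), n),
    fragment_index = rep(0:3, each = 2L),
    fragment_length = rep(diff(bounds), each = 2L),
    gc = 0.5, mappability = 1,
    fend_id = 1:8,
    stringsAsFactors = FALSE
  )
}

sam_line <- function(id, pos5, strand, mapq = 44L, chrom = "chrT", len = 50L) {
  flag <- if (strand == "-") 16L else 0L
  left <- if (strand == "-") pos5 - len + 1L else pos5
  sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
          id, flag, chrom, left + 1L, mapq, len, strrep("A", len),
          strrep("I", len))
}

write_sam <- function(lines, path) {
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrT\tLN:2000", lines), path)
}

test_that("MAPQ filtering keeps the >=30 boundary and drops unmapped reads", {
  mates <- data.frame(
    read_id = c("a", "b", "c", "d"), chrom = "chrT",
    pos = c(10L, 20L, 30L, 40L), pos5 = c(10L, 20L, 30L, 40L),
    strand = "+", mapq = c(30L, 29L, 60L, 60L),
    mapped = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE
  )
  kept <- filter_mapq(mates, 30L)
  expect_equal(kept$read_id, c("a", "c"))
})

test_that("pairing keeps the read-id intersection and counts singletons", {
  m <- function(ids) data.frame(read_id = ids, chrom = "chrT",
                                pos = seq_along(ids), pos5 = seq_along(ids),
                                strand = "+", mapq = 40L, mapped = TRUE,
                                stringsAsFactors = FALSE)
  res <- pair_mates(m(c("a", "b", "c")), m(c("b", "c", "d")))
  expect_equal(sort(res$pairs$read_id), c("b", "c"))
  expect_equal(res$n_singletons, 2L)
  expect_equal(nrow(pair_mates(m(c("a")), m(c("z")))$pairs), 0L)
  expect_equal(nrow(pair_mates(m(c("a", "b")), m(c("a", "b")))$pairs), 2L)
  expect_error(pair_mates(m(c("a", "a")), m("b")), "duplicate read_id")
})

test_that("fragment assignment locates the 5' position and strand-faced FEND", {
  frags <- data.frame(chrom = "c", start = c(0L, 4L, 13L),
                      end = c(4L, 13L, 20L), index = 0:2)
  fends <- data.frame(chrom = "c", coord = c(0L, 4L, 4L, 13L, 13L, 20L),
                      side = c("L", "R", "L", "R", "L", "R"),
                      fragment_index = c(0L, 0L, 1L, 1L, 2L, 2L),
                      fend_id = 1:6, stringsAsFactors = FALSE)
  a <- assign_to_fragment(5L, "+", frags, fends)
  expect_equal(a$fragment_index, 1L)
  expect_equal(a$fend_id, 4L)  # right end of fragment 1
  b <- assign_to_fragment(0L, "-", frags, fends)
  expect_equal(b$fragment_index, 0L)
  expect_equal(b$fend_id, 1L)  # left end of fragment 0
  expect_equal(assign_to_fragment(19L, "+", frags, fends)$fragment_index, 2L)
  expect_error(assign_to_fragment(20L, "+", frags, fends), "beyond")
})

test_that("pair classification matches the brute-force rule-table oracle", {
  expect_equal(classify_pair("c", 100L, "+", 5L, "c", 300L, "-", 5L),
               "dangling_end")
  expect_equal(classify_pair("c", 100L, "+", 5L, "c", 300L, "+", 6L),
               "re_ligation")
  expect_equal(classify_pair("c", 100L, "+", 2L, "c", 300L, "-", 9L), "valid")

  set.seed(21)
  n <- 400L
  chrom1 <- sample(c("c1", "c2"), n, TRUE)
  chrom2 <- sample(c("c1", "c2"), n, TRUE)
  frag1 <- sample(0:4, n, TRUE); frag2 <- sample(0:4, n, TRUE)
  pos1 <- sample(0:999, n, TRUE); pos2 <- sample(0:999, n, TRUE)
  strand1 <- sample(c("+", "-"), n, TRUE)
  strand2 <- sample(c("+", "-"), n, TRUE)
  expect_equal(
    classify_pair(chrom1, pos1, strand1, frag1, chrom2, pos2, strand2, frag2),
    oracle_classify(chrom1, pos1, strand1, frag1, chrom2, pos2, strand2, frag2)
  )
})

test_that("duplicate removal canonicalizes mate order and is idempotent", {
  p <- data.frame(
    chrom1 = "c", pos1 = c(10L, 10L, 50L, 10L), strand1 = c("+", "+", "-", "+"),
    chrom2 = "c", pos2 = c(50L, 50L, 10L, 51L), strand2 = c("-", "-", "+", "-"),
    stringsAsFactors = FALSE
  )
  # rows 1,2 identical; row 3 is the same pair with mates swapped; row 4
  # differs by 1 bp and survives
  res <- remove_duplicates(p)
  expect_equal(nrow(res$pairs), 2L)
  expect_equal(res$n_duplicates, 2L)
  again <- remove_duplicates(res$pairs)
  expect_equal(again$n_duplicates, 0L)
  # order-insensitive surviving-set size
  res_rev <- remove_duplicates(p[4:1, ])
  expect_equal(nrow(res_rev$pairs), 2L)
})

test_that("the full filter resolves a hand-built 10-pair SAM to known truth", {
  fe <- toy_fends()
  # 6 valid pairs (fragments >1 apart), 2 duplicates (one mate-swapped),
  # 1 self-circle, 1 low-MAPQ pair
  r1 <- c(sam_line("v1", 100L, "+"), sam_line("v2", 120L, "+"),
          sam_line("v3", 500L, "-"), sam_line("v4", 140L, "+"),
          sam_line("v5", 520L, "-"), sam_line("v6", 160L, "+"),
          sam_line("d1", 100L, "+"),    # duplicate of v1
          sam_line("d2", 1600L, "+"),   # duplicate of v3, mates swapped
          sam_line("s1", 460L, "-"),    # self-circle in fragment 1
          sam_line("q1", 200L, "+", mapq = 5L))
  r2 <- c(sam_line("v1", 1000L, "-"), sam_line("v2", 1500L, "+"),
          sam_line("v3", 1600L, "+"), sam_line("v4", 1010L, "-"),
          sam_line("v5", 1610L, "+"), sam_line("v6", 1020L, "-"),
          sam_line("d1", 1000L, "-"),
          sam_line("d2", 500L, "-"),
          sam_line("s1", 840L, "+"),
          sam_line("q1", 1200L, "-"))
  sam1 <- tempfile(fileext = ".sam"); sam2 <- tempfile(fileext = ".sam")
  write_sam(r1, sam1); write_sam(r2, sam2)

  res <- run_pair_filter(sam1, sam2, fe, mapq = 30L)
  expect_equal(nrow(res$pairs), 6L)
  expect_equal(res$report$duplicate, 2L)
  expect_equal(res$report$self_circle, 1L)
  expect_equal(res$report$paired, 9L)
  expect_equal(res$report$singletons, 1L)
  # conservation: categories partition the deduplicated paired input
  with(res$report, expect_equal(
    duplicate + self_circle + dangling_end + re_ligation + valid, paired))

  # all-low-MAPQ input: nothing survives
  r1q <- vapply(1:3, function(i) sam_line(paste0("x", i), 100L, "+", mapq = 0L),
                character(1))
  write_sam(r1q, sam1)
  write_sam(vapply(1:3, function(i) sam_line(paste0("x", i), 1000L, "-",
                                             mapq = 0L), character(1)), sam2)
  res0 <- run_pair_filter(sam1, sam2, fe)
  expect_equal(nrow(res0$pairs), 0L)
  expect_equal(res0$report$mapq_pass1, 0L)

  # chromosome missing from the FEND table is an error
  write_sam(sam_line("v1", 100L, "+"), sam1)
  write_sam(sam_line("v1", 1000L, "-"), sam2)
  fe_wrong <- fe; fe_wrong$chrom <- "chrZ"
  expect_error(run_pair_filter(sam1, sam2, fe_wrong), "chrT")
})

test_that("valid-pairs tables round-trip through gzip text", {
  p <- data.frame(chrom1 = "c1", pos1 = c(10L, 20L), strand1 = c("+", "-"),
                  fend1 = c(1L, 3L), chrom2 = c("c1", "c2"),
                  pos2 = c(500L, 700L), strand2 = c("-", "+"),
                  fend2 = c(9L, 11L), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv.gz")
  write_pairs(p, path)
  expect_equal(read_pairs(path), p)
  write_pairs(p[0, ], path)
  expect_equal(nrow(read_pairs(path)), 0L)
})

test_that("simulated SAM filter report equals planted truth exactly", {
  cfg <- sim_config(seed = 31, n_chroms = 2, chrom_length = 2e5,
                    frag_mean = 1000, n_pairs = 2000L, bin_size = 20000L)
  g <- simulate_genome(cfg)
  fe <- build_fend_table(g$genome, cfg$enzyme, gc_window = 50,
                         map_k = 12, map_window = 50)
  sam1 <- tempfile(fileext = ".sam"); sam2 <- tempfile(fileext = ".sam")
  sp <- simulate_pairs(cfg, fe)
  truth <- simulate_sam(sp$pairs, cfg, g$genome, fe, sam1, sam2)
  res <- run_pair_filter(sam1, sam2, fe)
  expect_equal(res$report$valid, truth$valid)
  expect_equal(res$report$duplicate, truth$duplicate)
  expect_equal(res$report$self_circle, truth$self_circle)
  expect_equal(res$report$dangling_end, truth$dangling_end)
  expect_equal(res$report$re_ligation, truth$re_ligation)
  expect_equal(res$report$singletons, truth$low_mapq)
})
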