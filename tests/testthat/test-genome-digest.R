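test_that("restriction enzymes validate palindromy, alphabet and cut offset", {
  e <- restriction_enzyme("HindIII", "AAGCTT", 1)
  expect_s3_class(e, "restriction_enzyme")
  expect_error(restriction_enzyme("bad", "AAGCTA", 1), "palindromic")
  expect_error(restriction_enzyme("amb", "GANTC", 1), "A/C/G/T")
  expect_error(restriction_enzyme("off", "AAGCTT", 4), "cut_offset")
  expect_equal(get_enzyme("DpnII")$site, "GATC")
  expect_error(get_enzyme("EcoRI"), "unknown enzyme")
})

test_that("digestion cuts at site + offset and tiles the sequence", {
  f <- digest_sequence("TTTAAGCTTGGGAAGCTTCC", "HindIII", "t")
  expect_equal(f$start, c(0, 4, 13))
  expect_equal(f$end, c(4, 13, 20))
  expect_equal(f$index, 0:2)

  f2 <- digest_sequence("AAGATCTT", "MboI", "t")
  expect_equal(f2$start, c(0, 2))
  expect_equal(f2$end, c(2, 8))

  f3 <- digest_sequence("TTTT", "HindIII", "t")
  expect_equal(nrow(f3), 1L)
  expect_equal(c(f3$start, f3$end), c(0, 4))

  expect_error(digest_sequence("", "HindIII"), "empty")
})

test_that("digestion matches a brute-force scan oracle on random sequences", {
  set.seed(11)
  enzymes <- c("HindIII", "NcoI", "DpnII", "MboI")
  for (en in enzymes) {
    e <- get_enzyme(en)
    for (rep in 1:6) {
      s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                 collapse = "")
      got <- digest_sequence(s, e, "c")
      want <- oracle_digest(s, e$site, e$cut_offset)
      expect_equal(cbind(start = got$start, end = got$end), want)
      # tiling invariant: no gaps, no overlaps
      expect_equal(got$start[1], 0)
      expect_equal(got$end[nrow(got)], nchar(s))
      if (nrow(got) > 1) expect_equal(got$start[-1], got$end[-nrow(got)])
    }
  }
})

test_that("fend GC content covers the interior window and flags all-N", {
  fend_L <- list(coord = 0L, side = "L", fragment_length = 4L)
  expect_equal(compute_gc("GGCCAAAA", fend_L, 4), 1.0)
  expect_equal(compute_gc("ATATAAAA", fend_L, 4), 0.0)
  expect_equal(compute_gc("GATCAAAA", fend_L, 4), 0.5)
  # right-side fend reads backwards from the cut
  fend_R <- list(coord = 8L, side = "R", fragment_length = 4L)
  expect_equal(compute_gc("ATATGGCC", fend_R, 4), 1.0)
  # window truncated at the fragment boundary
  expect_equal(compute_gc("GGAA", list(coord = 0L, side = "L",
                                       fragment_length = 2L), 100), 1.0)
  # all-N window yields the sentinel; N bases excluded otherwise
  expect_equal(compute_gc("NNNNAAAA", fend_L, 4), -1)
  expect_equal(compute_gc("GNNCAAAA", fend_L, 4), 1.0)
})

test_that("mappability counts genome-unique k-mers in the interior window", {
  g1 <- c(chr1 = "AAAACCCCAA")  # all 4-mers distinct across both strands
  fend <- list(chrom = "chr1", coord = 0L, side = "L", fragment_length = 10L)
  expect_equal(compute_mappability(g1, fend, k = 4, window = 7), 1.0)

  # duplicated chromosome: nothing is unique
  g2 <- c(chr1 = "AAAACCCCAA", chr2 = "AAAACCCCAA")
  expect_equal(compute_mappability(g2, fend, k = 4, window = 7), 0.0)

  # brute-force oracle on a toy genome: enumerate all 4-mers of both
  # strands independently and count occurrences of each window k-mer
  g3 <- c(chr1 = "ACGTACGTTT")
  win_starts <- 0:4
  kmer_at <- function(s, p) substr(s, p + 1, p + 4)
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  all_kmers <- sapply(0:6, kmer_at, s = g3[[1]])
  all_both <- c(all_kmers, sapply(all_kmers, rc))
  is_unique <- function(q) {
    sum(all_kmers == q) + sum(all_kmers == rc(q)) * (rc(q) != q) == 1
  }
  want <- mean(sapply(win_starts, function(p) is_unique(kmer_at(g3[[1]], p))))
  fend3 <- list(chrom = "chr1", coord = 0L, side = "L", fragment_length = 10L)
  expect_equal(compute_mappability(g3, fend3, k = 4, window = 5), want)

  # k-mers containing N are non-unique
  g4 <- c(chr1 = "ACGNACGTTT")
  expect_lt(compute_mappability(g4, fend3, k = 4, window = 5), 1)
})

test_that("fend table has two FENDs per fragment and is input-order invariant", {
  g <- c(chrA = "TTTAAGCTTGGGAAGCTTCC", chrB = "AAGCTTAAGCTTAAAA")
  fe <- build_fend_table(g, "HindIII", gc_window = 5, map_k = 4,
                         map_window = 5)
  # chrA: 2 internal cuts -> 3 fragments -> 6 FENDs
  expect_equal(sum(fe$chrom == "chrA"), 6L)
  expect_true(all(fe$gc >= -1 & fe$gc <= 1))
  expect_true(all(fe$mappability >= 0 & fe$mappability <= 1))
  # reversed chromosome input order: identical table
  fe_rev <- build_fend_table(g[c(2, 1)], "HindIII", gc_window = 5,
                             map_k = 4, map_window = 5)
  expect_identical(fe, fe_rev)
  # no cut site: single fragment, two FENDs
  fe1 <- build_fend_table(c(c1 = "ACACACAC"), "HindIII", gc_window = 4,
                          map_k = 2, map_window = 4)
  expect_equal(nrow(fe1), 2L)
  # duplicated-genome mappability is identically zero
  gd <- c(c1 = "ACGTTGCAATCCAT", c2 = "ACGTTGCAATCCAT")
  fed <- build_fend_table(gd, "MboI", gc_window = 4, map_k = 4,
                          map_window = 6)
  expect_true(all(fed$mappability == 0))
})

test_that("FEND BED round-trips exactly and rejects malformed lines", {
  g <- c(chrA = "TTTAAGCTTGGGAAGCTTCC")
  fe <- build_fend_table(g, "HindIII", gc_window = 5, map_k = 4,
                         map_window = 5)
  path <- tempfile(fileext = ".bed")
  write_fend_bed(fe, path)
  expect_identical(read_fend_bed(path), fe)

  # empty table -> header-only file that reads back empty
  write_fend_bed(fe[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_fend_bed(path)), 0L)

  # corrupt gc field -> error naming the line
  write_fend_bed(fe, path)
  lines <- readLines(path)
  parts <- strsplit(lines[3], "\t")[[1]]
  parts[6] <- "not_a_number"
  lines[3] <- paste(parts, collapse = "\t")
  writeLines(lines, path)
  expect_error(read_fend_bed(path), "line 3")
})
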