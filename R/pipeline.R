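.write_log <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.ensure_outdir <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outdir
}

#' Pre-truncation stage
#'
#' Runs ligation-junction pre-truncation on both mate FASTQ files
#' independently, writing truncated FASTQs, a JSON truncation log and a
#' read-length histogram table per mate. Existing outputs are only
#' overwritten with `force = TRUE`.
#'
#' @param fastq1,fastq2 Input FASTQ files (optionally gzipped).
#' @param enzyme Enzyme name or `restriction_enzyme`.
#' @param outdir Output directory.
#' @param force Overwrite existing outputs.
#' @return List of the two `truncation_report`s, invisibly.
#' @export
run_preprocess <- function(fastq1, fastq2, enzyme, outdir, force = FALSE) {
  .ensure_outdir(outdir)
  reports <- list()
  for (k in 1:2) {
    fq <- c(fastq1, fastq2)[k]
    if (!file.exists(fq)) stop("input FASTQ not found: ", fq)
    out <- file.path(outdir, paste0("mate", k, ".trunc.fastq",
                                    if (grepl("\\.gz$", fq)) ".gz" else ""))
    if (file.exists(out) && !force) {
      stop("output ", out, " exists; use force = TRUE to overwrite")
    }
    rep <- pretruncate_fastq(fq, out, enzyme)
    .write_log(list(input = fq, output = out,
                    total_reads = rep$total_reads,
                    truncated_reads = rep$truncated_reads,
                    percent_truncated = rep$percent_truncated),
               file.path(outdir, paste0("mate", k, ".trunc.json")))
    utils::write.table(
      data.frame(length = as.integer(names(rep$length_histogram)),
                 count = as.integer(rep$length_histogram)),
      file.path(outdir, paste0("mate", k, ".lengths.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    reports[[k]] <- rep
  }
  invisible(reports)
}

# Chromosome lengths implied by a FEND table (end of the last fragment).
.chrom_lengths <- function(fends) {
  vapply(split(fends, fends$chrom), function(f) max(f$coord), numeric(1L))
}

#' Normalization stage
#'
#' Filters the two aligned mate files into valid pairs, learns the
#' explicit-factor correction model (length/GC/mappability, FEND pairs
#' beyond `min_distance` only), and writes observed, correction,
#' normalized and log2 O/E matrices per chromosome in the compressed
#' triangular text format, plus the model JSON and a filter-report log.
#' Per-chromosome matrix jobs are independent and deterministic, so
#' serial (`threads = 1`) and forked (`threads > 1`) runs produce
#' identical files.
#'
#' @param bam1,bam2 Aligned mate SAM/BAM files.
#' @param fends FEND table or FEND BED path.
#' @param outdir Output directory.
#' @param bin_size Bin size in bp (default 40000).
#' @param mapq MAPQ threshold (default 30).
#' @param min_distance Correction-learning distance cutoff (default 5e5).
#' @param chroms Chromosomes to process (default: all in the FEND table).
#' @param threads Worker processes for per-chromosome jobs.
#' @return Invisibly, list with `pairs`, `report`, `model`, `outdir`.
#' @export
run_normalize <- function(bam1, bam2, fends, outdir, bin_size = 40000L,
                          mapq = 30L, min_distance = 500000,
                          chroms = NULL, threads = 1L) {
  .ensure_outdir(outdir)
  if (is.character(fends)) fends <- read_fend_bed(fends)
  fl <- run_pair_filter(bam1, bam2, fends, mapq = mapq)
  write_pairs(fl$pairs, file.path(outdir, "valid_pairs.tsv.gz"))
  .write_log(unclass(fl$report), file.path(outdir, "filter_report.json"))

  lens <- .chrom_lengths(fends)
  if (is.null(chroms)) chroms <- names(lens)
  missing <- setdiff(chroms, names(lens))
  if (length(missing) > 0L) {
    stop("chromosome(s) not in FEND table: ", paste(missing, collapse = ", "))
  }
  decay <- fend_distance_profile(fl$pairs, fends, bin_size)
  binning <- partition_fend_features(fends)
  model <- learn_corrections(fl$pairs, fends, binning, decay,
                             min_distance = min_distance)
  write_correction_model(model, file.path(outdir, "correction_model.json"))

  one_chrom <- function(cn) {
    O <- bin_pairs(fl$pairs, bin_size, lens[[cn]], cn)
    E <- correction_matrix(model, fl$pairs, fends, bin_size, cn, lens[[cn]])
    N <- normalize_matrix(O, E)
    oe <- observed_over_expected(O, model, fends)
    for (m in list(O, E, N, oe)) {
      write_matrix_txt(m, file.path(outdir,
                                    sprintf("%s.%s.matrix.txt", cn, m$role)))
    }
    cn
  }
  if (threads > 1L) {
    parallel::mclapply(chroms, one_chrom, mc.cores = threads)
  } else {
    lapply(chroms, one_chrom)
  }
  invisible(list(pairs = fl$pairs, report = fl$report, model = model,
                 outdir = outdir))
}

#' TAD-calling stage
#'
#' For each chromosome's normalized matrix in `matrixdir`, computes the
#' DI track, fits the three-state HMM (seeded, per chromosome), decodes
#' the "true DI" states, and derives TAD coordinates from the state
#' shifts; writes `.di.txt`, `.states.txt` and `.tads.txt` per
#' chromosome. Chromosomes with fewer than 30 finite DI values are
#' skipped with a log entry.
#'
#' @param matrixdir Directory holding `<chrom>.normalized.matrix.txt`
#'   files (as written by [run_normalize()]).
#' @param outdir Output directory.
#' @param window DI window in bp (default 2e6).
#' @param seed Seed for the HMM fit.
#' @return Invisibly, named list per chromosome with `di`, `states`,
#'   `tads`.
#' @export
run_tad <- function(matrixdir, outdir = matrixdir, window = 2e6, seed = 0L) {
  .ensure_outdir(outdir)
  files <- list.files(matrixdir, pattern = "\\.normalized\\.matrix\\.txt(\\.gz)?$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no normalized matrices found in ", matrixdir)
  out <- list()
  skipped <- character(0)
  for (fp in files) {
    N <- read_matrix_txt(fp)
    di <- directionality_index(N, window)
    if (sum(!di$masked) < 30L) {
      skipped <- c(skipped, N$chrom)
      next
    }
    model <- fit_hmm(di, seed = seed)
    st <- decode_states(model, di)
    tads <- call_tads(st)
    write_track(di$di, file.path(outdir, paste0(N$chrom, ".di.txt")))
    write_track(st$states, file.path(outdir, paste0(N$chrom, ".states.txt")))
    write_tads(tads, file.path(outdir, paste0(N$chrom, ".tads.txt")))
    out[[N$chrom]] <- list(di = di, states = st, tads = tads)
  }
  .write_log(list(chromosomes = names(out), skipped = skipped,
                  window = window, seed = seed),
             file.path(outdir, "tad_log.json"))
  invisible(out)
}
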