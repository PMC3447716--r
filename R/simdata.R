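#' Error model for simulated reads
#'
#' Describes how simulated base calls go wrong, emulating the failure modes
#' recalibration must fix: reported qualities that are systematically
#' miscalibrated relative to the true error probability, error rates that
#' climb toward the read ends, planted true variants, and fully
#' non-reference "systematic" positions that mimic alignment artifacts.
#'
#' The default reported-quality distribution puts almost half of all bases
#' near Q40 with a low-quality tail (including some Q0 calls, exercising
#' the zero-quality covariate). The default distortion makes the true error
#' probability ten times the probability the reported quality implies, so a
#' base reported at Q40 really errs at the Q30 rate. The default position
#' multiplier is flat over the first 80% of cycles and rises linearly to
#' 6x at the final cycle.
#'
#' @param read_length Bases per read (default 76).
#' @param reported_quality_levels,reported_quality_probs Support and
#'   probabilities of the reported-quality distribution.
#' @param distortion Function mapping the reported-quality-implied error
#'   probability to the true one (before the position multiplier).
#' @param position_multiplier Per-cycle multiplier on the true error
#'   probability; `NULL` for the default end-of-read ramp.
#' @param variants Data frame `pos`, `alt`, `freq`: planted variant sites;
#'   each overlapping read carries `alt` with probability `freq`.
#' @param systematic Data frame `pos`, `alt`: positions where *every*
#'   overlapping read carries `alt` (frequency 1), emulating systematic
#'   mapping artifacts.
#' @param error_cap Upper bound on any per-base true error probability.
#' @return Object of class `error_model_spec`.
#' @export
error_model_spec <- function(read_length = 76L,
                             reported_quality_levels = c(0L, 2L, 20L, 25L, 30L, 35L, 40L),
                             reported_quality_probs = c(0.02, 0.02, 0.06, 0.10, 0.15, 0.20, 0.45),
                             distortion = function(p) pmin(10 * p, 0.5),
                             position_multiplier = NULL,
                             variants = NULL,
                             systematic = NULL,
                             error_cap = 0.75) {
  read_length <- as.integer(read_length)
  stopifnot(read_length > 0L,
            length(reported_quality_levels) == length(reported_quality_probs),
            all(reported_quality_probs >= 0),
            is.function(distortion))
  if (is.null(position_multiplier)) {
    flat <- floor(0.8 * read_length)
    ramp <- seq_len(read_length) - flat
    position_multiplier <- ifelse(ramp <= 0, 1,
                                  1 + 5 * ramp / (read_length - flat))
  }
  stopifnot(length(position_multiplier) == read_length,
            all(position_multiplier > 0))
  if (!is.null(variants))
    stopifnot(all(c("pos", "alt", "freq") %in% names(variants)),
              all(variants$freq >= 0 & variants$freq <= 1))
  if (!is.null(systematic))
    stopifnot(all(c("pos", "alt") %in% names(systematic)))
  structure(list(read_length = read_length,
                 reported_quality_levels = as.integer(reported_quality_levels),
                 reported_quality_probs = reported_quality_probs / sum(reported_quality_probs),
                 distortion = distortion,
                 position_multiplier = position_multiplier,
                 variants = variants,
                 systematic = systematic,
                 error_cap = error_cap),
            class = "error_model_spec")
}

#' Generate a random reference FASTA
#'
#' Uniform A/C/G/T sequence, deterministic under the seed; the file is
#' faidx-indexed on write.
#'
#' @param length Sequence length (> 0).
#' @param seed RNG seed.
#' @param path Output FASTA path.
#' @param chrom Sequence name.
#' @return `path`, invisibly.
#' @export
simulate_reference <- function(length, seed = 1L,
                               path = tempfile(fileext = ".fa"),
                               chrom = "sim1") {
  length <- as.numeric(length)
  if (is.na(length) || length <= 0) stop("reference length must be > 0")
  set.seed(seed)
  seqchr <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  dna <- Biostrings::DNAStringSet(paste(seqchr, collapse = ""))
  names(dna) <- chrom
  Biostrings::writeXStringSet(dna, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Pick variant and systematic sites on a reference
#'
#' Chooses distinct positions using the current RNG state, assigns each a
#' non-reference alternate allele, and splits them into heterozygous-like
#' planted variants (allele frequency `var_freq`) and fully non-reference
#' systematic sites.
#'
#' @param ref_path Reference FASTA (used for length and reference alleles).
#' @param n_variants,n_systematic Site counts.
#' @param var_freq Allele frequency of planted variants (default 0.5).
#' @return List with data frames `variants` (`chrom`, `pos`, `alt`, `freq`)
#'   and `systematic` (`chrom`, `pos`, `alt`).
#' @export
sample_variant_sites <- function(ref_path, n_variants = 50L,
                                 n_systematic = 2L, var_freq = 0.5) {
  ref <- Biostrings::readDNAStringSet(ref_path)
  chrom <- sub("\\s.*$", "", names(ref)[1])
  refchr <- strsplit(as.character(ref[[1]]), "", fixed = TRUE)[[1]]
  n <- n_variants + n_systematic
  pos <- sort(sample.int(length(refchr), n))
  alt <- vapply(refchr[pos],
                function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                "", USE.NAMES = FALSE)
  vi <- seq_len(n_variants)
  list(variants = data.frame(chrom = chrom, pos = pos[vi], alt = alt[vi],
                             freq = var_freq, stringsAsFactors = FALSE),
       systematic = data.frame(chrom = chrom,
                               pos = pos[setdiff(seq_len(n), vi)],
                               alt = alt[setdiff(seq_len(n), vi)],
                               stringsAsFactors = FALSE))
}

#' Simulate a BAM with known per-base error labels
#'
#' Draws fixed-length, ungapped, single-end reads (CIGAR `<L>M`) uniformly
#' over the reference, plants variant and systematic alleles, assigns each
#' base a reported quality from the spec's distribution, and introduces
#' sequencing errors at the spec's true (distorted, position-dependent)
#' error probability. Output is a coordinate-sorted, indexed BAM plus a
#' truth table recording, for every base, whether it was a sequencing
#' error and whether it sits on a planted variant site — so tests can
#' separate miscalibration from variant contamination.
#'
#' @param ref_path Reference FASTA from [simulate_reference()].
#' @param spec An [error_model_spec()].
#' @param n_reads Number of reads.
#' @param out_prefix Output prefix; writes `<prefix>.bam`, `<prefix>.bam.bai`
#'   and `<prefix>.truth.tsv`.
#' @param seed RNG seed; the same seed reproduces the BAM byte for byte.
#' @return List with paths `bam`, `truth`, the `chrom` name and `n_reads`.
#' @export
simulate_bam <- function(ref_path, spec, n_reads, out_prefix, seed = 1L) {
  stopifnot(inherits(spec, "error_model_spec"), n_reads > 0)
  .check_samtools()
  set.seed(seed)
  ref <- Biostrings::readDNAStringSet(ref_path)
  chrom <- sub("\\s.*$", "", names(ref)[1])
  L <- Biostrings::width(ref)[1]
  rl <- spec$read_length
  if (rl > L) stop("read_length exceeds reference length")

  starts <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE))
  read_id <- rep.int(seq_len(n_reads), rep.int(rl, n_reads))
  cycle <- rep.int(seq_len(rl), n_reads)
  gpos <- starts[read_id] + cycle - 1L

  refchr <- strsplit(as.character(ref[[1]]), "", fixed = TRUE)[[1]]
  base <- refchr[gpos]
  is_variant_site <- rep(FALSE, length(gpos))

  if (!is.null(spec$variants)) {
    for (i in seq_len(nrow(spec$variants))) {
      hit <- which(gpos == spec$variants$pos[i])
      is_variant_site[hit] <- TRUE
      carrier <- hit[stats::runif(length(hit)) < spec$variants$freq[i]]
      base[carrier] <- spec$variants$alt[i]
    }
  }
  if (!is.null(spec$systematic)) {
    for (i in seq_len(nrow(spec$systematic))) {
      hit <- which(gpos == spec$systematic$pos[i])
      base[hit] <- spec$systematic$alt[i]
    }
  }

  q <- sample(spec$reported_quality_levels, length(gpos), replace = TRUE,
              prob = spec$reported_quality_probs)
  p_true <- pmin(spec$distortion(10^(-q / 10)) * spec$position_multiplier[cycle],
                 spec$error_cap)
  is_error <- stats::runif(length(gpos)) < p_true
  if (any(is_error)) {
    # substitute uniformly among the three other bases
    shift <- sample.int(3L, sum(is_error), replace = TRUE)
    cur <- match(base[is_error], c("A", "C", "G", "T"))
    base[is_error] <- c("A", "C", "G", "T")[(cur - 1L + shift) %% 4L + 1L]
  }

  seq_big <- paste(base, collapse = "")
  qual_big <- intToUtf8(q + 33L)
  ends <- seq_len(n_reads) * rl
  seqs <- substring(seq_big, ends - rl + 1L, ends)
  quals <- substring(qual_big, ends - rl + 1L, ends)
  qname <- sprintf("r%07d", seq_len(n_reads))

  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, L)), con)
  writeLines(paste(qname, 0L, chrom, starts, 60L, paste0(rl, "M"),
                   "*", 0L, 0L, seqs, quals, sep = "\t"), con)
  close(con)

  bam <- paste0(out_prefix, ".bam")
  if (system2("samtools", c("view", "--no-PG", "-b", "-o", shQuote(bam),
                            shQuote(sam))) != 0L)
    stop("samtools view failed while writing the simulated BAM")
  if (system2("samtools", c("index", shQuote(bam))) != 0L)
    stop("samtools index failed on the simulated BAM")

  truth <- paste0(out_prefix, ".truth.tsv")
  data.table::fwrite(data.table::data.table(
    read = qname[read_id], read_pos = cycle, chrom = chrom, pos = gpos,
    is_error = as.integer(is_error),
    is_variant_site = as.integer(is_variant_site)),
    truth, sep = "\t")

  list(bam = bam, truth = truth, chrom = chrom, n_reads = n_reads)
}
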