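# Fixture builders: tiny references and BAMs constructed in code, converted
# with the samtools CLI (also required by the package itself for output).

make_ref <- function(seq, chrom = "ref1", path = tempfile(fileext = ".fa")) {
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- chrom
  Biostrings::writeXStringSet(dna, path)
  Rsamtools::indexFa(path)
  path
}

# reads: data.frame(qname, chrom, pos, cigar, seq, qual[, flag, mapq])
make_bam <- function(reads, ref_len, chrom = "ref1",
                     path = tempfile(fileext = ".bam")) {
  if (is.null(reads$flag)) reads$flag <- 0L
  if (is.null(reads$mapq)) reads$mapq <- 60L
  reads <- reads[order(reads$pos), , drop = FALSE]
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, ref_len),
               paste(reads$qname, reads$flag, reads$chrom, reads$pos,
                     reads$mapq, reads$cigar, "*", 0L, 0L, reads$seq,
                     reads$qual, sep = "\t")), sam)
  stopifnot(system2("samtools", c("view", "-b", "-o", shQuote(path),
                                  shQuote(sam))) == 0L)
  stopifnot(system2("samtools", c("index", shQuote(path))) == 0L)
  unlink(sam)
  path
}

# random ungapped reads over a reference string; returns the reads frame
random_reads <- function(refchars, n, len = 8L, qual_levels = 10:40) {
  starts <- sample.int(length(refchars) - len + 1L, n, replace = TRUE)
  seqs <- vapply(starts, function(s)
    paste(refchars[s:(s + len - 1L)], collapse = ""), "")
  quals <- vapply(seq_len(n), function(i)
    intToUtf8(sample(qual_levels, len, replace = TRUE) + 33L), "")
  data.frame(qname = sprintf("t%05d", seq_len(n)), chrom = "ref1",
             pos = starts, cigar = paste0(len, "M"), seq = seqs,
             qual = quals, stringsAsFactors = FALSE)
}

# minimal fitted-model skeleton for prediction-side tests
make_model <- function(coefficients, flagged_positions = integer(),
                       q_max = 60L, read_length = 10L) {
  full <- c("(Intercept)" = 0, x1_qual = 0, x2_qual0 = 0, x3_read_avg = 0,
            x4_read_pos = 0, x5_baseA = 0, x6_baseC = 0, x7_baseG = 0)
  if (length(flagged_positions))
    full <- c(full, stats::setNames(rep(0, length(flagged_positions)),
                                    paste0("fp", flagged_positions)))
  full[names(coefficients)] <- coefficients
  structure(list(
    coefficients = full,
    flagged = structure(list(positions = as.integer(flagged_positions),
                             k = length(flagged_positions),
                             threshold = 0,
                             counts = integer(read_length),
                             read_length = read_length),
                        class = "flagged_positions"),
    subset_coefficients = matrix(full, nrow = 1,
                                 dimnames = list(NULL, names(full))),
    params = list(nerr = 2, nraf = 0.05, flag_multiplier = 1.5,
                  subset_size = 1e7, q_max = as.integer(q_max)),
    region = region_spec("ref1", 1, 1000),
    counts = list()),
    class = "recal_model")
}

# labeled-base frame builder for training/diagnostics tests
base_frame <- function(pos, base, ref_base, qual = 30L, chrom = "c1",
                       read_pos = 1L, read_mean_qual = 30) {
  n <- max(length(pos), length(base), length(ref_base), length(qual))
  data.frame(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             read_pos = rep_len(read_pos, n), base = rep_len(base, n),
             qual = rep_len(qual, n),
             read_mean_qual = rep_len(read_mean_qual, n),
             ref_base = rep_len(ref_base, n), stringsAsFactors = FALSE)
}
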