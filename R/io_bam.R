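#' Read aligned bases from a BAM training region
#'
#' Walks every read overlapping the region and emits one record per aligned
#' (CIGAR match/mismatch) base whose genomic position falls inside the
#' region. Insertions, soft clips and deletions contribute nothing. Reads
#' flagged unmapped, secondary or duplicate are skipped: training wants
#' trustworthy alignments. Records are returned in coordinate order of the
#' base (ties keep BAM file order), and collection stops after
#' `region$max_train` bases when that cap is set.
#'
#' `read_pos` is the 1-based offset of the base within the read as stored in
#' the BAM record, i.e. reference orientation; for reverse-strand reads this
#' is the aligned offset, not the sequencing cycle. `read_mean_qual` is the
#' mean of the full QUAL string of the containing read, including any
#' soft-clipped bases.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM.
#' @param region A `region_spec` or region string (see [parse_region()]).
#' @param ref Reference FASTA path or [Rsamtools::FaFile] covering the region.
#' @return A `data.frame` with columns `chrom`, `pos`, `read_pos`, `base`,
#'   `qual`, `read_mean_qual`, `ref_base`.
#' @export
read_aligned_bases <- function(bam_path, region, ref) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index (.bai) not found for ", bam_path,
         "; the input must be coordinate-sorted and indexed")
  fa <- .as_fafile(ref)
  region <- parse_region(region, ref = fa)

  fai <- as.data.frame(Rsamtools::scanFaIndex(fa))
  if (!region$chrom %in% as.character(fai$seqnames))
    stop("chromosome '", region$chrom, "' not present in the reference")

  which <- GenomicRanges::GRanges(region$chrom,
                                  IRanges::IRanges(region$start, region$end))
  param <- Rsamtools::ScanBamParam(
    what = c("pos", "cigar", "seq", "qual"),
    which = which,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  empty <- data.frame(chrom = character(), pos = integer(),
                      read_pos = integer(), base = character(),
                      qual = integer(), read_mean_qual = numeric(),
                      ref_base = character(), stringsAsFactors = FALSE)
  n_reads <- length(res$pos)
  if (n_reads == 0L) return(empty)

  # CIGAR M/=/X ranges in query and reference space, expanded base-wise
  ops <- c("M", "=", "X")
  qrl <- GenomicAlignments::cigarRangesAlongQuerySpace(res$cigar, ops = ops)
  qr <- unlist(qrl, use.names = FALSE)
  rr <- unlist(GenomicAlignments::cigarRangesAlongReferenceSpace(res$cigar, ops = ops),
               use.names = FALSE)
  op_read <- rep.int(seq_len(n_reads), lengths(qrl))
  w <- IRanges::width(qr)
  if (sum(w) == 0L) return(empty)

  base_read <- rep.int(op_read, w)
  qpos <- sequence(w, from = IRanges::start(qr))                   # offset in read
  gpos <- sequence(w, from = res$pos[op_read] + IRanges::start(rr) - 1L)

  keep <- gpos >= region$start & gpos <= region$end
  base_read <- base_read[keep]; qpos <- qpos[keep]; gpos <- gpos[keep]
  if (length(gpos) == 0L) return(empty)

  # flatten SEQ and QUAL once; per-read offsets index into the big vectors
  widths <- Biostrings::width(res$seq)
  offset <- c(0L, cumsum(widths))[seq_len(n_reads)]
  seq_chr <- strsplit(paste(as.character(res$seq), collapse = ""), "", fixed = TRUE)[[1]]
  qual_int <- as.integer(charToRaw(paste(as.character(res$qual), collapse = ""))) - 33L
  mean_q <- as.vector(rowsum(qual_int, rep.int(seq_len(n_reads), widths))) / widths

  flat <- offset[base_read] + qpos
  out <- data.frame(chrom = region$chrom,
                    pos = gpos,
                    read_pos = qpos,
                    base = seq_chr[flat],
                    qual = qual_int[flat],
                    read_mean_qual = mean_q[base_read],
                    stringsAsFactors = FALSE)
  rm(seq_chr, qual_int, flat, base_read, qpos, gpos, res, qr, rr)

  refseq <- Biostrings::getSeq(fa, GenomicRanges::GRanges(
    region$chrom, IRanges::IRanges(region$start,
                                   min(region$end, fai$end[match(region$chrom, fai$seqnames)]))))
  ref_chr <- strsplit(as.character(refseq[[1]]), "", fixed = TRUE)[[1]]
  ridx <- out$pos - region$start + 1L
  if (any(ridx > length(ref_chr)))
    stop("aligned bases extend past the end of the reference sequence")
  out$ref_base <- ref_chr[ridx]

  ord <- order(out$pos)   # stable: ties keep BAM order
  out <- out[ord, , drop = FALSE]
  if (!is.null(region$max_train) && nrow(out) > region$max_train)
    out <- out[seq_len(region$max_train), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a BAM with recalibrated quality scores
#'
#' Streams every record of `bam_in` through the fitted model and writes
#' `bam_out` with only the QUAL field changed: FLAG, CIGAR, SEQ, POS, tags,
#' read order and count are untouched. Every base of every read — aligned,
#' clipped, unmapped or duplicate — is recalibrated, because prediction needs
#' only read-level covariates, not a reference. Records without stored
#' qualities (QUAL `*`) pass through unchanged.
#'
#' Conversion of the rewritten SAM text to BAM and indexing are delegated to
#' the `samtools` executable, which must be on the PATH.
#'
#' @param bam_in Input BAM path.
#' @param bam_out Output BAM path.
#' @param model A fitted [recal_fit()] model.
#' @return Invisibly, a list with `reads_written` and `bases_recalibrated`.
#' @export
write_recalibrated_bam <- function(bam_in, bam_out, model) {
  .check_fitted(model)
  if (!file.exists(bam_in)) stop("BAM not found: ", bam_in)
  .check_samtools()

  tmp_sam <- tempfile(fileext = ".sam")
  on.exit(unlink(tmp_sam), add = TRUE)
  incon <- pipe(paste("samtools view -h", shQuote(bam_in)), open = "r")
  outcon <- file(tmp_sam, open = "w")
  reads <- 0L; bases <- 0L
  repeat {
    lines <- readLines(incon, n = 100000L)
    if (length(lines) == 0L) break
    hdr <- startsWith(lines, "@")
    if (any(hdr)) writeLines(lines[hdr], outcon)
    rec <- lines[!hdr]
    if (length(rec)) {
      sp <- strsplit(rec, "\t", fixed = TRUE)
      quals <- vapply(sp, `[[`, "", 11L)
      seqs <- vapply(sp, `[[`, "", 10L)
      ok <- quals != "*" & seqs != "*"
      if (any(ok)) {
        newq <- .recalibrate_qual_strings(model, seqs[ok], quals[ok])
        bases <- bases + sum(nchar(quals[ok]))
        j <- which(ok)
        for (i in seq_along(j)) sp[[j[i]]][11L] <- newq[i]
      }
      writeLines(vapply(sp, paste, "", collapse = "\t"), outcon)
      reads <- reads + length(rec)
    }
  }
  close(incon); close(outcon)

  status <- system2("samtools", c("view", "--no-PG", "-b", "-o",
                                  shQuote(bam_out), shQuote(tmp_sam)))
  if (status != 0L) stop("samtools view failed converting recalibrated SAM to BAM")
  idx <- suppressWarnings(system2("samtools", c("index", shQuote(bam_out)),
                                  stderr = FALSE))
  if (idx != 0L)
    warning("could not index ", bam_out, " (input not coordinate-sorted?)")
  invisible(list(reads_written = reads, bases_recalibrated = bases))
}

# Vectorized core shared by BAM rewriting: SEQ/QUAL strings in,
# recalibrated QUAL strings out.
.recalibrate_qual_strings <- function(model, seqs, quals) {
  widths <- nchar(quals)
  if (any(nchar(seqs) != widths)) stop("SEQ/QUAL length mismatch in BAM record")
  n <- length(quals)
  q <- as.integer(charToRaw(paste(quals, collapse = ""))) - 33L
  b <- charToRaw(paste(seqs, collapse = ""))
  read_id <- rep.int(seq_len(n), widths)
  newdata <- list(
    qual = q,
    read_mean_qual = (as.vector(rowsum(q, read_id)) / widths)[read_id],
    read_pos = sequence(widths),
    base_is_a = b == as.raw(65L) | b == as.raw(97L),
    base_is_c = b == as.raw(67L) | b == as.raw(99L),
    base_is_g = b == as.raw(71L) | b == as.raw(103L))
  p <- .predict_p(model, newdata)
  newq <- probability_to_phred(p, q_max = model$params$q_max)
  big <- intToUtf8(newq + 33L)
  ends <- cumsum(widths)
  substring(big, ends - widths + 1L, ends)
}

.check_samtools <- function() {
  if (Sys.which("samtools") == "")
    stop("the 'samtools' executable is required on the PATH for BAM output")
}
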