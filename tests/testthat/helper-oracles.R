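# Independent brute-force oracles. Deliberately written against the raw
# definitions, sharing no code with the implementation they check.

# walk one CIGAR string, emitting (genomic pos, read pos) pairs for M/=/X
oracle_cigar_walk <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  g <- pos; r <- 1L
  out <- list()
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      out[[length(out) + 1L]] <- cbind(gpos = g + seq_len(len[i]) - 1L,
                                       rpos = r + seq_len(len[i]) - 1L)
      g <- g + len[i]; r <- r + len[i]
    } else if (op[i] %in% c("D", "N")) {
      g <- g + len[i]
    } else if (op[i] %in% c("I", "S")) {
      r <- r + len[i]
    } # H, P consume nothing
  }
  if (length(out)) do.call(rbind, out) else
    cbind(gpos = integer(), rpos = integer())
}

# brute-force pileup over a reads frame: one row per aligned base in region
oracle_pileup <- function(reads, refchars, start, end) {
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    walk <- oracle_cigar_walk(reads$cigar[i], reads$pos[i])
    keep <- walk[, "gpos"] >= start & walk[, "gpos"] <= end
    if (!any(keep)) next
    walk <- walk[keep, , drop = FALSE]
    qv <- as.integer(charToRaw(reads$qual[i])) - 33L
    bv <- strsplit(reads$seq[i], "")[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      pos = walk[, "gpos"], read_pos = walk[, "rpos"],
      base = bv[walk[, "rpos"]], qual = qv[walk[, "rpos"]],
      read_mean_qual = mean(qv),
      ref_base = refchars[walk[, "gpos"]], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(), read_pos = integer(), base = character(),
               qual = integer(), read_mean_qual = numeric(),
               ref_base = character())
  out[order(out$pos), , drop = FALSE]
}

# per-position filter straight from the definition
oracle_position_filter <- function(bases, nerr = 2, nraf = 0.05) {
  keys <- unique(paste(bases$chrom, bases$pos))
  removed <- character()
  for (k in keys) {
    at <- bases[paste(bases$chrom, bases$pos) == k, ]
    n_nonref <- sum(at$base != at$ref_base)
    if (n_nonref > max(nerr, nraf * nrow(at))) removed <- c(removed, k)
  }
  bases[!(paste(bases$chrom, bases$pos) %in% removed), , drop = FALSE]
}

# FWSE straight from its definition, via an independent tally
oracle_fwse <- function(quals, errors, q_max = 60) {
  total <- 0
  n <- length(quals)
  for (q in unique(quals)) {
    at <- quals == q
    rate <- sum(errors[at]) / sum(at)
    e <- if (rate == 0) q_max else min(-10 * log10(rate), q_max)
    total <- total + (sum(at) / n) * (q - e)^2
  }
  total
}

# AUC by exhaustive pairwise comparison, ties counted one half
oracle_auc <- function(variant, error) {
  cmp <- outer(variant, error, function(v, e) (v > e) + 0.5 * (v == e))
  mean(cmp)
}
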