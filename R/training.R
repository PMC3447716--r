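#' Filter parameters for training-set construction
#'
#' A position is dropped from the training set when its number of called
#' errors exceeds `thresh = max(nerr, nraf * coverage)`: an absolute cap at
#' low coverage, a non-reference allele-frequency cap at high coverage.
#' Positions failing the cap are likely novel variants or systematic
#' alignment artifacts rather than independent sequencing errors.
#'
#' @param nerr Maximum number of tolerated errors at a position (default 2).
#' @param nraf Maximum tolerated non-reference allele frequency (default 0.05).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(nerr = 2, nraf = 0.05) {
  nerr <- as.numeric(nerr); nraf <- as.numeric(nraf)
  if (is.na(nerr) || nerr < 0) stop("nerr must be >= 0")
  if (is.na(nraf) || nraf < 0 || nraf > 1) stop("nraf must be in [0, 1]")
  structure(list(nerr = nerr, nraf = nraf), class = "filter_params")
}

#' Label sequencing errors against the reference
#'
#' A base is called a sequencing error when it differs from the reference
#' base at its position. Bases called `N`, or aligned over an `N` in the
#' reference, cannot be labeled and are dropped.
#'
#' @param bases Data frame from [read_aligned_bases()].
#' @return The same frame, minus unlabelable rows, with an integer
#'   `is_error` column (1 = mismatch).
#' @export
label_errors <- function(bases) {
  stopifnot(is.data.frame(bases), all(c("base", "ref_base") %in% names(bases)))
  keep <- bases$base != "N" & bases$ref_base != "N"
  out <- bases[keep, , drop = FALSE]
  out$is_error <- as.integer(out$base != out$ref_base)
  rownames(out) <- NULL
  out
}

#' Remove known-variant positions from a training set
#'
#' All bases at any listed position are removed, whatever their call: a
#' known variant site cannot contribute trustworthy error labels.
#'
#' @param bases Labeled training frame.
#' @param snp_positions Data frame with columns `chrom` and `pos`
#'   (see [read_known_variants()]); may be empty or `NULL`.
#' @return The surviving rows of `bases`.
#' @export
exclude_known_variants <- function(bases, snp_positions) {
  if (is.null(snp_positions) || nrow(snp_positions) == 0L) return(bases)
  stopifnot(all(c("chrom", "pos") %in% names(snp_positions)))
  key <- paste(bases$chrom, bases$pos)
  drop <- key %in% paste(snp_positions$chrom, snp_positions$pos)
  out <- bases[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a known-variant position list
#'
#' Accepts either a two-column whitespace/tab-delimited file of `chrom pos`
#' (1-based; lines starting `#` ignored) or a VCF, from which only CHROM and
#' POS are used.
#'
#' @param path File path.
#' @return Data frame with columns `chrom` (character) and `pos` (integer).
#' @export
read_known_variants <- function(path) {
  if (!file.exists(path)) stop("known-variant file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character",
                           stringsAsFactors = FALSE, fill = TRUE)
  if (nrow(tab) == 0L)
    return(data.frame(chrom = character(), pos = integer()))
  if (ncol(tab) < 2L) stop("known-variant file needs at least two columns (chrom, pos)")
  pos <- suppressWarnings(as.integer(tab[[2]]))
  if (anyNA(pos)) stop("non-numeric positions in known-variant file: ", path)
  unique(data.frame(chrom = tab[[1]], pos = pos, stringsAsFactors = FALSE))
}

#' Per-position error threshold
#'
#' `thresh = max(nerr, nraf * coverage)`, used as a real number with no
#' rounding. Positions whose called-error count strictly exceeds it are
#' removed from training.
#'
#' @param coverage Number of training-eligible bases at the position
#'   (vectorized).
#' @param params A [filter_params()] object.
#' @return Numeric threshold(s).
#' @export
compute_thresh <- function(coverage, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  if (any(coverage < 0)) stop("coverage must be >= 0")
  pmax(params$nerr, params$nraf * coverage)
}

#' Remove positions with too many called errors
#'
#' Positions where the non-reference base count strictly exceeds
#' [compute_thresh()] are removed wholesale — every base at the position
#' goes, error and non-error alike. Coverage is counted over the
#' training-eligible bases passed in (after N-dropping and known-variant
#' exclusion), since those are the bases whose labels the filter protects.
#' Boundary note: a position with exactly `thresh` errors is kept.
#'
#' @param bases Labeled training frame (needs `chrom`, `pos`, `is_error`).
#' @param params A [filter_params()] object.
#' @return A list with `kept` (surviving rows) and `removed_positions`
#'   (data frame `chrom`, `pos`, `coverage`, `n_nonref`).
#' @export
apply_position_filter <- function(bases, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"),
            all(c("chrom", "pos", "is_error") %in% names(bases)))
  if (nrow(bases) == 0L)
    return(list(kept = bases,
                removed_positions = data.frame(chrom = character(),
                                               pos = integer(),
                                               coverage = integer(),
                                               n_nonref = integer())))
  dt <- data.table::as.data.table(bases[c("chrom", "pos", "is_error")])
  summ <- dt[, list(coverage = .N, n_nonref = sum(is_error)),
             by = c("chrom", "pos")]
  summ$thresh <- compute_thresh(summ$coverage, params)
  bad <- summ[summ$n_nonref > summ$thresh, ]
  if (nrow(bad) == 0L) {
    kept <- bases
  } else {
    drop <- paste(bases$chrom, bases$pos) %in% paste(bad$chrom, bad$pos)
    kept <- bases[!drop, , drop = FALSE]
    rownames(kept) <- NULL
  }
  removed <- as.data.frame(bad[, c("chrom", "pos", "coverage", "n_nonref")])
  list(kept = kept, removed_positions = removed)
}
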