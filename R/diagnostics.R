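#' Tabulate empirical calibration per quality score
#'
#' Groups bases by their assigned quality score and computes, per score:
#' the base count, its relative frequency, the number of called errors,
#' and the empirical quality `-10*log10(errors/count)`. A perfectly
#' calibrated score has empirical quality equal to itself. Scores observed
#' with zero errors have no finite empirical quality; they are capped at
#' `q_max` and marked in the `zero_errors` column (they still contribute
#' `f * (q - q_max)^2` to [fwse()]).
#'
#' @param quals Integer vector of assigned quality scores.
#' @param errors Binary vector (1 = sequencing error), same length.
#' @param q_max Cap for empirical qualities of error-free bins (default 60).
#' @return A `calibration_table` data frame with columns `quality`,
#'   `count`, `errors`, `frequency`, `empirical_quality`, `zero_errors`.
#' @export
calibration_table <- function(quals, errors, q_max = 60L) {
  if (length(quals) == 0L) stop("cannot tabulate an empty set of bases")
  if (length(quals) != length(errors))
    stop("`quals` and `errors` must have the same length")
  err <- as.integer(errors)
  if (any(is.na(err)) || any(err < 0L | err > 1L))
    stop("`errors` must be binary")
  q <- as.integer(quals)
  cnt <- table(q)
  quality <- as.integer(names(cnt))
  count <- as.integer(cnt)
  nerrs <- as.integer(rowsum(err, q)[, 1L])
  emp <- ifelse(nerrs > 0L, -10 * log10(nerrs / count), as.numeric(q_max))
  emp <- pmin(emp, as.numeric(q_max))
  out <- data.frame(quality = quality,
                    count = count,
                    errors = nerrs,
                    frequency = count / sum(count),
                    empirical_quality = emp,
                    zero_errors = nerrs == 0L)
  .as_calibration_table(out, q_max)
}

.as_calibration_table <- function(df, q_max) {
  structure(as.data.frame(df), class = c("calibration_table", "data.frame"),
            q_max = as.integer(q_max))
}

#' Frequency-weighted squared error of a calibration table
#'
#' `sum over scores q of f(q) * (q - e(q))^2`, where `f` is the relative
#' frequency of bases assigned score `q` and `e(q)` its empirical quality:
#' the frequency-weighted squared vertical distance of the calibration
#' points from the 45-degree line. Zero means every assigned score matches
#' its observed error rate exactly. Empirical qualities enter unrounded.
#'
#' @param table A [calibration_table()].
#' @return Non-negative number.
#' @export
fwse <- function(table) {
  stopifnot(inherits(table, "calibration_table"))
  sum(table$frequency * (table$quality - table$empirical_quality)^2)
}

#' Export a calibration table as TSV
#'
#' @param table A [calibration_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  utils::write.table(table[c("quality", "count", "errors",
                             "empirical_quality", "frequency")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split non-reference bases into variant and error classes
#'
#' For discrimination analysis, every base differing from the reference is
#' assigned to one of two classes by position. Positions in the
#' known-variant list contribute their non-reference bases to the
#' **variant** class, but only when supported by at least
#' `max(3, nraf * coverage)` non-reference bases — weakly supported "known
#' variant" positions may really be errors. All other positions contribute
#' to the **error** class, but only when their non-reference count stays
#' within the training threshold `max(nerr, nraf * coverage)` — positions
#' above it may be novel variants or systematic alignment artifacts.
#' Positions failing their class's support rule are dropped entirely.
#'
#' @param bases Labeled frame over a test region (needs `chrom`, `pos`,
#'   `qual`, `is_error`; see [label_errors()]).
#' @param snp_positions Known-variant positions (`chrom`/`pos` data frame),
#'   or `NULL` for none.
#' @param params A [filter_params()] object.
#' @param min_variant_bases Minimum non-reference bases supporting a
#'   variant-class position (default 3).
#' @return Object of class `discrimination_set`: `variant_scores` and
#'   `error_scores`, the quality multisets of the two classes.
#' @export
build_discrimination_set <- function(bases, snp_positions,
                                     params = filter_params(),
                                     min_variant_bases = 3L) {
  stopifnot(inherits(params, "filter_params"),
            all(c("chrom", "pos", "qual", "is_error") %in% names(bases)))
  dt <- data.table::as.data.table(bases[c("chrom", "pos", "qual", "is_error")])
  summ <- dt[, list(coverage = .N, n_nonref = sum(is_error)),
             by = c("chrom", "pos")]
  key <- paste(summ$chrom, summ$pos)
  snp_key <- if (is.null(snp_positions) || nrow(snp_positions) == 0L) character()
             else paste(snp_positions$chrom, snp_positions$pos)
  is_snp <- key %in% snp_key

  err_ok <- !is_snp & summ$n_nonref <= compute_thresh(summ$coverage, params)
  var_ok <- is_snp & summ$n_nonref >= pmax(min_variant_bases,
                                           params$nraf * summ$coverage)
  base_key <- paste(dt$chrom, dt$pos)
  nonref <- dt$is_error == 1L
  structure(list(
    variant_scores = dt$qual[nonref & base_key %in% key[var_ok]],
    error_scores = dt$qual[nonref & base_key %in% key[err_ok]]),
    class = "discrimination_set")
}

#' @export
print.discrimination_set <- function(x, ...) {
  cat(sprintf("<discrimination set: %d variant-class, %d error-class bases>\n",
              length(x$variant_scores), length(x$error_scores)))
  invisible(x)
}

#' Discrimination AUC between variant and error quality scores
#'
#' The probability that a randomly chosen non-reference base at a
#' known-variant position has a higher quality score than a randomly
#' chosen presumed sequencing error, with ties counted one half — the
#' tie-corrected rank-sum (Mann-Whitney) estimator of the area under the
#' ROC curve. Variants are the positive class.
#'
#' @param variant_scores,error_scores Numeric score multisets; both must be
#'   non-empty. A `discrimination_set` may be given as the first argument.
#' @return AUC in \[0, 1\].
#' @export
auc_scores <- function(variant_scores, error_scores) {
  if (inherits(variant_scores, "discrimination_set")) {
    error_scores <- variant_scores$error_scores
    variant_scores <- variant_scores$variant_scores
  }
  nv <- length(variant_scores); ne <- length(error_scores)
  if (nv == 0L || ne == 0L)
    stop("both score classes must be non-empty to compute an AUC")
  r <- rank(c(variant_scores, error_scores), ties.method = "average")
  (sum(r[seq_len(nv)]) - nv * (nv + 1) / 2) / (nv * ne)
}
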