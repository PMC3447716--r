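#' Train a base-quality recalibration model
#'
#' The main fitting function. Aligned bases are collected from a training
#' region of the BAM, labeled as sequencing errors by comparison to the
#' reference, pruned of known-variant positions, and filtered by the
#' per-position error threshold `max(nerr, nraf * coverage)` (positions
#' exceeding it are removed wholesale: they are likely novel variants or
#' systematic alignment artifacts, not independent errors). Read positions
#' with unusually many errors are flagged, a logistic error model is fitted
#' by maximum likelihood on contiguous subsets of at most `subset_size`
#' bases, and the per-coefficient medians across subsets become the model.
#'
#' Covariates: reported quality, an indicator of reported quality zero
#' (many base callers use Q0 for randomly called bases), read mean quality,
#' read position, base identity (A/C/G against a T reference category), and
#' an indicator per flagged read position.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @param region Training region: a `region_spec` or a string
#'   (`"chrom:start-end"` or bare `"chrom"`).
#' @param ref Reference FASTA (path or [Rsamtools::FaFile]) covering the
#'   region.
#' @param snp Optional known-variant positions: a path accepted by
#'   [read_known_variants()] or a data frame with `chrom`/`pos`.
#' @param nerr,nraf Position-filter parameters, see [filter_params()].
#' @param max_train Optional cap on bases collected before filtering.
#' @param flag_multiplier Threshold multiplier for
#'   [flag_read_positions()] (default 1.5).
#' @param subset_size Maximum bases per regression subset (default 1e7).
#' @param q_max Quality cap for the Phred transform and for empirical
#'   qualities of error-free bins (default 60).
#' @param verbose Log training-set construction counts via [message()].
#' @return An object of class `recal_model`; see [predict.recal_model()],
#'   [plot.recal_model()], [write_recalibrated_bam()].
#' @examples
#' \dontrun{
#' fit <- recal_fit("aln.bam", "chr10", "ref.fa", snp = "dbsnp.tsv")
#' summary(fit)
#' write_recalibrated_bam("aln.bam", "aln.recal.bam", fit)
#' }
#' @export
recal_fit <- function(bam, region, ref, snp = NULL,
                      nerr = 2, nraf = 0.05, max_train = NULL,
                      flag_multiplier = 1.5, subset_size = 1e7,
                      q_max = 60L, verbose = TRUE) {
  cl <- match.call()
  params <- filter_params(nerr, nraf)
  fa <- .as_fafile(ref)
  region <- parse_region(region, ref = fa, max_train = max_train)

  say <- function(...) if (verbose) message(sprintf(...))
  bases <- read_aligned_bases(bam, region, fa)
  n_collected <- nrow(bases)
  say("collected %d aligned bases from %s:%d-%d",
      n_collected, region$chrom, region$start, region$end)
  if (n_collected == 0L) stop("no aligned bases in the training region")

  labeled <- label_errors(bases)
  rm(bases)
  say("labeled %d bases (%d N-bases dropped); %d called errors",
      nrow(labeled), n_collected - nrow(labeled), sum(labeled$is_error))

  if (is.character(snp)) snp <- read_known_variants(snp)
  n_before_snp <- nrow(labeled)
  labeled <- exclude_known_variants(labeled, snp)
  say("removed %d bases at known-variant positions", n_before_snp - nrow(labeled))

  filt <- apply_position_filter(labeled, params)
  n_labeled_kept <- nrow(labeled)
  # keep only the covariate columns from here on; the genomic coordinates
  # have served their purpose
  training <- filt$kept[c("qual", "read_mean_qual", "read_pos", "base",
                          "is_error")]
  filt$kept <- NULL
  rm(labeled); gc(FALSE)
  say("position filter removed %d bases at %d positions (thresh = max(%g, %g x coverage))",
      n_labeled_kept - nrow(training), nrow(filt$removed_positions),
      params$nerr, params$nraf)
  if (nrow(training) == 0L) stop("training set empty after filtering")
  if (sum(training$is_error) == 0L)
    stop("no sequencing errors left in the training set; cannot fit an error model")

  flagged <- flag_read_positions(training, flag_multiplier)
  say("flagged %d read position(s) above %.2f errors: %s", flagged$k,
      flagged$threshold,
      if (flagged$k) paste(flagged$positions, collapse = ", ") else "none")

  dm <- build_design_matrix(training, flagged)
  subset_coefficients <- fit_subsets(dm$x, dm$y, subset_size = subset_size)
  rm(dm); gc(FALSE)
  say("fitted %d regression subset(s) of <= %s bases",
      nrow(subset_coefficients),
      format(subset_size, big.mark = ",", scientific = FALSE))
  coefficients <- median_coefficients(subset_coefficients)
  zeroed <- names(coefficients)[is.na(coefficients)]
  if (length(zeroed)) {
    # covariate constant in every subset: it carries no information here
    coefficients[is.na(coefficients)] <- 0
    say("covariate(s) constant in all subsets, coefficient set to 0: %s",
        paste(zeroed, collapse = ", "))
  }

  model <- structure(list(
    call = cl,
    coefficients = coefficients,
    flagged = flagged,
    subset_coefficients = subset_coefficients,
    zeroed_coefficients = zeroed,
    params = list(nerr = params$nerr, nraf = params$nraf,
                  flag_multiplier = flag_multiplier,
                  subset_size = subset_size, q_max = as.integer(q_max)),
    region = region,
    counts = list(n_collected = n_collected,
                  n_labeled = n_before_snp,
                  n_snp_removed = n_before_snp - n_labeled_kept,
                  n_filter_removed_bases = n_labeled_kept - nrow(training),
                  n_filter_removed_positions = nrow(filt$removed_positions),
                  n_train = nrow(training),
                  n_errors = sum(training$is_error)),
    removed_positions = filt$removed_positions),
    class = "recal_model")

  recal_q <- probability_to_phred(.predict_p(model, training), q_max)
  model$cal_before <- calibration_table(training$qual, training$is_error,
                                        q_max = q_max)
  model$cal_after <- calibration_table(recal_q, training$is_error,
                                       q_max = q_max)
  model$fwse_before <- fwse(model$cal_before)
  model$fwse_after <- fwse(model$cal_after)
  say("training-set FWSE %.2f -> %.2f", model$fwse_before, model$fwse_after)
  model
}

#' @export
print.recal_model <- function(x, ...) {
  cat("Base-quality recalibration model\n")
  cat(sprintf("  training region: %s:%s-%s (%s bases kept of %s collected)\n",
              x$region$chrom,
              format(x$region$start, big.mark = ",", scientific = FALSE),
              format(x$region$end, big.mark = ",", scientific = FALSE),
              format(x$counts$n_train, big.mark = ","),
              format(x$counts$n_collected, big.mark = ",")))
  cat(sprintf("  flagged read positions (k = %d): %s\n", x$flagged$k,
              if (x$flagged$k) paste(x$flagged$positions, collapse = ", ")
              else "none"))
  cat(sprintf("  subsets fitted: %d; coefficients: %d\n",
              nrow(x$subset_coefficients), length(x$coefficients)))
  if (!is.null(x$fwse_before))
    cat(sprintf("  training FWSE: %.2f (reported) -> %.2f (recalibrated)\n",
                x$fwse_before, x$fwse_after))
  cat("\nCoefficients (median across subsets):\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.recal_model <- function(object, ...) object$coefficients

#' @export
summary.recal_model <- function(object, ...) {
  sc <- object$subset_coefficients
  tab <- cbind(median = object$coefficients,
               min = suppressWarnings(apply(sc, 2, min, na.rm = TRUE)),
               max = suppressWarnings(apply(sc, 2, max, na.rm = TRUE)),
               n_subsets = colSums(!is.na(sc)))
  structure(list(model = object, coefficient_table = tab),
            class = "summary.recal_model")
}

#' @export
print.summary.recal_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nPer-coefficient spread across subsets:\n")
  print(round(x$coefficient_table, 6))
  cat(sprintf("\nTraining-set construction:\n"))
  with(m$counts, {
    cat(sprintf("  %s collected; %s unlabelable (N); %s at known variants;\n",
                format(n_collected, big.mark = ","),
                format(n_collected - n_labeled, big.mark = ","),
                format(n_snp_removed, big.mark = ",")))
    cat(sprintf("  %s bases at %s positions over the error threshold;\n",
                format(n_filter_removed_bases, big.mark = ","),
                format(n_filter_removed_positions, big.mark = ",")))
    cat(sprintf("  %s trained on, of which %s called errors (%.4f%%)\n",
                format(n_train, big.mark = ","),
                format(n_errors, big.mark = ","), 100 * n_errors / n_train))
  })
  invisible(x)
}

#' Predict error probabilities or recalibrated qualities
#'
#' @param object A fitted `recal_model`.
#' @param newdata Data frame with columns `qual`, `read_mean_qual`,
#'   `read_pos`, `base`.
#' @param type `"response"` (error probability, default), `"phred"`
#'   (recalibrated integer quality) or `"link"` (log-odds).
#' @param ... Unused.
#' @return Numeric (or integer, for `"phred"`) vector, one value per row.
#' @export
predict.recal_model <- function(object, newdata,
                                type = c("response", "phred", "link"), ...) {
  type <- match.arg(type)
  .check_fitted(object)
  eta <- .linear_predictor(object, newdata)
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         phred = probability_to_phred(stats::plogis(eta),
                                      q_max = object$params$q_max))
}

#' Simulate error indicators from a fitted model
#'
#' Draws Bernoulli sequencing-error indicators at the model's predicted
#' per-base error probabilities, one column per replicate.
#'
#' @param object A fitted `recal_model`.
#' @param nsim Number of replicates.
#' @param seed Optional RNG seed.
#' @param newdata Covariate rows as in [predict.recal_model()].
#' @param ... Unused.
#' @return Data frame of 0/1 columns `sim_1 ... sim_nsim`.
#' @export
simulate.recal_model <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata, type = "response")
  out <- replicate(nsim, stats::rbinom(length(p), 1L, p), simplify = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}

#' Save or load a recalibration model as JSON
#'
#' The text document stores coefficients, flagged read positions, filter
#' parameters, the training region and the diagnostic tables, so a model
#' trained once can recalibrate many BAMs later.
#'
#' @param model A fitted `recal_model`.
#' @param path Output (or input) file path.
#' @return `write_recal_model` returns `path` invisibly;
#'   `read_recal_model` returns a `recal_model`.
#' @export
write_recal_model <- function(model, path) {
  .check_fitted(model)
  doc <- list(
    format = "baserecal_model",
    coefficients = as.list(model$coefficients),
    flagged = list(positions = model$flagged$positions,
                   k = model$flagged$k,
                   threshold = model$flagged$threshold,
                   counts = model$flagged$counts,
                   read_length = model$flagged$read_length),
    params = model$params,
    region = model$region[c("chrom", "start", "end", "max_train")],
    counts = model$counts,
    fwse = list(before = model$fwse_before, after = model$fwse_after),
    cal_before = as.data.frame(model$cal_before),
    cal_after = as.data.frame(model$cal_after))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recal_model
#' @export
read_recal_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$format) || doc$format != "baserecal_model")
    stop(path, " is not a baserecal model file")
  q_max <- as.integer(doc$params$q_max)
  flagged <- structure(list(positions = as.integer(doc$flagged$positions),
                            k = as.integer(doc$flagged$k),
                            threshold = doc$flagged$threshold,
                            counts = as.integer(doc$flagged$counts),
                            read_length = as.integer(doc$flagged$read_length)),
                       class = "flagged_positions")
  region <- region_spec(doc$region$chrom, doc$region$start, doc$region$end,
                        doc$region$max_train)
  model <- structure(list(call = NULL,
                          coefficients = unlist(doc$coefficients),
                          flagged = flagged,
                          subset_coefficients =
                            matrix(unlist(doc$coefficients), nrow = 1,
                                   dimnames = list(NULL, names(doc$coefficients))),
                          params = doc$params,
                          region = region,
                          counts = doc$counts,
                          fwse_before = doc$fwse$before,
                          fwse_after = doc$fwse$after),
                     class = "recal_model")
  if (!is.null(doc$cal_before)) {
    model$cal_before <- .as_calibration_table(doc$cal_before, q_max)
    model$cal_after <- .as_calibration_table(doc$cal_after, q_max)
  }
  model
}
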