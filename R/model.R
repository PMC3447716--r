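#' Flag high-error read positions
#'
#' Sequencing errors concentrate at particular read cycles (typically the
#' read ends). Any read position whose error count strictly exceeds
#' `multiplier` times the average number of errors per read position gets
#' its own indicator covariate in the regression model.
#'
#' @param training Labeled training frame (needs `read_pos`, `is_error`).
#' @param multiplier Threshold multiplier on the mean errors per read
#'   position (default 1.5).
#' @return Object of class `flagged_positions`: `positions` (ascending),
#'   `k`, `threshold`, `counts` (errors per read position), `read_length`.
#' @export
flag_read_positions <- function(training, multiplier = 1.5) {
  stopifnot(all(c("read_pos", "is_error") %in% names(training)))
  if (nrow(training) == 0L) stop("cannot flag read positions: empty training set")
  read_length <- max(training$read_pos)
  counts <- tabulate(training$read_pos[training$is_error == 1L],
                     nbins = read_length)
  threshold <- multiplier * sum(counts) / read_length
  structure(list(positions = as.integer(which(counts > threshold)),
                 k = sum(counts > threshold),
                 threshold = threshold,
                 counts = counts,
                 read_length = read_length),
            class = "flagged_positions")
}

#' @export
print.flagged_positions <- function(x, ...) {
  cat(sprintf("<%d flagged read position(s) of %d; threshold %.2f errors>\n",
              x$k, x$read_length, x$threshold))
  if (x$k) cat(" ", paste(x$positions, collapse = ", "), "\n")
  invisible(x)
}

#' Build the logistic-model design matrix
#'
#' Fixed column order: reported quality (x1), indicator of quality zero
#' (x2), read mean quality (x3), read position (x4), indicators of base
#' A/C/G (x5-x7; T and N form the reference category), then one indicator
#' per flagged read position.
#'
#' @param training Labeled training frame.
#' @param flagged A [flag_read_positions()] result.
#' @return List with `x` (numeric matrix, one row per base) and `y`
#'   (integer error labels).
#' @export
build_design_matrix <- function(training, flagged) {
  stopifnot(inherits(flagged, "flagged_positions"))
  cn <- c("x1_qual", "x2_qual0", "x3_read_avg", "x4_read_pos",
          "x5_baseA", "x6_baseC", "x7_baseG")
  if (flagged$k > 0L) cn <- c(cn, paste0("fp", flagged$positions))
  x <- matrix(0, nrow = nrow(training), ncol = length(cn),
              dimnames = list(NULL, cn))
  x[, 1L] <- training$qual
  x[, 2L] <- training$qual == 0L
  x[, 3L] <- training$read_mean_qual
  x[, 4L] <- training$read_pos
  x[, 5L] <- training$base == "A"
  x[, 6L] <- training$base == "C"
  x[, 7L] <- training$base == "G"
  for (m in seq_len(flagged$k))
    x[, 7L + m] <- training$read_pos == flagged$positions[m]
  list(x = x, y = as.integer(training$is_error))
}

#' Fit the logistic model on contiguous subsets
#'
#' Maximum-likelihood logistic regression (binomial IRLS via
#' [stats::glm.fit()]) on contiguous input-order slices of at most
#' `subset_size` rows. Splitting bounds memory on very large training sets;
#' slices follow input (coordinate) order for reproducibility. A column
#' that is constant within a slice (e.g. a flagged-position indicator that
#' never fires there) is dropped for that slice and its coefficient
#' recorded as `NA`. Slices with only one response class, or that fail to
#' converge, are skipped with a warning.
#'
#' @param x Design matrix from [build_design_matrix()].
#' @param y Binary response vector.
#' @param subset_size Maximum rows per slice (default 1e7).
#' @param epsilon,maxit IRLS convergence tolerance on the deviance and
#'   iteration cap.
#' @return Matrix of per-subset coefficient vectors (one row per converged
#'   subset; columns `(Intercept)` then the design columns).
#' @export
fit_subsets <- function(x, y, subset_size = 1e7, epsilon = 1e-8, maxit = 25L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  n <- nrow(x)
  if (n == 0L) stop("empty design matrix")
  n_sub <- ceiling(n / subset_size)
  cn <- c("(Intercept)", colnames(x))
  out <- matrix(NA_real_, nrow = 0L, ncol = length(cn),
                dimnames = list(NULL, cn))
  for (s in seq_len(n_sub)) {
    idx <- seq.int((s - 1L) * subset_size + 1L, min(s * subset_size, n))
    ys <- y[idx]
    if (length(unique(ys)) < 2L) {
      warning("subset ", s, " has a single response class; skipped")
      next
    }
    # avoid a full-matrix copy in the common single-subset case
    xs <- if (n_sub == 1L) x else x[idx, , drop = FALSE]
    keep <- vapply(seq_len(ncol(xs)), function(j) {
      r <- range(xs[, j]); r[1L] != r[2L]
    }, logical(1))
    xfit <- cbind(`(Intercept)` = 1, xs[, keep, drop = FALSE])
    if (n_sub > 1L) rm(xs)
    fit <- stats::glm.fit(xfit, ys, family = stats::binomial(),
                          control = stats::glm.control(epsilon = epsilon,
                                                       maxit = maxit))
    rm(xfit)
    converged <- fit$converged
    coefs <- fit$coefficients
    rm(fit); gc(FALSE)
    if (!converged) {
      warning("subset ", s, " did not converge in ", maxit,
              " iterations; skipped")
      next
    }
    row <- stats::setNames(rep(NA_real_, length(cn)), cn)
    row[names(coefs)] <- coefs
    out <- rbind(out, row)
  }
  if (nrow(out) == 0L) stop("no subset produced a converged logistic fit")
  rownames(out) <- NULL
  out
}

#' Combine subset fits by per-coefficient medians
#'
#' @param subset_coefficients Matrix from [fit_subsets()].
#' @return Named vector of element-wise medians across subsets (`NA`
#'   entries from dropped columns are ignored).
#' @export
median_coefficients <- function(subset_coefficients) {
  if (!is.matrix(subset_coefficients) || nrow(subset_coefficients) == 0L)
    stop("need at least one converged subset fit")
  apply(subset_coefficients, 2L, stats::median, na.rm = TRUE)
}

#' Convert an error probability to a Phred quality
#'
#' `floor(-10 * log10(p))`, clamped to `[0, q_max]`. The cap keeps extreme
#' linear predictors from producing absurd scores; at the default
#' `q_max = 60` the smallest representable error probability is 1e-6.
#'
#' @param p Error probabilities in (0, 1].
#' @param q_max Maximum reportable quality (default 60).
#' @return Integer qualities.
#' @export
probability_to_phred <- function(p, q_max = 60L) {
  if (any(p <= 0)) stop("error probability must be > 0")
  if (any(p > 1)) stop("error probability must be <= 1")
  q <- floor(-10 * log10(p))
  as.integer(pmin(pmax(q, 0), q_max))
}

# Linear predictor / probability for a fitted model. `newdata` supplies
# qual, read_mean_qual, read_pos, and either a `base` character column or
# precomputed base_is_a / base_is_c / base_is_g indicators.
.linear_predictor <- function(model, newdata) {
  b <- model$coefficients
  if (is.null(newdata$base_is_a)) {
    newdata$base_is_a <- newdata$base == "A"
    newdata$base_is_c <- newdata$base == "C"
    newdata$base_is_g <- newdata$base == "G"
  }
  eta <- b[["(Intercept)"]] +
    b[["x1_qual"]] * newdata$qual +
    b[["x2_qual0"]] * (newdata$qual == 0) +
    b[["x3_read_avg"]] * newdata$read_mean_qual +
    b[["x4_read_pos"]] * newdata$read_pos +
    b[["x5_baseA"]] * newdata$base_is_a +
    b[["x6_baseC"]] * newdata$base_is_c +
    b[["x7_baseG"]] * newdata$base_is_g
  for (fp in model$flagged$positions) {
    nm <- paste0("fp", fp)
    eta <- eta + b[[nm]] * (newdata$read_pos == fp)
  }
  eta
}

# inverse logit, kept strictly inside (0, 1) so the Phred transform is
# always defined even for saturating linear predictors
.predict_p <- function(model, newdata) {
  p <- stats::plogis(.linear_predictor(model, newdata))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Predicted sequencing-error probability for covariate rows
#'
#' @param model A fitted `recal_model`.
#' @param newdata Data frame with columns `qual`, `read_mean_qual`,
#'   `read_pos`, `base`.
#' @return Probabilities strictly inside (0, 1).
#' @export
predict_error_probability <- function(model, newdata) {
  .check_fitted(model)
  .predict_p(model, newdata)
}

.check_fitted <- function(model) {
  if (!inherits(model, "recal_model") || is.null(model$coefficients))
    stop("`model` must be a fitted recal_model (see recal_fit())")
  if (any(!is.finite(model$coefficients)))
    stop("model coefficients are not finite; refit before use")
  invisible(model)
}
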