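test_that("calibration tables tabulate counts, frequencies and empirical quality", {
  # 1000 bases at q=30 with exactly 1 error: rate 1e-3, empirical quality 30
  tab <- calibration_table(rep(30L, 1000), c(1L, rep(0L, 999)))
  expect_equal(tab$frequency, 1)
  expect_equal(tab$empirical_quality, 30)
  # 100 bases at q=20 with 10 errors: rate 0.1, empirical quality 10
  tab2 <- calibration_table(rep(20L, 100), rep(c(1L, 0L), c(10, 90)))
  expect_equal(tab2$empirical_quality, 10)
  expect_error(calibration_table(integer(), integer()), "empty")
  expect_error(calibration_table(1:3, c(0L, 1L)), "length")
})

test_that("mixed tables match a brute-force group-by tally", {
  set.seed(61)
  for (rep in 1:3) {
    q <- sample(c(2L, 10L, 20L, 30L, 40L), 4000, replace = TRUE)
    e <- rbinom(4000, 1, pmin(10^(-q / 10) * 3, 0.9))
    tab <- calibration_table(q, e)
    expect_equal(sum(tab$frequency), 1, tolerance = 1e-12)
    for (i in seq_len(nrow(tab))) {
      at <- q == tab$quality[i]
      expect_equal(tab$count[i], sum(at))
      expect_equal(tab$errors[i], sum(e[at]))
    }
    expect_equal(fwse(tab), oracle_fwse(q, e))
  }
})

test_that("zero-error bins are capped at q_max and marked", {
  tab <- calibration_table(rep(c(10L, 20L), c(50, 50)),
                           rep(c(1L, 0L), c(50, 50)))
  expect_equal(tab$empirical_quality[tab$quality == 20], 60)
  expect_true(tab$zero_errors[tab$quality == 20])
  expect_false(tab$zero_errors[tab$quality == 10])
  # the capped bin still contributes f * (q - q_max)^2
  expect_equal(fwse(tab), 0.5 * (10 - 0)^2 + 0.5 * (20 - 60)^2)
})

test_that("FWSE reproduces hand-computed values and the zero law", {
  # a single bin reported 40, empirical 30, frequency one half contributes 50
  quals <- rep(c(40L, 20L), c(1000, 1000))
  errs <- c(rep(c(1L, 0L), c(1, 999)),      # q40: rate 1e-3 -> empirical 30
            rep(c(1L, 0L), c(10, 990)))     # q20: rate 1e-2 -> empirical 20
  tab <- calibration_table(quals, errs)
  expect_equal(tab$empirical_quality, c(20, 30))
  expect_equal(fwse(tab), 0.5 * (40 - 30)^2)

  # two-bin table {q=10, e=12, f=0.25; q=20, e=20, f=0.75} -> 1.0
  tab2 <- structure(data.frame(quality = c(10, 20), count = c(25, 75),
                               errors = c(2, 1), frequency = c(0.25, 0.75),
                               empirical_quality = c(12, 20),
                               zero_errors = FALSE),
                    class = c("calibration_table", "data.frame"), q_max = 60L)
  expect_equal(fwse(tab2), 0.25 * (10 - 12)^2)

  # perfectly calibrated table: FWSE exactly 0; otherwise strictly positive
  perfect <- calibration_table(rep(20L, 100), rep(c(1L, 0L), c(1, 99)))
  expect_equal(perfect$empirical_quality, 20)
  expect_equal(fwse(perfect), 0)
  expect_gte(fwse(tab), 0)
})

test_that("AUC is the rank-sum estimator with ties counted one half", {
  expect_equal(auc_scores(rep(40, 5), rep(10, 7)), 1.0)
  expect_equal(auc_scores(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_error(auc_scores(numeric(), 1:3), "non-empty")
  set.seed(71)
  for (rep in 1:10) {
    v <- sample(0:6, sample(3:40, 1), replace = TRUE)
    e <- sample(0:6, sample(3:40, 1), replace = TRUE)
    expect_equal(auc_scores(v, e), oracle_auc(v, e))
    expect_equal(auc_scores(v, e) + auc_scores(e, v), 1)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(72)
  v <- sample(10:45, 200, replace = TRUE)
  e <- sample(0:40, 300, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(200, 300)), predictor = c(v, e),
    direction = "<", quiet = TRUE)))
  expect_equal(auc_scores(v, e), ref, tolerance = 1e-12)
})

test_that("discrimination classes respect the support filters", {
  params <- filter_params()
  # a lone mismatch at coverage 40 at a non-variant position -> error class
  err_pos <- label_errors(base_frame(pos = 1L, ref_base = "A",
                                     base = rep(c("C", "A"), c(1, 39)),
                                     qual = 17L))
  # a known-variant position with only 2 non-reference bases -> dropped
  weak_var <- label_errors(base_frame(pos = 2L, ref_base = "G",
                                      base = rep(c("T", "G"), c(2, 38)),
                                      qual = 25L))
  # coverage 200 with 8 non-reference (frequency 0.04 < 0.05) -> dropped
  lowfreq_var <- label_errors(base_frame(pos = 3L, ref_base = "C",
                                         base = rep(c("A", "C"), c(8, 192)),
                                         qual = 33L))
  # a solid variant: 30 of 60 non-reference
  good_var <- label_errors(base_frame(pos = 4L, ref_base = "T",
                                      base = rep(c("G", "T"), c(30, 30)),
                                      qual = 39L))
  bases <- rbind(err_pos, weak_var, lowfreq_var, good_var)
  snps <- data.frame(chrom = "c1", pos = 2:4)
  ds <- build_discrimination_set(bases, snps, params)
  expect_equal(ds$error_scores, 17L)
  expect_equal(ds$variant_scores, rep(39L, 30))

  # an overloaded non-variant position (above thresh) joins neither class
  sys <- label_errors(base_frame(pos = 5L, ref_base = "A",
                                 base = rep("G", 50), qual = 21L))
  ds2 <- build_discrimination_set(rbind(bases, sys), snps, params)
  expect_false(any(ds2$error_scores == 21L))
  expect_false(any(ds2$variant_scores == 21L))
})

test_that("diagnostic figure renders four panels to a file", {
  set.seed(81)
  q <- sample(c(10L, 20L, 30L, 40L), 5000, replace = TRUE)
  e <- rbinom(5000, 1, pmin(10^(-q / 10) * 5, 0.5))
  model <- make_model(c("(Intercept)" = qlogis(0.01)))
  model$cal_before <- calibration_table(q, e)
  model$cal_after <- calibration_table(pmax(q - 7L, 0L), e)
  model$fwse_before <- fwse(model$cal_before)
  model$fwse_after <- fwse(model$cal_after)
  png_path <- tempfile(fileext = ".png")
  plot_diagnostics(model, png_path)
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
  pdf_path <- tempfile(fileext = ".pdf")
  plot_diagnostics(model, pdf_path, format = "pdf")
  expect_true(file.exists(pdf_path) && file.size(pdf_path) > 0)
  model$cal_before <- NULL
  expect_error(plot(model), "calibration tables")
})
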