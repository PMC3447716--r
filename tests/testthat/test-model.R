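test_that("read-position flagging uses 1.5x the mean errors per position", {
  # per-position error counts [10, 10, 10, 100]: mean 32.5, threshold 48.75
  tr <- data.frame(read_pos = rep(1:4, c(30, 30, 30, 110)),
                   is_error = c(rep(c(1L, 0L), c(10, 20)),
                                rep(c(1L, 0L), c(10, 20)),
                                rep(c(1L, 0L), c(10, 20)),
                                rep(c(1L, 0L), c(100, 10))))
  fl <- flag_read_positions(tr)
  expect_equal(fl$counts, c(10L, 10L, 10L, 100L))
  expect_equal(fl$threshold, 48.75)
  expect_equal(fl$positions, 4L)
  expect_equal(fl$k, 1L)
})

test_that("uniform errors flag nothing; empty training errors out", {
  tr <- data.frame(read_pos = rep(1:5, each = 20),
                   is_error = rep(c(1L, 0L, 0L, 0L), 25))
  expect_equal(flag_read_positions(tr)$k, 0L)
  expect_error(flag_read_positions(tr[0, ]), "empty")
})

test_that("flagging equals an independent threshold scan on random data", {
  set.seed(11)
  for (rep in 1:5) {
    rl <- sample(5:20, 1)
    tr <- data.frame(read_pos = sample.int(rl, 2000, replace = TRUE),
                     is_error = rbinom(2000, 1, 0.1))
    tr$read_pos[1] <- rl  # pin the read length
    fl <- flag_read_positions(tr, multiplier = 1.5)
    cnt <- vapply(seq_len(rl), function(p)
      sum(tr$is_error[tr$read_pos == p]), 0L)
    expect_equal(fl$positions, which(cnt > 1.5 * mean(cnt)))
  }
})

test_that("design matrix columns follow the fixed covariate order", {
  tr <- data.frame(qual = c(0L, 35L, 20L), read_mean_qual = c(10, 30, 25),
                   read_pos = c(5L, 7L, 2L), base = c("G", "T", "A"),
                   is_error = c(1L, 0L, 0L))
  fl <- structure(list(positions = c(2L, 7L), k = 2L, threshold = 1,
                       counts = integer(7), read_length = 7L),
                  class = "flagged_positions")
  dm <- build_design_matrix(tr, fl)
  expect_equal(colnames(dm$x),
               c("x1_qual", "x2_qual0", "x3_read_avg", "x4_read_pos",
                 "x5_baseA", "x6_baseC", "x7_baseG", "fp2", "fp7"))
  # base G with quality 0 at unflagged position 5
  expect_equal(unname(dm$x[1, ]), c(0, 1, 10, 5, 0, 0, 1, 0, 0))
  # base T is the reference category, at flagged position fp7
  expect_equal(unname(dm$x[2, ]), c(35, 0, 30, 7, 0, 0, 0, 0, 1))
  # base A at flagged position fp2
  expect_equal(unname(dm$x[3, ]), c(20, 0, 25, 2, 1, 0, 0, 1, 0))
  expect_equal(dm$y, c(1L, 0L, 0L))
})

test_that("a single subset reproduces the direct full-data fit", {
  set.seed(21)
  n <- 5000
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.3))
  eta <- -2 + 1.2 * x[, 1] - 0.8 * x[, 2]
  y <- rbinom(n, 1, plogis(eta))
  sc <- fit_subsets(x, y, subset_size = 1e7)
  expect_equal(nrow(sc), 1L)
  direct <- glm(y ~ x, family = binomial())
  expect_equal(unname(sc[1, ]), unname(coef(direct)), tolerance = 1e-6)
})

test_that("subset slicing is contiguous ceiling division; degenerate slices are handled", {
  set.seed(22)
  n <- 2500
  x <- cbind(a = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + x[, 1]))
  sc <- fit_subsets(x, y, subset_size = 1000)
  expect_equal(nrow(sc), 3L)   # 1000 + 1000 + 500

  # last slice single-class: skipped with a warning, others survive
  y2 <- y; y2[2001:2500] <- 0L
  expect_warning(sc2 <- fit_subsets(x, y2, subset_size = 1000),
                 "single response class")
  expect_equal(nrow(sc2), 2L)
  expect_error(suppressWarnings(fit_subsets(x, rep(0L, n), subset_size = 1000)),
               "no subset")

  # a column constant within one slice is dropped there (NA), kept elsewhere
  x3 <- cbind(a = rnorm(n), flag = c(rep(0, 1000), rbinom(n - 1000, 1, 0.5)))
  y3 <- rbinom(n, 1, plogis(-1 + 0.5 * x3[, "flag"]))
  sc3 <- fit_subsets(x3, y3, subset_size = 1000)
  expect_true(is.na(sc3[1, "flag"]))
  expect_false(anyNA(sc3[2:3, "flag"]))
})

test_that("median combination is element-wise, with even-count interpolation", {
  m <- rbind(c(1, 5), c(2, 6), c(9, 7))
  colnames(m) <- c("a", "b")
  expect_equal(median_coefficients(m), c(a = 2, b = 6))
  m4 <- rbind(c(1), c(2), c(3), c(10)); colnames(m4) <- "a"
  expect_equal(median_coefficients(m4), c(a = 2.5))
  one <- matrix(c(3, 4), nrow = 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(median_coefficients(one), c(a = 3, b = 4))
  expect_error(median_coefficients(one[0, , drop = FALSE]), "at least one")
})

test_that("predicted probabilities match a hand-rolled inverse logit", {
  set.seed(33)
  for (rep in 1:20) {
    beta <- rnorm(8)
    names(beta) <- c("(Intercept)", "x1_qual", "x2_qual0", "x3_read_avg",
                     "x4_read_pos", "x5_baseA", "x6_baseC", "x7_baseG")
    model <- make_model(beta, flagged_positions = 3L)
    model$coefficients["fp3"] <- fp3 <- rnorm(1)
    row <- data.frame(qual = sample(0:40, 1), read_mean_qual = runif(1, 0, 40),
                      read_pos = sample(1:5, 1),
                      base = sample(c("A", "C", "G", "T"), 1))
    eta <- beta[1] + beta[2] * row$qual + beta[3] * (row$qual == 0) +
      beta[4] * row$read_mean_qual + beta[5] * row$read_pos +
      beta[6] * (row$base == "A") + beta[7] * (row$base == "C") +
      beta[8] * (row$base == "G") + fp3 * (row$read_pos == 3)
    p <- min(max(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)  # published clamp
    expect_equal(predict_error_probability(model, row), unname(p),
                 tolerance = 1e-12)
    expect_gt(predict_error_probability(model, row), 0)
    expect_lt(predict_error_probability(model, row), 1)
  }
})

test_that("constant-intercept models predict the intercept probability", {
  model <- make_model(c("(Intercept)" = 0))
  row <- data.frame(qual = 0, read_mean_qual = 0, read_pos = 1, base = "T")
  expect_equal(predict_error_probability(model, row), 0.5)
  model2 <- make_model(c("(Intercept)" = qlogis(0.001)))
  rows <- data.frame(qual = c(10, 40), read_mean_qual = 0, read_pos = 1:2,
                     base = "T")
  expect_equal(predict_error_probability(model2, rows), c(0.001, 0.001))
})

test_that("the Phred transform floors, clamps and rejects impossible inputs", {
  expect_identical(probability_to_phred(0.001), 30L)
  expect_identical(probability_to_phred(0.5), 3L)
  expect_identical(probability_to_phred(1), 0L)
  expect_identical(probability_to_phred(1e-9), 60L)       # capped at q_max
  expect_identical(probability_to_phred(1e-9, q_max = 90L), 90L)
  expect_error(probability_to_phred(0), "> 0")
  expect_error(probability_to_phred(-0.1), "> 0")
  expect_error(probability_to_phred(1.2), "<= 1")
  # non-increasing in p, always an integer in [0, q_max]
  p <- sort(runif(500, 1e-8, 1))
  q <- probability_to_phred(p)
  expect_true(all(diff(q) <= 0L))
  expect_true(all(q >= 0L & q <= 60L))
  expect_true(is.integer(q))
})

test_that("subset-median fitting recovers known generating coefficients", {
  set.seed(44)
  n <- 50000
  x <- cbind(x1_qual = sample(5:40, n, replace = TRUE),
             x4_read_pos = sample(1:76, n, replace = TRUE))
  beta <- c(`(Intercept)` = 1.2, x1_qual = -0.18, x4_read_pos = 0.015)
  y <- rbinom(n, 1, plogis(beta[1] + x %*% beta[-1]))
  sc <- fit_subsets(x, y, subset_size = 12500)
  expect_equal(nrow(sc), 4L)
  est <- median_coefficients(sc)
  # SE of a single-subset ML fit bounds the median's deviation generously
  se <- sqrt(diag(vcov(glm(y[1:12500] ~ x[1:12500, ], family = binomial()))))
  expect_true(all(abs(est - beta) < 3 * se))
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(55)
  beta <- rnorm(8, sd = 0.3)
  names(beta) <- c("(Intercept)", "x1_qual", "x2_qual0", "x3_read_avg",
                   "x4_read_pos", "x5_baseA", "x6_baseC", "x7_baseG")
  model <- make_model(beta, flagged_positions = c(7L, 9L))
  model$coefficients[c("fp7", "fp9")] <- c(0.8, 1.1)
  path <- tempfile(fileext = ".json")
  write_recal_model(model, path)
  back <- read_recal_model(path)
  rows <- data.frame(qual = c(0, 12, 40), read_mean_qual = c(5, 20, 38),
                     read_pos = c(7L, 9L, 3L), base = c("A", "T", "G"))
  expect_equal(predict_error_probability(back, rows),
               predict_error_probability(model, rows))
  expect_equal(back$flagged$positions, c(7L, 9L))
  expect_error(read_recal_model(tempfile()), "")
})
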