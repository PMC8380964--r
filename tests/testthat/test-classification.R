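test_that("confusion metrics reproduce printed fractions", {
  # 27/40 patients and 26/37 controls correct
  truth <- rep(c("patient", "control"), c(40, 37))
  pred <- c(rep("patient", 27), rep("control", 13),
            rep("control", 26), rep("patient", 11))
  cm <- confusion_metrics(pred, truth)
  expect_equal(round(cm$sensitivity, 2), 67.50)
  expect_equal(round(cm$specificity, 2), 70.27)
  expect_equal(cm$counts$positive, "27/40")
  expect_equal(cm$counts$negative, "26/37")
  expect_equal(cm$accuracy, 100 * 53 / 77)

  # exact accuracy identity in counts
  expect_equal(cm$accuracy * 77 / 100, cm$sensitivity * 40 / 100 +
                 cm$specificity * 37 / 100)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(c(perfect$sensitivity, perfect$specificity,
                 perfect$accuracy), c(100, 100, 100))
  flipped <- confusion_metrics(ifelse(truth == "patient", "control",
                                      "patient"), truth)
  expect_equal(c(flipped$sensitivity, flipped$specificity,
                 flipped$accuracy), c(0, 0, 0))
  expect_error(confusion_metrics(rep("control", 3), rep("control", 3)),
               "positive class")
})

test_that("a margin-separated feature classifies perfectly", {
  n <- 12L
  feats <- data.frame(subject_id = sprintf("s%02d", 1:(2 * n)),
                      region1 = c(withr::with_seed(1, runif(n, 1, 2)),
                                  withr::with_seed(2, runif(n, -2, -1))))
  labels <- rep(c("patient", "control"), each = n)
  res <- loo_svm_single_region(feats, labels, "region1")
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 100)
  expect_equal(res$accuracy, 100)
})

test_that("LOO classification is deterministic and validates input", {
  feats <- data.frame(subject_id = sprintf("s%02d", 1:16),
                      region1 = withr::with_seed(3, rnorm(16)))
  labels <- rep(c("patient", "control"), each = 8)
  a <- loo_svm_single_region(feats, labels, "region1")
  b <- loo_svm_single_region(feats, labels, "region1")
  expect_identical(a$predictions, b$predictions)
  expect_identical(c(a$C, a$gamma), c(b$C, b$gamma))
  expect_error(loo_svm_single_region(feats, labels, "nope"), "not found")
  expect_error(loo_svm_single_region(feats, labels, "region1",
                                     grid = data.frame()), "empty")
  expect_error(loo_svm_single_region(feats, rep("patient", 16),
                                     "region1"), "per class")
})

test_that("accuracy at separation d = 3 approaches the Bayes bound", {
  accs <- vapply(1:8, function(s) {
    x <- withr::with_seed(s, c(rnorm(20, 3), rnorm(20, 0)))
    feats <- data.frame(subject_id = sprintf("s%02d", 1:40), region1 = x)
    labels <- rep(c("patient", "control"), each = 20)
    loo_svm_single_region(feats, labels, "region1")$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 90)
})

test_that("label-permuted nulls hover at chance accuracy", {
  accs <- vapply(1:25, function(s) {
    withr::with_seed(400 + s, {
      x <- rnorm(20)
      labels <- sample(rep(c("patient", "control"), each = 10))
    })
    feats <- data.frame(subject_id = sprintf("s%02d", 1:20), region1 = x)
    loo_svm_single_region(feats, labels, "region1")$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 40)
  expect_lte(mean(accs), 60)
})

test_that("accuracy decreases as the planted separation shrinks", {
  acc_at_d <- function(d) {
    mean(vapply(1:6, function(s) {
      x <- withr::with_seed(1000 * d + s, c(rnorm(15, d), rnorm(15, 0)))
      feats <- data.frame(subject_id = sprintf("s%02d", 1:30),
                          region1 = x)
      labels <- rep(c("patient", "control"), each = 15)
      loo_svm_single_region(feats, labels, "region1")$accuracy
    }, numeric(1)))
  }
  accs <- vapply(c(3, 1, 0), acc_at_d, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("ties resolve to the smallest C then gamma", {
  g <- default_svm_grid()
  expect_equal(g$C[1], 2^-5)
  expect_equal(g$gamma[1], 2^-5)
  expect_true(!is.unsorted(g$C))
  # perfectly separable data: many grid points tie at 100%; the reported
  # pair must be the first in grid order among the winners
  feats <- data.frame(subject_id = sprintf("s%02d", 1:12),
                      region1 = rep(c(5, -5), each = 6))
  labels <- rep(c("patient", "control"), each = 6)
  res <- loo_svm_single_region(feats, labels, "region1")
  y <- factor(labels, levels = c("control", "patient"))
  accs <- vapply(seq_len(nrow(g)), function(i)
    mean(nethom:::loo_predictions(feats$region1, y, g$C[i],
                                  g$gamma[i]) == labels), numeric(1))
  first_best <- which(accs > max(accs) - 1e-12)[1]
  expect_equal(res$C, g$C[first_best])
  expect_equal(res$gamma, g$gamma[first_best])
})
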