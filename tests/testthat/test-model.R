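blob_data <- function(n = 100, sep = 3, seed = 61) {
  set.seed(seed)
  y <- rep(c(1, -1), n / 2)
  tibble::tibble(
    patient_id = rep(c("A", "B"), each = n / 2),
    slice = 1L, row = seq_len(n), col = 1L, label = y,
    f1 = (rnorm(n, 0, 0.6) + ifelse(y > 0, sep, 0) + 3) / 10,
    f2 = (rnorm(n, 0, 0.6) + ifelse(y > 0, sep, 0) + 3) / 10
  )
}

test_that("well-separated blobs are fit almost perfectly", {
  tab <- blob_data()
  m <- train_rbf_svm(tab, svm_hyperparams(10, 1))
  acc <- mean((decision_values(m, tab) > 0) == (tab$label > 0))
  expect_gte(acc, 0.99)
})

test_that("the RBF kernel solves XOR where linear classifiers cannot", {
  set.seed(62)
  n <- 200
  x1 <- runif(n); x2 <- runif(n)
  y <- ifelse(xor(x1 > 0.5, x2 > 0.5), 1, -1)
  tab <- tibble::tibble(patient_id = "A", slice = 1L, row = seq_len(n),
                        col = 1L, label = y, f1 = x1, f2 = x2)
  m <- train_rbf_svm(tab, svm_hyperparams(10, 10))
  acc <- mean((decision_values(m, tab) > 0) == (y > 0))
  expect_gt(acc, 0.9)
  lin <- stats::glm(I(y > 0) ~ x1 + x2, family = binomial())
  lin_acc <- mean((predict(lin) > 0) == (y > 0))
  expect_lte(lin_acc, 0.65)
})

test_that("duplicating every training point leaves the boundary unchanged", {
  # separable data fit hard-margin-like: the max-margin solution does not
  # depend on sample multiplicity
  tab <- blob_data(n = 60, sep = 4)
  m1 <- train_rbf_svm(tab, svm_hyperparams(100, 1))
  m2 <- train_rbf_svm(dplyr::bind_rows(tab, tab), svm_hyperparams(100, 1))
  set.seed(68)
  probe <- tibble::tibble(f1 = runif(50), f2 = runif(50))
  expect_equal(decision_values(m2, probe), decision_values(m1, probe),
               tolerance = 1e-3)
})

test_that("single-class training data is rejected", {
  tab <- blob_data()
  tab$label <- 1
  expect_error(train_rbf_svm(tab, svm_hyperparams(1, 1)), "classes")
})

test_that("the Platt probability formula is sane at A = 0, B = 0", {
  f <- c(-10, -1, 0, 1, 10)
  expect_equal(platt_probability(f, c(A = 0, B = 0)), rep(0.5, 5))
})

test_that("symmetric balanced decision values calibrate to P(0) = 0.5", {
  f <- c(rep(-1, 20), rep(1, 20))
  y <- c(rep(-1, 20), rep(1, 20))
  AB <- platt_calibrate(f, y)
  expect_lt(AB[["A"]], 0)
  expect_equal(platt_probability(0, AB), 0.5, tolerance = 1e-6)
})

test_that("Platt fit matches an independent optim() minimizer", {
  set.seed(63)
  f <- c(rnorm(30, 1.2), rnorm(40, -0.8))
  y <- c(rep(1, 30), rep(-1, 40))
  AB <- platt_calibrate(f, y)
  n_pos <- 30; n_neg <- 40
  t <- ifelse(y > 0, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  ref <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14))
  expect_equal(nll(c(AB[["A"]], AB[["B"]])), ref$value, tolerance = 1e-6)
  expect_equal(AB[["A"]], ref$par[1], tolerance = 1e-3)
})

test_that("label flip gives a mirror calibration with identical likelihood", {
  set.seed(64)
  f <- c(rnorm(25, 1), rnorm(25, -1))
  y <- c(rep(1, 25), rep(-1, 25))
  AB1 <- platt_calibrate(f, y)
  AB2 <- platt_calibrate(-f, -y)
  nll <- function(AB, f, y) {
    n_pos <- sum(y > 0); n_neg <- sum(y <= 0)
    t <- ifelse(y > 0, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
    z <- AB[["A"]] * f + AB[["B"]]
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  expect_equal(nll(AB1, f, y), nll(AB2, -f, -y), tolerance = 1e-6)
  expect_equal(AB1[["A"]], AB2[["A"]], tolerance = 1e-3)
})

test_that("calibration requires both classes and is monotone", {
  expect_error(platt_calibrate(c(1, 2), c(1, 1)), "classes")
  set.seed(65)
  f <- rnorm(60)
  y <- ifelse(f + rnorm(60, 0, 0.5) > 0, 1, -1)
  AB <- platt_calibrate(f, y)
  p <- platt_probability(sort(f), AB)
  expect_true(all(diff(p) >= 0))
})

test_that("AUROC identities and the hand-counted example hold", {
  expect_equal(auroc(c(0.1, 0.4, 0.8, 0.9), c(-1, -1, 1, 1)), 1)
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.3), c(-1, -1, 1, 1)), 0)
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.3), c(1, -1, 1, -1)), 0.75)
  expect_equal(auroc(c(0.5, 0.5, 0.5, 0.5), c(1, -1, 1, -1)), 0.5)  # ties
  expect_error(auroc(1:3, c(1, 1, 1)), "classes")
})

test_that("AUROC matches pair counting and pROC on random scores", {
  set.seed(66)
  for (i in 1:5) {
    n <- 40
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- sample(c(1, -1), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
    proc <- suppressMessages(pROC::auc(pROC::roc(
      response = labels, predictor = scores, quiet = TRUE,
      direction = "<", levels = c(-1, 1))))
    expect_equal(auroc(scores, labels), as.numeric(proc), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly increasing transforms", {
  set.seed(67)
  scores <- rnorm(50)
  labels <- sample(c(1, -1), 50, replace = TRUE)
  a0 <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), a0)
  expect_equal(auroc(3 * scores + 7, labels), a0)
})

test_that("thresholded metrics come from the confusion matrix", {
  scores <- c(2, 1, -1, -2, 0.5, -0.5)
  labels <- c(1, 1, 1, -1, -1, -1)
  met <- compute_metrics(scores, labels)
  expect_equal(met$sensitivity, 2 / 3)
  expect_equal(met$specificity, 2 / 3)
  expect_equal(met$accuracy, 4 / 6)
})

test_that("Dice identities hold, including the empty-mask convention", {
  a <- roi_mask(array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                      dim = c(1, 8, 1)), label = "cancer")
  expect_equal(dice(a, a), 1)
  b <- roi_mask(array(c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
                      dim = c(1, 8, 1)), label = "cancer")
  expect_equal(dice(a, b), 0)
  c4 <- roi_mask(array(c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                       dim = c(1, 8, 1)), label = "cancer")
  expect_equal(dice(a, c4), 0.5)  # |A|=|B|=4, overlap 2
  e <- roi_mask(array(FALSE, dim = c(1, 8, 1)), label = "cancer")
  expect_equal(dice(e, e), 1)
  wrong <- roi_mask(array(TRUE, dim = c(1, 4, 1)), label = "cancer")
  expect_error(dice(a, wrong), "grid")
})
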