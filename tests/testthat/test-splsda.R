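# Standardization, sparse fitting, prediction and the test-set NA
# imputation rule.

test_that("standardization uses observed entries and flags constants", {
  x <- rbind(c(0.2, 0.4, 0.5), c(0.4, 0.5, 0.5), c(NA, 0.6, 0.5))
  par <- standardize_fit(x)
  expect_equal(par$mean, c(0.3, 0.5, 0.5))
  expect_equal(par$sd[1], stats::sd(c(0.2, 0.4)))
  expect_true(par$constant[3])
  z <- standardize_apply(x, par)
  expect_equal(z[, 3], c(0, 0, 0))
  expect_true(is.na(z[3, 1]))
  # observed entries of non-constant features have mean 0, sd 1
  set.seed(2)
  x2 <- matrix(runif(160), 8, 20)
  x2[sample(160, 16)] <- NA
  z2 <- standardize_apply(x2, standardize_fit(x2))
  mu <- colMeans(z2, na.rm = TRUE)
  s <- apply(z2, 2, stats::sd, na.rm = TRUE)
  expect_true(all(abs(mu) < 1e-12))
  expect_true(all(abs(s - 1) < 1e-12))
})

test_that("the sparse weight vector has exactly keep_k nonzeros, even under ties", {
  w <- c(0.9, -0.5, 0.5, 0.1, -0.05)
  out <- snvdisc:::.sparsify(w, 2)
  expect_equal(sum(out != 0), 2)
  # tie at the boundary: kept entry is the lower index, not shrunk to zero
  expect_equal(which(out != 0), c(1, 2))
  expect_true(abs(out[2]) > 0)
})

test_that("a single separating feature is found at keep_k = 1 (covariance oracle)", {
  d <- separable_matrix()
  fit <- fit_splsda(d$x, d$y, keep_k = 1)
  expect_equal(colnames(d$x)[which(fit$weights[, 1] != 0)], "sep")
  # brute-force oracle: the feature with largest |cov(z, yc)|
  z <- standardize_apply(d$x, standardize_fit(d$x))
  yc <- as.numeric(d$y == "B") - mean(d$y == "B")
  oracle <- which.max(abs(as.vector(crossprod(z, yc))))
  expect_equal(which(fit$weights[, 1] != 0), oracle)
  # perfectly separable fixture predicts its training set exactly
  pr <- predict(fit, d$x)
  expect_equal(as.character(pr$label), as.character(d$y))
})

test_that("the dense limit reproduces the X^T y closed form and PLS-DA invariants", {
  set.seed(21)
  n <- 24; p <- 40
  x <- matrix(runif(n * p), n, p)
  y <- factor(rep(c("A", "B"), each = n / 2))
  fit <- fit_splsda(x, y, keep_k = p, n_components = 2)
  z <- standardize_apply(x, standardize_fit(x))
  yc <- as.numeric(y == "B") - mean(y == "B")
  expect_gt(abs(cor(fit$weights[, 1], as.vector(crossprod(z, yc)))),
            0.999999)
  # unit-norm weights, orthogonal scores
  expect_equal(sum(fit$weights[, 1]^2), 1, tolerance = 1e-12)
  expect_equal(sum(fit$weights[, 2]^2), 1, tolerance = 1e-12)
  expect_lt(abs(sum(fit$scores[, 1] * fit$scores[, 2])), 1e-8)
})

test_that("selection and weights agree with an independent sPLS-DA implementation", {
  set.seed(31)
  n <- 30; p <- 45
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("f", seq_len(p))
  y <- factor(rep(c("A", "B"), each = 15))
  x[, 1] <- x[, 1] + ifelse(y == "B", 2, 0)
  x[, 7] <- x[, 7] - ifelse(y == "B", 1.5, 0)
  fit <- fit_splsda(x, y, keep_k = 6)
  mo <- mixOmics::splsda(x, y, ncomp = 1, keepX = 6)
  w_mo <- mo$loadings$X[, 1]
  sel <- colnames(x)[fit$weights[, 1] != 0]
  expect_setequal(sel, names(which(w_mo != 0)))
  expect_gt(abs(cor(fit$weights[fit$weights[, 1] != 0, 1], w_mo[sel])),
            0.999999)
})

test_that("NA-aware fitting equals the ordinary fit when nothing is missing", {
  set.seed(41)
  x <- matrix(runif(200), 20, 10)
  y <- factor(rep(c("A", "B"), 10))
  fit <- fit_splsda(x, y, keep_k = 4)
  # inject an explicit all-observed mask path: identical data, no NA
  fit2 <- fit_splsda(x + 0, y, keep_k = 4)
  expect_identical(fit$weights, fit2$weights)
  # scores via NA-aware products match plain inner products
  z <- standardize_apply(x, standardize_fit(x))
  expect_equal(fit$scores[, 1], as.vector(z %*% fit$weights[, 1]),
               tolerance = 1e-12)
})

test_that("imputation fills the mean of the training-group standardized means", {
  x <- cbind(f1 = c(0.2, 0.4, 0.6, 0.8), f2 = c(0.1, 0.5, 0.2, 0.9))
  y <- factor(c("A", "A", "B", "B"))
  fit <- fit_splsda(x, y, keep_k = 2)
  z <- standardize_apply(x, fit$standardization)
  m_a <- colMeans(z[y == "A", ])
  m_b <- colMeans(z[y == "B", ])
  test <- matrix(NA_real_, 1, 2, dimnames = list(NULL, c("f1", "f2")))
  z_test <- standardize_apply(test, fit$standardization)
  filled <- impute_test_na(z_test, fit)
  expect_equal(as.vector(filled), unname((m_a + m_b) / 2))
  # symmetric groups fill zero
  expect_equal(unname(filled[1, 1]), 0)
  # observed entries untouched
  z_test2 <- z_test
  z_test2[1, 1] <- 1.23
  expect_equal(unname(impute_test_na(z_test2, fit)[1, 1]), 1.23)
})

test_that("prediction symmetries hold: label flip, sample order, feature scale", {
  d <- separable_matrix(n_per_group = 8, n_noise = 20, seed = 3)
  fit <- fit_splsda(d$x, d$y, keep_k = 5)
  pr <- predict(fit, d$x)
  # flipping the group encoding flips scores, not calls
  yf <- factor(d$y, levels = c("B", "A"))
  fitf <- fit_splsda(d$x, yf, keep_k = 5)
  prf <- predict(fitf, d$x)
  expect_equal(prf$score, -pr$score, tolerance = 1e-9)
  expect_equal(as.character(prf$label), as.character(pr$label))
  # permuting sample order permutes scores and leaves weights unchanged
  set.seed(4)
  perm <- sample(nrow(d$x))
  fitp <- fit_splsda(d$x[perm, ], d$y[perm], keep_k = 5)
  expect_equal(fitp$weights, fit$weights, tolerance = 1e-9)
  expect_equal(predict(fitp, d$x)$score, pr$score, tolerance = 1e-9)
  # multiplying a raw feature by a positive constant changes nothing
  xs <- d$x
  xs[, 2] <- xs[, 2] * 0.37
  fits <- fit_splsda(xs, d$y, keep_k = 5)
  expect_equal(fits$weights, fit$weights, tolerance = 1e-9)
  expect_equal(predict(fits, xs)$score, pr$score, tolerance = 1e-9)
})

test_that("an all-NA test sample scores as the imputed midpoint vector", {
  x <- cbind(f1 = c(0.1, 0.3, 0.7, 0.9), f2 = c(0.2, 0.4, 0.5, 0.6))
  y <- factor(c("A", "A", "B", "B"))
  fit <- fit_splsda(x, y, keep_k = 2)
  test <- matrix(NA_real_, 1, 2, dimnames = list(NULL, colnames(x)))
  pr <- predict(fit, test)
  # hand computation: standardized test row is the na_fill vector
  t1 <- sum(fit$na_fill * fit$weights[, 1])
  expected <- (fit$y_means[2] + t1 * fit$y_coef[2, 1]) -
    (fit$y_means[1] + t1 * fit$y_coef[1, 1])
  expect_equal(pr$score, unname(expected), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or clamped", {
  x <- matrix(runif(40), 10, 4)
  y1 <- factor(rep("A", 10))
  expect_error(fit_splsda(x, y1, keep_k = 2), "two groups")
  y <- factor(rep(c("A", "B"), 5))
  expect_warning(fit <- fit_splsda(x, y, keep_k = 10), "clamped")
  expect_equal(fit$keep_k, 4)
  colnames(x) <- paste0("f", 1:4)
  fit2 <- fit_splsda(x, y, keep_k = 2)
  bad <- x[, 1:3]
  expect_error(predict(fit2, bad), "missing training feature")
})
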