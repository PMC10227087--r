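# Two-stage regression, leave-two-subjects-out folds, agreement metrics.

# Small synthetic feature table with a known linear structure.
toy_features <- function(n, seed = 1, k = 6) {
  set.seed(seed)
  x <- matrix(runif(n * k), n, k)
  colnames(x) <- sprintf("feat_%02d", seq_len(k))
  sbp <- 100 + 40 * x[, 1]
  dbp <- 60 + 20 * x[, 2]
  df <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), x,
                   sbp_ref = sbp, dbp_ref = dbp)
  df$mbp_ref <- compute_reference_mbp(df$sbp_ref, df$dbp_ref)
  df
}

test_that("reference mean pressure follows the 1/3-2/3 formula", {
  expect_equal(compute_reference_mbp(120, 80), 120 / 3 + 160 / 3)
  expect_equal(compute_reference_mbp(90, 60), 70)
  expect_equal(compute_reference_mbp(100, 100 - 1e-9), 100, tolerance = 1e-6)
  expect_error(compute_reference_mbp(80, 80), "sbp > dbp")
  expect_error(compute_reference_mbp(80, 90), "sbp > dbp")
})

test_that("near-zero penalty recovers an exactly linear target", {
  df <- toy_features(24, seed = 2)
  x <- as.matrix(df[, grep("^feat_", names(df))])
  m <- fit_stage1(x[1:20, ], df$sbp_ref[1:20], df$mbp_ref[1:20],
                  lambda = c(1e-3, 1e-4, 1e-5))
  hat <- predict_stage1(m, x[21:24, ])
  expect_lt(max(abs(hat$sbp_hat - df$sbp_ref[21:24])), 0.5)
  expect_lt(max(abs(hat$mbp_hat - df$mbp_ref[21:24])), 0.5)
})

test_that("an overwhelming penalty collapses to the training mean", {
  df <- toy_features(20, seed = 3)
  x <- as.matrix(df[, grep("^feat_", names(df))])
  m <- fit_stage1(x, df$sbp_ref, df$mbp_ref, lambda = c(1e6, 1e5))
  hat <- predict_stage1(m, x)
  expect_equal(hat$sbp_hat, rep(mean(df$sbp_ref), 20), tolerance = 1e-6)
  expect_equal(hat$mbp_hat, rep(mean(df$mbp_ref), 20), tolerance = 1e-6)
})

test_that("stage 1 validates its inputs", {
  df <- toy_features(10)
  x <- as.matrix(df[, grep("^feat_", names(df))])
  expect_error(fit_stage1(x[1:3, ], df$sbp_ref[1:3], df$mbp_ref[1:3]),
               "4 training subjects")
  w <- capture_warnings(
    m <- fit_stage1(matrix(0.5, 10, 6), df$sbp_ref, df$mbp_ref))
  expect_match(w, "intercept-only", all = TRUE)
  expect_length(w, 2)  # one per target
  hat <- predict_stage1(m, matrix(0.5, 2, 6))
  expect_equal(hat$sbp_hat, rep(mean(df$sbp_ref), 2))
})

test_that("stage 2 recovers the diastolic identity from perfect stage 1", {
  df <- toy_features(30, seed = 4)
  m2 <- fit_stage2(df$sbp_ref, df$mbp_ref, df$dbp_ref)
  co <- m2$coef
  # DBP = 1.5*MBP - 0.5*SBP exactly, by the mean-pressure formula
  expect_equal(unname(co[1]), 0, tolerance = 1e-8)
  expect_equal(unname(co["sbp_hat"]), -0.5, tolerance = 1e-8)
  expect_equal(unname(co["mbp_hat"]), 1.5, tolerance = 1e-8)
  # OLS residuals are orthogonal to both features
  r <- df$dbp_ref - predict_stage2(m2, df$sbp_ref, df$mbp_ref)
  expect_equal(sum(r * df$sbp_ref), 0, tolerance = 1e-6)
  expect_equal(sum(r * df$mbp_ref), 0, tolerance = 1e-6)
})

test_that("stage 2 handles constant predictors but rejects collinearity", {
  dbp <- c(70, 72, 68, 71, 69)
  m <- fit_stage2(rep(120, 5), rep(93, 5), dbp)
  expect_equal(predict_stage2(m, 120, 93), mean(dbp))
  sbp_hat <- c(110, 120, 130, 125, 115)
  expect_error(fit_stage2(sbp_hat, 0.5 * sbp_hat + 3, dbp), "collinear")
})

test_that("leave-two-out folds partition the roster", {
  ids <- sprintf("S%02d", 1:24)
  folds <- make_folds(ids, seed = 5)
  expect_length(folds, 12)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), ids)
  expect_false(anyDuplicated(unlist(folds)) > 0)
  expect_identical(folds, make_folds(ids, seed = 5))
  expect_false(identical(folds, make_folds(ids, seed = 6)))
  expect_length(make_folds(letters[1:4], seed = 1), 2)
  expect_error(make_folds(letters[1:5], seed = 1), "even number")
})

test_that("cross-validation on identical subjects is error-free and exact", {
  df <- toy_features(8, seed = 6)
  for (cn in names(df)[-1]) df[[cn]] <- rep(df[[cn]][1], 8)
  suppressWarnings(cv <- cross_validate(df, seed = 1))
  expect_equal(cv$report$mae, rep(0, 3), tolerance = 1e-9)
  expect_equal(cv$report$bias, rep(0, 3), tolerance = 1e-9)
})

test_that("cross-validated predictions come from unseen-subject models", {
  df <- toy_features(12, seed = 7)
  folds <- make_folds(df$subject_id, seed = 2)
  cv1 <- cross_validate(df, seed = 2, folds = folds)
  # perturb one held-out subject's features: with the same folds, only that
  # subject's own prediction may change within its fold
  pair <- folds[[3]]
  df2 <- df
  k <- which(df2$subject_id == pair[1])
  df2[k, grep("^feat_", names(df2))] <- runif(6)
  cv2 <- cross_validate(df2, seed = 2, folds = folds)
  other <- cv1$predictions$subject_id == pair[2]
  expect_equal(cv1$predictions$sbp_hat[other],
               cv2$predictions$sbp_hat[other], tolerance = 1e-12)
  expect_equal(cv1$predictions$dbp_hat[other],
               cv2$predictions$dbp_hat[other], tolerance = 1e-12)
})

test_that("shuffling subject order leaves the report unchanged", {
  df <- toy_features(12, seed = 8)
  cv1 <- cross_validate(df, seed = 3)
  set.seed(99)
  cv2 <- cross_validate(df[sample(12), ], seed = 3)
  expect_equal(cv1$predictions, cv2$predictions, tolerance = 1e-12)
  expect_equal(cv1$report, cv2$report, tolerance = 1e-12)
})

test_that("agreement metrics match their definitions exactly", {
  set.seed(10)
  pred <- data.frame(sbp_hat = rnorm(20, 120, 10), sbp_ref = rnorm(20, 120, 10),
                     mbp_hat = rnorm(20, 93, 8), mbp_ref = rnorm(20, 93, 8),
                     dbp_hat = rnorm(20, 80, 6), dbp_ref = rnorm(20, 80, 6))
  rep <- accuracy_report(pred)
  e <- pred$sbp_hat - pred$sbp_ref
  i <- rep$target == "SBP"
  expect_equal(rep$bias[i], mean(e))
  expect_equal(rep$mae[i], mean(abs(e)))
  expect_equal(rep$sd_abs_error[i], sd(abs(e)))
  expect_equal(rep$loa_lower[i], mean(e) - 1.96 * sd(e))
  expect_equal(rep$loa_upper[i], mean(e) + 1.96 * sd(e))
})

test_that("fold structure errors are informative", {
  df <- toy_features(6, seed = 9)
  bad <- list(c("S001", "S002"), c("S003", "S004"))  # misses two subjects
  expect_error(cross_validate(df, folds = bad), "partition")
  tiny <- toy_features(4, seed = 9)
  expect_error(cross_validate(tiny, seed = 1), "4 training subjects")
})
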