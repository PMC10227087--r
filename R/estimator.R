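# Two-stage blood-pressure regression: L1-penalized linear models map the 18
# normalized oscillogram amplitudes to systolic and mean pressure; diastolic
# pressure is an ordinary linear regression on those two predictions.
# Validation is leave-two-subjects-out.

#' Reference mean blood pressure
#'
#' `MBP = SBP/3 + 2*DBP/3`.
#'
#' @param sbp,dbp Reference pressures in mmHg; requires `sbp > dbp`
#'   elementwise.
#' @return Mean pressure in mmHg.
#' @examples
#' compute_reference_mbp(120, 80)
#' @export
compute_reference_mbp <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) || any(sbp <= dbp)) {
    stop("require finite sbp > dbp", call. = FALSE)
  }
  sbp / 3 + 2 * dbp / 3
}

# Inner-CV LASSO for one target; intercept-only fallback when the feature
# matrix has no variance at all (degenerate cohort).
fit_lasso_one <- function(x, y, seed, standardize = FALSE, lambda = NULL) {
  if (all(apply(x, 2, var) == 0)) {
    warning("all features constant; fitting intercept-only model")
    return(structure(list(type = "intercept", mu = mean(y)),
                     class = "bp_lasso"))
  }
  n <- nrow(x)
  nfolds <- min(5L, n)
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                          standardize = standardize, grouped = FALSE,
                          lambda = lambda)
  structure(list(type = "glmnet", cv = cv, lambda = cv$lambda.min),
            class = "bp_lasso")
}

predict_lasso <- function(model, x) {
  if (model$type == "intercept") return(rep(model$mu, nrow(x)))
  as.numeric(predict(model$cv, newx = x, s = "lambda.min"))
}

#' Stage 1: LASSO models for systolic and mean pressure
#'
#' Fits one L1-penalized linear model per target (or a shared-penalty
#' multi-target model with `multi_target = TRUE`) on the 18 normalized
#' oscillogram amplitudes. The penalty is chosen by inner cross-validation
#' on the training subjects only; features are not re-standardized beyond
#' their common `[0, 1]` scale.
#'
#' @param x Numeric matrix (subjects x features), each entry in `[0, 1]`.
#' @param sbp,mbp Training targets in mmHg.
#' @param seed Seed for the inner-CV fold assignment.
#' @param multi_target Fit both targets jointly with a shared penalty.
#' @param standardize Passed to glmnet (default `FALSE`).
#' @param lambda Optional penalty grid.
#' @return An object of class `bp_stage1`; predict with [predict_stage1()].
#' @export
fit_stage1 <- function(x, sbp, mbp, seed = 1, multi_target = FALSE,
                       standardize = FALSE, lambda = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("need at least 4 training subjects", call. = FALSE)
  stopifnot(length(sbp) == nrow(x), length(mbp) == nrow(x))
  if (anyNA(x) || anyNA(sbp) || anyNA(mbp)) {
    stop("features and targets must be complete", call. = FALSE)
  }
  if (multi_target) {
    if (all(apply(x, 2, var) == 0)) {
      warning("all features constant; fitting intercept-only model")
      return(structure(list(multi = FALSE,
                            sbp = structure(list(type = "intercept",
                                                 mu = mean(sbp)),
                                            class = "bp_lasso"),
                            mbp = structure(list(type = "intercept",
                                                 mu = mean(mbp)),
                                            class = "bp_lasso")),
                       class = "bp_stage1"))
    }
    n <- nrow(x)
    nfolds <- min(5L, n)
    foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
    cv <- glmnet::cv.glmnet(x, cbind(sbp = sbp, mbp = mbp),
                            family = "mgaussian", alpha = 1,
                            foldid = foldid, standardize = standardize,
                            grouped = FALSE, lambda = lambda)
    return(structure(list(multi = TRUE, cv = cv), class = "bp_stage1"))
  }
  structure(list(
    multi = FALSE,
    sbp = fit_lasso_one(x, sbp, seed, standardize, lambda),
    mbp = fit_lasso_one(x, mbp, child_seed(seed, 1), standardize, lambda)),
    class = "bp_stage1")
}

#' Predict systolic and mean pressure from stage-1 models
#'
#' @param model A `bp_stage1` from [fit_stage1()].
#' @param x Feature matrix.
#' @return Data frame with columns `sbp_hat`, `mbp_hat`.
#' @export
predict_stage1 <- function(model, x) {
  stopifnot(inherits(model, "bp_stage1"))
  x <- as.matrix(x)
  if (isTRUE(model$multi)) {
    p <- predict(model$cv, newx = x, s = "lambda.min")
    return(data.frame(sbp_hat = p[, "sbp", 1], mbp_hat = p[, "mbp", 1]))
  }
  data.frame(sbp_hat = predict_lasso(model$sbp, x),
             mbp_hat = predict_lasso(model$mbp, x))
}

#' Stage 2: linear model for diastolic pressure
#'
#' Ordinary least squares of the reference diastolic pressure on exactly two
#' features: the stage-1 systolic and mean predictions. With perfect stage-1
#' predictions the fit recovers the identity `DBP = 1.5*MBP - 0.5*SBP`
#' implied by the mean-pressure formula. Coefficients of zero-variance
#' predictors are set to 0 (intercept-only behaviour); genuinely collinear
#' varying predictors raise an error.
#'
#' @param sbp_hat,mbp_hat Stage-1 predictions for the training subjects.
#' @param dbp Reference diastolic pressures.
#' @return An object of class `bp_stage2` with `$coef = c(intercept,
#'   sbp_hat, mbp_hat)`.
#' @export
fit_stage2 <- function(sbp_hat, mbp_hat, dbp) {
  stopifnot(length(sbp_hat) == length(dbp), length(mbp_hat) == length(dbp))
  fit <- lm(dbp ~ sbp_hat + mbp_hat)
  co <- coef(fit)
  if (anyNA(co)) {
    vars <- c(sbp_hat = var(sbp_hat), mbp_hat = var(mbp_hat))
    bad <- names(co)[is.na(co)]
    if (all(vars[bad] == 0, na.rm = TRUE)) {
      co[is.na(co)] <- 0
    } else {
      stop("collinear stage-1 predictions: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(coef = co, fit = fit), class = "bp_stage2")
}

#' Predict diastolic pressure from stage-2 coefficients
#'
#' @param model A `bp_stage2`.
#' @param sbp_hat,mbp_hat Stage-1 predictions.
#' @return Diastolic predictions in mmHg.
#' @export
predict_stage2 <- function(model, sbp_hat, mbp_hat) {
  stopifnot(inherits(model, "bp_stage2"))
  co <- model$coef
  unname(co[1] + co["sbp_hat"] * sbp_hat + co["mbp_hat"] * mbp_hat)
}

#' Leave-two-subjects-out fold assignment
#'
#' Subjects are sorted, randomly permuted under the seed, and split into
#' disjoint holdout pairs covering the roster exactly once (24 subjects ->
#' 12 folds).
#'
#' @param ids Subject identifiers; their count must be even (with an odd
#'   roster, explicitly drop or add a subject yourself).
#' @param seed Integer seed for the pairing.
#' @return A list of character/element pairs.
#' @export
make_folds <- function(ids, seed = 1) {
  ids <- sort(unique(ids))
  n <- length(ids)
  if (n < 2 || n %% 2 != 0) {
    stop("leave-two-out needs an even number of subjects; ",
         "drop or add one explicitly before calling make_folds",
         call. = FALSE)
  }
  perm <- with_seed(seed, sample(ids))
  unname(split(perm, rep(seq_len(n / 2), each = 2)))
}

feature_columns <- function(features) {
  cols <- grep("^feat_", names(features), value = TRUE)
  if (length(cols) == 0) stop("no feat_* columns found", call. = FALSE)
  cols
}

#' Leave-two-subjects-out cross-validation of the two-stage estimator
#'
#' For each fold the stage-1 LASSO models and the stage-2 linear model are
#' fitted on the training subjects only (stage-2 consumes the stage-1
#' predictions for those same training subjects), then applied to the two
#' held-out subjects. Held-out predictions are assembled into an accuracy
#' report (MAE, bias, Bland-Altman limits, correlation) per target.
#'
#' @param features Data frame with `subject_id`, `feat_*` columns,
#'   `sbp_ref`, `dbp_ref` and optionally `mbp_ref` (derived if absent).
#' @param seed Seed controlling fold pairing and inner CV.
#' @param folds Optional precomputed fold list from [make_folds()].
#' @param multi_target,standardize Passed to [fit_stage1()].
#' @return An object of class `bp_crossval`: `$predictions` (one row per
#'   subject, ordered by id) and `$report` (see [accuracy_report()]).
#' @export
cross_validate <- function(features, seed = 1, folds = NULL,
                           multi_target = FALSE, standardize = FALSE) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  if (!"mbp_ref" %in% names(features)) {
    features$mbp_ref <- compute_reference_mbp(features$sbp_ref,
                                              features$dbp_ref)
  }
  cols <- feature_columns(features)
  rownames(features) <- features$subject_id
  if (is.null(folds)) folds <- make_folds(features$subject_id, seed)
  held <- unlist(folds)
  if (anyDuplicated(held) || !setequal(held, features$subject_id)) {
    stop("folds must partition the subject roster", call. = FALSE)
  }
  x <- as.matrix(features[, cols])
  preds <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    test_ids <- folds[[k]]
    tr <- !(features$subject_id %in% test_ids)
    if (sum(tr) < 4) stop("fold has fewer than 4 training subjects",
                          call. = FALSE)
    m1 <- fit_stage1(x[tr, , drop = FALSE], features$sbp_ref[tr],
                     features$mbp_ref[tr], seed = child_seed(seed, k),
                     multi_target = multi_target, standardize = standardize)
    tr_hat <- predict_stage1(m1, x[tr, , drop = FALSE])
    m2 <- fit_stage2(tr_hat$sbp_hat, tr_hat$mbp_hat, features$dbp_ref[tr])
    te <- features$subject_id %in% test_ids
    te_hat <- predict_stage1(m1, x[te, , drop = FALSE])
    preds[[k]] <- data.frame(
      subject_id = features$subject_id[te], fold = k,
      sbp_hat = te_hat$sbp_hat, mbp_hat = te_hat$mbp_hat,
      dbp_hat = predict_stage2(m2, te_hat$sbp_hat, te_hat$mbp_hat),
      sbp_ref = features$sbp_ref[te], mbp_ref = features$mbp_ref[te],
      dbp_ref = features$dbp_ref[te])
  }
  predictions <- do.call(rbind, preds)
  predictions <- predictions[order(predictions$subject_id), ]
  rownames(predictions) <- NULL
  structure(list(predictions = predictions,
                 report = accuracy_report(predictions),
                 folds = folds, seed = seed),
            class = "bp_crossval")
}

#' Agreement statistics of held-out predictions
#'
#' Per target (SBP, MBP, DBP): mean absolute error with the standard
#' deviation of the absolute errors, bias (mean signed error, prediction
#' minus reference), Bland-Altman limits of agreement
#' (`bias +/- 1.96 * sd(error)`), and the Pearson correlation.
#'
#' @param predictions Data frame with `*_hat` and `*_ref` columns for
#'   `sbp`, `mbp`, `dbp`.
#' @return A data frame of class `bp_accuracy`, one row per target.
#' @export
accuracy_report <- function(predictions) {
  one <- function(tgt) {
    e <- predictions[[paste0(tgt, "_hat")]] -
      predictions[[paste0(tgt, "_ref")]]
    data.frame(target = toupper(tgt), n = length(e),
               mae = mean(abs(e)), sd_abs_error = sd(abs(e)),
               bias = mean(e), sd_error = sd(e),
               loa_lower = mean(e) - 1.96 * sd(e),
               loa_upper = mean(e) + 1.96 * sd(e),
               r = if (sd(e) == 0 ||
                       sd(predictions[[paste0(tgt, "_ref")]]) == 0) {
                 NA_real_
               } else {
                 cor(predictions[[paste0(tgt, "_hat")]],
                     predictions[[paste0(tgt, "_ref")]])
               })
  }
  out <- do.call(rbind, lapply(c("sbp", "mbp", "dbp"), one))
  rownames(out) <- NULL
  structure(out, class = c("bp_accuracy", "data.frame"))
}

#' @export
print.bp_accuracy <- function(x, ...) {
  cat("Held-out agreement (mmHg):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s: MAE %.2f +/- %.2f, bias %.2f, LoA [%.2f, %.2f]\n",
                x$target[i], x$mae[i], x$sd_abs_error[i], x$bias[i],
                x$loa_lower[i], x$loa_upper[i]))
  }
  invisible(x)
}

#' @export
print.bp_crossval <- function(x, ...) {
  cat(sprintf("<bp_crossval> %d subjects, %d folds (seed %d)\n",
              nrow(x$predictions), length(x$folds), x$seed))
  print(x$report)
  invisible(x)
}

#' @importFrom stats cor
NULL
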