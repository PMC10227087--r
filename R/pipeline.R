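# End-to-end plumbing from recordings to the screened cohort feature table.

#' Raw oscillogram of one recorded session
#'
#' @param recording A `session_recording`.
#' @param spring,geom Mechanics models for the pressure axis.
#' @param ... Passed to [build_oscillogram()].
#' @return A raw `oscillogram`.
#' @export
subject_oscillogram <- function(recording, spring = spring_model(),
                                geom = contact_geometry(), ...) {
  build_oscillogram(session_levels(recording), spring, geom, ...)
}

#' Screened feature table of a synthetic cohort
#'
#' For every subject: build the raw oscillogram, apply the screening rules
#' (no detectable pulse; pulse pressure > 80 mmHg), and for retained
#' subjects compute the normalized 18-point feature vector by endpoint
#' exclusion and min--max rescaling.
#'
#' @param cohort A `bp_cohort` from [synth_cohort()].
#' @param spring,geom Mechanics models.
#' @param amp_floor No-pulse screening floor in grey levels.
#' @param ... Passed to [build_oscillogram()].
#' @return A list: `features` (data frame, retained subjects only:
#'   `subject_id`, `feat_01..feat_k`, `sbp_ref`, `dbp_ref`, `mbp_ref`),
#'   `screening` (all subjects: `subject_id`, `retained`, `reason`), and
#'   `manifest` (ground truth, see [cohort_manifest()]).
#' @export
build_cohort_features <- function(cohort, spring = spring_model(),
                                  geom = contact_geometry(), amp_floor = 1,
                                  ...) {
  stopifnot(inherits(cohort, "bp_cohort"))
  screening <- list()
  feats <- list()
  for (el in cohort) {
    s <- el$subject
    osc <- subject_oscillogram(el$recording, spring, geom, ...)
    sc <- screen_subject(osc, s$sbp_true, s$dbp_true, amp_floor = amp_floor)
    screening[[el$subject_id]] <- data.frame(
      subject_id = el$subject_id, retained = sc$retained, reason = sc$reason)
    if (sc$retained) {
      norm <- exclude_and_normalize(osc)
      row <- as.data.frame(as.list(stats::setNames(
        norm$amplitude, sprintf("feat_%02d", seq_len(nrow(norm))))))
      row <- cbind(data.frame(subject_id = el$subject_id), row,
                   data.frame(sbp_ref = s$sbp_true, dbp_ref = s$dbp_true,
                              mbp_ref = s$mbp_true))
      feats[[el$subject_id]] <- row
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  if (!is.null(features)) rownames(features) <- NULL
  screening <- do.call(rbind, screening)
  rownames(screening) <- NULL
  list(features = features, screening = screening,
       manifest = cohort_manifest(cohort))
}

#' Estimate blood pressure for one subject from a trained model
#'
#' @param osc A raw or normalized `oscillogram`; raw oscillograms are
#'   endpoint-excluded and normalized first.
#' @param model A trained model from [train_bp_model()].
#' @return A one-row data frame: `sbp_hat`, `mbp_hat`, `dbp_hat` in mmHg.
#' @export
estimate_bp <- function(osc, model) {
  stopifnot(inherits(osc, "oscillogram"), inherits(model, "bp_model"))
  if (!isTRUE(attr(osc, "normalized"))) osc <- exclude_and_normalize(osc)
  x <- matrix(osc$amplitude, nrow = 1)
  if (ncol(x) != length(model$stage1_sbp) - 1) {
    stop(sprintf("model expects %d features, oscillogram has %d",
                 length(model$stage1_sbp) - 1, ncol(x)), call. = FALSE)
  }
  sbp_hat <- model$stage1_sbp[1] + sum(model$stage1_sbp[-1] * x)
  mbp_hat <- model$stage1_mbp[1] + sum(model$stage1_mbp[-1] * x)
  dbp_hat <- model$stage2[1] + model$stage2[2] * sbp_hat +
    model$stage2[3] * mbp_hat
  data.frame(sbp_hat = sbp_hat, mbp_hat = mbp_hat, dbp_hat = dbp_hat)
}

#' Train the two-stage model on a full feature table
#'
#' Fits stage 1 and stage 2 on all provided subjects and freezes the
#' coefficients into a plain-numeric model that [estimate_bp()] can apply
#' and that serializes losslessly to JSON.
#'
#' @param features Feature table as accepted by [cross_validate()].
#' @param seed Seed for the inner CV.
#' @param ... Passed to [fit_stage1()].
#' @return An object of class `bp_model` holding coefficient vectors
#'   `stage1_sbp`, `stage1_mbp` (intercept first) and `stage2`
#'   (intercept, sbp_hat, mbp_hat).
#' @export
train_bp_model <- function(features, seed = 1, ...) {
  if (!"mbp_ref" %in% names(features)) {
    features$mbp_ref <- compute_reference_mbp(features$sbp_ref,
                                              features$dbp_ref)
  }
  cols <- feature_columns(features)
  x <- as.matrix(features[, cols])
  m1 <- fit_stage1(x, features$sbp_ref, features$mbp_ref, seed = seed, ...)
  hat <- predict_stage1(m1, x)
  m2 <- fit_stage2(hat$sbp_hat, hat$mbp_hat, features$dbp_ref)
  lasso_coef <- function(m) {
    if (m$type == "intercept") return(c(m$mu, rep(0, ncol(x))))
    as.numeric(coef(m$cv, s = "lambda.min"))
  }
  structure(list(stage1_sbp = lasso_coef(m1$sbp),
                 stage1_mbp = lasso_coef(m1$mbp),
                 stage2 = as.numeric(m2$coef),
                 n_train = nrow(x), seed = seed),
            class = "bp_model")
}
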