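#' Fit the annotation-support bias model for ASR normalization
#'
#' Annotated isoform counts depend on how much experimental evidence backed
#' the annotation: genomes whose CDSs are largely model-derived
#' systematically under-report splicing. This fits a polynomial regression
#' of ASR on an annotation-support covariate across species; the fitted
#' trend is what [normalize_asr()] subtracts to obtain ASR*.
#'
#' @param profiles data.frame with one row per species containing an `asr`
#'   column and the support-fraction column(s): `frac_fully_supported`,
#'   and for the multivariate mode also `frac_known` and `frac_model`.
#'   All fractions must lie in \[0, 1\].
#' @param degree polynomial degree (default 2). `degree = 0` fits a constant,
#'   making the subsequent normalization an identity.
#' @param covariate name of the support column to use (default
#'   `"frac_fully_supported"`, the dominant predictor).
#' @param multivariate when `TRUE`, additive polynomial terms in all three
#'   support fractions are used instead of the single covariate.
#' @param select_degree when `TRUE`, `degree` is chosen among 1..4 by
#'   minimum AIC.
#' @param reference_value covariate value at which no correction is applied;
#'   defaults to the cross-species mean of the covariate. (In the
#'   multivariate mode, the per-column means.)
#' @return object of class `support_norm_model`.
#' @export
fit_support_model <- function(profiles, degree = 2,
                              covariate = "frac_fully_supported",
                              multivariate = FALSE, select_degree = FALSE,
                              reference_value = NULL) {
  stopifnot(is.data.frame(profiles), "asr" %in% names(profiles))
  covs <- if (multivariate)
    c("frac_fully_supported", "frac_known", "frac_model") else covariate
  if (!all(covs %in% names(profiles)))
    stop("profiles must contain column(s): ", paste(covs, collapse = ", "))
  dat <- profiles[stats::complete.cases(profiles[, c("asr", covs)]), , drop = FALSE]
  for (cv in covs)
    if (any(dat[[cv]] < 0 | dat[[cv]] > 1))
      stop("support fractions must lie in [0, 1] (column ", cv, ")")

  fit_deg <- function(d) {
    if (d == 0) return(stats::lm(asr ~ 1, data = dat))
    if (any(vapply(covs, function(cv) stats::sd(dat[[cv]]) == 0, TRUE)))
      stop("constant covariate with degree >= 1; use degree = 0")
    rhs <- paste(sprintf("poly(%s, %d, raw = TRUE)", covs, d),
                 collapse = " + ")
    stats::lm(stats::as.formula(paste("asr ~", rhs)), data = dat)
  }

  if (select_degree) {
    cand <- 1:4
    cand <- cand[nrow(dat) >= cand + 2]
    if (!length(cand)) stop("too few species to fit any degree in 1..4")
    aics <- vapply(cand, function(d) stats::AIC(fit_deg(d)), 0)
    degree <- cand[which.min(aics)]
  }
  # degree + 1 points saturate the polynomial; anything less is unidentifiable
  if (nrow(dat) < degree + 1)
    stop("need at least degree + 1 species with finite ASR (have ",
         nrow(dat), ")")
  fit <- fit_deg(degree)
  if (degree >= 1 && any(is.na(stats::coef(fit))))
    stop("rank-deficient polynomial fit; reduce degree")
  if (is.null(reference_value))
    reference_value <- vapply(covs, function(cv) mean(dat[[cv]]), 0)
  reference_value <- stats::setNames(rep_len(reference_value, length(covs)), covs)

  structure(list(fit = fit, degree = degree, covariates = covs,
                 reference_value = reference_value, n_species = nrow(dat)),
            class = "support_norm_model")
}

.predict_support <- function(model, values) {
  nd <- as.data.frame(values)
  names(nd) <- model$covariates
  as.numeric(stats::predict(model$fit, newdata = nd))
}

#' Normalize ASR for annotation-support bias (ASR*)
#'
#' ASR* is the raw ASR minus the fitted support trend, re-centred at the
#' reference covariate value: `ASR* = ASR - f(c) + f(c_ref)`. A species
#' whose support equals the reference is unchanged; among species with
#' equal support the ordering and spacing of ASR values are preserved.
#' Normalized values are standardized estimates for cross-species
#' comparison, not absolute measurements.
#'
#' @param asr numeric vector of raw ASR values.
#' @param covariate numeric vector (recycled) of support-fraction values in
#'   \[0, 1\] — or, for a multivariate model, a data.frame with the model's
#'   covariate columns.
#' @param model a `support_norm_model` from [fit_support_model()].
#' @return numeric vector of ASR* values.
#' @export
normalize_asr <- function(asr, covariate, model) {
  stopifnot(inherits(model, "support_norm_model"))
  if (is.data.frame(covariate)) {
    vals <- covariate[, model$covariates, drop = FALSE]
  } else {
    if (length(model$covariates) > 1)
      stop("multivariate model requires a data.frame covariate")
    vals <- data.frame(covariate)
    names(vals) <- model$covariates
  }
  if (any(vals < 0 | vals > 1, na.rm = TRUE))
    stop("support covariate outside [0, 1]")
  ref <- .predict_support(model, as.data.frame(as.list(model$reference_value)))
  asr - .predict_support(model, vals) + ref
}

#' @export
print.support_norm_model <- function(x, ...) {
  cat("<support_norm_model> degree", x$degree, "polynomial of",
      paste(x$covariates, collapse = " + "), "\n")
  cat("  fitted on", x$n_species, "species; reference:",
      paste(sprintf("%s = %.4g", names(x$reference_value),
                    x$reference_value), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a support model to JSON (and back)
#'
#' @param model a `support_norm_model`.
#' @return JSON string with coefficients, degree, covariates and reference.
#' @export
support_model_json <- function(model) {
  stopifnot(inherits(model, "support_norm_model"))
  jsonlite::toJSON(list(degree = model$degree,
                        covariates = model$covariates,
                        coefficients = as.list(stats::coef(model$fit)),
                        reference_value = as.list(model$reference_value),
                        n_species = model$n_species),
                   auto_unbox = TRUE, digits = NA)
}
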