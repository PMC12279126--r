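# Multivariate Cox prognostic models: a clinical reference model and
# clinical + rad-score models, backward-AIC stepwise selection, and
# Harrell-optimism bootstrap validation.  Fits delegate to survival::coxph
# with Breslow ties; absolute risk at t is 1 - exp(-Lambda0(t) * exp(lp))
# from the Breslow baseline.

CLINICAL_TERMS <- c("gender", "age", "diabetes", "lesion_mm", "position",
                    "loc_premolar", "loc_molar")

#' Model specification
#'
#' Builds the covariate list of one of the study's models: `reference`
#' (six clinical variables: gender, age, diabetes, lesion diameter, tooth
#' position, tooth location as two dummies) or `clinical + rad-score`
#' (`model1` to `model4`, adding the S1-S4 rad-score respectively).
#'
#' @param name One of "reference", "model1", "model2", "model3", "model4".
#' @param radscore_col Column name of the rad-score covariate; defaults to
#'   `"radscore_Sk"` for model k.
#' @return A `model_spec`: list with `name` and `covariates`.
#' @export
model_spec <- function(name = c("reference", "model1", "model2", "model3", "model4"),
                       radscore_col = NULL) {
  name <- match.arg(name)
  cov <- CLINICAL_TERMS
  if (name != "reference") {
    k <- substring(name, 6)
    if (is.null(radscore_col)) radscore_col <- paste0("radscore_S", k)
    cov <- c(cov, radscore_col)
  }
  structure(list(name = name, covariates = cov), class = "model_spec")
}

#' Fit a multivariate Cox model
#'
#' Partial-likelihood maximization with Breslow ties and Breslow baseline
#' cumulative hazard.  Emits a warning when the events-per-variable ratio
#' falls below 10 (Harrell's guideline).
#'
#' @param spec A [model_spec()] (or character vector of covariate names).
#' @param data Data frame with the covariates plus `time_months`, `event`.
#' @return A `cox_fit`: list with `terms`, `beta`, `covariance`,
#'   `baseline_cumhaz` (data.frame time/hazard), `loglik`, `aic`, `fit`.
#' @export
fit_cox <- function(spec, data) {
  cov <- if (inherits(spec, "model_spec")) spec$covariates else as.character(spec)
  miss <- setdiff(cov, colnames(data))
  if (length(miss)) stopf("apexfa_schema_error", "missing covariate(s): %s",
                          paste(miss, collapse = ", "))
  if (sum(data$event) < 10 * length(cov)) {
    warning(sprintf("events (%d) < 10 x covariates (%d): estimates may be unstable",
                    sum(data$event), length(cov)), call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                                 paste(cov, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = data, ties = "breslow", model = TRUE),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w))) {
        stopf("apexfa_convergence_error", "Cox fit failed: %s", conditionMessage(w))
      }
      suppressWarnings(survival::coxph(fml, data = data, ties = "breslow",
                                       model = TRUE))
    })
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(terms = cov,
                 beta = stats::coef(fit),
                 covariance = fit$var,
                 baseline_cumhaz = data.frame(time = bh$time, hazard = bh$hazard),
                 loglik = fit$loglik[2],
                 aic = stats::AIC(fit),
                 name = if (inherits(spec, "model_spec")) spec$name else "custom",
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit '%s': %d terms, loglik %.2f, AIC %.2f>\n",
              x$name, length(x$terms), x$loglik, x$aic))
  invisible(x)
}

#' Predicted event risk at a time point
#'
#' `risk(t | z) = 1 - exp(-Lambda0(t) * exp(beta' z))` with the Breslow
#' baseline; non-decreasing in `t` for fixed covariates.
#'
#' @param fit A `cox_fit`.
#' @param newdata Data frame of covariates.
#' @param t Time point(s) in months.
#' @return Matrix (patients x length(t)) of risks in `[0, 1]`, or a vector
#'   when `t` is scalar.
#' @export
predict_risk <- function(fit, newdata, t) {
  stopifnot(inherits(fit, "cox_fit"))
  lp <- as.numeric(stats::predict(fit$fit, newdata = newdata,
                                  type = "lp", reference = "zero"))
  bh <- fit$baseline_cumhaz
  L0 <- stats::approx(bh$time, bh$hazard, xout = t, method = "constant",
                      yleft = 0, rule = 2)$y
  out <- 1 - exp(-outer(exp(lp), L0))
  if (length(t) == 1L) as.numeric(out) else out
}

#' Backward stepwise selection by AIC
#'
#' Iteratively removes the term whose removal most improves AIC until no
#' single removal improves it.  Deterministic given the data; the outcome
#' columns are never dropped.
#'
#' @param fit A `cox_fit` (the full model).
#' @param data The data used for the fit.
#' @param keep Terms never dropped (e.g. the rad-score), default none.
#' @return A `cox_fit` for the selected model.
#' @export
stepwise_select <- function(fit, data, keep = character(0)) {
  stopifnot(inherits(fit, "cox_fit"))
  current <- fit$terms
  best <- fit
  repeat {
    droppable <- setdiff(current, keep)
    if (length(droppable) == 0 || length(current) <= 1) break
    cand <- lapply(droppable, function(tm) {
      suppressWarnings(fit_cox(setdiff(current, tm), data))
    })
    aics <- vapply(cand, function(f) f$aic, 0)
    if (min(aics) < best$aic - 1e-9) {
      k <- which.min(aics)
      best <- cand[[k]]
      current <- setdiff(current, droppable[k])
    } else break
  }
  best$name <- paste0(fit$name, "_step")
  best
}

#' Bootstrap internal validation (Harrell optimism correction)
#'
#' Refits the model (optionally with stepwise selection) on `B` bootstrap
#' resamples; optimism is the mean difference between each resample's
#' apparent concordance and its concordance on the original data, and the
#' corrected concordance is apparent minus optimism.
#'
#' @param spec A [model_spec()] or covariate vector.
#' @param data Data frame.
#' @param B Number of resamples (default 200, minimum 1).
#' @param stepwise Re-run stepwise selection inside each resample.
#' @param seed RNG seed.
#' @return List with `apparent`, `optimism`, `corrected`, `B`.
#' @export
bootstrap_validate <- function(spec, data, B = 200L, stepwise = FALSE, seed = 1L) {
  if (B < 1) stopf("apexfa_value_error", "B must be >= 1")
  full <- suppressWarnings(fit_cox(spec, data))
  if (stepwise) full <- stepwise_select(full, data)
  cindex <- function(fit, newdata) {
    lp <- as.numeric(stats::predict(fit$fit, newdata = newdata, type = "lp",
                                    reference = "zero"))
    survival::concordance(survival::Surv(time_months, event) ~ lp,
                          data = cbind(newdata, lp = lp), reverse = TRUE)$concordance
  }
  apparent <- cindex(full, data)
  opt <- numeric(B)
  with_local_seed(seed, {
    b <- 1L
    tries <- 0L
    while (b <= B) {
      idx <- sample.int(nrow(data), replace = TRUE)
      boot <- data[idx, , drop = FALSE]
      tries <- tries + 1L
      if (sum(boot$event) < 2) {
        if (tries > 20L * B) stopf("apexfa_value_error", "resampling keeps failing")
        warning("bootstrap resample without events redrawn", call. = FALSE)
        next
      }
      fb <- suppressWarnings(fit_cox(spec, boot))
      if (stepwise) fb <- stepwise_select(fb, boot)
      opt[b] <- cindex(fb, boot) - cindex(fb, data)
      b <- b + 1L
    }
  })
  optimism <- mean(opt)
  list(apparent = apparent, optimism = optimism,
       corrected = apparent - optimism, B = B)
}

#' Serialize a Cox fit as JSON
#' @param fit A `cox_fit`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_cox_fit <- function(fit, path) {
  jsonlite::write_json(list(name = fit$name, terms = fit$terms,
                            beta = as.list(fit$beta),
                            covariance = unname(as.matrix(fit$covariance)),
                            baseline_cumhaz = fit$baseline_cumhaz,
                            loglik = fit$loglik, aic = fit$aic),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
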