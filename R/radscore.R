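# Rad-score construction: LASSO-penalized Cox selection over texture
# features (delegated to glmnet with Breslow ties), deviance-minimizing
# ten-fold cross-validation, the linear rad-score, optimal-cutpoint risk
# stratification (an exhaustive log-rank scan standing in for X-tile),
# Kaplan-Meier estimation and the G-rho weighted log-rank test.

prep_xy <- function(X, time, event) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stopf("apexfa_value_error", "non-finite feature values")
  if (sum(event) < 2) stopf("apexfa_no_events_error", "need at least 2 events")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  keep <- sd_ > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")
  list(Xs = Xs, mu = mu[keep], sd = sd_[keep], keep = keep)
}

#' LASSO-penalized Cox coefficient path
#'
#' Coefficients maximizing the L1-penalized Cox partial likelihood (Breslow
#' ties) over a grid of penalties.  Features are standardized internally;
#' coefficients are reported on the standardized scale.
#'
#' @param X Numeric feature matrix (patients x features).
#' @param time,event Right-censored outcome (months; event 1 = healed).
#' @param lambda Optional decreasing penalty grid; by default glmnet's grid
#'   from `lambda_max` downward.
#' @return A `lasso_cox_path`: list with `lambda`, `beta` (features x
#'   lambda, standardized scale), `standardization`, and the glmnet fit.
#' @export
lasso_cox_path <- function(X, time, event, lambda = NULL) {
  pr <- prep_xy(X, time, event)
  y <- survival::Surv(time, event)
  fit <- glmnet::glmnet(pr$Xs, y, family = "cox", lambda = lambda,
                        standardize = FALSE, thresh = 1e-12)
  structure(list(lambda = fit$lambda,
                 beta = as.matrix(fit$beta),
                 standardization = list(mu = pr$mu, sd = pr$sd),
                 keep = pr$keep, fit = fit),
            class = "lasso_cox_path")
}

#' Select the penalty by ten-fold cross-validated deviance
#'
#' Folds are stratified by the event indicator so each fold carries events;
#' the reported `lambda` minimizes the mean cross-validated partial-
#' likelihood deviance (the single-penalty rule matching a per-model
#' reported lambda).
#'
#' @inheritParams lasso_cox_path
#' @param k Number of folds (default 10).
#' @param seed RNG seed controlling the fold assignment.
#' @param rule `"min"` (default) picks the deviance-minimizing penalty;
#'   `"1se"` the largest penalty within one standard error of it (more
#'   conservative: under pure noise it usually selects nothing).
#' @return List with `lambda`, `cv` (data.frame lambda/mean/se), `path`.
#' @export
cv_select_lambda <- function(X, time, event, k = 10L, seed = 1L,
                             rule = c("min", "1se")) {
  rule <- match.arg(rule)
  if (k < 2) stopf("apexfa_value_error", "k must be >= 2")
  pr <- prep_xy(X, time, event)
  y <- survival::Surv(time, event)
  n <- length(time)
  foldid <- integer(n)
  with_local_seed(seed, {
    for (g in unique(event)) {
      idx <- which(event == g)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  cvfit <- glmnet::cv.glmnet(pr$Xs, y, family = "cox", foldid = foldid,
                             type.measure = "deviance", standardize = FALSE,
                             thresh = 1e-12)
  list(lambda = if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se,
       cv = data.frame(lambda = cvfit$lambda, mean = cvfit$cvm, se = cvfit$cvsd),
       foldid = foldid, cvfit = cvfit)
}

#' Build a rad-score model from a feature table
#'
#' Runs [cv_select_lambda()] and extracts the selected signatures and their
#' coefficients at the chosen penalty.  The rad-score of a patient is the
#' linear combination of the selected standardized features weighted by
#' their coefficients.
#'
#' @inheritParams cv_select_lambda
#' @return A `rad_score_model`: list with `selected`, `coefficients`,
#'   `lambda`, `standardization` (per-feature mean and sd), and
#'   `cutpoint` (NA until [optimal_cutpoint()] is applied).
#' @export
build_rad_score <- function(X, time, event, k = 10L, seed = 1L,
                            rule = c("min", "1se")) {
  cv <- cv_select_lambda(X, time, event, k = k, seed = seed, rule = rule)
  beta <- as.numeric(glmnet::coef.glmnet(cv$cvfit, s = cv$lambda))
  pr <- prep_xy(X, time, event)
  names(beta) <- colnames(pr$Xs)
  sel <- beta != 0
  structure(list(selected = names(beta)[sel],
                 coefficients = beta[sel],
                 lambda = cv$lambda,
                 standardization = list(mu = pr$mu[sel], sd = pr$sd[sel]),
                 cutpoint = NA_real_,
                 cv = cv$cv),
            class = "rad_score_model")
}

#' @export
print.rad_score_model <- function(x, ...) {
  cat(sprintf("<rad_score_model: %d signatures at lambda=%.4g, cutpoint=%s>\n",
              length(x$selected), x$lambda,
              if (is.na(x$cutpoint)) "unset" else sprintf("%.3f", x$cutpoint)))
  invisible(x)
}

#' Compute per-patient rad-scores
#'
#' `score_i = sum_j coef_j * (x_ij - mu_j) / sd_j` over the selected
#' signatures.
#'
#' @param model A `rad_score_model`.
#' @param X Feature matrix containing all selected features (by name).
#' @return Numeric vector of scores.
#' @export
rad_score <- function(model, X) {
  stopifnot(inherits(model, "rad_score_model"))
  X <- as.matrix(X)
  missing <- setdiff(model$selected, colnames(X))
  if (length(missing)) {
    stopf("apexfa_schema_error", "missing selected feature(s): %s",
          paste(missing, collapse = ", "))
  }
  if (length(model$selected) == 0) return(rep(0, nrow(X)))
  Xs <- sweep(sweep(X[, model$selected, drop = FALSE], 2,
                    model$standardization$mu), 2, model$standardization$sd, "/")
  as.numeric(Xs %*% model$coefficients)
}

#' Serialize / restore a rad-score model as JSON
#' @param model A `rad_score_model`.
#' @param path JSON path.
#' @return `write_rad_score_model`: the path invisibly;
#'   `read_rad_score_model`: the model.
#' @export
write_rad_score_model <- function(model, path) {
  jsonlite::write_json(list(selected = model$selected,
                            coefficients = as.list(model$coefficients),
                            lambda = model$lambda,
                            standardization = lapply(model$standardization, as.list),
                            cutpoint = model$cutpoint),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rad_score_model
#' @export
read_rad_score_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected = as.character(j$selected),
                 coefficients = stats::setNames(unlist(j$coefficients),
                                                names(j$coefficients)),
                 lambda = j$lambda,
                 standardization = lapply(j$standardization, unlist),
                 cutpoint = ifelse(is.null(j$cutpoint), NA_real_, j$cutpoint)),
            class = "rad_score_model")
}

# Vectorized log-rank chi-square for every cutpoint simultaneously.
# For threshold c the groups are {score > c} vs {score <= c}; returns the
# standard (unweighted) log-rank statistic for each candidate.
logrank_scan_stats <- function(score, time, event, candidates) {
  o <- order(time)
  time <- time[o]; event <- event[o]; score <- score[o]
  ut <- unique(time[event == 1])
  k <- length(candidates)
  U <- numeric(k); V <- numeric(k)
  for (t in ut) {
    at_risk <- time >= t
    ev <- time == t & event == 1
    n <- sum(at_risk); dth <- sum(ev)
    if (n < 2 || dth == 0) next
    for (ci in seq_len(k)) {
      g <- score > candidates[ci]
      n1 <- sum(at_risk & g)
      d1 <- sum(ev & g)
      e1 <- dth * n1 / n
      v1 <- dth * (n1 / n) * (1 - n1 / n) * (n - dth) / max(n - 1, 1)
      U[ci] <- U[ci] + d1 - e1
      V[ci] <- V[ci] + v1
    }
  }
  ifelse(V > 0, U^2 / V, 0)
}

#' Optimal rad-score cutpoint by exhaustive log-rank scan
#'
#' Deterministic reconstruction of "optimal cutpoint" software: every
#' midpoint between adjacent unique scores whose induced groups both hold at
#' least `min_group_frac` of the patients is scored by the standard log-rank
#' chi-square, and the maximizer is returned.  Because the maximum of many
#' correlated chi-squares is anti-conservative, the Miller-Siegmund corrected
#' p-value for a maximally selected rank statistic is reported alongside the
#' naive one.
#'
#' @param score Numeric scores.
#' @param time,event Outcome.
#' @param min_group_frac Minimum fraction of patients in each group.
#' @return List with `cutpoint`, `chisq`, `p_naive`, `p_corrected`,
#'   and the scan table.
#' @export
optimal_cutpoint <- function(score, time, event, min_group_frac = 0.1) {
  us <- sort(unique(score))
  if (length(us) < 2) stopf("apexfa_cutpoint_error", "need >= 2 distinct scores")
  mid <- (us[-1] + us[-length(us)]) / 2
  n <- length(score)
  frac_high <- vapply(mid, function(c) mean(score > c), 0)
  ok <- frac_high >= min_group_frac & (1 - frac_high) >= min_group_frac
  if (!any(ok)) stopf("apexfa_cutpoint_error", "no admissible cutpoint")
  cand <- mid[ok]
  chis <- logrank_scan_stats(score, time, event, cand)
  best <- which.max(chis)
  z <- sqrt(max(chis[best], 0))
  p_naive <- stats::pchisq(chis[best], df = 1, lower.tail = FALSE)
  # Miller & Siegmund approximation for a maximally selected statistic over
  # the quantile band [eps, 1 - eps]
  eps <- min_group_frac
  p_ms <- if (z > 1e-8) {
    stats::dnorm(z) * (z - 1 / z) * log((1 - eps)^2 / eps^2) + 4 * stats::dnorm(z) / z
  } else 1
  list(cutpoint = cand[best], chisq = chis[best],
       p_naive = p_naive, p_corrected = min(1, p_ms),
       scan = data.frame(cutpoint = cand, chisq = chis))
}

#' Kaplan-Meier estimate with Greenwood confidence intervals
#'
#' Thin wrapper around the product-limit estimator returning a tidy curve
#' per group, plus median survival when reached.
#'
#' @param time,event Outcome.
#' @param group Optional grouping factor.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `curves` (data.frame: group, time, n_risk, n_event,
#'   surv, lower, upper) and `median` (named vector).
#' @export
km_estimate <- function(time, event, group = NULL, conf_level = 0.95) {
  df <- data.frame(time = time, event = event,
                   group = if (is.null(group)) factor("all") else factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                           conf.int = conf_level, conf.type = "log")
  sm <- summary(fit)
  grp <- if (is.null(sm$strata)) rep("all", length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv,
                       lower = sm$lower, upper = sm$upper)
  med <- summary(fit)$table
  med_v <- if (is.null(dim(med))) med["median"] else med[, "median"]
  list(curves = curves, median = med_v, fit = fit)
}

#' G-rho (Harrington-Fleming) weighted log-rank test
#'
#' Weights each event time by `S(t-)^rho` on the pooled Kaplan-Meier;
#' `rho = 0` is the standard log-rank, `rho = 1` the Peto-Peto test
#' emphasizing early differences.
#'
#' @param time,event Outcome.
#' @param group Two-level grouping.
#' @param rho Weight exponent (default 1).
#' @return List with `chisq`, `df`, `p`.
#' @export
grho_logrank <- function(time, event, group, rho = 1) {
  if (sum(event) == 0) stopf("apexfa_test_error", "no events: test undefined")
  g <- factor(group)
  if (nlevels(g) < 2 || any(table(g) == 0)) {
    stopf("apexfa_test_error", "need two non-empty groups")
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, rho = rho)
  df <- length(sd_$n) - 1
  list(chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE))
}

#' Univariate Cox regression
#'
#' Newton-Raphson partial-likelihood fit with Breslow ties; Wald confidence
#' interval `exp(beta +/- z * se)`.
#'
#' @param x Predictor (numeric or 2-level factor).
#' @param time,event Outcome.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `hr`, `ci` (length 2), `beta`, `se`, `p`.
#' @export
univariate_cox <- function(x, time, event, conf_level = 0.95) {
  df <- data.frame(x = x, time = time, event = event)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = df,
                         ties = "breslow")
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    stopf("apexfa_convergence_error", "Cox fit did not converge")
  }
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * zq * se),
       beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)))
}
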