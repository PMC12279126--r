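# External-validation metrics for time-to-event prediction: IPCW
# cumulative-case / dynamic-control ROC and AUC at a fixed horizon with an
# influence-function standard error, a paired influence-function comparison
# of two AUCs (the time-dependent analogue of the DeLong test), fixed-time
# calibration slope/intercept from decile-binned Kaplan-Meier observed
# risks, and survival decision-curve analysis.

# Kaplan-Meier of the censoring distribution evaluated just before t
censor_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t) {
    s <- summary(fit, times = t, extend = TRUE)$surv
    pmax(s, 1e-12)
  }
}

ipcw_weights <- function(time, event, t) {
  case <- time <= t & event == 1
  control <- time > t
  if (!any(case) || !any(control)) {
    stopf("apexfa_auc_error", "no cases or no controls at t=%g", t)
  }
  G <- censor_km(time, event)
  w <- numeric(length(time))
  # G(T-) for cases, G(t) for controls
  w[case] <- 1 / G(pmax(time[case] - 1e-9, 0))
  w[control] <- 1 / G(t)
  list(case = case, control = control, w = w)
}

#' Time-dependent ROC curve and AUC with IPCW
#'
#' Cumulative-case / dynamic-control definition at horizon `t`: cases are
#' subjects with an event by `t`, controls are subjects event-free at `t`.
#' Subjects censored before `t` receive zero weight; cases and controls are
#' reweighted by the inverse Kaplan-Meier of the censoring distribution.
#' The standard error comes from the influence-function (DeLong-type)
#' representation of the weighted two-sample U-statistic.
#'
#' @param marker Numeric marker (higher = higher event risk).
#' @param time,event Outcome.
#' @param t Evaluation horizon (months).
#' @return List with `auc`, `se`, `ci` (95 percent), `curve` (data.frame
#'   fpr/tpr), `n_cases`, `n_controls`, and the per-subject influence
#'   values `infl`.
#' @export
time_dependent_roc <- function(marker, time, event, t) {
  stopifnot(length(marker) == length(time))
  wts <- ipcw_weights(time, event, t)
  case <- wts$case; control <- wts$control; w <- wts$w
  mi <- marker[case]; wi <- w[case]
  mj <- marker[control]; wj <- w[control]
  Wc <- sum(wi); Wd <- sum(wj)
  # weighted sum over pairs w_i w_j [1(m_i > m_j) + 0.5 1(m_i = m_j)],
  # accumulated over sorted tie groups rather than the full pair matrix
  cmp_sum <- function(mc, wc, md, wd) {
    val <- c(md, mc)
    wgt_d <- c(wd, rep(0, length(mc)))
    wgt_c <- c(rep(0, length(md)), wc)
    o <- order(val)
    val <- val[o]; wgt_d <- wgt_d[o]; wgt_c <- wgt_c[o]
    total <- 0; cd_below <- 0
    i <- 1L; n <- length(val)
    while (i <= n) {
      j <- i
      while (j < n && val[j + 1L] == val[i]) j <- j + 1L
      wd_here <- sum(wgt_d[i:j])
      wc_here <- sum(wgt_c[i:j])
      total <- total + wc_here * (cd_below + 0.5 * wd_here)
      cd_below <- cd_below + wd_here
      i <- j + 1L
    }
    total
  }
  U <- cmp_sum(mi, wi, mj, wj)
  auc <- U / (Wc * Wd)
  # influence values: cases p_i - AUC, controls q_j - AUC
  p_i <- vapply(mi, function(m) sum(wj * ((m > mj) + 0.5 * (m == mj))) / Wd, 0)
  q_j <- vapply(mj, function(m) sum(wi * ((mi > m) + 0.5 * (mi == m))) / Wc, 0)
  infl <- numeric(length(marker))
  infl[case] <- (wi / Wc) * (p_i - auc)
  infl[control] <- (wj / Wd) * (q_j - auc)
  se <- sqrt(sum(infl^2))
  thr <- sort(unique(marker), decreasing = TRUE)
  tpr <- vapply(thr, function(c) sum(wi[mi >= c]) / Wc, 0)
  fpr <- vapply(thr, function(c) sum(wj[mj >= c]) / Wd, 0)
  list(auc = auc, se = se,
       ci = pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1),
       curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       n_cases = sum(case), n_controls = sum(control), infl = infl)
}

#' Paired comparison of two time-dependent AUCs
#'
#' Tests `AUC_A(t) = AUC_B(t)` for two markers measured on the same subjects
#' using the joint influence-function covariance of the two IPCW AUC
#' estimates - the time-dependent analogue of the paired DeLong test (the
#' literal DeLong test is undefined under censoring).
#'
#' @param markerA,markerB Markers on the same subjects.
#' @param time,event Outcome.
#' @param t Horizon.
#' @return List with `auc_a`, `auc_b`, `z`, `p`.
#' @export
compare_auc <- function(markerA, markerB, time, event, t) {
  ra <- time_dependent_roc(markerA, time, event, t)
  rb <- time_dependent_roc(markerB, time, event, t)
  d <- ra$infl - rb$infl
  se <- sqrt(sum(d^2))
  diff <- ra$auc - rb$auc
  if (se < 1e-12) {
    z <- 0; p <- 1
  } else {
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ra$auc, auc_b = rb$auc, diff = diff, z = z, p = p)
}

#' Fixed-time calibration slope and intercept
#'
#' Subjects are binned by deciles of predicted risk at `t`; the observed
#' risk in each bin is `1 - KM(t)` within the bin, and slope/intercept come
#' from least squares of observed on predicted across bins.  A slope below 1
#' flags overconfident (too extreme) predictions.
#'
#' @param predicted Predicted event risks at `t` (from [predict_risk()]).
#' @param time,event Outcome.
#' @param t Horizon.
#' @param n_bins Number of risk bins (default 10).
#' @return List with `slope`, `intercept`, `curve` (data.frame
#'   predicted/observed/n per bin).
#' @export
calibration_at_time <- function(predicted, time, event, t, n_bins = 10L) {
  if (length(unique(predicted)) < 2) {
    stopf("apexfa_calibration_error", "all predictions identical: slope undefined")
  }
  br <- unique(stats::quantile(predicted, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(predicted, breaks = br, include.lowest = TRUE)
  km_risk <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    f <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    s <- summary(f, times = t, extend = TRUE)$surv
    1 - s
  }
  levs <- levels(bins)
  obs <- pred <- nb <- numeric(0)
  pend <- integer(0)
  for (l in levs) {
    idx <- which(bins == l)
    if (length(idx) == 0) next
    # bins with no subjects at risk before t merge into the next bin
    if (max(time[idx]) < t && sum(event[idx]) == 0) {
      pend <- c(pend, idx)
      next
    }
    idx <- c(pend, idx); pend <- integer(0)
    obs <- c(obs, km_risk(idx))
    pred <- c(pred, mean(predicted[idx]))
    nb <- c(nb, length(idx))
  }
  keep <- is.finite(obs) & is.finite(pred)
  obs <- obs[keep]; pred <- pred[keep]; nb <- nb[keep]
  if (length(obs) < 2 || stats::sd(pred) == 0) {
    stopf("apexfa_calibration_error", "fewer than two usable calibration bins")
  }
  ls <- stats::lm.fit(cbind(1, pred), obs)
  list(slope = unname(ls$coefficients[2]),
       intercept = unname(ls$coefficients[1]),
       curve = data.frame(predicted = pred, observed = obs, n = nb))
}

#' Survival decision-curve analysis
#'
#' Net benefit of treating patients whose predicted risk at `t` meets each
#' threshold: `NB(p) = TP/n - FP/n * p / (1 - p)`, with the event
#' probability inside the treated group estimated by Kaplan-Meier at `t`
#' (censoring-aware).  `nb_all` treats everyone, `nb_none` is identically 0.
#'
#' @param predicted Predicted event risks at `t`.
#' @param time,event Outcome.
#' @param t Horizon.
#' @param thresholds Probability grid (default 0.01 to 0.99 by 0.01).
#' @return A data.frame with columns threshold, nb_model, nb_all, nb_none.
#' @export
decision_curve <- function(predicted, time, event, t,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stopf("apexfa_value_error", "thresholds must lie strictly inside (0, 1)")
  }
  n <- length(predicted)
  km_at <- function(idx) {
    f <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    summary(f, times = t, extend = TRUE)$surv
  }
  risk_all <- 1 - km_at(seq_len(n))
  nb_model <- vapply(thresholds, function(p) {
    pos <- which(predicted >= p)
    if (length(pos) == 0) return(0)
    risk_pos <- 1 - km_at(pos)
    frac_pos <- length(pos) / n
    tp <- frac_pos * risk_pos
    fp <- frac_pos * (1 - risk_pos)
    tp - fp * p / (1 - p)
  }, 0)
  nb_all <- risk_all - (1 - risk_all) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, nb_model = nb_model,
             nb_all = nb_all, nb_none = 0)
}
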