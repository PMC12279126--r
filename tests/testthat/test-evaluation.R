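# Time-dependent IPCW ROC/AUC, paired AUC comparison, fixed-time
# calibration, and decision-curve analysis.

sim_surv_marker <- function(n, beta = 1, seed = 1, cens_max = 40,
                            shape = 1.5, scale = 20) {
  set.seed(seed)
  x <- rnorm(n)
  t_lat <- scale * (-log(runif(n)) / exp(beta * x))^(1 / shape)
  cn <- if (is.finite(cens_max)) runif(n, 0, cens_max) else rep(Inf, n)
  list(x = x, time = pmin(t_lat, cn), event = as.integer(t_lat <= cn),
       latent = t_lat)
}

test_that("a perfect marker gives AUC 1 and the null marker ~0.5", {
  set.seed(31)
  n <- 400
  t_lat <- rexp(n, 0.08)
  roc <- time_dependent_roc(-t_lat, t_lat, rep(1L, n), t = 12)
  expect_equal(roc$auc, 1)
  d <- sim_surv_marker(2000, beta = 0, seed = 32)
  roc0 <- time_dependent_roc(rnorm(2000), d$time, d$event, t = 12)
  expect_lt(abs(roc0$auc - 0.5), 0.03)
  expect_true(roc0$ci[1] <= roc0$auc && roc0$auc <= roc0$ci[2])
})

test_that("without censoring the IPCW AUC equals the brute-force rank AUC", {
  set.seed(33)
  n <- 150
  d <- sim_surv_marker(n, beta = 0.8, seed = 33, cens_max = Inf)
  expect_true(all(d$event == 1))
  for (t in c(8, 15)) {
    roc <- time_dependent_roc(d$x, d$time, d$event, t)
    oracle <- oracle_rank_auc(d$x, d$time <= t)
    expect_equal(roc$auc, oracle, tolerance = 1e-12)
  }
})

test_that("undefined AUC errors when a horizon has no cases or controls", {
  d <- sim_surv_marker(50, seed = 34)
  expect_error(time_dependent_roc(d$x, d$time, d$event, t = 0.001),
               class = "apexfa_auc_error")
})

test_that("paired AUC comparison: identity, rank invariance, and power", {
  d <- sim_surv_marker(300, beta = 1, seed = 35)
  same <- compare_auc(d$x, d$x, d$time, d$event, t = 12)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  mono <- compare_auc(d$x, exp(2 * d$x) + 5, d$time, d$event, t = 12)
  expect_equal(mono$z, 0)
  # power: strong vs weak marker on the same subjects
  rej <- 0L
  for (r in 1:60) {
    set.seed(600 + r)
    n <- 300
    x <- rnorm(n)
    t_lat <- 20 * (-log(runif(n)) / exp(1.2 * x))^(1 / 1.5)
    cn <- runif(n, 0, 40)
    time <- pmin(t_lat, cn); event <- as.integer(t_lat <= cn)
    weak <- 0.2 * x + rnorm(n)
    ct <- compare_auc(x, weak, time, event, t = 12)
    rej <- rej + (ct$p < 0.05)
  }
  expect_gte(rej / 60, 0.8)
})

test_that("calibration is near-ideal for data simulated from the model", {
  d <- sim_clinical2 <- local({
    set.seed(36)
    n <- 2000
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    eta <- 0.7 * x1 - 0.5 * x2
    t_lat <- 20 * (-log(runif(n)) / exp(eta))^(1 / 1.5)
    cn <- runif(n, 5, 60)
    data.frame(x1 = x1, x2 = x2, time_months = pmin(t_lat, cn),
               event = as.integer(t_lat <= cn))
  })
  fit <- suppressWarnings(fit_cox(c("x1", "x2"), d))
  pred <- predict_risk(fit, d, t = 12)
  cal <- calibration_at_time(pred, d$time_months, d$event, t = 12)
  expect_gt(cal$slope, 0.9); expect_lt(cal$slope, 1.1)
  expect_lt(abs(cal$intercept), 0.05)
  expect_error(calibration_at_time(rep(0.4, 100), d$time_months[1:100],
                                   d$event[1:100], 12),
               class = "apexfa_calibration_error")
})

test_that("an overfit model shows slope below 1 out of sample", {
  set.seed(37)
  n <- 160
  train <- data.frame(matrix(rnorm(n * 12), n, 12))
  names(train) <- paste0("z", 1:12)
  eta <- 0.5 * train$z1
  t_lat <- 20 * (-log(runif(n)) / exp(eta))^(1 / 1.5)
  cn <- runif(n, 5, 60)
  train$time_months <- pmin(t_lat, cn); train$event <- as.integer(t_lat <= cn)
  test <- data.frame(matrix(rnorm(n * 12), n, 12))
  names(test) <- paste0("z", 1:12)
  eta2 <- 0.5 * test$z1
  t_lat2 <- 20 * (-log(runif(n)) / exp(eta2))^(1 / 1.5)
  cn2 <- runif(n, 5, 60)
  test$time_months <- pmin(t_lat2, cn2); test$event <- as.integer(t_lat2 <= cn2)
  fit <- suppressWarnings(fit_cox(paste0("z", 1:12), train))
  pred <- predict_risk(fit, test, t = 12)
  cal <- calibration_at_time(pred, test$time_months, test$event, t = 12)
  expect_lt(cal$slope, 1)
})

test_that("decision curves obey the treat-none and treat-all limits", {
  d <- sim_surv_marker(500, beta = 1, seed = 38)
  risk <- pnorm(d$x)                              # any monotone risk proxy
  dc <- decision_curve(risk, d$time, d$event, t = 12,
                       thresholds = c(0.01, seq(0.05, 0.95, 0.05)))
  expect_true(all(dc$nb_none == 0))
  km <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  overall <- 1 - summary(km, times = 12)$surv
  expect_equal(dc$nb_all[1], overall, tolerance = 0.02)
  expect_error(decision_curve(risk, d$time, d$event, 12, thresholds = c(0, 0.5)),
               class = "apexfa_value_error")
})

test_that("without censoring the decision curve equals the binary-outcome DCA", {
  set.seed(39)
  n <- 400
  d <- sim_surv_marker(n, beta = 1, seed = 39, cens_max = Inf)
  risk <- pnorm(d$x)
  t0 <- 12
  dc <- decision_curve(risk, d$time, d$event, t = t0,
                       thresholds = seq(0.1, 0.9, 0.1))
  y <- d$time <= t0                               # fully observed outcome
  for (i in seq_len(nrow(dc))) {
    p <- dc$threshold[i]
    pos <- risk >= p
    nb_oracle <- (sum(y & pos) - sum(!y & pos) * p / (1 - p)) / n
    expect_equal(dc$nb_model[i], nb_oracle, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly monotone marker transforms", {
  d <- sim_surv_marker(300, beta = 1, seed = 40)
  a <- time_dependent_roc(d$x, d$time, d$event, 12)$auc
  b <- time_dependent_roc(atan(d$x) * 3 + 1, d$time, d$event, 12)$auc
  expect_equal(a, b, tolerance = 1e-12)
})
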