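# LASSO-Cox path and selection, rad-score arithmetic and round-trip,
# cutpoint scan (with survdiff cross-check and null calibration), KM,
# G-rho test, and univariate Cox.

sim_ph_data <- function(n, p, beta, seed, scale = 20, shape = 1.5,
                        cens = 40) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- as.numeric(X %*% beta)
  t_lat <- scale * (-log(runif(n)) / exp(eta))^(1 / shape)
  cn <- runif(n, 0, cens)
  list(X = X, time = pmin(t_lat, cn), event = as.integer(t_lat <= cn))
}

test_that("penalty dominance and the unpenalized limit hold", {
  d <- sim_ph_data(300, 5, c(0.8, -0.6, 0.5, 0, 0), seed = 1)
  path <- lasso_cox_path(d$X, d$time, d$event)
  # glmnet's first lambda is lambda_max: all coefficients exactly zero
  expect_true(all(path$beta[, 1] == 0))
  expect_true(all(abs(path$beta[, ncol(path$beta)]) > 0) ||
                any(path$beta[, ncol(path$beta)] != 0))
  # near-zero penalty matches the unpenalized Breslow Cox fit
  Xs <- scale(d$X)
  small <- glmnet::glmnet(Xs, survival::Surv(d$time, d$event), family = "cox",
                          lambda = c(0.05, 1e-5), standardize = FALSE,
                          thresh = 1e-14)
  ref <- survival::coxph(survival::Surv(d$time, d$event) ~ Xs, ties = "breslow")
  expect_lt(max(abs(small$beta[, 2] - coef(ref))), 1e-4)
})

test_that("true signatures enter the path before noise features", {
  beta <- c(1, -1, 0.8, rep(0, 17))
  d <- sim_ph_data(500, 20, beta, seed = 2)
  path <- lasso_cox_path(d$X, d$time, d$event)
  entry <- apply(path$beta != 0, 1, function(z) if (any(z)) which(z)[1] else Inf)
  expect_setequal(names(sort(entry)[1:3]), c("f1", "f2", "f3"))
})

test_that("cross-validated selection is seed-deterministic", {
  d <- sim_ph_data(150, 8, c(1, -0.8, rep(0, 6)), seed = 3)
  a <- cv_select_lambda(d$X, d$time, d$event, k = 5, seed = 42)
  b <- cv_select_lambda(d$X, d$time, d$event, k = 5, seed = 42)
  expect_identical(a$lambda, b$lambda)
  expect_identical(a$foldid, b$foldid)
  # folds stratified by event
  for (f in 1:5) expect_gt(sum(d$event[a$foldid == f]), 0)
})

test_that("pure-noise features are mostly screened out", {
  hits_1se <- 0L
  n_sel_min <- integer(25)
  for (r in 1:25) {
    d <- sim_ph_data(120, 10, rep(0, 10), seed = 100 + r)
    m1 <- build_rad_score(d$X, d$time, d$event, k = 5, seed = r, rule = "1se")
    if (length(m1$selected) == 0) hits_1se <- hits_1se + 1L
    m0 <- build_rad_score(d$X, d$time, d$event, k = 5, seed = r, rule = "min")
    n_sel_min[r] <- length(m0$selected)
  }
  # the conservative 1-SE rule screens pure noise out almost always;
  # the deviance-minimizing rule keeps selections sparse (median zero)
  expect_gte(hits_1se / 25, 0.8)
  expect_lte(median(n_sel_min), 1)
  expect_lte(mean(n_sel_min), 3)
})

test_that("rad-score arithmetic and serialization round-trip", {
  m <- structure(list(selected = "f1", coefficients = c(f1 = 2),
                      lambda = 0.1,
                      standardization = list(mu = c(f1 = 10), sd = c(f1 = 2)),
                      cutpoint = NA_real_),
                 class = "rad_score_model")
  X <- matrix(13, 1, 1, dimnames = list(NULL, "f1"))  # standardized value 1.5
  expect_equal(rad_score(m, X), 3.0)
  expect_error(rad_score(m, matrix(0, 1, 1, dimnames = list(NULL, "f2"))),
               class = "apexfa_schema_error")
  d <- sim_ph_data(200, 6, c(1, -1, rep(0, 4)), seed = 4)
  fitm <- build_rad_score(d$X, d$time, d$event, k = 5, seed = 9)
  f <- tempfile(fileext = ".json")
  write_rad_score_model(fitm, f)
  back <- read_rad_score_model(f)
  expect_equal(rad_score(back, d$X), rad_score(fitm, d$X), tolerance = 1e-12)
})

test_that("cutpoint scan recovers a mixture split and matches survdiff", {
  set.seed(5)
  n <- 200
  grp <- rep(0:1, each = n / 2)
  score <- rnorm(n, mean = ifelse(grp == 1, 3, 0), sd = 0.3)  # disjoint clusters
  t_lat <- 10 * (-log(runif(n)) / exp(1.5 * grp))^(1 / 1.5)
  cens <- runif(n, 5, 30)
  time <- pmin(t_lat, cens); event <- as.integer(t_lat <= cens)
  res <- optimal_cutpoint(score, time, event)
  # the recovered threshold reproduces the true mixture split (the log-rank
  # surface is near-flat across the empty gap, so allow <= 2 strays)
  expect_lte(sum((score > res$cutpoint) != (grp == 1)), 2)
  expect_gt(res$cutpoint, 0); expect_lt(res$cutpoint, 3)
  # the scanned chi-square agrees with survival::survdiff at each candidate
  for (ci in sample(nrow(res$scan), 10)) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~
                                (score > res$scan$cutpoint[ci]))
    expect_equal(res$scan$chisq[ci], sd_$chisq, tolerance = 1e-8)
  }
  expect_error(optimal_cutpoint(rep(1, 50), time[1:50], event[1:50]),
               class = "apexfa_cutpoint_error")
})

test_that("the corrected maximal-statistic p is conservative vs the naive p", {
  set.seed(6)
  reps <- 120
  p_naive <- p_corr <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 60
    score <- rnorm(n)
    t_lat <- rexp(n, 0.1)
    cens <- runif(n, 5, 30)
    time <- pmin(t_lat, cens); event <- as.integer(t_lat <= cens)
    res <- optimal_cutpoint(score, time, event)
    p_naive[r] <- res$p_naive
    p_corr[r] <- res$p_corrected
  }
  # naive maximal p is anti-conservative; the correction tempers it
  expect_gt(mean(p_naive < 0.05), 0.10)
  expect_lt(mean(p_corr < 0.05), mean(p_naive < 0.05))
  expect_lte(mean(p_corr < 0.05), 0.12)
})

test_that("KM matches the hand-computed 6-subject product-limit", {
  # classic example: times 1, 2+, 3, 4, 4, 5+ (+ = censored)
  time <- c(1, 2, 3, 4, 4, 5)
  event <- c(1, 0, 1, 1, 1, 0)
  km <- km_estimate(time, event)
  s <- km$curves
  expect_equal(s$surv[s$time == 1], 5 / 6)
  expect_equal(s$surv[s$time == 3], 5 / 6 * 3 / 4)
  expect_equal(s$surv[s$time == 4], 5 / 6 * 3 / 4 * 1 / 3)
  # single subject and no-event limits
  one <- km_estimate(5, 1)
  expect_equal(one$curves$surv, 0)
  none <- km_estimate(c(2, 4), c(0, 0))
  expect_true(all(none$curves$surv == 1) || nrow(none$curves) == 0)
})

test_that("G-rho test degenerates and reduces correctly", {
  set.seed(11)
  time <- rexp(40, 0.1); event <- rbinom(40, 1, 0.8)
  dup_time <- c(time, time); dup_event <- c(event, event)
  g <- rep(c("a", "b"), each = 40)
  expect_lt(grho_logrank(dup_time, dup_event, g, rho = 1)$chisq, 1e-10)
  # rho = 0 equals the standard log-rank
  g2 <- rbinom(40, 1, 0.5)
  ours <- grho_logrank(time, event, g2, rho = 0)
  ref <- survival::survdiff(survival::Surv(time, event) ~ g2, rho = 0)
  expect_equal(ours$chisq, unname(ref$chisq), tolerance = 1e-12)
  expect_error(grho_logrank(time, rep(0, 40), g2),
               class = "apexfa_test_error")
})

test_that("rho = 1 up-weights early differences", {
  set.seed(12)
  n <- 200
  g <- rep(0:1, each = n / 2)
  # early separation that vanishes later: group effect only below t = 5
  t0 <- rexp(n, ifelse(g == 1, 0.5, 0.15))
  t1 <- 5 + rexp(n, 0.2)
  time <- ifelse(t0 < 5, t0, t1)
  event <- rep(1L, n)
  r0 <- grho_logrank(time, event, g, rho = 0)
  r1 <- grho_logrank(time, event, g, rho = 1)
  expect_gt(r1$chisq, r0$chisq)
})

test_that("univariate Cox recovers a known hazard ratio and rescales", {
  set.seed(13)
  n <- 2000
  x <- rnorm(n)
  t_lat <- 20 * (-log(runif(n)) / exp(log(1.6) * x))^(1 / 1.5)
  cens <- runif(n, 5, 60)
  time <- pmin(t_lat, cens); event <- as.integer(t_lat <= cens)
  fit <- univariate_cox(x, time, event)
  expect_gt(fit$hr, 1.45); expect_lt(fit$hr, 1.77)
  fit10 <- univariate_cox(x * 10, time, event)
  expect_equal(fit10$beta, fit$beta / 10, tolerance = 1e-6)
})
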