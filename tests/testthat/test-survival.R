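cohort_from_counts <- function(sizes, deaths,
                               groups = c("2-6", "7", "8-10")) {
  data.frame(gleason_group = rep(groups, sizes),
             event = unlist(mapply(function(n, d)
               c(rep(1, d), rep(0, n - d)), sizes, deaths,
               SIMPLIFY = FALSE)))
}

test_that("cohort summary reproduces percentages from raw counts", {
  co <- cohort_from_counts(c(124, 127, 89), c(2, 4, 29))
  s <- cohort_summary(co)
  expect_equal(s$n, 340L)
  expect_equal(s$n_deaths, 35)
  tab <- s$table[match(c("2-6", "7", "8-10"), s$table$group), ]
  expect_equal(tab$pct_samples, c(36.47, 37.35, 26.18))
  expect_equal(tab$pct_dod, c(5.71, 11.43, 82.86))
  # single-sample cohort: 100% in its group
  s1 <- cohort_summary(data.frame(gleason_group = "7", event = 0))
  expect_equal(s1$table$pct_samples, 100)
  expect_error(cohort_summary(data.frame()), "empty")
})

test_that("marker standardization gives mean 0 / sd 1 and is idempotent", {
  d <- data.frame(m = c(1, 2, 3))
  z <- standardize_markers(d, "m")$m
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  expect_error(standardize_markers(data.frame(m = rep(2, 5)), "m"),
               "zero variance")
  # re-standardizing a standardized marker is a numerical fixed point
  # after undoing the log offset: apply to strictly positive markers
  d2 <- data.frame(m = exp(stats::rnorm(50, 1, 0.4)))
  z1 <- standardize_markers(d2, "m")$m
  d3 <- data.frame(m = expm1(z1 - min(z1) + 0.5))  # positive again
  z2 <- standardize_markers(d3, "m")$m
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z2), 1, tolerance = 1e-12)
})

test_that("Cox coefficient matches brute-force partial-likelihood maximization", {
  x <- c(1, 0, 1, 0, 1, 0)
  tm <- c(1.1, 2.3, 3.7, 4.1, 5.9, 6.2)
  ev <- rep(1, 6)
  fit <- fit_cox(matrix(x, ncol = 1), tm, ev)
  expect_equal(unname(fit$coefficients), cox_grid_1d(x, tm, ev),
               tolerance = 2e-3)
  expect_equal(fit$risk, x * fit$coefficients[[1]], ignore_attr = TRUE)
})

test_that("Cox fit on permuted covariates is usually non-significant", {
  set.seed(55)
  n <- 80
  tm <- stats::rexp(n); ev <- stats::rbinom(n, 1, 0.7)
  x <- stats::rnorm(n)
  nonsig <- 0
  for (i in 1:100) {
    xp <- sample(x)
    f <- survival::coxph(survival::Surv(tm, ev) ~ xp, ties = "efron")
    p <- summary(f)$coefficients[, "Pr(>|z|)"]
    if (p > 0.05) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 90)
})

test_that("Cox recovers a planted log-hazard of 0.7", {
  set.seed(77)
  n <- 2000
  x <- stats::rnorm(n)
  tm <- stats::rexp(n, rate = 0.1 * exp(0.7 * x))
  ev <- rep(1, n)
  fit <- fit_cox(matrix(x, ncol = 1), tm, ev)
  expect_equal(unname(fit$coefficients), 0.7, tolerance = 0.1)
})

test_that("logistic fit: closed forms, separation, grid oracle, glm agreement", {
  # intercept-only: fitted probability equals the case fraction
  y <- c(1, 1, 0, 0, 0)
  f0 <- fit_logistic(matrix(numeric(0), nrow = 5, ncol = 0), y)
  expect_equal(unname(f0$probabilities), rep(0.4, 5), tolerance = 1e-8)
  # perfectly separated 1-D toy: monotone probabilities, AUC 1
  x <- c(-3, -2, -1, 1, 2, 3)
  ys <- c(0, 0, 0, 1, 1, 1)
  fs <- fit_logistic(matrix(x, ncol = 1), ys)
  expect_true(all(diff(fs$probabilities) > 0))
  expect_equal(roc_auc(fs$probabilities, ys), 1.0)
  # grid oracle on a non-separated toy
  set.seed(8)
  xg <- stats::rnorm(40)
  yg <- stats::rbinom(40, 1, stats::plogis(0.5 + 0.8 * xg))
  fg <- fit_logistic(matrix(xg, ncol = 1), yg)
  expect_equal(unname(fg$coefficients), logistic_grid_2d(xg, yg),
               tolerance = 1e-2)
  # agrees with glm when the MLE is finite (ridge is negligible)
  gfit <- stats::glm(yg ~ xg, family = stats::binomial())
  expect_equal(unname(fg$coefficients), unname(coef(gfit)),
               tolerance = 1e-4)
  expect_error(fit_logistic(matrix(xg, ncol = 1), rep(1, 40)),
               "both classes")
})

test_that("tertile split takes the correct third with deterministic tie handling", {
  g <- tertile_split(1:9, "positive")
  expect_equal(which(g == "high-risk"), 7:9)
  g2 <- tertile_split(1:9, "negative")
  expect_equal(which(g2 == "high-risk"), 1:3)
  expect_equal(levels(g), c("high-risk", "rest"))
  # ties at the boundary: sizes stay ceiling(n/3) for any input order
  v <- c(5, 5, 5, 5, 1, 2, 3, 9, 9, 9)
  for (i in 1:10) {
    gt <- tertile_split(v, "positive")
    expect_equal(sum(gt == "high-risk"), 4L)
  }
  expect_error(tertile_split(rep(2, 10)), "identical")
  expect_error(tertile_split(1:2), "at least 3")
})

test_that("KM/log-rank/HR agree with hand computation on a worked toy", {
  # 6 subjects, all events, no censoring
  tm <- c(1, 2, 3, 4, 5, 6)
  ev <- rep(1, 6)
  gr <- factor(c("high-risk", "high-risk", "high-risk", "rest", "rest",
                 "rest"), levels = c("high-risk", "rest"))
  res <- km_logrank_hr(tm, ev, gr)
  expect_equal(res$logrank_chisq, logrank_brute(tm, ev, gr),
               tolerance = 1e-10)
  # KM product-limit steps for the high-risk group: 2/3, 1/3, 0
  km_hr <- res$km[["high-risk"]]
  expect_equal(km_hr$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km_hr$n_risk, c(3, 2, 1))
  # identical survival experience in both groups: chi-square 0, HR 1
  tm2 <- rep(c(1, 2, 3), 2); ev2 <- rep(1, 6)
  gr2 <- factor(rep(c("high-risk", "rest"), each = 3),
                levels = c("high-risk", "rest"))
  res2 <- km_logrank_hr(tm2, ev2, gr2)
  expect_equal(res2$logrank_chisq, 0, tolerance = 1e-10)
  expect_equal(res2$hr, 1, tolerance = 1e-6)
  # no events at all: HR undefined
  res3 <- km_logrank_hr(c(1, 2, 3, 4), c(0, 0, 0, 0),
                        factor(c("a", "a", "b", "b")))
  expect_true(is.na(res3$hr))
})

test_that("log-rank statistic is invariant under label swap and HR inverts", {
  set.seed(12)
  tm <- stats::rexp(60, rate = c(rep(1, 30), rep(0.4, 30)))
  ev <- stats::rbinom(60, 1, 0.8)
  gr <- factor(rep(c("high-risk", "rest"), each = 30),
               levels = c("high-risk", "rest"))
  gr_sw <- factor(as.character(gr), levels = c("rest", "high-risk"))
  a <- km_logrank_hr(tm, ev, gr)
  b <- km_logrank_hr(tm, ev, gr_sw)
  expect_equal(a$logrank_chisq, b$logrank_chisq, tolerance = 1e-10)
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-6)
  # KM curves are non-increasing and within [0, 1]
  for (k in a$km) {
    expect_true(all(diff(k$surv) <= 1e-12))
    expect_true(all(k$surv >= 0 & k$surv <= 1))
  }
})

test_that("a 3-fold survival-time ratio yields HR near 3", {
  set.seed(19)
  n <- 1000
  t1 <- stats::rexp(n / 2, rate = 1)
  t2 <- stats::rexp(n / 2, rate = 1 / 3)
  gr <- factor(rep(c("high-risk", "rest"), each = n / 2),
               levels = c("high-risk", "rest"))
  res <- km_logrank_hr(c(t1, t2), rep(1, n), gr)
  expect_equal(res$hr, 3, tolerance = 0.45)
})

test_that("concordance index and AUC match brute-force enumeration on toys", {
  # perfectly ordered risks
  expect_equal(concordance_index(5:1, 1:5, rep(1, 5)), 1.0)
  expect_equal(concordance_index(rep(2, 5), 1:5, rep(1, 5)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  # 5-subject toy with one censored subject
  risk <- c(2.0, 1.5, 3.0, 0.5, 1.0)
  tm <- c(2, 4, 1, 5, 3)
  ev <- c(1, 1, 1, 0, 1)
  expect_equal(concordance_index(risk, tm, ev),
               cindex_brute(risk, tm, ev))
  # 8-point AUC toy with a tie
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9, 0.5, 0.2)
  lb <- c(0, 0, 1, 1, 0, 1, 1, 0)
  expect_equal(roc_auc(sc, lb), auc_brute(sc, lb))
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("CI and AUC equal their all-pairs oracles on random small instances", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    risk <- round(stats::rnorm(n), 1)          # induce occasional ties
    tm <- stats::rexp(n)
    ev <- stats::rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[sample(n, 1)] <- 1
    expect_equal(concordance_index(risk, tm, ev),
                 cindex_brute(risk, tm, ev), tolerance = 1e-12)
    lb <- stats::rbinom(n, 1, 0.5)
    if (length(unique(lb)) == 2)
      expect_equal(roc_auc(risk, lb), auc_brute(risk, lb),
                   tolerance = 1e-12)
  }
})

test_that("AUC of scores independent of labels sits near one half", {
  set.seed(66)
  sc <- stats::rnorm(200)
  lb <- sample(rep(c(0, 1), each = 100))
  expect_lt(abs(roc_auc(sc, lb) - 0.5), 0.1)
})

test_that("bootstrap evaluation is reproducible and honours out-of-bag discipline", {
  d <- simulate_cohort(cohort_design(n = 150, target_events = 25), seed = 4)
  mk <- c("SMAD4", "CCND1", "SPP1")
  b1 <- bootstrap_evaluate(d, mk, B = 8, seed = 99)
  b2 <- bootstrap_evaluate(d, mk, B = 8, seed = 99)
  expect_identical(b1$indices, b2$indices)
  expect_equal(b1$replicates, b2$replicates)
  for (idx in b1$indices) {
    oob <- setdiff(seq_len(b1$n), idx)
    expect_true(length(oob) > 0)
    expect_length(intersect(oob, idx), 0)
  }
  expect_true(all(unlist(b1$replicates) >= 0 & unlist(b1$replicates) <= 1))
})

test_that("bootstrap on a null cohort shows resampling optimism around chance", {
  design <- cohort_design(beta = c(SMAD4 = 0, CCND1 = 0, SPP1 = 0),
                          target_events = 35)
  d <- simulate_cohort(design, seed = 21)
  b <- bootstrap_evaluate(d, c("SMAD4", "CCND1", "SPP1"), B = 60, seed = 5)
  m_test <- mean(b$replicates$logit_test_auc)
  m_train <- mean(b$replicates$logit_train_auc)
  expect_gte(m_train, m_test)
  expect_gt(m_test, 0.38); expect_lt(m_test, 0.62)
})

test_that("bootstrap test AUC tracks a planted binormal separation", {
  # cases N(mu, 1), controls N(0, 1) with mu chosen for AUC 0.75
  mu <- sqrt(2) * stats::qnorm(0.75)
  set.seed(31)
  n <- 340
  y <- stats::rbinom(n, 1, 0.25)
  x <- stats::rnorm(n, mean = mu * y)
  d <- data.frame(time_years = ifelse(y == 1, stats::rexp(n, 1),
                                      stats::rexp(n, 0.05)),
                  event = y, M = exp(x))
  b <- bootstrap_evaluate(d, "M", B = 200, seed = 13)
  expect_equal(mean(b$replicates$logit_test_auc), 0.75, tolerance = 0.05)
})

test_that("univariate marker analysis composes the tertile pipeline", {
  d <- simulate_cohort(cohort_design(), seed = 5)
  u <- univariate_marker(standardize_markers(d, "pPRAS40"), "pPRAS40")
  expect_equal(as.integer(u$n[["high-risk"]]), ceiling(340 / 3))
  expect_gt(u$hr, 1)   # positively planted marker
  expect_true(u$logrank_p >= 0 && u$logrank_p <= 1)
})
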