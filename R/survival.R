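#' Cohort composition summary
#'
#' Per-Gleason-group counts: number of samples, percent of samples, number of
#' disease-specific deaths (DOD) and percent of all deaths, with percentages
#' reported to two decimals; plus mean (SD) age at diagnosis and median
#' follow-up.
#'
#' @param cohort data frame with columns `gleason_group`, `event` (dead of
#'   disease, 0/1), and optionally `age` and `time_years`.
#' @return List with `table` (data frame: group, n_samples, pct_samples,
#'   n_dod, pct_dod), `n`, `n_deaths`, `age_mean`, `age_sd`,
#'   `median_followup`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (!nrow(cohort)) stop("empty cohort")
  need <- c("gleason_group", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  g <- factor(cohort$gleason_group)
  n <- nrow(cohort)
  deaths <- sum(cohort$event)
  ns <- as.integer(table(g))
  nd <- as.integer(tapply(cohort$event, g, sum, default = 0))
  tab <- data.frame(group = levels(g),
                    n_samples = ns,
                    pct_samples = round(100 * ns / n, 2),
                    n_dod = nd,
                    pct_dod = if (deaths > 0) round(100 * nd / deaths, 2)
                    else NA_real_)
  list(table = tab, n = n, n_deaths = deaths,
       age_mean = if ("age" %in% names(cohort)) mean(cohort$age) else NA_real_,
       age_sd = if ("age" %in% names(cohort)) stats::sd(cohort$age)
       else NA_real_,
       median_followup = if ("time_years" %in% names(cohort))
         stats::median(cohort$time_years) else NA_real_)
}

#' Standardize marker columns
#'
#' Applies `log1p` then a z-score per marker (mean 0, sd 1 over non-missing
#' values). Model fits operate on this scale so coefficients are comparable
#' across markers.
#'
#' @param cohort data frame containing the marker columns.
#' @param markers character vector of marker column names.
#' @return The cohort with the marker columns transformed.
#' @export
standardize_markers <- function(cohort, markers) {
  miss <- setdiff(markers, names(cohort))
  if (length(miss)) stop("missing marker column(s): ",
                         paste(miss, collapse = ", "))
  for (mk in markers) {
    v <- cohort[[mk]]
    if (any(v < 0, na.rm = TRUE)) stop("marker ", mk, " has negative values")
    x <- log1p(v)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("marker ", mk, " has zero variance")
    cohort[[mk]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  cohort
}

#' Fit a multivariate Cox proportional-hazards model
#'
#' Thin wrapper around [survival::coxph()] with Efron tie handling, returning
#' the coefficients and the linear-predictor risk scores used throughout the
#' tertile and bootstrap analyses.
#'
#' @param X numeric matrix or data frame of covariates (no missing values).
#' @param times positive follow-up times.
#' @param events event indicators (0/1).
#' @return Object of class `qmif_cox`: list with `coefficients`, `risk`
#'   (linear predictor, centered as by coxph), and the underlying `fit`.
#' @export
fit_cox <- function(X, times, events) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(times) || anyNA(events)) stop("missing values")
  if (nrow(X) <= ncol(X)) stop("need n > p")
  df <- data.frame(X)
  fit <- survival::coxph(survival::Surv(times, events) ~ .,
                         data = df, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    stop("Cox fit did not converge")
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop("Cox fit produced undefined coefficients")
  structure(list(coefficients = stats::setNames(as.numeric(beta),
                                                colnames(X)),
                 risk = drop(as.matrix(X) %*% beta),
                 fit = fit),
            class = "qmif_cox")
}

#' @export
print.qmif_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.qmif_cox <- function(object, newdata, ...) {
  drop(as.matrix(newdata)[, names(object$coefficients), drop = FALSE] %*%
         object$coefficients)
}

#' Fit a ridge-stabilized logistic regression
#'
#' Maximum-likelihood logistic regression by Newton/IRLS with a small L2
#' ridge (default 1e-6) on the non-intercept coefficients; the ridge keeps
#' the fit finite under quasi-separation, which bootstrap resamples of a
#' 35-event cohort readily produce.
#'
#' @param X numeric matrix or data frame of covariates.
#' @param y binary case labels (1 = dead of disease).
#' @param ridge L2 penalty on non-intercept coefficients (default 1e-6).
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `qmif_logistic`: list with `coefficients`
#'   (intercept first), `probabilities` (fitted case probabilities).
#' @export
fit_logistic <- function(X, y, ridge = 1e-6, max_iter = 100, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (anyNA(X) || anyNA(y)) stop("missing values")
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- crossprod(Xd, y - mu) - pen %*% beta
    H <- crossprod(Xd, Xd * w) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(Xd %*% beta)
  structure(list(coefficients = stats::setNames(drop(beta), colnames(Xd)),
                 probabilities = stats::plogis(eta)),
            class = "qmif_logistic")
}

#' @export
print.qmif_logistic <- function(x, ...) {
  cat("logistic regression fit (ridge-stabilized)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.qmif_logistic <- function(object, newdata, ...) {
  b <- object$coefficients
  eta <- b[1L] + drop(as.matrix(newdata)[, names(b)[-1L], drop = FALSE] %*%
                        b[-1L])
  stats::plogis(eta)
}

#' Tertile split of risk scores
#'
#' Splits the cohort into the high-risk third and the remaining two thirds.
#' For a positively correlated score the high-risk group is the top third;
#' for a negatively correlated score it is the bottom third. Ties are broken
#' by stable sample order, so the group sizes are always ceiling(n/3) and
#' n - ceiling(n/3) regardless of ties.
#'
#' @param risk numeric risk scores.
#' @param direction `"positive"` (default) or `"negative"`.
#' @return Factor with levels `c("high-risk", "rest")`.
#' @export
tertile_split <- function(risk, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  n <- length(risk)
  if (n < 3L) stop("need at least 3 samples")
  if (length(unique(risk)) == 1L) stop("all risk scores identical")
  k <- ceiling(n / 3)
  ord <- if (direction == "positive")
    order(-risk, seq_len(n)) else order(risk, seq_len(n))
  grp <- rep("rest", n)
  grp[ord[seq_len(k)]] <- "high-risk"
  factor(grp, levels = c("high-risk", "rest"))
}

#' Kaplan-Meier curves, log-rank test and hazard ratio for two groups
#'
#' @param times positive follow-up times.
#' @param events event indicators (0/1).
#' @param groups factor with two levels; the first level is the high-risk
#'   group whose hazard ratio is reported relative to the second.
#' @return Object of class `univariate_result`: list with `hr` (may be `NA`
#'   when no events occur), `logrank_chisq`, `logrank_p`, `n` (per-group
#'   sizes), and `km` (per-group data frames: time, surv, n_risk, n_event).
#' @export
km_logrank_hr <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two non-empty groups required")
  df <- data.frame(t = times, e = events, g = groups)
  km <- lapply(split(df, df$g), function(d) {
    f <- survival::survfit(survival::Surv(t, e) ~ 1, data = d)
    data.frame(time = f$time, surv = f$surv, n_risk = f$n.risk,
               n_event = f$n.event)
  })
  if (sum(events) == 0L) {
    return(structure(list(hr = NA_real_, hr_reason = "no events",
                          logrank_chisq = 0, logrank_p = 1,
                          n = table(groups), km = km),
                     class = "univariate_result"))
  }
  sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
  chisq <- sd$chisq
  pval <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  # HR of level 1 (high-risk) vs level 2 from a univariate Cox fit
  ind <- as.numeric(df$g == levels(groups)[1L])
  hr <- tryCatch({
    cf <- survival::coxph(survival::Surv(t, e) ~ ind, data = df,
                          ties = "efron")
    exp(unname(stats::coef(cf)))
  }, error = function(e) NA_real_, warning = function(w) {
    cf <- suppressWarnings(survival::coxph(survival::Surv(t, e) ~ ind,
                                           data = df, ties = "efron"))
    exp(unname(stats::coef(cf)))
  })
  structure(list(hr = hr, logrank_chisq = chisq, logrank_p = pval,
                 n = table(groups), km = km),
            class = "univariate_result")
}

#' @export
print.univariate_result <- function(x, ...) {
  cat(sprintf("univariate survival: HR = %.3g, log-rank chi^2 = %.3g (p = %.3g)\n",
              x$hr, x$logrank_chisq, x$logrank_p))
  cat("  groups:", paste(names(x$n), as.integer(x$n), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Plot Kaplan-Meier curves of a univariate result
#'
#' @param x a `univariate_result`.
#' @param col per-group line colors.
#' @param ... passed to [graphics::plot()].
#' @export
plot.univariate_result <- function(x, col = c("firebrick", "steelblue"), ...) {
  graphics::plot(NA, xlim = c(0, max(unlist(lapply(x$km, `[[`, "time")))),
                 ylim = c(0, 1), xlab = "years", ylab = "survival", ...)
  for (i in seq_along(x$km)) {
    k <- x$km[[i]]
    graphics::lines(stats::stepfun(k$time, c(1, k$surv)), col = col[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", names(x$km), col = col[seq_along(x$km)],
                   lty = 1, bty = "n")
  invisible(x)
}

#' Run the univariate tertile analysis for one marker
#'
#' Trains a univariate Cox model on the (standardized) marker, splits the
#' cohort at the risk-score tertile and reports the Kaplan-Meier/log-rank/HR
#' comparison of the high-risk third against the rest.
#'
#' @param cohort data frame with `time_years`, `event` and the marker column
#'   (already standardized or raw).
#' @param marker marker column name.
#' @return A `univariate_result` with the marker name and Cox direction
#'   attached.
#' @export
univariate_marker <- function(cohort, marker) {
  keep <- stats::complete.cases(cohort[, c("time_years", "event", marker)])
  d <- cohort[keep, ]
  fit <- fit_cox(d[, marker, drop = FALSE], d$time_years, d$event)
  grp <- tertile_split(fit$risk, "positive")
  res <- km_logrank_hr(d$time_years, d$event, grp)
  res$marker <- marker
  res$cox_coefficient <- unname(fit$coefficients)
  res
}

#' Harrell's concordance index
#'
#' Fraction of usable subject pairs (the member with the shorter follow-up
#' experienced the event) whose risk ordering matches their survival
#' ordering; risk ties count one half. Computed via
#' [survival::concordance()].
#'
#' @param risk numeric risk scores (higher = expected earlier event).
#' @param times follow-up times.
#' @param events event indicators (0/1).
#' @return Concordance in \[0, 1\].
#' @export
concordance_index <- function(risk, times, events) {
  fit <- survival::concordance(survival::Surv(times, events) ~ risk,
                               reverse = TRUE)
  cnt <- as.numeric(fit$count)
  if (sum(cnt[1:3]) == 0) stop("no comparable pairs")
  unname(fit$concordance)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midranks for ties.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels (1 = case).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap evaluation of a marker signature
#'
#' Draws `B` bootstrap resamples of the cohort; on each, trains a
#' multivariate Cox model and a logistic regression (cases = dead of
#' disease) on the resample and evaluates AUC and concordance index on the
#' out-of-bag complement. Replicates whose complement is empty or
#' single-class, or whose fits fail, are redrawn (counted in `n_redrawn`).
#' Whole-cohort "train mode" fits (train and test on the full cohort) are
#' reported alongside.
#'
#' @param cohort data frame with `time_years`, `event` and marker columns.
#' @param markers character vector of marker column names.
#' @param B number of bootstrap replicates (default 10000; use a few hundred
#'   for exploration).
#' @param seed integer seed; all resampling derives from it.
#' @param standardize log1p + z-score the markers first (default TRUE).
#' @return Object of class `bootstrap_evaluation`: list with `replicates`
#'   (data frame of per-replicate train/test AUC and CI for both models),
#'   `summary` (mean and 2.5/97.5 percentiles per metric), `train_mode`
#'   (whole-cohort metrics), `n`, `B`, `n_redrawn`, `markers`.
#' @export
bootstrap_evaluate <- function(cohort, markers, B = 10000, seed = 1,
                               standardize = TRUE) {
  stopifnot(B >= 1)
  keep <- stats::complete.cases(cohort[, c("time_years", "event", markers)])
  d <- cohort[keep, , drop = FALSE]
  if (standardize) d <- standardize_markers(d, markers)
  X <- as.matrix(d[, markers, drop = FALSE])
  tm <- d$time_years; ev <- d$event
  n <- nrow(X)
  if (length(unique(ev)) < 2L) stop("cohort must contain both outcomes")

  eval_models <- function(tr, te) {
    cox <- fit_cox(X[tr, , drop = FALSE], tm[tr], ev[tr])
    logit <- fit_logistic(X[tr, , drop = FALSE], ev[tr])
    risk_te <- predict(cox, X[te, , drop = FALSE])
    prob_te <- predict(logit, X[te, , drop = FALSE])
    c(cox_test_auc = roc_auc(risk_te, ev[te]),
      cox_test_ci = concordance_index(risk_te, tm[te], ev[te]),
      logit_test_auc = roc_auc(prob_te, ev[te]),
      logit_test_ci = concordance_index(prob_te, tm[te], ev[te]),
      cox_train_auc = roc_auc(cox$risk, ev[tr]),
      cox_train_ci = concordance_index(cox$risk, tm[tr], ev[tr]),
      logit_train_auc = roc_auc(logit$probabilities, ev[tr]),
      logit_train_ci = concordance_index(logit$probabilities, tm[tr], ev[tr]))
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  reps <- matrix(NA_real_, B, 8L)
  boot_idx <- vector("list", B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      ok <- length(oob) > 0L && length(unique(ev[oob])) == 2L &&
        length(unique(ev[idx])) == 2L
      if (ok) {
        m <- tryCatch(suppressWarnings(eval_models(idx, oob)),
                      error = function(e) NULL)
        if (!is.null(m)) { reps[b, ] <- m; boot_idx[[b]] <- idx; break }
      }
      n_redrawn <- n_redrawn + 1L
    }
  }
  colnames(reps) <- c("cox_test_auc", "cox_test_ci", "logit_test_auc",
                      "logit_test_ci", "cox_train_auc", "cox_train_ci",
                      "logit_train_auc", "logit_train_ci")
  reps <- as.data.frame(reps)

  train_mode <- suppressWarnings(
    eval_models(seq_len(n), seq_len(n)))[c("cox_train_auc", "cox_train_ci",
                                           "logit_train_auc",
                                           "logit_train_ci")]
  summ <- do.call(rbind, lapply(names(reps), function(nm) {
    v <- reps[[nm]]
    data.frame(metric = nm, mean = mean(v),
               lower = stats::quantile(v, 0.025, names = FALSE),
               upper = stats::quantile(v, 0.975, names = FALSE))
  }))
  structure(list(replicates = reps, summary = summ,
                 train_mode = train_mode, indices = boot_idx,
                 n = n, B = B, n_redrawn = n_redrawn, markers = markers,
                 seed = seed),
            class = "bootstrap_evaluation")
}

#' @export
print.bootstrap_evaluation <- function(x, ...) {
  cat(sprintf("bootstrap evaluation: %s; n = %d, B = %d (%d redrawn)\n",
              paste(x$markers, collapse = " + "), x$n, x$B, x$n_redrawn))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s %.3f [%.3f, %.3f]\n", s$metric[i], s$mean[i],
                s$lower[i], s$upper[i]))
  cat(sprintf("  whole-cohort train mode: Cox AUC %.3f CI %.3f | logit AUC %.3f CI %.3f\n",
              x$train_mode[["cox_train_auc"]], x$train_mode[["cox_train_ci"]],
              x$train_mode[["logit_train_auc"]],
              x$train_mode[["logit_train_ci"]]))
  invisible(x)
}
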