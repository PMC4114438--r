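# Independent brute-force oracles. Each is written from the defining
# formula, without reference to the implementation it checks.

# Otsu on log1p values: exhaustive loop over all cuts between consecutive
# distinct values, maximizing between-class variance computed directly.
otsu_brute <- function(v, offset = 1.0) {
  x <- log1p(as.numeric(v))
  u <- sort(unique(x))
  if (length(u) < 2L) return(NA_real_)
  best <- -Inf
  best_cut <- NA_real_
  for (i in seq_len(length(u) - 1L)) {
    cut <- (u[i] + u[i + 1L]) / 2
    g1 <- x[x <= cut]; g2 <- x[x > cut]
    w1 <- length(g1) / length(x); w2 <- 1 - w1
    bc <- w1 * w2 * (mean(g1) - mean(g2))^2
    if (bc > best) { best <- bc; best_cut <- cut }
  }
  expm1(best_cut) * offset
}

# AUC as the fraction of concordant case/control pairs (ties count half).
auc_brute <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}

# Harrell's C by exhaustive pair enumeration: a pair is usable when the
# member with the shorter follow-up has an event (pairs tied on time are
# skipped); risk ties count half.
cindex_brute <- function(risk, times, events) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (times[i] == times[j]) next
    s <- if (times[i] < times[j]) i else j   # shorter follow-up
    l <- if (s == i) j else i
    if (events[s] != 1) next
    den <- den + 1
    num <- num + if (risk[s] > risk[l]) 1 else if (risk[s] == risk[l]) 0.5
    else 0
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Two-group log-rank chi-square from the observed-vs-expected tables at
# each distinct event time.
logrank_brute <- function(times, events, groups) {
  g <- as.integer(as.factor(groups))
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at_risk <- times >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & g == 1L)
    o_minus_e <- o_minus_e + (d1 - n1 * d / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# Cox partial log-likelihood for one covariate (no ties expected in the
# toys this oracle serves).
cox_partial_loglik_1d <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    at_risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Brute-force maximization over a two-stage 1-D grid.
cox_grid_1d <- function(x, times, events, lim = 5) {
  g1 <- seq(-lim, lim, by = 0.01)
  l1 <- vapply(g1, cox_partial_loglik_1d, numeric(1L), x, times, events)
  b0 <- g1[which.max(l1)]
  g2 <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  l2 <- vapply(g2, cox_partial_loglik_1d, numeric(1L), x, times, events)
  g2[which.max(l2)]
}

# Ridge-penalized logistic log-likelihood (intercept unpenalized), matching
# the fitting contract; maximized over a two-stage 2-D grid.
logistic_loglik <- function(b0, b1, x, y, ridge = 1e-6) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta))) - ridge * b1^2 / 2
}
logistic_grid_2d <- function(x, y, lim = 6) {
  g <- seq(-lim, lim, by = 0.05)
  best <- c(NA, NA); bl <- -Inf
  for (b0 in g) for (b1 in g) {
    l <- logistic_loglik(b0, b1, x, y)
    if (l > bl) { bl <- l; best <- c(b0, b1) }
  }
  g2a <- seq(best[1] - 0.1, best[1] + 0.1, by = 1e-3)
  g2b <- seq(best[2] - 0.1, best[2] + 0.1, by = 1e-3)
  for (b0 in g2a) for (b1 in g2b) {
    l <- logistic_loglik(b0, b1, x, y)
    if (l > bl) { bl <- l; best <- c(b0, b1) }
  }
  best
}
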