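# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Cox log partial likelihood (no ties assumed, so Efron == Breslow)
oracle_cox_loglik <- function(beta, x, time, event) {
  eta <- drop(x %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# 1-D grid maximiser of the partial likelihood
oracle_cox_grid <- function(x, time, event, lo = -10, hi = 10, by = 1e-4) {
  grid <- seq(lo, hi, by = by)
  ll <- vapply(grid, function(b)
    oracle_cox_loglik(b, cbind(x), time, event), numeric(1))
  grid[which.max(ll)]
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  stepped <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(stepped)))
  pmin(adj, 1)[order(o)]
}

# AUC as pairwise case/control concordance (ties get half credit)
oracle_auc_concordance <- function(score, is_case) {
  s1 <- score[is_case]
  s0 <- score[!is_case]
  mean(outer(s1, s0, ">") + 0.5 * outer(s1, s0, "=="))
}

# Exact two-sided Mann-Whitney p by full enumeration of label assignments
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    xx <- pooled[idx]
    yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_all <- apply(utils::combn(n, nx), 2, u_of)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  mu <- nx * (n - nx) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Two-group log-rank chi-square from the observed-minus-expected table
oracle_logrank_chi2 <- function(time, event, group) {
  g1 <- group == levels(factor(group))[1]
  o1 <- 0; e1 <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n_t
    if (n_t > 1)
      v <- v + d * (n_t - d) * n1 * (n_t - n1) / (n_t^2 * (n_t - 1))
  }
  (o1 - e1)^2 / v
}

# small shared cohort + fit, built once per test run
shared_sim <- local({
  value <- NULL
  function() {
    if (is.null(value))
      value <<- simulate_cohort(sim_config(
        n_tumor = 200, n_normal = 25, n_lnc = 40, n_srg = 12,
        frac_de = 0.7, frac_coexpressed = 0.7, seed = 7))
    value
  }
})

shared_fit <- local({
  value <- NULL
  function() {
    if (is.null(value))
      value <<- pair_signature_sim(
        shared_sim(),
        control = signature_control(n_reps = 40, freq_min = 4),
        seed = 7)
    value
  }
})
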