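mk_model <- function(coefs) {
  parts <- strsplit(names(coefs), "|", fixed = TRUE)
  structure(list(pairs = data.frame(
    lnc_a = vapply(parts, `[`, "", 1),
    lnc_b = vapply(parts, `[`, "", 2),
    stringsAsFactors = FALSE),
    coefficients = coefs, fit = NULL, provenance = list()),
    class = "signature_model")
}

mk_pm <- function(values) {
  structure(list(values = values, pairs = NULL,
                 one_fraction = colMeans(values)), class = "pair_matrix")
}

test_that("riskscore is the coefficient-weighted sum of indicators", {
  values <- cbind(`A|B` = c(0L, 1L, 1L), `C|D` = c(0L, 0L, 1L))
  rownames(values) <- paste0("S", 1:3)
  model <- mk_model(c(`A|B` = 0.5, `C|D` = -0.25))
  sc <- compute_riskscore(model, mk_pm(values))
  expect_equal(unname(sc), c(0, 0.5, 0.25))
  expect_identical(names(sc), paste0("S", 1:3))
  expect_error(compute_riskscore(mk_model(c(`X|Y` = 1)), mk_pm(values)),
               "X\\|Y")
})

test_that("risk score and stratification inherit monotone invariance", {
  set.seed(20)
  m <- matrix(stats::rexp(6 * 40), 6, 40,
              dimnames = list(sprintf("G%d", 1:6), sprintf("S%02d", 1:40)))
  model <- mk_model(c(`G1|G4` = 0.8, `G2|G5` = -0.6))
  warped <- sweep(m^2, 2, stats::runif(40, 0.5, 3), `*`)
  s1 <- compute_riskscore(model, pair_indicators(m, model$pairs))
  s2 <- compute_riskscore(model, pair_indicators(warped, model$pairs))
  expect_identical(s1, s2)
  expect_identical(stratify(s1, 0.1), stratify(s2, 0.1))
})

test_that("subgroup product-limit evaluation matches survfit", {
  set.seed(21)
  n <- 80
  tt <- round(stats::rexp(n, 0.01)) + 1
  ev <- stats::rbinom(n, 1, 0.6)
  for (h in c(30, 90, 200)) {
    sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    s_ref <- summary(sf, times = h, extend = TRUE)$surv
    expect_equal(lncPairRisk:::km_surv_at(tt, ev, h), s_ref,
                 tolerance = 1e-12)
  }
})

test_that("AUC equals case/control concordance when nothing is censored", {
  set.seed(22)
  n <- 150
  score <- stats::rnorm(n)
  tt <- stats::rexp(n, 0.01 * exp(0.7 * score))
  h <- stats::median(tt)
  roc <- time_dependent_roc(score, tt, rep(1L, n), h)
  expect_equal(roc$auc, oracle_auc_concordance(score, tt <= h),
               tolerance = 1e-10)
  # complementarity and monotone invariance of the score
  roc_neg <- time_dependent_roc(-score, tt, rep(1L, n), h)
  expect_equal(roc$auc + roc_neg$auc, 1, tolerance = 1e-10)
  roc_mono <- time_dependent_roc(exp(2 * score), tt, rep(1L, n), h)
  expect_equal(roc_mono$auc, roc$auc, tolerance = 1e-12)
})

test_that("perfect separation gives AUC 1 and degenerate horizons error", {
  tt <- c(10, 20, 30, 100, 200, 300, 400)
  ev <- rep(1L, 7)
  score <- c(7, 6, 5, 3, 2, 1, 0)  # all cases above all controls at h = 50
  roc <- time_dependent_roc(score, tt, ev, 50)
  expect_equal(roc$auc, 1)
  expect_error(time_dependent_roc(score, tt, ev, 1000), "follow-up")
  expect_error(time_dependent_roc(score, tt, rep(0L, 7), 50), "degenerate")
})

test_that("null scores give AUC near one half", {
  set.seed(23)
  aucs <- vapply(1:10, function(s) {
    n <- 300
    score <- stats::rnorm(n)
    tt <- stats::rexp(n, 0.005)
    ev <- stats::rbinom(n, 1, 0.8)
    time_dependent_roc(score, tt, ev, stats::quantile(tt, 0.4))$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("the AIC cutoff search equals exhaustive enumeration", {
  set.seed(24)
  n <- 120
  score <- stats::rnorm(n)
  tt <- stats::rexp(n, 0.005 * exp(0.8 * (score > 0.3)))
  ev <- rep(1L, n)
  cs <- aic_optimal_cutoff(score, tt, ev, min_group_frac = 0.1)
  us <- sort(unique(score))
  mids <- (us[-1] + us[-length(us)]) / 2
  mids <- mids[pmin(vapply(mids, function(c) sum(score > c), 0),
                    vapply(mids, function(c) sum(score <= c), 0)) >= 0.1 * n]
  aics <- vapply(mids, function(c) {
    f <- survival::coxph(survival::Surv(tt, ev) ~ I(score > c))
    -2 * f$loglik[2] + 2
  }, numeric(1))
  expect_equal(cs$cutoff, mids[which.min(aics)])
  expect_true(all(is.finite(cs$trace$criterion)))
})

test_that("cutoff recovers two well-separated planted risk strata", {
  # The minimum-AIC scan can land a few samples inside a stratum (the
  # maximally-selected-statistic effect), so the planted-truth check is on
  # the recovered partition: essentially all samples must fall on the
  # correct side of the chosen cutoff.
  miss <- vapply(1:20, function(s) {
    set.seed(500 + s)
    n <- 400
    score <- c(stats::runif(n / 2, 0, 1), stats::runif(n / 2, 3, 4))
    strata <- rep(0:1, each = n / 2)
    tt <- stats::rexp(n, 0.002 * exp(log(4) * strata))
    cc <- stats::rexp(n, 0.001)
    cs <- aic_optimal_cutoff(score, pmin(tt, cc), as.integer(tt <= cc))
    mean((score > cs$cutoff) != (strata == 1))
  }, numeric(1))
  expect_gte(mean(miss <= 0.02), 0.9)
  expect_lte(stats::median(miss), 0.01)
})

test_that("two distinct scores admit exactly one cutoff candidate", {
  score <- rep(c(0, 1), each = 20)
  set.seed(25)
  tt <- stats::rexp(40, 0.01 * exp(score))
  cs <- aic_optimal_cutoff(score, tt, rep(1L, 40))
  expect_identical(nrow(cs$trace), 1L)
  expect_equal(cs$cutoff, 0.5)
})

test_that("group-size guard refuses degenerate splits", {
  score <- c(rep(0, 39), 5)
  set.seed(26)
  tt <- stats::rexp(40, 0.01)
  expect_error(aic_optimal_cutoff(score, tt, rep(1L, 40)),
               "min_group_frac")
})

test_that("stratification uses a strict threshold", {
  sc <- c(a = 0.4, b = 1.557, c = 2)
  g <- stratify(sc, 1.557)
  expect_identical(as.character(g), c("low", "low", "high"))
  expect_identical(names(g), names(sc))
  expect_error(stratify(sc, Inf), "finite")
})
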