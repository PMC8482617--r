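surv_toy <- function(n, beta, x, seed = 1, censor = 0) {
  set.seed(seed)
  tt <- stats::rexp(n, rate = 0.002 * exp(drop(x %*% beta)))
  cc <- if (censor > 0) stats::rexp(n, censor) else rep(Inf, n)
  list(time = pmin(tt, cc), event = as.integer(tt <= cc))
}

test_that("fit_cox rejects unidentifiable designs", {
  x <- cbind(a = rep(1, 20), b = stats::rnorm(20))
  tt <- stats::rexp(20, 0.01)
  expect_error(fit_cox(x, tt, rep(1, 20)), "constant covariate.*a")
  x2 <- cbind(a = stats::rnorm(20))
  x2 <- cbind(x2, twice = 2 * x2[, 1])
  expect_error(fit_cox(x2, tt, rep(1, 20)), "collinear.*twice")
  expect_error(fit_cox(x2[, 1, drop = FALSE], tt, rep(0, 20)),
               "at least one event")
  expect_error(fit_cox(x2[, 1, drop = FALSE], c(tt[-1], -1), rep(1, 20)),
               "positive")
})

test_that("fit_cox matches the brute-force partial-likelihood oracle", {
  # 1 covariate: fine grid over [-10, 10]
  x <- c(0, 1, 0, 1)
  tt <- c(2, 1, 4, 3)
  ev <- rep(1, 4)
  f <- fit_cox(cbind(z = x), tt, ev)
  expect_lt(abs(unname(f$coefficients) - oracle_cox_grid(x, tt, ev)), 1e-4)
  expect_equal(f$log_partial_likelihood,
               oracle_cox_loglik(f$coefficients, cbind(x), tt, ev),
               tolerance = 1e-8)
  expect_equal(f$aic, -2 * f$log_partial_likelihood + 2)
  # 2 covariates: direct optimisation of the oracle likelihood
  set.seed(8)
  x2 <- cbind(a = stats::rnorm(40), b = stats::rbinom(40, 1, 0.5))
  s <- surv_toy(40, c(0.7, -0.5), x2, seed = 8)
  f2 <- fit_cox(x2, s$time, s$event)
  opt <- stats::optim(c(0, 0), function(b)
    -oracle_cox_loglik(b, x2, s$time, s$event))
  expect_equal(unname(f2$coefficients), opt$par, tolerance = 1e-3)
  expect_equal(unname(f2$hr), exp(unname(f2$coefficients)))
  expect_equal(unname(f2$ci95[, "lo"]),
               exp(unname(f2$coefficients) - 1.96 * unname(f2$se)))
})

test_that("Wald test keeps its nominal size under the null", {
  set.seed(9)
  n <- 500
  rej <- vapply(1:1000, function(i) {
    x <- cbind(z = stats::rnorm(n))
    tt <- stats::rexp(n, 0.002)
    fit_cox(x, tt, rep(1L, n))$wald_p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("univariate screen has power on planted pairs and controls size", {
  set.seed(10)
  n <- 400
  n_noise <- 60
  retained_true <- logical(10)
  noise_rates <- numeric(10)
  for (s in 1:10) {
    set.seed(300 + s)
    x <- cbind(matrix(stats::rbinom(n * n_noise, 1, 0.5), n),
               true = stats::rbinom(n, 1, 0.5))
    colnames(x) <- c(sprintf("N%02d|M%02d", 1:n_noise, 1:n_noise), "T|U")
    tt <- stats::rexp(n, 0.002 * exp(1 * x[, "T|U"]))
    pm <- structure(list(values = x,
                         pairs = NULL, one_fraction = colMeans(x)),
                    class = "pair_matrix")
    scr <- univariate_screen(pm, tt, rep(1L, n))
    retained_true[s] <- "T|U" %in% scr$kept
    noise_rates[s] <- mean(scr$table$kept[scr$table$pair != "T|U"])
  }
  expect_gte(mean(retained_true), 0.95)
  expect_gt(mean(noise_rates), 0.02)
  expect_lt(mean(noise_rates), 0.08)
})

test_that("screen drops constant pair columns with a message", {
  n <- 50
  x <- cbind(`A|B` = rep(0L, n), `C|D` = rep(c(0L, 1L), n / 2))
  pm <- structure(list(values = x, pairs = NULL,
                       one_fraction = colMeans(x)), class = "pair_matrix")
  set.seed(1)
  tt <- stats::rexp(n, 0.01)
  expect_message(scr <- univariate_screen(pm, tt, rep(1L, n)), "dropped")
  expect_identical(scr$dropped, "A|B")
})

test_that("lasso frequency selection is deterministic and respects bounds", {
  set.seed(11)
  n <- 120
  x <- matrix(stats::rbinom(n * 8, 1, 0.5) + 0, n, 8,
              dimnames = list(NULL, paste0("P", 1:8)))
  tt <- stats::rexp(n, 0.002 * exp(1.2 * x[, 1]))
  a <- lasso_frequency_select(x, tt, rep(1L, n), n_reps = 30, n_folds = 5,
                              freq_min = 3, seed = 42)
  b <- lasso_frequency_select(x, tt, rep(1L, n), n_reps = 30, n_folds = 5,
                              freq_min = 3, seed = 42)
  expect_identical(a$frequency, b$frequency)
  expect_identical(a$lambda_trace, b$lambda_trace)
  expect_true(all(a$frequency <= 30))
  expect_identical(a$selected, a$frequency > 3)
  # freq_min = n_reps: only ever-present pairs can survive
  expect_warning(
    cap <- lasso_frequency_select(x, tt, rep(1L, n), n_reps = 10,
                                  n_folds = 5, freq_min = 10, seed = 1),
    "every repetition")
  expect_true(all(cap$frequency[cap$selected] == 10))
  expect_error(lasso_frequency_select(x[, 1, drop = FALSE], tt, rep(1L, n)),
               "at least 2")
  expect_error(lasso_frequency_select(x, tt, rep(1L, n), n_folds = 500),
               "must not exceed")
})

test_that("a strongly prognostic pair is recovered among noise pairs", {
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 300
    x <- cbind(matrix(stats::rbinom(n * 20, 1, 0.5) + 0, n),
               stats::rbinom(n, 1, 0.5))
    colnames(x) <- c(sprintf("N%02d|M%02d", 1:20, 1:20), "TRUE|PAIR")
    tt <- stats::rexp(n, 0.002 * exp(1.5 * x[, "TRUE|PAIR"]))
    cc <- stats::rexp(n, 0.001)
    las <- lasso_frequency_select(x, pmin(tt, cc),
                                  as.integer(tt <= cc),
                                  n_reps = 100, freq_min = 10,
                                  seed = 400 + s)
    las$selected[["TRUE|PAIR"]]
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("stepwise elimination prunes redundancy and keeps real effects", {
  set.seed(12)
  n <- 400
  true_col <- stats::rbinom(n, 1, 0.5)
  x <- cbind(`A|B` = true_col, `C|D` = true_col)  # exact duplicate
  tt <- stats::rexp(n, 0.002 * exp(0.9 * true_col))
  expect_warning(m <- stepwise_cox(x, tt, rep(1L, n)), "collinear")
  expect_identical(names(m$coefficients), "A|B")  # canonical order kept
  expect_gt(m$coefficients[["A|B"]], 0)           # sign matches planted
  # single strong candidate is retained
  m1 <- stepwise_cox(x[, 1, drop = FALSE], tt, rep(1L, n))
  expect_identical(nrow(m1$pairs), 1L)
  expect_equal(unname(m1$coefficients), 0.9, tolerance = 0.35)
  expect_error(stepwise_cox(x[, 0], tt, rep(1L, n)), "at least 1")
})

test_that("removing a null covariate decreases AIC in expectation", {
  set.seed(13)
  n <- 100
  delta <- vapply(1:200, function(i) {
    x <- cbind(real = stats::rbinom(n, 1, 0.5), null = stats::rnorm(n))
    tt <- stats::rexp(n, 0.002 * exp(0.8 * x[, 1]))
    full <- fit_cox(x, tt, rep(1L, n))
    red <- fit_cox(x[, 1, drop = FALSE], tt, rep(1L, n))
    full$aic - red$aic
  }, numeric(1))
  expect_gt(mean(delta), 0)
})

test_that("signature serialization round-trips exactly", {
  fit <- shared_fit()
  path <- tempfile(fileext = ".json")
  write_signature(fit$model, path)
  back <- read_signature(path)
  expect_identical(back$coefficients, fit$model$coefficients)
  expect_identical(back$pairs, fit$model$pairs)
})
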