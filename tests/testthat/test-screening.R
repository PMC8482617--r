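make_expr <- function(values, group) {
  expression_set(values, group, rep("lncRNA", nrow(values)))
}

test_that("BH adjustment matches the step-up oracle and handles edge cases", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.04), 0.04)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:25) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("log2 fold changes and degenerate genes follow the contract", {
  set.seed(1)
  norm <- matrix(2^stats::rnorm(40, 5), 4, 10)
  vals <- cbind(norm * 4, norm)  # tumor exactly 4x normal
  vals <- rbind(vals, constant = 7)
  rownames(vals) <- c(paste0("G", 1:4), "CONST")
  colnames(vals) <- paste0("S", 1:20)
  grp <- rep(c("tumor", "normal"), each = 10)
  de <- differential_expression(vals, sample_group = grp, pseudocount = 0)
  expect_equal(de$log2fc[1:4], rep(2, 4), tolerance = 1e-12)
  # identical value in every sample: undefined t, p = 1, ns
  expect_identical(de$p_value[de$gene_id == "CONST"], 1)
  expect_identical(de$direction[de$gene_id == "CONST"], "ns")
  expect_true(all(de$fdr >= de$p_value))
  expect_identical(sum(table(de$direction)), nrow(de))
  expect_error(differential_expression(vals, sample_group = rep("tumor", 20)),
               "at least 2 samples")
})

test_that("zero prior weight reduces the moderated t to the pooled t", {
  set.seed(2)
  vals <- matrix(2^stats::rnorm(600, 6), 30, 20,
                 dimnames = list(paste0("G", 1:30), paste0("S", 1:20)))
  grp <- rep(c("tumor", "normal"), each = 10)
  de0 <- differential_expression(vals, sample_group = grp, prior_df = 0)
  lx <- log2(vals + 1)
  p_pooled <- apply(lx, 1, function(v)
    stats::t.test(v[grp == "tumor"], v[grp == "normal"],
                  var.equal = TRUE)$p.value)
  expect_equal(de0$p_value, unname(p_pooled), tolerance = 1e-10)
})

test_that("the moderated t agrees with the limma empirical-Bayes pipeline", {
  set.seed(3)
  vals <- matrix(2^stats::rnorm(2000, 6, 1.5), 100, 20,
                 dimnames = list(paste0("G", 1:100), paste0("S", 1:20)))
  grp <- rep(c("tumor", "normal"), each = 10)
  de <- differential_expression(vals, sample_group = grp)
  design <- cbind(1, tumor = as.numeric(grp == "tumor"))
  fit <- limma::eBayes(limma::lmFit(log2(vals + 1), design))
  expect_equal(de$log2fc, unname(fit$coefficients[, "tumor"]),
               tolerance = 1e-10)
  expect_equal(de$p_value, unname(fit$p.value[, "tumor"]), tolerance = 1e-8)
})

test_that("coexpression screen keeps lncRNAs with a qualifying partner", {
  set.seed(4)
  srg <- matrix(stats::rnorm(40), 2, 20,
                dimnames = list(c("SRG1", "SRG2"), paste0("S", 1:20)))
  lnc <- rbind(POS = srg[1, ],                      # identical: rho = 1
               NEG = max(srg[1, ]) - srg[1, ],      # reversed ranks: rho = -1
               NOISE = stats::rnorm(20))
  colnames(lnc) <- colnames(srg)
  res <- coexpression_screen(lnc, srg)
  expect_identical(res$rho[["POS", "SRG1"]], 1)
  expect_identical(res$rho[["NEG", "SRG1"]], -1)
  expect_true(res$kept[["POS"]])
  expect_true(res$kept[["NEG"]])  # absolute-value rule admits repression
  signed <- coexpression_screen(lnc, srg, signed = TRUE)
  expect_false(signed$kept[["NEG"]])
  expect_error(coexpression_screen(lnc[, 1:3], srg[, 1:3]),
               "at least 4 samples")
})

test_that("Spearman values match cor.test and the rank-formula oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  # rank formula: 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d^2 summing to 4
  expect_equal(rank_correlation(x, y)$rho, 1 - 6 * 4 / (5 * 24))
  set.seed(5)
  lnc <- matrix(stats::rnorm(60), 3, 20,
                dimnames = list(paste0("L", 1:3), paste0("S", 1:20)))
  srg <- matrix(stats::rnorm(40), 2, 20,
                dimnames = list(paste0("R", 1:2), paste0("S", 1:20)))
  res <- coexpression_screen(lnc, srg)
  for (i in 1:3) for (j in 1:2) {
    ct <- suppressWarnings(
      stats::cor.test(lnc[i, ], srg[j, ], method = "spearman",
                      exact = FALSE))
    expect_equal(res$rho[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p[i, j], ct$p.value, tolerance = 1e-10)
  }
})

test_that("the screen is invariant under strictly increasing transforms", {
  set.seed(6)
  lnc <- matrix(stats::rexp(100), 5, 20,
                dimnames = list(paste0("L", 1:5), paste0("S", 1:20)))
  srg <- matrix(stats::rexp(60), 3, 20,
                dimnames = list(paste0("R", 1:3), paste0("S", 1:20)))
  base <- coexpression_screen(lnc, srg)
  warped <- coexpression_screen(exp(2 * lnc + 1), srg^3)
  expect_identical(base$rho, warped$rho)
  expect_identical(base$kept, warped$kept)
})

test_that("candidate selection is the intersection of the two screens", {
  de <- data.frame(gene_id = c("A", "B", "C", "D"),
                   direction = c("up", "ns", "down", "up"))
  coex <- structure(list(kept = c(A = TRUE, B = TRUE, C = FALSE, D = TRUE)),
                    class = "coexpression_result")
  expect_identical(select_desrlnc(de, coex), c("A", "D"))
  coex$kept[] <- FALSE
  expect_warning(out <- select_desrlnc(de, coex), "no lncRNA")
  expect_identical(out, character(0))
})

test_that("planted DE + coexpressed lncRNAs are recovered at default thresholds", {
  recovered <- vapply(1:5, function(s) {
    sim <- simulate_cohort(sim_config(
      n_tumor = 400, n_normal = 40, n_lnc = 60, n_srg = 10,
      frac_de = 1 / 3, frac_coexpressed = 1 / 3, n_true_pairs = 0,
      true_betas = numeric(0), seed = 200 + s))
    lnc <- sim$expr$values[sim$expr$gene_class == "lncRNA", , drop = FALSE]
    de <- differential_expression(lnc, sample_group = sim$expr$sample_group)
    tum <- sim$clinical$sample_id
    coex <- coexpression_screen(lnc[, tum], sim$expr$values[sim$srg_ids, tum])
    cand <- select_desrlnc(de, coex)
    planted <- intersect(sim$truth$de_lnc_ids, sim$truth$coexpressed_lnc_ids)
    sum(planted %in% cand) / length(planted)
  }, numeric(1))
  expect_gte(stats::median(recovered), 18 / 20)
})
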