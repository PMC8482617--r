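#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the structure of a typical TCGA-style gastric cancer
#' cohort: 375 tumor and 32 normal RNA-seq profiles and a 42-gene
#' stemness-related gene (SRG) anchor set. Expression is generated on the
#' log2 scale from a Gaussian latent-factor model and exponentiated, so
#' values are positive and heavy-tailed like FPKM. A fraction of lncRNAs is
#' coexpressed with an SRG through a shared latent factor; a fraction is
#' differentially expressed tumor vs normal; survival follows an exponential
#' hazard acting through planted pair indicators.
#'
#' @param n_tumor,n_normal tumor and normal sample counts.
#' @param n_lnc,n_srg number of lncRNAs and stemness-related (mRNA) genes.
#' @param frac_coexpressed fraction of lncRNAs sharing a latent factor with
#'   an SRG.
#' @param frac_de fraction of lncRNAs differentially expressed in tumor.
#' @param de_log2fc mean tumor minus normal difference on the log2 scale for
#'   differentially expressed lncRNAs.
#' @param latent_corr target Spearman correlation between a coexpressed
#'   lncRNA and its partner SRG, in `[0, 1]`. Internally converted to the
#'   Pearson correlation `2 * sin(pi * latent_corr / 6)` of the bivariate
#'   Gaussian log-expression so that the expected Spearman rho equals
#'   `latent_corr`.
#' @param n_true_pairs number of disjoint planted lncRNA pairs whose rank
#'   indicator drives the hazard.
#' @param true_betas log hazard ratio per planted pair (length
#'   `n_true_pairs`).
#' @param baseline_hazard constant baseline hazard, events per day.
#' @param censor_rate exponential censoring rate per day; `0` disables
#'   censoring.
#' @param noise_sd standard deviation of log2 expression around the gene
#'   baseline.
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_tumor = 375L, n_normal = 32L,
                       n_lnc = 300L, n_srg = 42L,
                       frac_coexpressed = 0.4, frac_de = 0.3,
                       de_log2fc = 2, latent_corr = 0.7,
                       n_true_pairs = 3L,
                       true_betas = c(1, 0.9, 0.8),
                       baseline_hazard = 1 / 1500,
                       censor_rate = 1 / 3000,
                       noise_sd = 1, seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_lnc = as.integer(n_lnc), n_srg = as.integer(n_srg),
              frac_coexpressed = frac_coexpressed, frac_de = frac_de,
              de_log2fc = de_log2fc, latent_corr = latent_corr,
              n_true_pairs = as.integer(n_true_pairs),
              true_betas = as.numeric(true_betas),
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              noise_sd = noise_sd, seed = as.integer(seed))
  counts <- c("n_tumor", "n_normal", "n_lnc", "n_srg")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("`", f, "` must be a positive count")
  for (f in c("frac_coexpressed", "frac_de", "latent_corr"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("`", f, "` must lie in [0, 1]")
  if (cfg$n_true_pairs < 0L || 2L * cfg$n_true_pairs > cfg$n_lnc)
    stop("`n_true_pairs` must satisfy 0 <= n_true_pairs <= n_lnc / 2")
  if (length(cfg$true_betas) != cfg$n_true_pairs)
    stop("`true_betas` must have length `n_true_pairs`")
  if (cfg$baseline_hazard <= 0) stop("`baseline_hazard` must be > 0")
  if (cfg$censor_rate < 0) stop("`censor_rate` must be >= 0")
  if (cfg$noise_sd <= 0) stop("`noise_sd` must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a cohort with planted pair-indicator survival signal
#'
#' Generates expression for `n_lnc` lncRNAs and `n_srg` SRG mRNAs across
#' tumor and normal samples, a clinical table for the tumor samples, and a
#' ground-truth record. Planted pairs are disjoint couples of lncRNAs that
#' are both differentially expressed and SRG-coexpressed (so the screening
#' stages can recover them); the two members of a pair share the same
#' baseline mean and tumor shift, keeping the pair indicator balanced across
#' samples. Survival times for tumor samples are exponential with hazard
#' `baseline_hazard * exp(sum(beta_k * I[expr_Ak > expr_Bk]))`; censoring
#' times are exponential with rate `censor_rate`.
#'
#' Clinical covariates `age`, `grade` and `stage` are generated independent
#' of the hazard, i.e. as null covariates for independence analyses.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_cohort` with elements:
#'   \describe{
#'     \item{expr}{an [expression_set()] (lncRNAs then SRGs in rows).}
#'     \item{clinical}{data.frame with `sample_id`, `time` (days), `event`
#'       (0/1), `age`, `grade` (1-3), `stage` (1-4) for tumor samples only.}
#'     \item{srg_ids}{character vector of SRG gene IDs.}
#'     \item{truth}{list with `de_lnc_ids`, `coexpressed_lnc_ids`,
#'       `coex_partner`, `true_pairs` (data.frame `lnc_a`, `lnc_b`, `beta`
#'       in canonical order), and `true_risk` (named per-tumor-sample linear
#'       predictor).}
#'   }
#' @examples
#' sim <- simulate_cohort(sim_config(n_tumor = 40, n_normal = 10,
#'                                   n_lnc = 20, n_srg = 5, seed = 1))
#' sim$truth$true_pairs
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lnc))
  srg_ids <- sprintf("SRG%03d", seq_len(config$n_srg))
  tumor_ids <- sprintf("T%04d", seq_len(config$n_tumor))
  normal_ids <- sprintf("N%04d", seq_len(config$n_normal))
  sample_ids <- c(tumor_ids, normal_ids)
  n <- length(sample_ids)
  is_tumor <- c(rep(TRUE, config$n_tumor), rep(FALSE, config$n_normal))

  # planted pair members come first so they can be forced into both screens
  planted <- if (config$n_true_pairs > 0)
    sample(config$n_lnc, 2L * config$n_true_pairs) else integer(0)
  pick_extra <- function(target) {
    extra <- max(0L, target - length(planted))
    pool <- setdiff(seq_len(config$n_lnc), planted)
    union(planted, if (extra > 0) sample(pool, min(extra, length(pool)))
          else integer(0))
  }
  coex_idx <- pick_extra(round(config$frac_coexpressed * config$n_lnc))
  de_idx <- pick_extra(round(config$frac_de * config$n_lnc))

  # gene baselines on log2 scale; planted pair members share a baseline so
  # the pair indicator stays balanced (a valid pair by construction)
  mu_lnc <- stats::runif(config$n_lnc, 2, 6)
  if (config$n_true_pairs > 0) {
    pair_a <- planted[seq_len(config$n_true_pairs)]
    pair_b <- planted[config$n_true_pairs + seq_len(config$n_true_pairs)]
    mu_lnc[pair_b] <- mu_lnc[pair_a]
  }
  mu_srg <- stats::runif(config$n_srg, 4, 8)

  # coexpression partner: each coexpressed lncRNA loads on one SRG's latent
  # factor; the two members of a planted pair get distinct partners
  partner <- rep(NA_integer_, config$n_lnc)
  partner[coex_idx] <- sample(config$n_srg, length(coex_idx), replace = TRUE)
  if (config$n_true_pairs > 0 && config$n_srg > 1) {
    clash <- which(partner[pair_a] == partner[pair_b])
    for (k in clash)
      partner[pair_b[k]] <- (partner[pair_a[k]] %% config$n_srg) + 1L
  }

  r <- 2 * sin(pi * config$latent_corr / 6)  # Pearson for target Spearman
  fac <- matrix(stats::rnorm(config$n_srg * n), config$n_srg, n)

  z_srg <- sqrt(r) * fac +
    sqrt(1 - r) * matrix(stats::rnorm(config$n_srg * n), config$n_srg, n)
  z_lnc <- matrix(stats::rnorm(config$n_lnc * n), config$n_lnc, n)
  has_partner <- !is.na(partner)
  z_lnc[has_partner, ] <- sqrt(r) * fac[partner[has_partner], , drop = FALSE] +
    sqrt(1 - r) * z_lnc[has_partner, , drop = FALSE]

  delta <- numeric(config$n_lnc)
  delta[de_idx] <- config$de_log2fc
  log2_lnc <- mu_lnc + outer(delta, as.numeric(is_tumor)) +
    config$noise_sd * z_lnc
  log2_srg <- mu_srg + config$noise_sd * z_srg

  values <- 2^rbind(log2_lnc, log2_srg)
  dimnames(values) <- list(c(lnc_ids, srg_ids), sample_ids)
  expr <- expression_set(values,
                         ifelse(is_tumor, "tumor", "normal"),
                         c(rep("lncRNA", config$n_lnc),
                           rep("mRNA", config$n_srg)))

  # survival for tumor samples: hazard through planted pair indicators
  true_pairs <- data.frame(lnc_a = character(0), lnc_b = character(0),
                           beta = numeric(0), stringsAsFactors = FALSE)
  eta <- stats::setNames(numeric(config$n_tumor), tumor_ids)
  if (config$n_true_pairs > 0) {
    a_ids <- lnc_ids[pair_a]
    b_ids <- lnc_ids[pair_b]
    swap <- a_ids > b_ids  # canonical order: lnc_a precedes lnc_b
    tmp <- a_ids[swap]; a_ids[swap] <- b_ids[swap]; b_ids[swap] <- tmp
    true_pairs <- data.frame(lnc_a = a_ids, lnc_b = b_ids,
                             beta = config$true_betas,
                             stringsAsFactors = FALSE)
    for (k in seq_len(config$n_true_pairs)) {
      ind <- as.numeric(values[a_ids[k], tumor_ids] > values[b_ids[k], tumor_ids])
      eta <- eta + config$true_betas[k] * ind
    }
  }
  t_event <- stats::rexp(config$n_tumor,
                         rate = config$baseline_hazard * exp(eta))
  t_cens <- if (config$censor_rate > 0)
    stats::rexp(config$n_tumor, rate = config$censor_rate) else
    rep(Inf, config$n_tumor)
  clinical <- data.frame(
    sample_id = tumor_ids,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    age = round(stats::rnorm(config$n_tumor, 65, 10)),
    grade = sample(1:3, config$n_tumor, replace = TRUE),
    stage = sample(1:4, config$n_tumor, replace = TRUE),
    stringsAsFactors = FALSE)

  truth <- list(de_lnc_ids = sort(lnc_ids[de_idx]),
                coexpressed_lnc_ids = sort(lnc_ids[coex_idx]),
                coex_partner = stats::setNames(
                  ifelse(has_partner, srg_ids[partner], NA_character_),
                  lnc_ids),
                true_pairs = true_pairs,
                true_risk = eta)
  structure(list(expr = expr, clinical = clinical, srg_ids = srg_ids,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort (seed", x$config$seed, "):",
      x$config$n_tumor, "tumor /", x$config$n_normal, "normal samples;",
      x$config$n_lnc, "lncRNAs,", x$config$n_srg, "SRGs\n")
  cat("  planted pairs:", nrow(x$truth$true_pairs),
      " events:", sum(x$clinical$event), "/", nrow(x$clinical), "\n")
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `expression.tsv` (first column `gene_id`), `annotation.tsv`
#' (`sample_id`, `group`), `clinical.tsv`, `srg_ids.txt` and `truth.json`
#' into `dir`. Useful for interoperability and byte-level reproducibility
#' checks.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- data.frame(gene_id = rownames(sim$expr$values),
                   sim$expr$values, check.names = FALSE)
  utils::write.table(ex, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  anno <- data.frame(sample_id = colnames(sim$expr$values),
                     group = as.character(sim$expr$sample_group))
  utils::write.table(anno, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sim$srg_ids, file.path(dir, "srg_ids.txt"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
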