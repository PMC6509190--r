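# P-gp group comparison and random-forest regression analyses.

make_panel <- function(values, ids) {
  pgp_panel(data.frame(sample_id = ids, pgp = values,
                       stringsAsFactors = FALSE))
}

fake_md <- function(cls) {
  n <- length(cls)
  cohort_metadata(data.frame(
    sample_id = paste0("s", seq_len(n)), subject_id = paste0("u", seq_len(n)),
    month = 1, dementia_class = cls, age_category = 2, frailty = 3,
    malnutrition = 2, ppi = 0, statin = 0, antipsychotic = 0,
    polypharmacy = 0, cdr = 1, stringsAsFactors = FALSE))
}

test_that("group comparison holds its size and detects a shifted class", {
  cls <- rep(c("NO", "AD", "OTHER"), each = 9)
  md <- fake_md(cls)
  set.seed(26)
  rej_null <- mean(replicate(200, {
    compare_pgp_groups(make_panel(exp(rnorm(27)), md$sample_id),
                       md)$p_value < 0.05
  }))
  expect_gte(rej_null, 0.02)
  expect_lte(rej_null, 0.09)
  set.seed(27)
  power <- mean(replicate(200, {
    v <- exp(rnorm(27))
    v[cls == "AD"] <- exp(rnorm(9, -1))
    compare_pgp_groups(make_panel(v, md$sample_id), md)$p_value < 0.05
  }))
  expect_gt(power, 0.5)
})

test_that("constant expression values flag a degenerate comparison", {
  cls <- rep(c("NO", "AD", "OTHER"), each = 4)
  md <- fake_md(cls)
  res <- compare_pgp_groups(make_panel(rep(2, 12), md$sample_id), md)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_error(compare_pgp_groups(
    make_panel(1:5, fake_md(c("NO", "NO", "NO", "AD", "AD"))$sample_id),
    fake_md(c("NO", "NO", "NO", "AD", "AD"))), ">= 3 samples")
})

test_that("a deterministic driver taxon dominates the regression", {
  set.seed(28)
  n <- 250
  x <- matrix(runif(n * 8), n, 8, dimnames = list(paste0("s", 1:n),
                                                  paste0("t", 1:8)))
  y <- 3 * x[, "t3"]
  reg <- rf_regress_pgp(x, y, n_trees = 300, seeds = 1:5)
  expect_equal(names(which.max(reg$mean_importance)), "t3")
  expect_lt(mean(reg$mse), 0.1 * var(y))
  # determinism under identical seeds
  reg2 <- rf_regress_pgp(x, y, n_trees = 300, seeds = 1:5)
  expect_identical(reg$mse, reg2$mse)
  expect_identical(reg$importance, reg2$importance)
})

test_that("pure-noise responses yield importances consistent with zero", {
  # within one dataset spurious feature-response correlations give some
  # taxa persistently nonzero importance, so the null must be assessed
  # across fresh datasets: each replicate draws new features and response
  set.seed(29)
  n <- 200
  imps <- replicate(30, {
    x <- matrix(runif(n * 6), n, 6, dimnames = list(paste0("s", 1:n),
                                                    paste0("t", 1:6)))
    reg <- rf_regress_pgp(x, rnorm(n), n_trees = 150,
                          seeds = sample.int(1e6, 2))
    reg$mean_importance
  })
  m <- rowMeans(imps)
  se <- apply(imps, 1, sd) / sqrt(ncol(imps))
  expect_true(all(abs(m) <= 3 * se))
})

test_that("restricted = full gives identically zero MSE differences", {
  ch <- make_test_cohort(seed = 30, n_no = 10, n_ad = 10, n_species = 15,
                         n_genera = 5, drivers = c(sp001 = 0.3))
  cmp <- compare_restricted_vs_full(ch$abundance, ch$pgp,
                                    colnames(ch$abundance$values),
                                    n_trees = 100, seeds = 1:5)
  expect_identical(cmp$mse_restricted, cmp$mse_full)
  expect_equal(cmp$p_value, 1)
})

test_that("excluding the planted drivers degrades the restricted model", {
  drv <- c(sp001 = 1.0, sp002 = -1.0, sp003 = 0.8)
  ch <- make_test_cohort(seed = 31, n_no = 25, n_ad = 25, n_species = 30,
                         n_genera = 10, n_shifted = 0, drivers = drv, pgp_intercept = 25,
                         samples_per_subject_range = c(2, 2),
                         pgp_noise_sd = 0.1)
  restricted <- setdiff(colnames(ch$abundance$values), names(drv))[1:15]
  cmp <- compare_restricted_vs_full(ch$abundance, ch$pgp, restricted,
                                    n_trees = 200, seeds = 1:15)
  expect_gt(mean(cmp$mse_restricted), mean(cmp$mse_full))
  expect_lt(cmp$p_value, 0.05)
  expect_output(print(cmp), "Restricted vs full")
})

test_that("OOB MSE curve trends downward on planted-signal data", {
  drv <- c(sp001 = 1.0, sp002 = -1.0)
  ch <- make_test_cohort(seed = 32, n_no = 20, n_ad = 20, n_species = 20,
                         n_genera = 5, n_shifted = 0, drivers = drv, pgp_intercept = 25,
                         pgp_noise_sd = 0.1)
  reg <- rf_regress_pgp(ch$abundance$values, ch$pgp, n_trees = 500,
                        seeds = 1:5)
  avg <- rowMeans(reg$mse_curve)
  expect_true(all(diff(avg) <= 0.05 * avg[-length(avg)]))
  expect_lt(avg[length(avg)], avg[1])
})

test_that("sufficiency is not rejected when the restricted set holds the drivers", {
  drv <- c(sp001 = 0.3, sp002 = -0.3, sp003 = 0.25)
  ok <- sapply(1:5, function(r) {
    ch <- make_test_cohort(seed = 600 + r, n_no = 25, n_ad = 25,
                           n_species = 30, n_genera = 10, n_shifted = 6,
                           drivers = drv, pgp_noise_sd = 0.2,
                           pgp_intercept = 25,
                           samples_per_subject_range = c(1, 2))
    cmp <- compare_restricted_vs_full(ch$abundance, ch$pgp,
                                      sprintf("sp%03d", 1:15),
                                      n_trees = 150, seeds = 1:10)
    cmp$p_value >= 0.05
  })
  expect_gte(mean(ok), 0.8)
})

test_that("positive-importance taxa get the planted directions", {
  drv <- c(sp001 = 1.2, sp002 = -1.2)
  ch <- make_test_cohort(seed = 34, n_no = 25, n_ad = 25, n_species = 15,
                         n_genera = 5, n_shifted = 0, drivers = drv, pgp_intercept = 25,
                         samples_per_subject_range = c(2, 2),
                         pgp_noise_sd = 0.05)
  reg <- rf_regress_pgp(ch$abundance$values, ch$pgp, n_trees = 300,
                        seeds = 1:5)
  pit <- positive_importance_taxa(reg, ch$abundance$values, ch$pgp)
  expect_true(pit$selected[pit$taxon == "sp001"])
  expect_equal(pit$direction[pit$taxon == "sp001"], "induce")
  expect_true(pit$selected[pit$taxon == "sp002"])
  expect_equal(pit$direction[pit$taxon == "sp002"], "repress")
  expect_true(all(pit$selected == (pit$mean_importance > 0)))
})

test_that("the driver dwarfs noise taxa in every replicate at large n", {
  # strict importance > 0 is a noisy selector for pure-noise taxa (their
  # within-dataset importance is near zero with either sign), so the
  # robust null statement is relative: the planted driver's importance
  # exceeds every noise taxon's magnitude by orders of magnitude
  set.seed(35)
  ratios <- replicate(20, {
    n <- 500
    x <- matrix(runif(n * 4), n, 4,
                dimnames = list(paste0("s", 1:n),
                                c("drv", "n1", "n2", "n3")))
    y <- 2 * x[, "drv"] + rnorm(n, 0, 0.1)
    reg <- rf_regress_pgp(x, y, n_trees = 100, seeds = sample.int(1e6, 3))
    pit <- positive_importance_taxa(reg, x, y)
    expect_true(pit$selected[pit$taxon == "drv"])
    pit$mean_importance[pit$taxon == "drv"] /
      max(abs(pit$mean_importance[pit$taxon != "drv"]))
  })
  expect_gte(mean(ratios > 20), 0.9)
})

test_that("mrp2 is summarized descriptively when present", {
  cls <- rep(c("NO", "AD", "OTHER"), each = 4)
  md <- fake_md(cls)
  pg <- pgp_panel(data.frame(sample_id = md$sample_id,
                             pgp = exp(rnorm(12)), mrp2 = exp(rnorm(12))))
  sm <- summarize_mrp2(pg, md)
  expect_equal(nrow(sm), 3)
  expect_null(summarize_mrp2(make_panel(1:12 / 12, md$sample_id), md))
})
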