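# Butyrate gene statistics: pathway grouping, mixed-model contrasts,
# Spearman correlation with P-gp.

gene_fixture <- function(n_sub_per_class = 10, k = 2, n_genes = 8,
                         ad_fold = 1, sigma_subj = 0.3, sigma = 0.2,
                         seed = 1, enriched = "but01") {
  set.seed(seed)
  ns <- 2 * n_sub_per_class
  cls <- rep(c("NO", "AD"), each = n_sub_per_class)
  subj <- sprintf("U%02d", seq_len(ns))
  md <- cohort_metadata(data.frame(
    sample_id = paste0(rep(subj, each = k), "_m", rep(seq_len(k), ns)),
    subject_id = rep(subj, each = k), month = rep(seq_len(k), ns),
    dementia_class = rep(cls, each = k), age_category = 2, frailty = 3,
    malnutrition = 2, ppi = 0, statin = 0, antipsychotic = 0,
    polypharmacy = 0, cdr = 1, stringsAsFactors = FALSE))
  genes <- sprintf("but%02d", seq_len(n_genes))
  b <- rnorm(ns, 0, sigma_subj)
  logv <- sapply(genes, function(g) {
    base <- rnorm(1, 2, 0.2) + b[match(md$subject_id, subj)] +
      rnorm(nrow(md), 0, sigma)
    if (g %in% enriched)
      base <- base + log(ad_fold) * (md$dementia_class == "AD")
    base
  })
  v <- exp(logv)
  dimnames(v) <- list(md$sample_id, genes)
  list(md = md,
       genes = butyrate_gene_table(
         v, setNames(rep_len(paste0("p", 1:4), n_genes), genes),
         n_pathways = NULL))
}

test_that("pathway grouping is additive and the identity when 1:1", {
  m <- rbind(s1 = c(g1 = 3, g2 = 5, g3 = 2), s2 = c(g1 = 1, g2 = 1, g3 = 7))
  tb <- butyrate_gene_table(m, c(g1 = "pA", g2 = "pA", g3 = "pB"),
                            n_pathways = 2)
  pw <- group_pathways(tb)
  expect_equal(pw[, "pA"], c(s1 = 8, s2 = 2))
  expect_equal(pw[, "pB"], c(s1 = 2, s2 = 7))
  tb1 <- butyrate_gene_table(m, c(g1 = "x", g2 = "y", g3 = "z"),
                             n_pathways = 3)
  expect_equal(unname(group_pathways(tb1)[, c("x", "y", "z")]), unname(m))
})

test_that("pathway sums match a brute-force oracle on generated data", {
  ch <- make_test_cohort(seed = 36, n_no = 6, n_ad = 6)
  pw <- group_pathways(ch$butyrate_genes)
  pm <- ch$butyrate_genes$pathway_map
  for (p in unique(pm)) {
    ref <- rowSums(ch$butyrate_genes$values[, names(pm)[pm == p],
                                            drop = FALSE])
    expect_equal(pw[, p], ref)
  }
})

test_that("ML log-likelihood equals the closed-form marginal normal", {
  fx <- gene_fixture(n_sub_per_class = 1, k = 2, n_genes = 1, seed = 37)
  md <- fx$md
  x <- fx$genes$values[, 1]
  pc <- min(x[x > 0]) / 2
  d <- data.frame(y = log(x + pc),
                  cls = factor(md$dementia_class, levels = c("NO", "AD")),
                  subj = md$subject_id)
  fit <- lme4::lmer(y ~ cls + (1 | subj), data = d, REML = FALSE)
  su2 <- unname(lme4::VarCorr(fit)$subj[1])
  s2 <- sigma(fit)^2
  Xf <- model.matrix(~cls, d)
  mu <- drop(Xf %*% lme4::fixef(fit))
  J <- outer(d$subj, d$subj, "==") * 1
  Sig <- su2 * J + s2 * diag(nrow(d))
  r <- d$y - mu
  ll_closed <- -0.5 * (nrow(d) * log(2 * pi) +
                         determinant(Sig)$modulus[1] +
                         drop(r %*% solve(Sig, r)))
  expect_lt(abs(as.numeric(logLik(fit)) - ll_closed), 1e-8)
})

test_that("a planted AD enrichment is recovered with controlled type I error", {
  hits <- logical(20)
  null_p <- c()
  for (r in 1:20) {
    fx <- gene_fixture(n_sub_per_class = 40, k = 2, n_genes = 6,
                       ad_fold = 2, sigma = 0.3, seed = 500 + r)
    res <- lmm_gene_contrast(fx$genes, fx$md)
    hit <- res[res$gene == "but01", ]
    hits[r] <- hit$p_value < 0.05 && hit$estimate > 0
    null_p <- c(null_p, res$p_value[res$gene != "but01"])
  }
  expect_gte(mean(hits), 0.9)
  fr <- mean(null_p < 0.05)
  expect_gte(fr, 0.01)
  expect_lte(fr, 0.10)
})

test_that("zero-variance genes are flagged degenerate", {
  fx <- gene_fixture(n_sub_per_class = 4, seed = 38)
  v <- fx$genes$values
  v[, "but02"] <- 1
  tb <- butyrate_gene_table(v, fx$genes$pathway_map)
  res <- lmm_gene_contrast(tb, fx$md)
  expect_true(res$degenerate[res$gene == "but02"])
  expect_false(any(res$degenerate[res$gene != "but02"]))
})

test_that("effect estimates are invariant to multiplicative rescaling", {
  fx <- gene_fixture(n_sub_per_class = 10, ad_fold = 1.5, seed = 39)
  res1 <- lmm_gene_contrast(fx$genes, fx$md)
  v <- fx$genes$values * 1000
  res2 <- lmm_gene_contrast(butyrate_gene_table(v, fx$genes$pathway_map),
                            fx$md)
  expect_lt(max(abs(res1$estimate - res2$estimate), na.rm = TRUE), 1e-6)
})

test_that("a zero subject variance is estimated near zero", {
  est <- replicate(20, {
    fx <- gene_fixture(n_sub_per_class = 15, sigma_subj = 0, n_genes = 1,
                       seed = sample.int(1e6, 1))
    lmm_gene_contrast(fx$genes, fx$md)$sigma_u
  })
  expect_gte(mean(est <= 0.05), 0.9)
})

test_that("Spearman correlation honors rank arithmetic and invariances", {
  ids <- paste0("s", 1:5)
  pg <- pgp_panel(data.frame(sample_id = ids, pgp = c(2, 4, 1, 5, 3)))
  mk <- function(v) butyrate_gene_table(
    matrix(v, 5, 1, dimnames = list(ids, "g1")), c(g1 = "p1"),
    n_pathways = 1)
  # monotone transform of P-gp -> rho = 1
  r <- correlate_genes_pgp(mk(exp(pg$pgp)), pg)
  expect_equal(r$rho, 1)
  # reversed ranks -> rho = -1
  r <- correlate_genes_pgp(mk(6 - pg$pgp), pg)
  expect_equal(r$rho, -1)
  # toy vectors against the rank-covariance oracle
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  pg2 <- pgp_panel(data.frame(sample_id = ids, pgp = y))
  rho_oracle <- cov(rank(x), rank(y)) / (sd(rank(x)) * sd(rank(y)))
  r <- correlate_genes_pgp(mk(x), pg2)
  expect_equal(r$rho, rho_oracle)
  # strictly increasing transform of the gene leaves rho unchanged
  r2 <- correlate_genes_pgp(mk(log(x + 1)), pg2)
  expect_equal(r2$rho, r$rho)
  # constant gene flagged
  r3 <- correlate_genes_pgp(mk(rep(1, 5)), pg2)
  expect_true(r3$degenerate)
  expect_true(is.na(r3$rho))
  expect_error(correlate_genes_pgp(mk(x), pgp_panel(
    data.frame(sample_id = c("a", "b", "c"), pgp = 1:3))), "4 overlapping")
})
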