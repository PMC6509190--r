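# Jaccard distances, PERMANOVA, and the t-SNE wrapper.

test_that("jaccard distance reproduces set arithmetic", {
  m <- rbind(s1 = c(A = .2, B = .3, C = .5, D = 0),
             s2 = c(A = 0, B = .4, C = .3, D = .3),
             s3 = c(A = .2, B = .3, C = .5, D = 0))
  d <- jaccard_matrix(abundance_table(m))
  expect_equal(d$values["s1", "s3"], 0)            # identical presence sets
  expect_equal(d$values["s1", "s2"], 1 - 2 / 4)    # {A,B,C} vs {B,C,D}
  disj <- rbind(s1 = c(1, 0), s2 = c(0, 1))
  colnames(disj) <- c("A", "B")
  expect_equal(jaccard_matrix(disj)$values["s1", "s2"], 1)
  expect_true(isSymmetric(d$values))
  expect_equal(unname(diag(d$values)), rep(0, 3))
})

test_that("jaccard is permutation-equivariant and warns on empty samples", {
  set.seed(1)
  m <- matrix(rbinom(60, 1, 0.4) * runif(60), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  ord <- c(3, 1, 6, 2, 5, 4)
  d1 <- jaccard_matrix(m)$values
  d2 <- jaccard_matrix(m[ord, ])$values
  expect_equal(d2, d1[ord, ord])
  m0 <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0))
  colnames(m0) <- c("x", "y")
  expect_warning(d0 <- jaccard_matrix(m0), "no present taxa")
  expect_equal(d0$values["a", "b"], 0)
})

test_that("Monte-Carlo PERMANOVA p agrees with exhaustive enumeration", {
  set.seed(11)
  m <- matrix(rbinom(6 * 12, 1, 0.5) * runif(72), 6, 12,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:12)))
  labels <- rep(c("a", "b"), each = 3)
  d <- jaccard_matrix(m)
  p_exact <- oracle_permanova_exact(d$values, labels)
  res <- permanova(d, labels, n_permutations = 1000, seed = 5)
  expect_lt(abs(res$p_value - p_exact), 0.05)
  expect_gte(res$pseudo_f, 0)
})

test_that("pseudo-F matches vegan::adonis2 on a random instance", {
  set.seed(8)
  m <- matrix(rbinom(10 * 20, 1, 0.5) * runif(200), 10, 20,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:20)))
  labels <- rep(c("x", "y"), each = 5)
  d <- jaccard_matrix(m)
  ours <- permanova(d, labels, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d$values) ~ g,
                        data = data.frame(g = labels), permutations = 99)
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("p-value is invariant to group renaming and sample reordering", {
  set.seed(3)
  m <- matrix(rbinom(8 * 15, 1, 0.5) * runif(120), 8, 15,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:15)))
  labels <- rep(c("g1", "g2"), 4)
  d <- jaccard_matrix(m)
  a <- permanova(d, labels, 499, seed = 7)
  b <- permanova(d, c(g1 = "blue", g2 = "red")[labels], 499, seed = 7)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$pseudo_f, b$pseudo_f)
})

test_that("degenerate all-zero distances return p = 1 with a warning", {
  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(res <- permanova(d0, rep(c("a", "b"), 2), 99), "degenerate")
  expect_equal(res$p_value, 1)
  expect_equal(res$pseudo_f, 0)
  expect_true(res$degenerate)
})

test_that("permanova rejects undersized groups and bad input", {
  d <- matrix(0.5, 5, 5); diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  expect_error(permanova(d, c("a", "a", "a", "a", "b"), 99), "at least 2")
  expect_error(permanova(d, rep("a", 5), 99), "2 groups")
  dn <- d; dn[1, 2] <- NA
  expect_error(permanova(dn, c("a", "a", "b", "b", "b"), 99), "non-finite")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(42)
  ps <- replicate(200, {
    m <- matrix(rbinom(12 * 15, 1, 0.5) * runif(180), 12, 15)
    dimnames(m) <- list(paste0("s", 1:12), paste0("t", 1:15))
    permanova(jaccard_matrix(m), rep(c("a", "b"), each = 6),
              n_permutations = 99, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("subject-block permutation keeps within-subject samples together", {
  ch <- make_test_cohort(seed = 6, n_no = 12, n_ad = 12, delta = 1.5,
                         n_shifted = 8, n_species = 30, n_genera = 10,
                         samples_per_subject_range = c(2, 3))
  d <- jaccard_matrix(ch$abundance)
  res <- permanova(d, ch$metadata$dementia_class, 199, seed = 2,
                   strata = ch$metadata$subject_id)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("t-SNE is deterministic, separates planted clusters, guards input", {
  set.seed(2)
  base <- rbind(matrix(rnorm(5 * 8, 0), 5, 8), matrix(rnorm(5 * 8, 6), 5, 8))
  d <- as.matrix(dist(base)) / max(dist(base))
  dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  y1 <- embed_tsne(d, seed = 4, perplexity = 3, n_iter = 200)
  y2 <- embed_tsne(d, seed = 4, perplexity = 3, n_iter = 200)
  expect_identical(y1, y2)
  expect_true(all(is.finite(y1)))
  grp <- rep(1:2, each = 5)
  dd <- as.matrix(dist(y1))
  intra <- mean(dd[grp == 1, grp == 1]) + mean(dd[grp == 2, grp == 2])
  inter <- mean(dd[grp == 1, grp == 2])
  expect_gt(inter, intra / 2)
  expect_error(embed_tsne(d[1:3, 1:3]), "at least 4")
  expect_error(embed_tsne(d[1:5, 1:5], perplexity = 10), "perplexity")
})
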