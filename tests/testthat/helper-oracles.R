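# Independent oracles and small fixture builders used across the suite.

# Brute-force marginal log-likelihood of the zero-inflated beta mixed model
# by trapezoid integration over the random intercept, subject by subject.
# Deliberately naive: shares no code with the quadrature path it checks.
oracle_zib_loglik <- function(beta, gamma, phi, sigma_u, y, X, Z, subj,
                              n_nodes = 1e5, span = 10) {
  pi0 <- plogis(drop(Z %*% gamma))
  tot <- sum(log(pi0[y == 0]))
  b <- seq(-span * sigma_u, span * sigma_u, length.out = n_nodes)
  db <- b[2] - b[1]
  eta0 <- drop(X %*% beta)
  for (s in unique(subj)) {
    i <- which(subj == s & y > 0)
    if (!length(i)) next
    lg <- dnorm(b, 0, sigma_u, log = TRUE)
    for (j in i) {
      mu <- plogis(eta0[j] + b)
      lg <- lg + log(1 - pi0[j]) +
        dbeta(y[j], mu * phi, (1 - mu) * phi, log = TRUE)
    }
    m <- max(lg)
    tot <- tot + m + log(sum(exp(lg - m)) * db)
  }
  tot
}

# Random small ZIB instance (data + parameters) for likelihood checks.
random_zib_instance <- function(seed) {
  set.seed(seed)
  ns <- sample(3:5, 1)
  k <- sample(2:3, 1)
  n <- ns * k
  subj <- rep(seq_len(ns), each = k)
  X <- cbind(1, rnorm(n))
  Z <- matrix(1, n, 1)
  beta <- c(runif(1, -2.5, -1), runif(1, -0.5, 0.5))
  gamma <- runif(1, -1.5, 0.5)
  phi <- runif(1, 5, 25)
  sigma_u <- runif(1, 0.3, 1.2)
  mu <- plogis(drop(X %*% beta) + rnorm(ns, 0, sigma_u)[subj])
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  y[runif(n) < plogis(gamma)] <- 0
  list(beta = beta, gamma = gamma, phi = phi, sigma_u = sigma_u,
       y = y, X = X, Z = Z, subj = subj)
}

# Monte-Carlo oracle for the softmax-adjusted planted log-abundance
# contrast: simulates the generator's logistic-normal model directly
# (flat baseline) and returns mean log relative abundance of taxon 1
# in the shifted class minus the unshifted class.
oracle_softmax_contrast <- function(delta, n_species, subject_sd, species_sd,
                                    n_draws = 1e6, chunk = 1e5) {
  mean_log <- function(shift) {
    tot <- 0; done <- 0
    while (done < n_draws) {
      m <- min(chunk, n_draws - done)
      L <- matrix(rnorm(m * n_species, 0,
                        sqrt(subject_sd^2 + species_sd^2)), m, n_species)
      L[, 1] <- L[, 1] + shift
      P <- exp(L - apply(L, 1, max))
      tot <- tot + sum(log(P[, 1] / rowSums(P)))
      done <- done + m
    }
    tot / n_draws
  }
  mean_log(delta) - mean_log(0)
}

# Exact PERMANOVA p-value on a 2-groups-of-3 toy by enumerating all 20
# label assignments (pseudo-F recomputed from first principles).
oracle_permanova_exact <- function(d, labels) {
  n <- nrow(d)
  D2 <- d^2
  f_of <- function(lab) {
    sst <- sum(D2[upper.tri(D2)]) / n
    ssw <- 0
    for (lv in unique(lab)) {
      i <- lab == lv
      ssw <- ssw + sum(D2[i, i][upper.tri(D2[i, i])]) / sum(i)
    }
    ((sst - ssw) / (length(unique(lab)) - 1)) / (ssw / (n - length(unique(lab))))
  }
  f_obs <- f_of(labels)
  g1 <- which(labels == unique(labels)[1])
  combos <- utils::combn(n, length(g1))
  f_all <- apply(combos, 2, function(i) {
    lab <- rep("b", n); lab[i] <- "a"; f_of(lab)
  })
  mean(f_all >= f_obs - 1e-12)
}

# Small planted-effect cohort shared by several tests.
make_test_cohort <- function(seed = 1, n_no = 20, n_ad = 20, n_other = 0,
                             n_species = 40, n_genera = 12,
                             delta = 1.0, n_shifted = 6,
                             read_depth = 1e4, drivers = NULL, ...) {
  em <- if (n_shifted > 0)
    data.frame(taxon = sprintf("sp%03d", seq_len(n_shifted)),
               class = "AD",
               delta = rep_len(c(delta, -delta), n_shifted))
  else NULL
  generate_cohort(sim_config(
    n_subjects_per_class = c(NO = n_no, AD = n_ad, OTHER = n_other),
    n_species = n_species, n_genera = n_genera,
    species_effect_map = em, read_depth = read_depth,
    pgp_driver_weights = if (is.null(drivers)) numeric(0) else drivers,
    seed = seed, ...))
}
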