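# Beta diversity: Jaccard distances, permutation-based PERMANOVA, and a
# t-SNE embedding for visualization only.

#' Jaccard distance matrix on presence/absence
#'
#' Species-level community dissimilarity: \code{d(i,j) = 1 - |P_i & P_j| /
#' |P_i | P_j|} where \code{P_i} is the set of taxa with abundance strictly
#' above \code{presence_threshold} in sample i. Two samples with empty
#' presence sets get distance 0 by convention (with a warning).
#'
#' @param table an \code{\link{abundance_table}} (or plain matrix).
#' @param presence_threshold abundance above which a taxon counts as present
#'   (default 0: any nonzero abundance).
#' @return list of class \code{"distance_matrix"}: \code{sample_ids},
#'   \code{values} (symmetric, zero diagonal, entries in [0,1]).
#' @export
jaccard_matrix <- function(table, presence_threshold = 0) {
  stopifnot(presence_threshold >= 0)
  m <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  B <- (m > presence_threshold) * 1
  inter <- tcrossprod(B)
  sz <- rowSums(B)
  uni <- outer(sz, sz, "+") - inter
  d <- 1 - inter / uni
  if (any(uni == 0)) {
    warning("sample pair(s) with no present taxa: distance set to 0")
    d[uni == 0] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(list(sample_ids = rownames(m), values = d),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("Distance matrix over", length(x$sample_ids), "samples; mean off-diag",
      format(mean(x$values[upper.tri(x$values)]), digits = 4), "\n")
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix. The pseudo-F statistic uses
#' the classic sums-of-squares decomposition on squared distances:
#' \code{SS_total = sum_{i<j} d_ij^2 / N}, \code{SS_within = sum_g
#' sum_{i<j in g} d_ij^2 / n_g}, \code{F = (SS_between/(g-1)) /
#' (SS_within/(N-g))}. The null distribution comes from permuting group
#' labels; the p-value uses the add-one rule
#' \code{p = (1 + #(F_perm >= F_obs)) / (1 + n_permutations)}.
#'
#' With repeated measures, free permutation of sample labels is the default;
#' \code{strata} (a per-sample subject id) switches to the stricter scheme
#' that permutes class labels at the subject level, keeping each subject's
#' samples together.
#'
#' A degenerate all-zero distance matrix returns F = 0 and p = 1 with a
#' warning rather than erroring, so batch simulation runs survive.
#'
#' @param dist a \code{\link{jaccard_matrix}} result or symmetric matrix.
#' @param labels per-sample group labels (length n).
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param strata optional per-sample subject ids for subject-block
#'   permutation.
#' @return list of class \code{"permanova_result"}: \code{pseudo_f},
#'   \code{p_value}, \code{n_permutations}, \code{group_sizes}, \code{ss},
#'   \code{degenerate}.
#' @export
permanova <- function(dist, labels, n_permutations = 999, seed = 1,
                      strata = NULL) {
  d <- if (inherits(dist, "distance_matrix")) dist$values else as.matrix(dist)
  n <- nrow(d)
  stopifnot(length(labels) == n, n_permutations >= 1)
  if (any(!is.finite(d))) stop("non-finite distances")
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples; got ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  D2 <- d^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  g <- length(sizes)

  ss_within_for <- function(lab) {
    sw <- 0
    for (lv in unique(lab)) {
      i <- lab == lv
      sw <- sw + sum(D2[i, i][upper.tri(D2[i, i])]) / sum(i)
    }
    sw
  }
  fstat <- function(lab) {
    sw <- ss_within_for(lab)
    ((ss_total - sw) / (g - 1)) / (sw / (n - g))
  }

  if (ss_total < 1e-15) {
    warning("all distances zero: degenerate PERMANOVA, returning p = 1")
    return(structure(list(pseudo_f = 0, p_value = 1,
                          n_permutations = n_permutations,
                          group_sizes = c(sizes), ss = c(total = 0,
                          within = 0, between = 0), degenerate = TRUE),
                     class = "permanova_result"))
  }

  f_obs <- fstat(labels)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(strata)) {
    f_perm <- replicate(n_permutations, fstat(sample(labels)))
  } else {
    strata <- as.character(strata)
    us <- unique(strata)
    slab <- labels[match(us, strata)]   # class is constant within subject
    f_perm <- replicate(n_permutations, {
      perm <- sample(slab)
      fstat(perm[match(strata, us)])
    })
  }
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  sw <- ss_within_for(labels)
  structure(list(pseudo_f = f_obs, p_value = p,
                 n_permutations = n_permutations, group_sizes = c(sizes),
                 ss = c(total = ss_total, within = sw,
                        between = ss_total - sw),
                 degenerate = FALSE),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", format(x$pseudo_f, digits = 5),
      ", p =", format(x$p_value, digits = 4),
      "(", x$n_permutations, "permutations )\n")
  if (x$degenerate) cat("  [degenerate: all distances zero]\n")
  invisible(x)
}

#' t-SNE embedding of a distance matrix
#'
#' Exact (non-Barnes-Hut) t-distributed stochastic neighbor embedding into
#' two dimensions, suitable for the few hundred samples of a cohort.
#' Input affinities come from a per-sample Gaussian kernel calibrated to
#' \code{perplexity} by bisection; the embedding minimizes KL divergence to
#' the Student-t affinities by momentum gradient descent with early
#' exaggeration. Deterministic for a fixed seed. Visualization only: no
#' inferential claims attach to the coordinates.
#'
#' @param dist a \code{distance_matrix} or symmetric matrix.
#' @param seed integer seed (random normal initialization).
#' @param perplexity target perplexity; default 30, capped at (n-1)/3.
#' @param n_iter gradient-descent iterations (default 500).
#' @return matrix n x 2 of embedding coordinates (rownames = sample ids).
#' @export
embed_tsne <- function(dist, seed = 1, perplexity = 30, n_iter = 500) {
  d <- if (inherits(dist, "distance_matrix")) dist$values else as.matrix(dist)
  n <- nrow(d)
  if (n < 4) stop("t-SNE needs at least 4 samples")
  if (!missing(perplexity) && perplexity >= n - 1)
    stop("perplexity must be < n - 1; use a smaller value")
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- d^2
  # conditional affinities with per-point bandwidth calibrated by bisection
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in 1:n) {
    di <- D2[i, -i]
    lo <- -20; hi <- 20
    for (it in 1:60) {
      beta <- exp((lo + hi) / 2)
      w <- exp(-di * beta); s <- sum(w)
      if (s < 1e-300) { hi <- log(beta); next }
      p <- w / s
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (H > logU) lo <- log(beta) else hi <- log(beta)
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - 200 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 250) momentum <- 0.8
  }
  rownames(Y) <- rownames(d); colnames(Y) <- c("tsne1", "tsne2")
  Y
}
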