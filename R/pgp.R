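# P-glycoprotein analyses: group comparison of measured expression,
# random-forest regression from taxa, and the restricted-vs-full model
# comparison testing whether disease-discriminating taxa suffice to
# predict the epithelial readout.

#' Compare P-gp expression across dementia classes
#'
#' Kruskal-Wallis test across the (>= 2) classes plus pairwise two-sided
#' Mann-Whitney tests with Benjamini-Hochberg correction; reports group
#' medians. Constant expression values yield a degenerate flag and p = 1.
#'
#' @param pgp a \code{\link{pgp_panel}}.
#' @param metadata a \code{\link{cohort_metadata}}.
#' @return list of class \code{"pgp_group_test"}: \code{kruskal_stat},
#'   \code{p_value}, \code{pairwise} (BH-adjusted), \code{medians},
#'   \code{degenerate}.
#' @export
compare_pgp_groups <- function(pgp, metadata) {
  stopifnot(inherits(pgp, "pgp_panel"))
  cls <- metadata$dementia_class[match(pgp$sample_id, metadata$sample_id)]
  if (anyNA(cls)) stop("P-gp sample ids missing from metadata")
  sizes <- table(cls)
  if (length(sizes) < 2 || any(sizes < 3))
    stop("need >= 2 groups with >= 3 samples each")
  x <- pgp$pgp
  med <- tapply(x, cls, stats::median)
  if (stats::var(x) == 0) {
    return(structure(list(kruskal_stat = 0, p_value = 1, pairwise = NULL,
                          medians = med, degenerate = TRUE),
                     class = "pgp_group_test"))
  }
  kw <- stats::kruskal.test(x, factor(cls))
  pw <- stats::pairwise.wilcox.test(x, factor(cls), p.adjust.method = "BH",
                                    exact = FALSE)
  structure(list(kruskal_stat = unname(kw$statistic),
                 p_value = kw$p.value, pairwise = pw$p.value,
                 medians = med, degenerate = FALSE),
            class = "pgp_group_test")
}

#' @export
print.pgp_group_test <- function(x, ...) {
  cat("Kruskal-Wallis on P-gp by class: chi^2 =",
      format(x$kruskal_stat, digits = 5), ", p =",
      format(x$p_value, digits = 4), "\n")
  cat("medians:\n"); print(round(x$medians, 4))
  if (!is.null(x$pairwise)) {
    cat("pairwise Mann-Whitney (BH):\n"); print(round(x$pairwise, 4))
  }
  invisible(x)
}

#' Random-forest regression of P-gp on taxa
#'
#' For each seed, fits a regression forest predicting per-sample P-gp from
#' the feature matrix and records the out-of-bag mean squared error, the
#' unscaled permutation importance (increase in MSE), and the OOB MSE as a
#' function of tree count on a log-spaced grid.
#'
#' @param features numeric matrix samples x features (e.g. species relative
#'   abundances).
#' @param pgp numeric response aligned to rows, or a \code{pgp_panel} whose
#'   sample ids match the rownames.
#' @param n_trees trees per forest (default 3000).
#' @param seeds integer vector of seeds, one forest per seed (field default
#'   500 seeds).
#' @param importance compute permutation importance (default TRUE; skipping
#'   it roughly halves the cost when only MSE is needed).
#' @return list of class \code{"pgp_regression"}: \code{mse} (per seed),
#'   \code{importance} (features x seeds), \code{mean_importance},
#'   \code{mse_curve} (tree grid x seeds), \code{tree_grid}.
#' @export
rf_regress_pgp <- function(features, pgp, n_trees = 3000, seeds = 1:500,
                           importance = TRUE) {
  if (inherits(pgp, "pgp_panel")) {
    y <- pgp$pgp[match(rownames(features), pgp$sample_id)]
    if (anyNA(y)) stop("P-gp panel missing values for some samples")
  } else y <- pgp
  n <- nrow(features)
  if (n < 2) stop("need at least 2 samples")
  if (n < 10) warning("fewer than 10 samples: regression will be unstable")
  grid <- unique(round(exp(seq(log(10), log(n_trees), length.out = 12))))
  grid <- grid[grid <= n_trees]
  mse <- numeric(length(seeds))
  imp <- matrix(NA_real_, ncol(features), length(seeds),
                dimnames = list(colnames(features), NULL))
  curve <- matrix(NA_real_, length(grid), length(seeds))
  for (i in seq_along(seeds)) {
    set.seed(seeds[i])
    rf <- randomForest::randomForest(features, y, ntree = n_trees,
                                     importance = importance)
    mse[i] <- rf$mse[n_trees]
    if (importance)
      imp[, i] <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    curve[, i] <- rf$mse[grid]
  }
  structure(list(mse = mse, importance = imp,
                 mean_importance = rowMeans(imp),
                 mse_curve = curve, tree_grid = grid, seeds = seeds,
                 n_trees = n_trees),
            class = "pgp_regression")
}

#' Restricted-vs-full feature-set comparison for P-gp prediction
#'
#' Fits \code{\link{rf_regress_pgp}} twice — once on a restricted feature
#' set (typically the consensus disease-discriminating taxa) and once on
#' all taxa — with the same seeds, and applies a one-sample t test to the
#' per-seed paired MSE differences (restricted minus full) against zero.
#'
#' The scientific claim under test is sufficiency: the restricted taxa are
#' sufficient when the restricted model predicts no worse than the full
#' one. The default test is therefore one-sided against the alternative
#' that the restricted model's MSE is larger; failing to reject supports
#' sufficiency. (A two-sided test would also reject when the restricted
#' model is \emph{better} — which routinely happens, because the features
#' dropped from the restricted set are exactly the uninformative ones whose
#' presence dilutes the full forest — and that rejection direction says
#' nothing against sufficiency.) \code{alternative = "two.sided"} restores
#' the symmetric test.
#'
#' @param table an \code{\link{abundance_table}}.
#' @param pgp a \code{\link{pgp_panel}} (or aligned numeric response).
#' @param restricted_features character vector of taxa (subset of the
#'   table's taxa).
#' @param n_trees trees per forest (field default 3000).
#' @param seeds seeds shared by both models (field default 500).
#' @param alternative direction of the t test on (restricted - full);
#'   default \code{"greater"} (restricted worse).
#' @return list of class \code{"pgp_comparison"}: \code{mse_restricted},
#'   \code{mse_full} (per seed), \code{t_statistic}, \code{p_value},
#'   \code{mean_diff}, \code{curves} (mean MSE vs tree grid for both),
#'   \code{restricted} and \code{full} regression objects.
#' @export
compare_restricted_vs_full <- function(table, pgp, restricted_features,
                                       n_trees = 3000, seeds = 1:500,
                                       alternative = c("greater",
                                                       "two.sided",
                                                       "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(table, "abundance_table"))
  if (!length(restricted_features)) stop("restricted feature set is empty")
  miss <- setdiff(restricted_features, colnames(table$values))
  if (length(miss)) stop("restricted features absent from the table: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  full <- rf_regress_pgp(table$values, pgp, n_trees, seeds,
                         importance = FALSE)
  restr <- rf_regress_pgp(
    table$values[, restricted_features, drop = FALSE], pgp, n_trees, seeds,
    importance = FALSE)
  d <- restr$mse - full$mse
  if (stats::sd(d) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else tt <- stats::t.test(d, mu = 0, alternative = alternative)
  structure(list(mse_restricted = restr$mse, mse_full = full$mse,
                 mean_diff = mean(d),
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 curves = list(tree_grid = full$tree_grid,
                               restricted = rowMeans(restr$mse_curve),
                               full = rowMeans(full$mse_curve)),
                 restricted = restr, full = full),
            class = "pgp_comparison")
}

#' @export
print.pgp_comparison <- function(x, ...) {
  cat("Restricted vs full P-gp regression over", length(x$mse_full),
      "seeds\n")
  cat("mean OOB MSE: restricted", format(mean(x$mse_restricted), digits = 5),
      "| full", format(mean(x$mse_full), digits = 5), "\n")
  cat("one-sample t on paired MSE differences: t =",
      format(x$t_statistic, digits = 4), ", p =",
      format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Taxa with positive regression importance
#'
#' Flags taxa whose mean permutation importance (increase in MSE) is
#' strictly positive — the taxa contributing to the P-gp regression — and
#' assigns each a predicted direction ("induce" or "repress") from the sign
#' of the Spearman correlation between its abundance and P-gp.
#'
#' @param regression a \code{\link{rf_regress_pgp}} result.
#' @param features the feature matrix the regression was fit on.
#' @param pgp aligned P-gp values (or \code{pgp_panel}).
#' @return data frame per taxon: \code{mean_importance}, \code{selected},
#'   \code{rho}, \code{direction} (NA when not selected).
#' @export
positive_importance_taxa <- function(regression, features, pgp) {
  stopifnot(inherits(regression, "pgp_regression"))
  if (inherits(pgp, "pgp_panel"))
    pgp <- pgp$pgp[match(rownames(features), pgp$sample_id)]
  mi <- regression$mean_importance
  rho <- suppressWarnings(apply(features[, names(mi), drop = FALSE], 2,
                                stats::cor, y = pgp, method = "spearman"))
  sel <- mi > 0
  data.frame(taxon = names(mi), mean_importance = unname(mi),
             selected = unname(sel), rho = unname(rho),
             direction = ifelse(sel, ifelse(rho >= 0, "induce", "repress"),
                                NA_character_),
             stringsAsFactors = FALSE)
}

#' Descriptive MRP2 summary
#'
#' MRP2 is ingested and summarized descriptively only (medians and IQR per
#' class); no model is attached to it.
#'
#' @param pgp a \code{pgp_panel} with an \code{mrp2} column.
#' @param metadata a \code{cohort_metadata}.
#' @return data frame of per-class median and IQR, or NULL when MRP2 absent.
#' @export
summarize_mrp2 <- function(pgp, metadata) {
  if (is.null(pgp$mrp2)) return(NULL)
  cls <- metadata$dementia_class[match(pgp$sample_id, metadata$sample_id)]
  do.call(rbind, lapply(split(pgp$mrp2, cls), function(v)
    data.frame(n = length(v), median = stats::median(v),
               iqr = stats::IQR(v))))
}
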