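# Subsample-and-consensus random-forest classification protocol for
# repeated-measures cohorts: repeated one-sample-per-subject trials under
# many seeds, importance rank aggregation, and a consensus discriminatory
# feature set.

#' Draw one sample per subject
#'
#' Uniformly selects a single sample id for each subject, the device that
#' removes repeated-measures dependence before fitting a forest.
#'
#' @param metadata a \code{\link{cohort_metadata}}.
#' @param subjects subject ids to draw for (default: all in metadata).
#' @return character vector of selected sample ids, one per subject, in
#'   subject order.
#' @export
subsample_one_per_subject <- function(metadata, subjects = NULL) {
  if (is.null(subjects)) subjects <- unique(metadata$subject_id)
  miss <- setdiff(subjects, metadata$subject_id)
  if (length(miss)) stop("subject(s) with zero samples: ",
                         paste(miss, collapse = ", "))
  vapply(subjects, function(s) {
    ids <- metadata$sample_id[metadata$subject_id == s]
    if (length(ids) == 1L) ids else sample(ids, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' One classification trial
#'
#' Fits a single random forest of \code{n_trees} trees on a
#' one-sample-per-subject matrix and returns (a) the out-of-bag error and
#' unscaled permutation importance (mean decrease in accuracy) from the
#' all-sample forest and (b), optionally, leave-one-subject-out predictions:
#' the forest is refit on n-1 subjects and predicts the held-out subject.
#'
#' @param features numeric matrix samples x features.
#' @param labels factor of binary class labels, aligned to rows.
#' @param n_trees trees per forest (default 3000).
#' @param loo also run the leave-one-out loop (default FALSE; costs one
#'   forest per subject).
#' @return list with \code{oob_error}, \code{importance} (named vector),
#'   \code{err_rate} (cumulative OOB and per-class error by tree count),
#'   and if requested \code{loo_accuracy} and \code{loo_pred}.
#' @export
run_trial <- function(features, labels, n_trees = 3000, loo = FALSE) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("binary labels required")
  if (min(table(labels)) < 1) stop("a class is absent from the training data")
  rf <- randomForest::randomForest(features, labels, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  out <- list(oob_error = unname(rf$err.rate[n_trees, "OOB"]),
              importance = imp, err_rate = rf$err.rate)
  if (loo) {
    n <- nrow(features)
    pred <- character(n)
    for (i in seq_len(n)) {
      tr <- droplevels(labels[-i])
      if (nlevels(tr) != 2) stop("a class is absent from a training fold")
      rfi <- randomForest::randomForest(features[-i, , drop = FALSE], tr,
                                        ntree = n_trees)
      pred[i] <- as.character(stats::predict(
        rfi, features[i, , drop = FALSE]))
    }
    out$loo_pred <- pred
    out$loo_accuracy <- mean(pred == as.character(labels))
  }
  out
}

#' Multi-seed stability selection of discriminatory features
#'
#' The consensus protocol: for each of \code{n_seeds} seeds, run
#' \code{n_trials} trials — each drawing one sample per subject at random
#' and fitting a forest of \code{n_trees} trees — average each feature's
#' permutation importance over the seed's trials, and rank features. A
#' feature's rank frequency is the fraction of seeds in which its
#' seed-level rank is within \code{top_k}; features with rank frequency of
#' at least \code{consensus_frac} form the consensus discriminatory set.
#' Ties in the seed-level ranking break lexicographically by feature id so
#' the protocol is deterministic given the top-level seed.
#'
#' @param table an \code{\link{abundance_table}} of species (features).
#' @param metadata a \code{\link{cohort_metadata}}.
#' @param contrast length-2 character vector of dementia classes, e.g.
#'   \code{c("AD", "NO")}.
#' @param n_seeds,n_trials,n_trees,top_k,consensus_frac protocol knobs;
#'   field defaults are 100 seeds x 30 trials x 3000 trees, top 30 at 90\%.
#'   A reduced preset for routine testing is 20 x 10 x 500.
#' @param include_clinical append frailty, malnutrition, age category and
#'   medication flags as candidate features.
#' @param compute_loo run a leave-one-subject-out loop once per seed on the
#'   seed's first subsample and report the per-seed accuracy distribution
#'   (default FALSE; adds one forest per subject per seed).
#' @param seed top-level seed; seed i of the protocol uses
#'   \code{\link{derive_seed}(seed, i)}.
#' @return list of class \code{"stability_result"}: \code{summary} (per
#'   feature: mean importance, rank frequency), \code{consensus_set},
#'   \code{oob_curve} (mean OOB and per-class error by tree count),
#'   \code{mean_oob}, \code{loo_accuracy} (or NULL), \code{config}.
#' @export
stability_selection <- function(table, metadata, contrast = c("AD", "NO"),
                                n_seeds = 100, n_trials = 30,
                                n_trees = 3000, top_k = 30,
                                consensus_frac = 0.90,
                                include_clinical = FALSE,
                                compute_loo = FALSE, seed = 1) {
  stopifnot(inherits(table, "abundance_table"),
            length(contrast) == 2, consensus_frac > 0, consensus_frac <= 1)
  md <- metadata[metadata$dementia_class %in% contrast, , drop = FALSE]
  subj <- unique(md[, c("subject_id", "dementia_class")])
  if (min(table(subj$dementia_class)) < 5)
    stop("need at least 5 subjects per class in the contrast")
  feats <- table$values[md$sample_id, , drop = FALSE]
  if (include_clinical) {
    clin <- as.matrix(md[, c("frailty", "malnutrition", "age_category",
                             "ppi", "statin", "antipsychotic",
                             "polypharmacy")])
    rownames(clin) <- md$sample_id
    feats <- cbind(feats, clin)
  }
  if (top_k > ncol(feats))
    stop("top_k (", top_k, ") exceeds the number of features (",
         ncol(feats), ")")
  fnames <- colnames(feats)
  lab_of <- stats::setNames(md$dementia_class, md$sample_id)

  in_top <- matrix(0, n_seeds, length(fnames),
                   dimnames = list(NULL, fnames))
  imp_sum <- stats::setNames(numeric(length(fnames)), fnames)
  err_sum <- NULL; n_err <- 0
  oob_all <- numeric(0)
  loo_acc <- if (compute_loo) numeric(n_seeds) else NULL

  for (s in seq_len(n_seeds)) {
    set.seed(derive_seed(seed, s))
    seed_imp <- stats::setNames(numeric(length(fnames)), fnames)
    for (t in seq_len(n_trials)) {
      ids <- subsample_one_per_subject(md, subj$subject_id)
      tr <- run_trial(feats[ids, , drop = FALSE],
                      factor(lab_of[ids], levels = contrast),
                      n_trees = n_trees,
                      loo = compute_loo && t == 1L)
      seed_imp <- seed_imp + tr$importance
      oob_all <- c(oob_all, tr$oob_error)
      err_sum <- if (is.null(err_sum)) tr$err_rate else err_sum + tr$err_rate
      n_err <- n_err + 1
      if (compute_loo && t == 1L) loo_acc[s] <- tr$loo_accuracy
    }
    seed_imp <- seed_imp / n_trials
    imp_sum <- imp_sum + seed_imp
    # rank by importance, ties broken lexicographically by feature id
    rk <- order(-seed_imp, fnames)
    in_top[s, rk[seq_len(top_k)]] <- 1
  }
  rank_freq <- colMeans(in_top)
  mean_imp <- imp_sum / n_seeds
  summary_df <- data.frame(feature = fnames,
                           mean_importance = unname(mean_imp),
                           rank_frequency = unname(rank_freq),
                           stringsAsFactors = FALSE)
  summary_df <- summary_df[order(-summary_df$mean_importance,
                                 summary_df$feature), ]
  rownames(summary_df) <- NULL
  consensus <- sort(fnames[rank_freq >= consensus_frac])
  structure(list(summary = summary_df, consensus_set = consensus,
                 oob_curve = err_sum / n_err, mean_oob = mean(oob_all),
                 loo_accuracy = loo_acc,
                 config = list(contrast = contrast, n_seeds = n_seeds,
                               n_trials = n_trials, n_trees = n_trees,
                               top_k = top_k,
                               consensus_frac = consensus_frac,
                               include_clinical = include_clinical,
                               seed = seed)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cf <- x$config
  cat("Stability selection", paste(cf$contrast, collapse = " vs "), ":",
      cf$n_seeds, "seeds x", cf$n_trials, "trials x", cf$n_trees,
      "trees; top", cf$top_k, "at", cf$consensus_frac, "\n")
  cat("mean OOB error:", format(x$mean_oob, digits = 4), "\n")
  cat("consensus set (", length(x$consensus_set), "):",
      paste(x$consensus_set, collapse = ", "), "\n")
  invisible(x)
}
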