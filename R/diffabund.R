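# Genus-level differential abundance: aggregation plus a per-genus
# zero-inflated beta mixed-model screen against dementia class.

#' Aggregate a species table to genus level
#'
#' Sums member-species relative abundances per genus using the table's
#' taxonomy map. Species without a genus assignment are pooled into
#' \code{"unclassified"} (with a message). Row sums are preserved.
#'
#' @param table an \code{\link{abundance_table}} with taxonomy.
#' @return an \code{abundance_table} of genera (taxonomy maps each genus to
#'   itself).
#' @export
aggregate_to_genus <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$taxonomy) || !length(table$taxonomy))
    stop("abundance table has no taxonomy map")
  gen <- table$taxonomy[colnames(table$values)]
  un <- is.na(gen) | gen == ""
  if (any(un)) {
    message("pooling ", sum(un), " unmapped species into 'unclassified'")
    gen[un] <- "unclassified"
  }
  agg <- t(rowsum(t(table$values), gen))
  abundance_table(agg, taxonomy = stats::setNames(colnames(agg),
                                                  colnames(agg)),
                  tol = 1e-6)
}

#' Genus-level differential-abundance screen
#'
#' Fits a \code{\link{zib_glmm}} for every genus above the mean-abundance
#' filter, modelling genus proportion as a function of dementia class (two
#' contrasts against the NO baseline), age category, frailty, malnutrition
#' and medication flags, with a per-subject random intercept. Reports the
#' dementia-class contrasts with raw Wald p-values (no multiplicity
#' correction, matching field practice for this screen; a
#' Benjamini-Hochberg column is appended for reference). Genera failing to
#' converge are listed in diagnostics and excluded from the significant set.
#'
#' @param table genus-level \code{abundance_table} (see
#'   \code{\link{aggregate_to_genus}}); a species table with taxonomy is
#'   aggregated automatically.
#' @param metadata a \code{\link{cohort_metadata}}.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @param min_mean_abund mean relative-abundance filter (default 0.001,
#'   i.e. 0.1\%).
#' @param covariates character vector of clinical covariates entered as
#'   fixed effects alongside dementia class.
#' @param nAGQ quadrature order passed to \code{zib_glmm}.
#' @return list of class \code{"genus_screen"}: \code{results} (all fitted
#'   genus x contrast rows), \code{significant} (direction, contrast, p,
#'   mean abundance), \code{diagnostics}.
#' @export
screen_genera <- function(table, metadata, alpha = 0.05,
                          min_mean_abund = 0.001,
                          covariates = c("age_category", "frailty",
                                         "malnutrition", "ppi", "statin",
                                         "antipsychotic", "polypharmacy"),
                          nAGQ = 15) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.null(table$taxonomy) &&
      !identical(unname(table$taxonomy), colnames(table$values)))
    table <- aggregate_to_genus(table)
  m <- table$values[metadata$sample_id, , drop = FALSE]
  mean_ab <- colMeans(m)
  keep <- names(mean_ab)[mean_ab > min_mean_abund]
  md <- as.data.frame(metadata)
  md$dementia_class <- droplevels(factor(md$dementia_class,
                                         levels = c("NO", "AD", "OTHER")))
  if (!"NO" %in% levels(md$dementia_class))
    stop("reference class NO absent from metadata")
  contrasts_present <- intersect(c("AD", "OTHER"),
                                 levels(md$dementia_class))
  rhs <- paste(c("dementia_class", covariates), collapse = " + ")
  rows <- list(); diag_msgs <- character(0)
  for (gn in keep) {
    md$.y <- m[, gn]
    fit <- tryCatch(
      zib_glmm(stats::as.formula(paste(".y ~", rhs)), md,
               subject = "subject_id", nAGQ = nAGQ),
      error = function(e) e)
    if (inherits(fit, "error") || !fit$identified || !fit$converged ||
        all(is.na(fit$se))) {
      diag_msgs <- c(diag_msgs, paste0(gn, ": ",
        if (inherits(fit, "error")) conditionMessage(fit)
        else "did not converge"))
      next
    }
    for (ct in contrasts_present) {
      cf <- paste0("dementia_class", ct)
      rows[[paste(gn, ct)]] <- data.frame(
        genus = gn, contrast = ct,
        estimate = unname(fit$beta[cf]),
        se = unname(fit$se[match(cf, names(fit$beta))]),
        p_value = unname(fit$p_values[match(cf, names(fit$beta))]),
        direction = if (fit$beta[cf] > 0) "increased" else "decreased",
        mean_abundance = unname(mean_ab[gn]),
        sigma_u = fit$sigma_u, converged = fit$converged,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genus = character(0), contrast = character(0),
               estimate = numeric(0), se = numeric(0), p_value = numeric(0),
               direction = character(0), mean_abundance = numeric(0),
               sigma_u = numeric(0), converged = logical(0))
  rownames(res) <- NULL
  res$p_bh <- stats::p.adjust(res$p_value, "BH")
  sig <- res[!is.na(res$p_value) & res$p_value < alpha, , drop = FALSE]
  structure(list(results = res, significant = sig,
                 diagnostics = diag_msgs, alpha = alpha,
                 min_mean_abund = min_mean_abund,
                 n_genera_tested = length(keep),
                 n_genera_filtered = sum(mean_ab <= min_mean_abund)),
            class = "genus_screen")
}

#' @export
print.genus_screen <- function(x, ...) {
  cat("Genus screen:", x$n_genera_tested, "genera tested (",
      x$n_genera_filtered, "below the", x$min_mean_abund,
      "mean-abundance filter )\n")
  cat(nrow(x$significant), "genus x contrast associations at p <",
      x$alpha, "\n")
  if (nrow(x$significant))
    print(x$significant[order(x$significant$p_value),
                        c("genus", "contrast", "direction", "p_value",
                          "mean_abundance")], row.names = FALSE)
  if (length(x$diagnostics))
    cat("non-converged:", paste(x$diagnostics, collapse = "; "), "\n")
  invisible(x)
}
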