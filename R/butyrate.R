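# Butyrate biosynthesis gene analysis: pathway grouping, per-gene linear
# mixed-model contrasts between dementia classes, and Spearman correlation
# of gene abundance with P-gp expression.

#' Sum gene abundances into pathways
#'
#' Pathway abundance per sample is the sum of its member genes' abundances
#' (four major butyrate biosynthetic pathways in the default map).
#'
#' @param genes a \code{\link{butyrate_gene_table}}.
#' @return numeric matrix samples x pathways.
#' @export
group_pathways <- function(genes) {
  stopifnot(inherits(genes, "butyrate_gene_table"))
  t(rowsum(t(genes$values), genes$pathway_map[colnames(genes$values)]))
}

#' Per-gene mixed-model contrast between dementia classes
#'
#' For each butyrate gene, fits a linear mixed model on log-transformed
#' abundance with the class contrast as fixed effect and a per-subject
#' random intercept (maximum likelihood via \pkg{lme4}); Wald p-values on
#' the class coefficient. The transform is \code{log(x + pseudocount)} with
#' the pseudocount set to half the gene's smallest nonzero value. Genes
#' with zero variance are flagged degenerate and skipped.
#'
#' @param genes a \code{\link{butyrate_gene_table}}.
#' @param metadata a \code{\link{cohort_metadata}}.
#' @param contrast length-2 character vector \code{c(test, reference)};
#'   default \code{c("AD", "NO")}.
#' @return data frame of class \code{"gene_effect_result"}: per gene the
#'   pathway, effect estimate (log scale, test vs reference), SE, p-value,
#'   random-intercept SD, and \code{converged}/\code{degenerate} flags,
#'   plus a BH-adjusted column.
#' @export
lmm_gene_contrast <- function(genes, metadata, contrast = c("AD", "NO")) {
  stopifnot(inherits(genes, "butyrate_gene_table"), length(contrast) == 2)
  md <- metadata[metadata$dementia_class %in% contrast, , drop = FALSE]
  nsub <- table(unique(md[, c("subject_id",
                              "dementia_class")])$dementia_class)
  if (length(nsub) < 2 || any(nsub < 2))
    stop("need at least 2 subjects per class in the contrast")
  m <- genes$values[md$sample_id, , drop = FALSE]
  cls <- factor(md$dementia_class, levels = rev(contrast)) # ref first
  rows <- lapply(colnames(m), function(g) {
    x <- m[, g]
    out <- data.frame(gene = g,
                      pathway = unname(genes$pathway_map[g]),
                      estimate = NA_real_, se = NA_real_,
                      p_value = NA_real_, sigma_u = NA_real_,
                      converged = FALSE, degenerate = FALSE,
                      stringsAsFactors = FALSE)
    if (stats::var(x) == 0) { out$degenerate <- TRUE; return(out) }
    pc <- min(x[x > 0]) / 2
    d <- data.frame(y = log(x + pc), cls = cls, subj = md$subject_id)
    fit <- tryCatch(suppressMessages(
      lme4::lmer(y ~ cls + (1 | subj), data = d, REML = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) return(out)
    cf <- summary(fit)$coefficients
    i <- grep("^cls", rownames(cf))
    out$estimate <- cf[i, "Estimate"]; out$se <- cf[i, "Std. Error"]
    out$p_value <- 2 * stats::pnorm(-abs(cf[i, "t value"]))
    out$sigma_u <- sqrt(unname(lme4::VarCorr(fit)$subj[1]))
    out$converged <- TRUE
    out
  })
  res <- do.call(rbind, rows)
  res$p_bh <- stats::p.adjust(res$p_value, "BH")
  class(res) <- c("gene_effect_result", "data.frame")
  attr(res, "contrast") <- contrast
  res
}

#' Spearman correlation of butyrate genes with P-gp
#'
#' Rank correlation (average ranks for ties) of each gene's abundance with
#' per-sample P-gp expression across overlapping samples; p-values exact
#' where the sample count permits, asymptotic otherwise. Constant genes are
#' flagged with \code{rho = NA}.
#'
#' @param genes a \code{\link{butyrate_gene_table}}.
#' @param pgp a \code{\link{pgp_panel}}.
#' @return data frame per gene: \code{rho}, \code{p_value}, \code{n},
#'   \code{degenerate}.
#' @export
correlate_genes_pgp <- function(genes, pgp) {
  stopifnot(inherits(genes, "butyrate_gene_table"),
            inherits(pgp, "pgp_panel"))
  common <- intersect(rownames(genes$values), pgp$sample_id)
  if (length(common) < 4) stop("need at least 4 overlapping samples")
  y <- pgp$pgp[match(common, pgp$sample_id)]
  m <- genes$values[common, , drop = FALSE]
  rows <- lapply(colnames(m), function(g) {
    x <- m[, g]
    if (stats::var(x) == 0 || stats::var(y) == 0)
      return(data.frame(gene = g, rho = NA_real_, p_value = NA_real_,
                        n = length(x), degenerate = TRUE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(gene = g, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(x), degenerate = FALSE)
  })
  do.call(rbind, rows)
}
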