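# Table containers and TSV I/O.
#
# TSV is the canonical interchange (taxonomic profilers and marker-gene
# quantifiers emit plain tables); all readers validate schemas up front and
# fail with messages naming the offending sample/column.

#' Relative-abundance table
#'
#' Validating constructor for the compositional core object: a samples x
#' taxa matrix of relative abundances with an optional species -> genus
#' taxonomy map. Rows must sum to 1 within \code{tol} unless
#' \code{renormalize} is set, in which case rows are rescaled and a message
#' is emitted.
#'
#' @param values numeric matrix, rownames = sample ids, colnames = taxon ids.
#' @param taxonomy named character vector mapping species to genus (optional).
#' @param renormalize rescale rows to sum to 1 instead of erroring.
#' @param tol row-sum tolerance (default 1e-6).
#' @return list of class \code{"abundance_table"} with \code{values} and
#'   \code{taxonomy}.
#' @export
abundance_table <- function(values, taxonomy = NULL, renormalize = FALSE,
                            tol = 1e-6) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs sample rownames and taxon colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon ids")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("abundance values must be finite numerics")
  if (any(values < 0)) stop("negative abundances")
  rs <- rowSums(values)
  off <- abs(rs - 1) > tol
  if (any(off)) {
    if (!renormalize)
      stop("rows do not sum to 1 (tolerance ", tol, "): ",
           paste(utils::head(rownames(values)[off], 5), collapse = ", "),
           "; pass renormalize = TRUE to rescale")
    message("renormalizing ", sum(off), " rows to unit sum")
    values <- values / rs
  }
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("taxonomy must be a named vector")
    miss <- setdiff(colnames(values), names(taxonomy))
    if (length(miss)) stop("taxonomy missing species: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    taxonomy <- taxonomy[colnames(values)]
  }
  structure(list(values = values, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", nrow(x$values), "samples x", ncol(x$values),
      "taxa")
  if (!is.null(x$taxonomy))
    cat(" (", length(unique(x$taxonomy)), "genera )")
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.abundance_table <- function(x, ...) x$values

#' Cohort metadata table
#'
#' Validates the per-sample clinical metadata: sample/subject ids, month,
#' dementia class in NO/AD/OTHER, age category 1-4, frailty 1-7 (CSHA),
#' malnutrition 1-3 (MNA category), four medication flags, CDR >= 0.
#' Missing values are rejected, not imputed.
#'
#' @param df data frame with the columns above.
#' @return the validated data frame with class \code{"cohort_metadata"}.
#' @export
cohort_metadata <- function(df) {
  need <- c("sample_id", "subject_id", "month", "dementia_class",
            "age_category", "frailty", "malnutrition", "ppi", "statin",
            "antipsychotic", "polypharmacy", "cdr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(df[need])) stop("metadata contains missing values; ",
                            "imputation is not supported")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  bad <- setdiff(unique(df$dementia_class), c("NO", "AD", "OTHER"))
  if (length(bad))
    stop("unknown dementia_class label(s) ", paste(bad, collapse = ", "),
         "; allowed: NO, AD, OTHER")
  chk <- function(col, lo, hi)
    if (any(df[[col]] < lo | df[[col]] > hi))
      stop(col, " out of range [", lo, ", ", hi, "]")
  chk("age_category", 1, 4); chk("frailty", 1, 7); chk("malnutrition", 1, 3)
  chk("cdr", 0, Inf)
  for (m in c("ppi", "statin", "antipsychotic", "polypharmacy"))
    if (!all(df[[m]] %in% c(0, 1)))
      stop("medication flag ", m, " must be 0/1")
  # class constant within subject
  cls <- tapply(df$dementia_class, df$subject_id,
                function(v) length(unique(v)))
  if (any(cls > 1)) stop("dementia_class varies within a subject")
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Butyrate gene table
#'
#' Samples x genes non-negative abundances with a gene -> pathway map
#' covering every gene (4 biosynthetic pathways by default).
#'
#' @param values numeric matrix (samples x genes), non-negative.
#' @param pathway_map named character vector gene -> pathway label.
#' @param n_pathways expected number of distinct pathways (default 4;
#'   set NULL to skip the check).
#' @return list of class \code{"butyrate_gene_table"}.
#' @export
butyrate_gene_table <- function(values, pathway_map, n_pathways = 4) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene matrix needs sample rownames and gene colnames")
  if (any(!is.finite(values)) || any(values < 0))
    stop("gene abundances must be finite and non-negative")
  miss <- setdiff(colnames(values), names(pathway_map))
  if (length(miss)) stop("pathway map missing genes: ",
                         paste(miss, collapse = ", "))
  pathway_map <- pathway_map[colnames(values)]
  if (!is.null(n_pathways) &&
      length(unique(pathway_map)) != n_pathways)
    stop("expected ", n_pathways, " distinct pathways, found ",
         length(unique(pathway_map)))
  structure(list(values = values, pathway_map = pathway_map),
            class = "butyrate_gene_table")
}

#' P-glycoprotein expression panel
#'
#' Per-sample normalized P-gp expression (positive scalars), optionally with
#' MRP2 values. MRP2 is carried descriptively only.
#'
#' @param df data frame with columns \code{sample_id}, \code{pgp} and
#'   optionally \code{mrp2}.
#' @return validated data frame of class \code{"pgp_panel"}.
#' @export
pgp_panel <- function(df) {
  stopifnot(all(c("sample_id", "pgp") %in% names(df)))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in P-gp panel")
  if (anyNA(df$pgp) || any(df$pgp <= 0))
    stop("P-gp values must be positive and non-missing")
  if (!is.null(df$mrp2) && all(is.na(df$mrp2))) df$mrp2 <- NULL
  class(df) <- c("pgp_panel", "data.frame")
  df
}

#' Read a relative-abundance TSV
#'
#' Expects a header of taxon ids with sample ids in the first column, plus a
#' two-column taxonomy TSV (\code{species}, \code{genus}).
#'
#' @param path abundance TSV path.
#' @param taxonomy_path optional taxonomy TSV path.
#' @param renormalize,tol passed to \code{\link{abundance_table}}.
#' @return an \code{abundance_table}.
#' @export
read_abundance <- function(path, taxonomy_path = NULL, renormalize = FALSE,
                           tol = 1e-6) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance TSV needs sample id + taxon columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance cell in ", path)
  rownames(m) <- ids
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    td <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
    if (!all(c("species", "genus") %in% names(td)))
      stop("taxonomy TSV needs columns species, genus")
    tax <- stats::setNames(td$genus, td$species)
  }
  abundance_table(m, taxonomy = tax, renormalize = renormalize, tol = tol)
}

#' @rdname read_abundance
#' @param table an \code{abundance_table} to write.
#' @export
write_abundance <- function(table, path, taxonomy_path = NULL) {
  df <- data.frame(sample_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(table$taxonomy))
    utils::write.table(
      data.frame(species = names(table$taxonomy),
                 genus = unname(table$taxonomy)),
      taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write cohort metadata, butyrate genes and P-gp TSVs
#'
#' @param path TSV path.
#' @return the validated object of the corresponding class.
#' @export
read_metadata <- function(path) {
  cohort_metadata(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_metadata
#' @param metadata a \code{cohort_metadata}.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_metadata
#' @param pathway_path two-column TSV (\code{gene}, \code{pathway}).
#' @param n_pathways expected pathway count (see
#'   \code{\link{butyrate_gene_table}}).
#' @export
read_genes <- function(path, pathway_path, n_pathways = 4) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  pd <- utils::read.delim(pathway_path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway") %in% names(pd)))
    stop("pathway TSV needs columns gene, pathway")
  butyrate_gene_table(m, stats::setNames(pd$pathway, pd$gene),
                      n_pathways = n_pathways)
}

#' @rdname read_metadata
#' @param genes a \code{butyrate_gene_table}.
#' @export
write_genes <- function(genes, path, pathway_path) {
  df <- data.frame(sample_id = rownames(genes$values), genes$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(genes$pathway_map),
               pathway = unname(genes$pathway_map)),
    pathway_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_metadata
#' @export
read_pgp <- function(path) {
  pgp_panel(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_metadata
#' @param pgp a \code{pgp_panel}.
#' @export
write_pgp <- function(pgp, path) {
  utils::write.table(pgp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-table id consistency check
#'
#' Verifies that every abundance, gene and P-gp sample id resolves against
#' the metadata (the join validator run before any analysis stage).
#'
#' @param metadata a \code{cohort_metadata}.
#' @param abundance optional \code{abundance_table}.
#' @param genes optional \code{butyrate_gene_table}.
#' @param pgp optional \code{pgp_panel}.
#' @return invisibly TRUE; errors name the orphan sample ids.
#' @export
validate_cohort <- function(metadata, abundance = NULL, genes = NULL,
                            pgp = NULL) {
  known <- metadata$sample_id
  orphan <- function(ids, what) {
    o <- setdiff(ids, known)
    if (length(o)) stop(what, " has sample ids absent from metadata: ",
                        paste(utils::head(o, 5), collapse = ", "))
  }
  if (!is.null(abundance)) orphan(rownames(abundance$values), "abundance")
  if (!is.null(genes)) orphan(rownames(genes$values), "gene table")
  if (!is.null(pgp)) orphan(pgp$sample_id, "P-gp panel")
  invisible(TRUE)
}

#' Derive a stage seed from a top-level seed
#'
#' Deterministic counter scheme so every randomized stage is independently
#' reproducible from one top-level seed: stage k uses
#' \code{(seed * 97 + k) mod 2^31 - 1}.
#'
#' @param seed top-level integer seed.
#' @param stage integer stage counter (>= 0).
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 97 + stage) %% (2^31 - 1))
}
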