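# Synthetic cohort generator.
#
# Emulates the study design the pipeline targets: ~108 nursing-home elders
# split across no-dementia / Alzheimer's / other-dementia classes, 1-4
# monthly stool samples each, species relative abundances with subject-level
# covariance, planted class shifts on designated taxa, sequencing-depth
# sampling zeros, clinical covariates correlated with class, butyrate gene
# abundances driven by producer taxa, and a P-gp readout generated from a
# subset of taxa plus noise.

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by
#' \code{\link{generate_cohort}}. Defaults encode the emulated study:
#' 51/24/33 subjects in the NO/AD/OTHER dementia classes, one to four
#' monthly samples per subject, and clinical covariate means per class in
#' the direction of the cohort's clinical table (higher frailty and
#' malnutrition in the dementia classes, antipsychotics essentially absent
#' in NO, proton-pump inhibitors more common in NO).
#'
#' Species log-abundances are logistic-normal: per sample,
#' \code{log a = baseline + class shift + subject intercept + noise}, closed
#' by softmax, then resampled multinomially at \code{read_depth} reads and
#' renormalized, which induces sampling zeros. \code{read_depth = Inf}
#' switches to exact proportions. The subject intercept is drawn per
#' subject-by-species cell (a shared scalar would cancel in the softmax).
#'
#' @param n_subjects_per_class named integer vector \code{c(NO=, AD=, OTHER=)}.
#' @param samples_per_subject_range integer pair; samples per subject drawn
#'   uniformly over this range (months 1..k).
#' @param n_species,n_genera community size; species are assigned to genera
#'   cyclically so every genus has at least one member.
#' @param species_effect_map data frame with columns \code{taxon},
#'   \code{class}, \code{delta}: log-scale shift added to \code{taxon} in
#'   samples of \code{class}. Empty by default (null cohort).
#' @param subject_sd,species_sd log-scale SDs of the subject intercept and
#'   per-sample noise.
#' @param baseline_sd SD of baseline log-abundances (controls how uneven the
#'   rank-abundance curve is).
#' @param read_depth multinomial resampling depth (reads per sample);
#'   \code{Inf} disables resampling.
#' @param pgp_driver_weights named numeric vector taxon -> weight in the
#'   P-gp linear predictor. Empty by default.
#' @param pgp_intercept,pgp_noise_sd intercept and noise SD of the P-gp
#'   generator \code{pgp = b0 + sum w_t log(x_t + 1e-6) + noise}.
#' @param clinical_class_shifts list with per-class means for \code{frailty}
#'   and \code{malnutrition} (named vectors over NO/AD/OTHER).
#' @param n_genes number of butyrate genes (grouped into 4 pathways).
#' @param butyrate_producers taxa whose abundances drive the butyrate genes;
#'   defaults to the last 8 species.
#' @param gene_noise_sd lognormal noise SD on gene abundances.
#' @param seed integer seed; the same config is byte-identical to regenerate.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects_per_class = c(NO = 51, AD = 24, OTHER = 33),
                       samples_per_subject_range = c(1L, 4L),
                       n_species = 120, n_genera = 40,
                       species_effect_map = NULL,
                       subject_sd = 1.0, species_sd = 0.5, baseline_sd = 1.5,
                       read_depth = 1e5,
                       pgp_driver_weights = numeric(0),
                       pgp_intercept = 5, pgp_noise_sd = 0.3,
                       clinical_class_shifts = list(
                         frailty = c(NO = 2.9, AD = 3.4, OTHER = 3.7),
                         malnutrition = c(NO = 1.7, AD = 2.3, OTHER = 2.3)),
                       n_genes = 12, butyrate_producers = NULL,
                       gene_noise_sd = 0.3, seed = 1L) {
  classes <- c("NO", "AD", "OTHER")
  stopifnot(all(classes %in% names(n_subjects_per_class)),
            all(n_subjects_per_class >= 0),
            length(samples_per_subject_range) == 2L,
            samples_per_subject_range[1] >= 1,
            diff(samples_per_subject_range) >= 0,
            n_species >= 2, n_genera >= 1, n_genera <= n_species,
            subject_sd >= 0, species_sd >= 0, baseline_sd >= 0,
            read_depth >= 1, pgp_noise_sd >= 0, gene_noise_sd >= 0,
            n_genes >= 4)
  taxa <- sprintf("sp%03d", seq_len(n_species))
  if (is.null(species_effect_map))
    species_effect_map <- data.frame(taxon = character(0),
                                     class = character(0),
                                     delta = numeric(0))
  stopifnot(all(c("taxon", "class", "delta") %in% names(species_effect_map)))
  bad <- setdiff(species_effect_map$taxon, taxa)
  if (length(bad)) stop("species_effect_map names unknown taxa: ",
                        paste(bad, collapse = ", "))
  if (!all(species_effect_map$class %in% classes))
    stop("species_effect_map classes must be among ",
         paste(classes, collapse = "/"))
  bad <- setdiff(names(pgp_driver_weights), taxa)
  if (length(bad)) stop("pgp_driver_weights names unknown taxa: ",
                        paste(bad, collapse = ", "))
  if (is.null(butyrate_producers))
    butyrate_producers <- utils::tail(taxa, 8)
  stopifnot(all(butyrate_producers %in% taxa))
  structure(list(
    n_subjects_per_class = n_subjects_per_class[classes],
    samples_per_subject_range = as.integer(samples_per_subject_range),
    n_species = as.integer(n_species), n_genera = as.integer(n_genera),
    taxa = taxa,
    species_effect_map = species_effect_map,
    subject_sd = subject_sd, species_sd = species_sd,
    baseline_sd = baseline_sd, read_depth = read_depth,
    pgp_driver_weights = pgp_driver_weights,
    pgp_intercept = pgp_intercept, pgp_noise_sd = pgp_noise_sd,
    clinical_class_shifts = clinical_class_shifts,
    n_genes = as.integer(n_genes),
    butyrate_producers = butyrate_producers,
    gene_noise_sd = gene_noise_sd, seed = as.integer(seed)),
    class = "sim_config")
}

softmax_rows <- function(L) {
  M <- L - apply(L, 1, max)   # overflow guard
  E <- exp(M)
  E / rowSums(E)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic longitudinal cohort
#'
#' Draws a full synthetic data set from a \code{\link{sim_config}}: sample
#' metadata with clinical covariates, a species relative-abundance table
#' with taxonomy, a butyrate gene table with a 4-pathway map, a per-sample
#' P-gp panel, and a \code{truth} record of all planted effects for recovery
#' testing. Identical configs (including seed) reproduce identical cohorts.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{"synthetic_cohort"} with elements
#'   \code{metadata}, \code{abundance} (an \code{\link{abundance_table}}),
#'   \code{butyrate_genes}, \code{pgp}, \code{truth}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed <- config$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)

  cls_n <- config$n_subjects_per_class
  classes <- rep(names(cls_n), cls_n)
  n_subj <- length(classes)
  if (n_subj == 0) stop("config defines zero subjects")
  subj_ids <- sprintf("S%03d", seq_len(n_subj))

  rng <- config$samples_per_subject_range
  k <- if (rng[1] == rng[2]) rep(rng[1], n_subj) else
    sample(seq(rng[1], rng[2]), n_subj, replace = TRUE)
  sample_subj <- rep(subj_ids, k)
  month <- unlist(lapply(k, seq_len), use.names = FALSE)
  sample_ids <- paste0(sample_subj, "_M", month)
  n_samp <- length(sample_ids)
  sample_class <- rep(classes, k)

  taxa <- config$taxa
  p <- config$n_species
  baseline <- stats::rnorm(p, 0, config$baseline_sd)
  shift <- matrix(0, 3, p, dimnames = list(c("NO", "AD", "OTHER"), taxa))
  em <- config$species_effect_map
  if (nrow(em))
    for (i in seq_len(nrow(em)))
      shift[em$class[i], em$taxon[i]] <- shift[em$class[i], em$taxon[i]] +
        em$delta[i]
  subj_int <- matrix(stats::rnorm(n_subj * p, 0, config$subject_sd),
                     n_subj, p, dimnames = list(subj_ids, taxa))

  L <- matrix(baseline, n_samp, p, byrow = TRUE) +
    shift[sample_class, , drop = FALSE] +
    subj_int[sample_subj, , drop = FALSE] +
    matrix(stats::rnorm(n_samp * p, 0, config$species_sd), n_samp, p)
  P <- softmax_rows(L)
  if (is.finite(config$read_depth)) {
    D <- as.integer(config$read_depth)
    cnt <- apply(P, 1, function(pr) stats::rmultinom(1, D, pr))
    P <- t(cnt) / D
  }
  dimnames(P) <- list(sample_ids, taxa)

  genus_of <- sprintf("g%02d", rep_len(seq_len(config$n_genera), p))
  taxonomy <- stats::setNames(genus_of, taxa)

  # clinical covariates with class-dependent means, clamped to valid ranges
  ccs <- config$clinical_class_shifts
  frail_mu <- ccs$frailty[classes]
  maln_mu <- ccs$malnutrition[classes]
  frailty <- clamp(round(stats::rnorm(n_subj, frail_mu, 1.0)), 1, 7)
  malnutrition <- clamp(round(stats::rnorm(n_subj, maln_mu, 0.6)), 1, 3)
  age_category <- clamp(round(stats::rnorm(
    n_subj, c(NO = 2.3, AD = 2.5, OTHER = 2.8)[classes], 1.0)), 1, 4)
  ppi <- stats::rbinom(n_subj, 1,
                       c(NO = 0.31, AD = 0.05, OTHER = 0.18)[classes])
  statin <- stats::rbinom(n_subj, 1, 0.21)
  antipsychotic <- stats::rbinom(n_subj, 1,
                                 c(NO = 0.01, AD = 0.17, OTHER = 0.06)[classes])
  polypharmacy <- stats::rbinom(n_subj, 1, 0.65)
  cdr <- clamp(stats::rnorm(n_subj,
                            c(NO = 0.25, AD = 2.12, OTHER = 1.88)[classes],
                            c(NO = 0.2, AD = 0.33, OTHER = 0.95)[classes]),
               0, 3)
  subj_df <- data.frame(subject_id = subj_ids, dementia_class = classes,
                        age_category = age_category, frailty = frailty,
                        malnutrition = malnutrition, ppi = ppi,
                        statin = statin, antipsychotic = antipsychotic,
                        polypharmacy = polypharmacy, cdr = round(cdr, 2),
                        stringsAsFactors = FALSE)
  metadata <- cbind(data.frame(sample_id = sample_ids,
                               subject_id = sample_subj, month = month,
                               stringsAsFactors = FALSE),
                    subj_df[match(sample_subj, subj_df$subject_id),
                            -1, drop = FALSE])
  rownames(metadata) <- NULL
  metadata <- cohort_metadata(metadata)

  # butyrate genes: weighted sums of producer-taxon abundances, lognormal noise
  ng <- config$n_genes
  gene_ids <- sprintf("but%02d", seq_len(ng))
  pathways <- c("pathway_acetylCoA", "pathway_glutarate",
                "pathway_4aminobutyrate", "pathway_lysine")
  pathway_map <- stats::setNames(rep_len(pathways, ng), gene_ids)
  prod_idx <- match(config$butyrate_producers, taxa)
  W <- matrix(stats::runif(ng * length(prod_idx), 0, 1), ng)
  G <- P[, prod_idx, drop = FALSE] %*% t(W)
  G <- G * matrix(exp(stats::rnorm(n_samp * ng, 0, config$gene_noise_sd)),
                  n_samp, ng)
  dimnames(G) <- list(sample_ids, gene_ids)

  # P-gp: linear in log-abundances of driver taxa
  w <- config$pgp_driver_weights
  lp <- rep(config$pgp_intercept, n_samp)
  if (length(w))
    lp <- lp + drop(log(P[, names(w), drop = FALSE] + 1e-6) %*% w)
  pgp <- lp + stats::rnorm(n_samp, 0, config$pgp_noise_sd)
  if (any(pgp <= 0)) {
    warning("clamping ", sum(pgp <= 0), " non-positive P-gp draws to 1e-6")
    pgp <- pmax(pgp, 1e-6)
  }

  structure(list(
    metadata = metadata,
    abundance = abundance_table(P, taxonomy = taxonomy),
    butyrate_genes = butyrate_gene_table(G, pathway_map = pathway_map),
    pgp = pgp_panel(data.frame(sample_id = sample_ids, pgp = pgp,
                               stringsAsFactors = FALSE)),
    truth = list(species_effects = em,
                 pgp_driver_weights = w,
                 subject_intercepts = subj_int,
                 butyrate_producers = config$butyrate_producers,
                 gene_weights = W),
    config = config), class = "synthetic_cohort")
}

#' Planted-effect truth table
#'
#' Returns the taxa, class shifts and P-gp driver weights planted by the
#' generator, for recovery tests downstream.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @return data frame with columns \code{taxon}, \code{kind}
#'   (\code{"class_shift"} or \code{"pgp_driver"}), \code{class} (NA for
#'   drivers), \code{value}.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  em <- cohort$truth$species_effects
  w <- cohort$truth$pgp_driver_weights
  rbind(
    if (nrow(em)) data.frame(taxon = em$taxon, kind = "class_shift",
                             class = em$class, value = em$delta,
                             stringsAsFactors = FALSE),
    if (length(w)) data.frame(taxon = names(w), kind = "pgp_driver",
                              class = NA_character_, value = unname(w),
                              stringsAsFactors = FALSE))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$abundance$values), "samples,",
      length(unique(x$metadata$subject_id)), "subjects,",
      ncol(x$abundance$values), "species,",
      ncol(x$butyrate_genes$values), "butyrate genes\n")
  print(table(x$metadata$dementia_class[!duplicated(x$metadata$subject_id)]))
  invisible(x)
}

#' Write the four cohort tables plus truth to a directory
#'
#' Emits the TSVs \code{abundance.tsv}, \code{taxonomy.tsv},
#' \code{metadata.tsv}, \code{genes.tsv}, \code{pathways.tsv},
#' \code{pgp.tsv} and a JSON-like \code{truth.tsv}, in the schemas the
#' readers in this package consume.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             genes = file.path(dir, "genes.tsv"),
             pathways = file.path(dir, "pathways.tsv"),
             pgp = file.path(dir, "pgp.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_abundance(cohort$abundance, paths["abundance"], paths["taxonomy"])
  write_metadata(cohort$metadata, paths["metadata"])
  write_genes(cohort$butyrate_genes, paths["genes"], paths["pathways"])
  write_pgp(cohort$pgp, paths["pgp"])
  tr <- truth_report(cohort)
  if (is.null(tr)) tr <- data.frame(taxon = character(0), kind = character(0),
                                    class = character(0), value = numeric(0))
  utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
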