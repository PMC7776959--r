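.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(cfg)), f)
  unname(tools::md5sum(f))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the genomic hybrid-zone chain end to end
#'
#' Parental frequencies -> per-individual ancestry -> hybrid-category
#' classification -> zone composition -> distance-binned cline fit, and
#' (when a morphology table is supplied) the PCA hybrid index and its
#' correlation with genomic ancestry. All stochastic stages (the cline
#' bootstrap) are governed by `seed`, so a rerun with the same inputs and
#' seed is byte-identical.
#'
#' @param G a [genotype_matrix()].
#' @param S a [sample_frame()].
#' @param morph optional [morph_table()].
#' @param band_width transect band width (m), default 10.
#' @param min_loci usable-locus threshold for ancestry/classification.
#' @param boot cline bootstrap replicates.
#' @param seed integer seed (mandatory, for reproducibility).
#' @param out_dir optional directory; when given, writes `ancestry.tsv`,
#'   `assignments.tsv`, `cline.json` and `summary.json`.
#' @return A list of class `hz_report`: `ancestry`, `assignments`,
#'   `composition`, `cline`, `morphology` (index table or `NULL`),
#'   `correlation` (or `NULL`), and `summary` (hybrid fraction, F1
#'   fraction, cline center/width, correlation r, config hash, package
#'   version).
#' @export
run_hybridzone <- function(G, S, morph = NULL, band_width = 10,
                           min_loci = 50, boot = 500, seed = 1,
                           out_dir = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  validate_samples(S, G)
  queries <- S$sample_id[S$role == "query"]
  if (!length(queries))
    stop("ancestry stage: no query samples to analyse")
  freqs <- parental_frequencies(G, S)
  anc <- estimate_ancestry(G, freqs, min_loci = min_loci)
  qG <- G[S$sample_id[S$role == "query"], , drop = FALSE]
  class(qG) <- class(G)
  assign <- classify_all(qG, freqs, min_loci = min_loci)
  comp <- zone_composition(assign, S)
  ok <- !is.na(anc$q)
  bands <- bin_transect(anc$q[ok],
                        S$position[match(anc$sample_id[ok], S$sample_id)],
                        band_width = band_width)
  cl <- fit_cline(bands, boot = boot, seed = seed)
  morph_idx <- NULL; corr <- NULL
  if (!is.null(morph)) {
    morph_idx <- leaf_pca_index(morph, S)
    shared <- intersect(morph_idx$sample_id, anc$sample_id[ok])
    # index anchors pool 1 at -2, so pair it with pool-2 ancestry (1 - q)
    # to report the correlation on a common orientation
    corr <- genotype_morphology_correlation(
      1 - anc$q[match(shared, anc$sample_id)],
      morph_idx$index[match(shared, morph_idx$sample_id)])
  }
  eco <- comp[comp$habitat == "ecotone", ]
  cfg <- list(band_width = band_width, min_loci = min_loci, boot = boot,
              seed = seed, n_samples = nrow(S), n_loci = ncol(G))
  summary <- list(
    n_samples = nrow(S), n_loci = ncol(G),
    ecotone_hybrid_frac = if (nrow(eco)) eco$hybrid_frac else NA,
    ecotone_f1_frac_of_hybrids = if (nrow(eco)) eco$f1_frac_of_hybrids else NA,
    cline_center_m = cl$center, cline_width_m = cl$width,
    cline_width_ci = cl$ci_width,
    genotype_morphology_r = if (!is.null(corr)) corr$r else NULL,
    config_hash = .config_hash(cfg),
    package_version = as.character(utils::packageVersion("hybzone")))
  out <- structure(list(ancestry = anc, assignments = assign,
                        composition = comp, cline = cl,
                        morphology = morph_idx, correlation = corr,
                        summary = summary),
                   class = "hz_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(anc, file.path(out_dir, "ancestry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assign, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_json(unclass(cl), file.path(out_dir, "cline.json"))
    .write_json(summary, file.path(out_dir, "summary.json"))
  }
  out
}

#' Run the reciprocal-transplant chain end to end
#'
#' Selection coefficients with bootstrap CIs, the negative binomial GLM
#' habitat x phenotype interaction test on composite fitness, a
#' water x phenotype interaction test per habitat when both water levels
#' are present, and backward-stepwise log-linear analyses of burial and
#' herbivory mortality.
#'
#' @param T a [transplant_table()].
#' @param B bootstrap replicates for the selection CIs.
#' @param seed integer seed (mandatory).
#' @param out_dir optional output directory (`fitness.tsv`,
#'   `transplant_report.json`).
#' @return A list of class `transplant_report`: `fitness`,
#'   `interaction_test` (GLM LR), `water_tests` (per habitat or `NULL`),
#'   `mortality` (per cause: stepwise trail and final model), `summary`.
#' @export
run_transplant <- function(T, B = 1000, seed = 1, out_dir = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  T <- transplant_table(as.data.frame(T))
  fs <- selection_coefficients(T, B = B, seed = seed)
  dat <- data.frame(T, fitness = composite_fitness(T))
  full <- fit_nb_glm(fitness ~ habitat * phenotype, dat)
  red <- fit_nb_glm(fitness ~ habitat + phenotype, dat)
  lr <- lr_interaction_test(full, red)

  water_tests <- NULL
  if (length(unique(T$water)) == 2) {
    water_tests <- list()
    for (h in intersect(c("desert", "dune"), unique(T$habitat))) {
      d <- dat[dat$habitat == h & dat$phenotype %in% c("P1", "P2"), ]
      if (length(unique(d$phenotype)) < 2 || length(unique(d$water)) < 2)
        next
      wf <- fit_nb_glm(fitness ~ phenotype * water, d)
      wr <- fit_nb_glm(fitness ~ phenotype + water, d)
      water_tests[[h]] <- lr_interaction_test(wf, wr)
    }
  }

  mortality <- list()
  for (cause in c("burial", "herbivory")) {
    tab <- mortality_table(T, cause)
    if (any(dim(tab) < 2) || sum(tab[, , 2]) == 0) next
    st <- backward_stepwise(tab)
    mortality[[cause]] <- list(trail = st$trail,
                               final_model = vapply(
                                 st$model, .term_label, character(1),
                                 dnn = names(dimnames(tab))),
                               G2 = st$fit$G2, df = st$fit$df)
  }
  cfg <- list(B = B, seed = seed, n_plants = nrow(T))
  summary <- list(n_plants = nrow(T),
                  interaction_lr = lr$lr, interaction_df = lr$df,
                  interaction_p = lr$p_value,
                  config_hash = .config_hash(cfg),
                  package_version = as.character(
                    utils::packageVersion("hybzone")))
  out <- structure(list(fitness = fs, interaction_test = lr,
                        water_tests = water_tests, mortality = mortality,
                        summary = summary),
                   class = "transplant_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(fs), file.path(out_dir, "fitness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_json(list(interaction_test = lr, water_tests = water_tests,
                     mortality = mortality, summary = summary),
                file.path(out_dir, "transplant_report.json"))
  }
  out
}
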