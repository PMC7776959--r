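#' Allele-origin distributions of the six hybrid-zone categories
#'
#' Rows are classes; columns are the probabilities that, at a locus, the
#' two allele copies descend (both from pool 1, one from each pool, both
#' from pool 2). These weights define both the classifier model and the
#' genotype simulator.
#' @keywords internal
hz_origin_weights <- rbind(
  P1  = c(1,    0,   0),
  P2  = c(0,    0,   1),
  F1  = c(0,    1,   0),
  F2  = c(0.25, 0.5, 0.25),
  BC1 = c(0.5,  0.5, 0),
  BC2 = c(0,    0.5, 0.5)
)
colnames(hz_origin_weights) <- c("both_P1", "one_each", "both_P2")

hz_classes <- rownames(hz_origin_weights)

#' True admixture proportion (toward pool 1) of each category
#' @keywords internal
hz_true_q <- c(P1 = 1, P2 = 0, F1 = 0.5, F2 = 0.5, BC1 = 0.75, BC2 = 0.25)

#' Simulation configuration for a synthetic hybrid zone
#'
#' Bundles every tunable of the generator. Defaults describe a two-species
#' ecotone comparable in scale to a desert/dune transition: a 300-m
#' transect, a 100-m-wide ancestry cline centred on the ecotone midline,
#' strongly divergent parental gene pools (mean allele-frequency
#' differential 0.6), and a 3 habitat x 3 phenotype reciprocal-transplant
#' design of about 30 plants per cell.
#'
#' @param n_loci number of biallelic loci.
#' @param divergence either `list(a=, b=)` for `f1 ~ Beta(a, b)` and
#'   `f2 ~ Beta(b, a)` draws, or `list(f1=, f2=)` fixed frequency vectors
#'   (recycled to `n_loci`).
#' @param class_counts named integer vector over
#'   `P1, P2, F1, F2, BC1, BC2` giving query individuals per category.
#' @param ref_counts named integer vector `c(P1=, P2=)` of pure reference
#'   individuals per parental panel.
#' @param cline list with `center`, `width` (m), tails `pmin`, `pmax`,
#'   Beta `concentration` of individual ancestry around the cline
#'   expectation, and transect `span` (m).
#' @param transplant list with `n_per_cell`, `cells` (a data.frame as
#'   returned by [default_transplant_cells()]), and `biomass_model`
#'   (`"lognormal"` or `"nbinom"`).
#' @param seed integer seed; fixes every draw of the generators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 1000,
                       divergence = list(a = 8, b = 2),
                       class_counts = c(P1 = 20, P2 = 20, F1 = 20,
                                        F2 = 10, BC1 = 10, BC2 = 10),
                       ref_counts = c(P1 = 20, P2 = 20),
                       cline = list(center = 0, width = 100, pmin = 0.02,
                                    pmax = 0.98, concentration = 50,
                                    span = 300),
                       transplant = list(n_per_cell = 30,
                                         cells = default_transplant_cells(),
                                         biomass_model = "lognormal"),
                       seed = NULL) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (!all(names(class_counts) %in% hz_classes))
    stop("invalid class name in class_counts: ",
         paste(setdiff(names(class_counts), hz_classes), collapse = ", "))
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  if (!is.null(cline$width) && cline$width <= 0) stop("cline width must be > 0")
  for (p in c("pmin", "pmax"))
    if (!is.null(cline[[p]]) && (cline[[p]] < 0 || cline[[p]] > 1))
      stop(p, " must lie in [0, 1]")
  cfg <- list(n_loci = n_loci, divergence = divergence,
              class_counts = class_counts, ref_counts = ref_counts,
              cline = cline, transplant = transplant, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

.draw_frequencies <- function(cfg) {
  d <- cfg$divergence
  if (!is.null(d$f1)) {
    list(f1 = rep_len(d$f1, cfg$n_loci), f2 = rep_len(d$f2, cfg$n_loci))
  } else {
    list(f1 = stats::rbeta(cfg$n_loci, d$a, d$b),
         f2 = stats::rbeta(cfg$n_loci, d$b, d$a))
  }
}

.sim_individual <- function(cls, f1, f2) {
  w <- hz_origin_weights[cls, ]
  L <- length(f1)
  z <- sample.int(3L, L, replace = TRUE, prob = w)
  g <- integer(L)
  i1 <- z == 1L; i2 <- z == 2L; i3 <- z == 3L
  if (any(i1)) g[i1] <- stats::rbinom(sum(i1), 2, f1[i1])
  if (any(i2)) g[i2] <- stats::rbinom(sum(i2), 1, f1[i2]) +
      stats::rbinom(sum(i2), 1, f2[i2])
  if (any(i3)) g[i3] <- stats::rbinom(sum(i3), 2, f2[i3])
  g
}

#' Simulate genotypes for a hybrid zone
#'
#' Draws parental allele frequencies, pure reference panels for both
#' pools, and query individuals of the requested categories. Each query
#' genotype is generated by first drawing the two allele-origin states
#' from the category's origin distribution ([hz_origin_weights]) and then
#' drawing alleles from `f1`/`f2` accordingly. Reference individuals are
#' placed on the outer transect (desert side for pool 1, dune side for
#' pool 2); query parentals sit on their own side and admixed classes near
#' the ecotone.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `G` ([genotype_matrix()]), `S`
#'   ([sample_frame()]), and `truth` (`true_class`, `true_q`, `f1`, `f2`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (!length(cfg$class_counts) || sum(cfg$class_counts) == 0)
    stop("class_counts must request at least one individual")
  fr <- .draw_frequencies(cfg)
  half <- cfg$cline$span / 2

  ids <- character(0); cls <- character(0); role <- character(0)
  pos <- numeric(0)
  add <- function(n, label, r, lo, hi) {
    if (n <= 0) return(invisible(NULL))
    ids <<- c(ids, sprintf("%s_%s_%02d", r, label, seq_len(n)))
    cls <<- c(cls, rep(label, n))
    role <<- c(role, rep(r, n))
    pos <<- c(pos, stats::runif(n, lo, hi))
    invisible(NULL)
  }
  add(cfg$ref_counts[["P1"]], "P1", "reference_P1", -half, -0.4 * half)
  add(cfg$ref_counts[["P2"]], "P2", "reference_P2", 0.4 * half, half)
  spans <- list(P1 = c(-half, -15), P2 = c(15, half),
                F1 = c(-10, 10), F2 = c(-10, 10),
                BC1 = c(-20, 10), BC2 = c(-10, 20))
  for (cl in names(cfg$class_counts))
    add(cfg$class_counts[[cl]], cl, "query", spans[[cl]][1], spans[[cl]][2])

  G <- t(vapply(cls, .sim_individual, integer(cfg$n_loci),
                f1 = fr$f1, f2 = fr$f2))
  rownames(G) <- ids
  G <- genotype_matrix(G, sample_ids = ids,
                       locus_ids = sprintf("l%04d", seq_len(cfg$n_loci)))
  habitat <- ifelse(pos < -10, "desert", ifelse(pos > 10, "dune", "ecotone"))
  S <- sample_frame(ids, pos, habitat, role)
  list(G = G, S = S,
       truth = list(true_class = stats::setNames(cls, ids),
                    true_q = stats::setNames(unname(hz_true_q[cls]), ids),
                    f1 = fr$f1, f2 = fr$f2))
}

#' Simulate individual ancestries along a transect
#'
#' Positions are uniform over the transect span; the expected ancestry
#' follows the tanh cline ([cline_expected()]); individual ancestry is
#' Beta-distributed around the expectation with the configured
#' concentration (shape1 = p*conc, shape2 = (1-p)*conc), which keeps
#' draws in `[0, 1]`.
#'
#' @param cfg a [sim_config()].
#' @param n_individuals number of individuals to place.
#' @return A list with `position`, `q` (individual draws), and `expected`
#'   (the cline expectation at each position).
#' @export
simulate_transect <- function(cfg, n_individuals) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cl <- cfg$cline
  if (cl$width <= 0) stop("cline width must be > 0")
  pos <- stats::runif(n_individuals, -cl$span / 2, cl$span / 2)
  p <- cline_expected(pos, cl$center, cl$width, cl$pmin, cl$pmax)
  nu <- cl$concentration
  q <- stats::rbeta(n_individuals, p * nu, (1 - p) * nu)
  list(position = pos, q = q, expected = p)
}

#' Expected mean of ln(1 + biomass) under a lognormal biomass model
#'
#' Computed by numerical integration of `ln(1 + exp(z))` against the
#' normal density of `z = ln(biomass)`; used both to parameterise the
#' generator and as an independent truth oracle in tests.
#'
#' @param meanlog,sdlog lognormal parameters of biomass.
#' @return Expected value of `log1p(biomass)`.
#' @export
expected_ln1p_lognormal <- function(meanlog, sdlog) {
  stats::integrate(function(z) log1p(exp(z)) * stats::dnorm(z, meanlog, sdlog),
                   meanlog - 8 * sdlog, meanlog + 8 * sdlog,
                   rel.tol = 1e-10)$value
}

.meanlog_for_growth <- function(target, sdlog) {
  stats::uniroot(function(m) expected_ln1p_lognormal(m, sdlog) - target,
                 c(-10, 10), tol = 1e-9)$root
}

#' Default habitat x phenotype transplant cell parameters
#'
#' The stated world of the generator: parental survival below 10% in the
#' nonnative habitat, and per-cell expected growth solved numerically so
#' that the expected composite fitness reproduces selection coefficients
#' of 0.983 (P1 in dune), 0.755 (P2 in desert), 0.702/0.097 (hybrids in
#' dune/desert) and 0.582/0.460 (P1/P2 in ecotone), with hybrids fittest
#' in the ecotone. Burial mortality is absent in the desert and never
#' affects the dune phenotype (P2); herbivory occurs in all habitats.
#'
#' @param sdlog lognormal biomass dispersion (log scale), default 0.5.
#' @return A data.frame with one row per habitat x phenotype cell:
#'   survival probability `p_surv`, lognormal biomass `meanlog`/`sdlog`,
#'   cause-of-death probabilities `p_burial`, `p_herbivory`, `p_other`
#'   (conditional on death), and the implied expected composite fitness
#'   `composite_true`.
#' @export
default_transplant_cells <- function(sdlog = 0.5) {
  cells <- expand.grid(habitat = .habitats, phenotype = .phenotypes,
                       stringsAsFactors = FALSE)
  surv <- c(desert.P1 = 0.60, desert.HYB = 0.55, desert.P2 = 0.09,
            ecotone.P1 = 0.35, ecotone.HYB = 0.60, ecotone.P2 = 0.40,
            dune.P1 = 0.03, dune.HYB = 0.30, dune.P2 = 0.60)
  comp <- c(desert.P1 = 1.2, desert.HYB = 1.2 * (1 - 0.097),
            desert.P2 = 1.2 * (1 - 0.755),
            ecotone.HYB = 1.3, ecotone.P1 = 1.3 * (1 - 0.582),
            ecotone.P2 = 1.3 * (1 - 0.460),
            dune.P2 = 1.4, dune.HYB = 1.4 * (1 - 0.702),
            dune.P1 = 1.4 * (1 - 0.983))
  key <- paste(cells$habitat, cells$phenotype, sep = ".")
  cells$p_surv <- unname(surv[key])
  cells$composite_true <- unname(comp[key])
  cells$meanlog <- vapply(seq_len(nrow(cells)), function(i)
    .meanlog_for_growth(cells$composite_true[i] / cells$p_surv[i], sdlog),
    numeric(1))
  cells$sdlog <- sdlog
  burial <- c(desert = 0, ecotone = 0.12, dune = 0.35)
  herb <- c(desert = 0.30, ecotone = 0.20, dune = 0.20)
  cells$p_burial <- unname(burial[cells$habitat])
  cells$p_herbivory <- unname(herb[cells$habitat])
  cells$p_burial[cells$phenotype == "P2"] <- 0
  cells$p_other <- 1 - cells$p_burial - cells$p_herbivory
  cells
}

#' Simulate a reciprocal-transplant outcome table
#'
#' Survival is Bernoulli per cell; biomass is lognormal (default) or
#' negative binomial with the cell mean; non-survivors draw a death cause
#' from the cell's multinomial over burial/herbivory/other. Dead plants
#' carry the biomass they had accumulated at death (drawn with the cell's
#' location shifted down one log unit).
#'
#' @param cfg a [sim_config()].
#' @param water water treatment label recorded for all plants
#'   (`"ambient"` default); cell parameters are taken as given.
#' @return A [transplant_table()]. True per-cell expected composite
#'   fitness is attached as attribute `"truth"`.
#' @export
simulate_transplant <- function(cfg, water = "ambient") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tp <- cfg$transplant
  cells <- tp$cells
  need <- c("habitat", "phenotype", "p_surv", "meanlog", "sdlog",
            "p_burial", "p_herbivory", "p_other")
  if (!all(need %in% names(cells)))
    stop("transplant cells must provide: ", paste(need, collapse = ", "))
  bad <- abs(cells$p_burial + cells$p_herbivory + cells$p_other - 1) > 1e-8
  if (any(bad)) stop("cause probabilities must sum to 1 in every cell")
  n <- tp$n_per_cell
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    surv <- stats::rbinom(n, 1, ci$p_surv)
    if (identical(tp$biomass_model, "nbinom")) {
      mu <- exp(ci$meanlog + ci$sdlog^2 / 2)
      biomass <- stats::rnbinom(n, size = 2, mu = mu)
      biomass[surv == 0] <- stats::rnbinom(sum(surv == 0), size = 2,
                                           mu = mu * exp(-1))
    } else {
      biomass <- stats::rlnorm(n, ci$meanlog, ci$sdlog)
      biomass[surv == 0] <- stats::rlnorm(sum(surv == 0), ci$meanlog - 1,
                                          ci$sdlog)
    }
    cause <- rep("alive", n)
    ndead <- sum(surv == 0)
    if (ndead)
      cause[surv == 0] <- sample(c("burial", "herbivory", "other"), ndead,
                                 replace = TRUE,
                                 prob = c(ci$p_burial, ci$p_herbivory,
                                          ci$p_other))
    rows[[i]] <- data.frame(
      plant_id = sprintf("%s_%s_%03d", ci$habitat, ci$phenotype, seq_len(n)),
      phenotype = ci$phenotype, habitat = ci$habitat, water = water,
      survived = surv, biomass = biomass, death_cause = cause,
      stringsAsFactors = FALSE)
  }
  out <- transplant_table(do.call(rbind, rows))
  if (!is.null(cells$composite_true)) {
    truth <- cells[, c("habitat", "phenotype", "composite_true")]
    best <- stats::ave(truth$composite_true, truth$habitat, FUN = max)
    truth$s_true <- 1 - truth$composite_true / best
    attr(out, "truth") <- truth
  }
  out
}
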