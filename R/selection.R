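#' Per-plant composite fitness
#'
#' The study's fitness proxy: binary survival multiplied by
#' `ln(1 + biomass)`. Plants that died contribute 0 (not missing);
#' survivors with zero biomass also score 0.
#'
#' @param T a [transplant_table()].
#' @return Numeric vector, one value per plant.
#' @export
composite_fitness <- function(T) {
  if (any(T$biomass < 0)) stop("biomass must be >= 0")
  T$survived * log1p(T$biomass)
}

#' Selection coefficients per habitat x phenotype with bootstrap CIs
#'
#' Cell means of composite fitness are standardised within each habitat
#' by the fittest phenotype (relative fitness), and the selection
#' coefficient is `s = 1 - relative fitness`, so exactly one phenotype
#' per habitat has `s = 0`. Percentile bootstrap intervals (simple
#' 2.5/97.5 percentiles by default) resample plants within cells (or
#' within habitats) and are truncated to the unit interval. A habitat whose best
#' cell mean is 0 has undefined relative fitness and reports `NA`.
#'
#' @param T a [transplant_table()].
#' @param B bootstrap replicates (default 1000; 0 skips the CIs).
#' @param seed seed for the bootstrap (required when `B > 0`).
#' @param conf confidence level.
#' @param resample `"cell"` (default) or `"habitat"`.
#' @return A data.frame of class `fitness_summary`, one row per cell:
#'   `habitat`, `phenotype`, `n`, `survival_frac`, `mean_growth`
#'   (mean ln(1+biomass)), `composite` (cell mean composite fitness),
#'   `relative_w`, `s`, `ci_lo`, `ci_hi` (bootstrap CI for `s`,
#'   truncated to the unit interval).
#' @export
selection_coefficients <- function(T, B = 1000, seed = NULL, conf = 0.95,
                                   resample = c("cell", "habitat")) {
  resample <- match.arg(resample)
  T <- transplant_table(as.data.frame(T))
  habs <- unique(T$habitat)
  for (h in habs)
    if (length(unique(T$phenotype[T$habitat == h])) < 2)
      stop("habitat '", h, "' has fewer than 2 phenotypes")
  fit <- composite_fitness(T)

  cell_stats <- function(fitv, idx) {
    agg <- stats::aggregate(
      list(composite = fitv[idx]),
      by = list(habitat = T$habitat[idx], phenotype = T$phenotype[idx]),
      FUN = mean)
    best <- stats::ave(agg$composite, agg$habitat, FUN = max)
    agg$relative_w <- ifelse(best > 0, agg$composite / best, NA_real_)
    agg$s <- 1 - agg$relative_w
    agg
  }
  obs <- cell_stats(fit, seq_len(nrow(T)))
  extra <- stats::aggregate(
    list(n = seq_len(nrow(T)), survival_frac = T$survived,
         mean_growth = log1p(T$biomass)),
    by = list(habitat = T$habitat, phenotype = T$phenotype),
    FUN = function(v) if (length(v)) mean(v) else NA_real_)
  extra$n <- as.integer(stats::aggregate(
    list(n = rep(1L, nrow(T))),
    by = list(habitat = T$habitat, phenotype = T$phenotype), FUN = sum)$n)
  obs <- merge(extra, obs, by = c("habitat", "phenotype"))

  obs$ci_lo <- NA_real_; obs$ci_hi <- NA_real_
  if (B > 0) {
    if (is.null(seed)) stop("a seed is required for the bootstrap")
    set.seed(seed)
    groups <- if (resample == "cell")
      interaction(T$habitat, T$phenotype, drop = TRUE) else factor(T$habitat)
    gidx <- split(seq_len(nrow(T)), groups)
    smat <- matrix(NA_real_, nrow = B, ncol = nrow(obs))
    key <- paste(obs$habitat, obs$phenotype)
    for (b in seq_len(B)) {
      idx <- unlist(lapply(gidx, function(ii)
        ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
      st <- cell_stats(fit, idx)
      smat[b, ] <- st$s[match(key, paste(st$habitat, st$phenotype))]
    }
    alpha <- (1 - conf) / 2
    qs <- apply(smat, 2, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE)
    obs$ci_lo <- pmin(pmax(qs[1, ], 0), 1)
    obs$ci_hi <- pmin(pmax(qs[2, ], 0), 1)
  }
  obs <- obs[order(obs$habitat, obs$phenotype), ]
  rownames(obs) <- NULL
  class(obs) <- c("fitness_summary", "data.frame")
  obs
}

#' Negative binomial GLM (log link) on a fitness response
#'
#' Wraps `MASS::glm.nb`, the routine used for the source analysis, with
#' dispersion estimated by profile maximum likelihood inside IRLS.
#' Non-integer responses (e.g. `ln(1+x)`-transformed biomass) are
#' accepted in the quasi-likelihood sense — this mirrors the analysis
#' being replicated and is flagged in the documentation as unusual. A
#' Gamma GLM (log link) is offered as a conventional alternative for
#' strictly positive responses.
#'
#' @param formula model formula; response must be non-negative.
#' @param data data.frame with the response and design columns.
#' @param family `"negbin"` (default) or `"gamma"`.
#' @return A list of class `hz_glm`: `coefficients` (matrix with
#'   estimates and standard errors), `theta` (NB dispersion, `NA` for
#'   Gamma), `deviance`, `loglik`, `df`, `formula`, and the underlying
#'   `model` object.
#' @export
fit_nb_glm <- function(formula, data, family = c("negbin", "gamma")) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0)) stop("response must be non-negative")
  X <- stats::model.matrix(formula, data)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  cells <- apply(X, 1, paste, collapse = "/")
  zero_cells <- tapply(y, cells, function(v) all(v == 0))
  if (any(zero_cells)) warning("all-zero response in some design cell(s)")
  if (family == "negbin") {
    m <- tryCatch(suppressWarnings(MASS::glm.nb(formula, data = data)),
                  error = function(e) NULL)
    if (is.null(m)) {
      # theta.ml can diverge on sparse cells; fall back to a moment
      # estimate of the dispersion with a fixed-theta NB fit
      mu <- mean(y); v <- stats::var(y)
      th <- if (v > mu && mu > 0) mu^2 / (v - mu) else 100
      warning("NB dispersion estimation failed; using moment estimate theta = ",
              signif(th, 3))
      m <- suppressWarnings(stats::glm(formula, data = data,
                                       family = MASS::negative.binomial(th)))
      m$theta <- th
    }
    theta <- m$theta
  } else {
    if (any(y <= 0)) stop("gamma family requires a strictly positive response")
    m <- stats::glm(formula, data = data, family = stats::Gamma(link = "log"))
    theta <- NA_real_
  }
  cf <- summary(m)$coefficients
  structure(list(coefficients = cf[, 1:2, drop = FALSE], theta = theta,
                 deviance = stats::deviance(m),
                 loglik = as.numeric(stats::logLik(m)),
                 df = length(stats::coef(m)),
                 formula = stats::formula(formula), model = m),
            class = "hz_glm")
}

#' Likelihood-ratio test between nested GLMs
#'
#' `LR = 2 * (loglik_full - loglik_reduced)` referred to a chi-square
#' with degrees of freedom equal to the difference in mean-model
#' parameter counts. The reduced model's terms must be a subset of the
#' full model's.
#'
#' @param full,reduced fits from [fit_nb_glm()].
#' @return A list: `lr`, `df`, `p_value`.
#' @export
lr_interaction_test <- function(full, reduced) {
  tf <- attr(stats::terms(full$formula), "term.labels")
  tr <- attr(stats::terms(reduced$formula), "term.labels")
  if (!all(tr %in% tf))
    stop("models are not nested: reduced terms must be a subset of full terms")
  lr <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$df - reduced$df
  if (df < 0) stop("reduced model has more parameters than the full model")
  p <- if (df == 0) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  list(lr = lr, df = df, p_value = p)
}
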