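#' Three-way mortality contingency table from a transplant table
#'
#' Cross-tabulates habitat x phenotype x outcome for one death cause,
#' where outcome is "died of that cause" vs "did not" (survivors and
#' other deaths pooled), the tabulation used for cause-specific
#' log-linear analysis.
#'
#' @param T a [transplant_table()].
#' @param cause `"burial"` or `"herbivory"` (any recorded cause works).
#' @return A 3-dimensional table (habitat, phenotype, outcome).
#' @export
mortality_table <- function(T, cause = "burial") {
  out <- factor(ifelse(T$death_cause == cause, cause, "not"),
                levels = c("not", cause))
  table(habitat = factor(T$habitat, levels = intersect(.habitats, T$habitat)),
        phenotype = factor(T$phenotype),
        outcome = out)
}

.normalize_margins <- function(margins, ndim) {
  margins <- lapply(margins, function(m) sort(unique(as.integer(m))))
  if (any(vapply(margins, function(m)
    any(m < 1 | m > ndim), logical(1))))
    stop("margin indices out of range")
  # drop margins that are subsets of another (redundant in a generating class)
  keep <- vapply(seq_along(margins), function(i)
    !any(vapply(seq_along(margins), function(j)
      i != j && all(margins[[i]] %in% margins[[j]]) &&
        length(margins[[i]]) < length(margins[[j]]), logical(1))),
    logical(1))
  unique(margins[keep])
}

.model_df <- function(dims, margins) {
  subsets <- list(integer(0))
  for (m in margins) {
    idx <- seq_along(m)
    for (k in seq_along(m))
      subsets <- c(subsets, utils::combn(m, k, simplify = FALSE))
  }
  subsets <- unique(lapply(subsets, sort))
  n_par <- sum(vapply(subsets, function(s)
    if (!length(s)) 1 else prod(dims[s] - 1), numeric(1)))
  prod(dims) - n_par
}

#' Fit a hierarchical log-linear model by iterative proportional fitting
#'
#' IPF successively scales a fitted table to match each observed margin
#' named in the generating class, iterating until every fitted margin
#' agrees with its observed margin to within `tol`. The deviance is
#' `G^2 = 2 * sum(obs * log(obs / fitted))` over cells with positive
#' observed counts, and degrees of freedom follow the standard
#' hierarchical parameter count. Sampling zeros are tolerated (nothing is
#' added to the table); a margin term is redundant if it is a subset of
#' another and is dropped.
#'
#' @param counts a non-negative integer array (the 3-way tables of this
#'   package, but any dimensionality works).
#' @param margins list of integer vectors, the generating class (e.g.
#'   `list(c(1, 2), 3)` for habitat x phenotype jointly and outcome
#'   independent).
#' @param tol convergence tolerance on margin discrepancies.
#' @param max_iter maximum IPF sweeps.
#' @return A list of class `ipf_fit`: `fitted`, `G2`, `df`, `margins`,
#'   `converged`, `iterations`.
#' @export
ipf_fit <- function(counts, margins, tol = 1e-8, max_iter = 2000) {
  counts <- as.array(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  dims <- dim(counts)
  margins <- .normalize_margins(margins, length(dims))
  if (!length(margins)) stop("empty model specification")
  obs_m <- lapply(margins, function(m) apply(counts, m, sum))
  fit <- array(sum(counts) / prod(dims), dim = dims, dimnames = dimnames(counts))
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    for (k in seq_along(margins)) {
      m <- margins[[k]]
      cur <- apply(fit, m, sum)
      ratio <- obs_m[[k]] / cur
      ratio[!is.finite(ratio)] <- 0
      fit <- sweep(fit, m, ratio, `*`)
    }
    disc <- max(vapply(seq_along(margins), function(k)
      max(abs(apply(fit, margins[[k]], sum) - obs_m[[k]])), numeric(1)))
    if (disc < tol) { converged <- TRUE; break }
  }
  pos <- counts > 0
  G2 <- 2 * sum(counts[pos] * log(counts[pos] / fit[pos]))
  structure(list(fitted = fit, G2 = G2, df = .model_df(dims, margins),
                 margins = margins, converged = converged, iterations = it),
            class = "ipf_fit")
}

.term_label <- function(m, dnn) {
  if (is.null(dnn)) paste(m, collapse = ":")
  else paste(dnn[m], collapse = ":")
}

.reduce_class <- function(margins) {
  keep <- vapply(seq_along(margins), function(i)
    !any(vapply(seq_along(margins), function(j)
      i != j && all(margins[[i]] %in% margins[[j]]) &&
        (length(margins[[i]]) < length(margins[[j]]) || i > j),
      logical(1))), logical(1))
  margins[keep]
}

#' Backward stepwise selection of a hierarchical log-linear model
#'
#' Starting from the saturated model, repeatedly drop the highest-order
#' term whose removal gives the largest likelihood-ratio p-value above
#' `alpha`, respecting hierarchy (a term is removable only if it is
#' maximal in the current generating class); main effects are never
#' removed. The first candidate from a 3-way table is the three-way
#' interaction, so the first trail row is the habitat x phenotype x
#' outcome test. A removal whose IPF fit fails (structural zeros) is
#' flagged and the term is kept.
#'
#' @param counts a contingency-table array (see [ipf_fit()]).
#' @param alpha retention threshold on the removal p-value.
#' @return A list of class `loglin_stepwise`: `model` (final generating
#'   class, as index vectors), `fit` (its [ipf_fit()]), and `trail`, a
#'   data.frame of candidate removals actually taken or refused:
#'   `term`, `delta_G2`, `df`, `p_value`, `removed`, `flagged`.
#' @export
backward_stepwise <- function(counts, alpha = 0.05) {
  counts <- as.array(counts)
  dims <- dim(counts)
  dnn <- names(dimnames(counts))
  current <- list(seq_along(dims))
  cur_fit <- ipf_fit(counts, current)
  trail <- data.frame(term = character(0), delta_G2 = numeric(0),
                      df = integer(0), p_value = numeric(0),
                      removed = logical(0), flagged = logical(0))
  repeat {
    removable <- Filter(function(m) length(m) >= 2, current)
    if (!length(removable)) break
    cands <- lapply(removable, function(t) {
      rest <- current[!vapply(current, identical, logical(1), t)]
      facets <- utils::combn(t, length(t) - 1, simplify = FALSE)
      .reduce_class(c(rest, facets))
    })
    stats_ <- lapply(seq_along(removable), function(i) {
      f <- ipf_fit(counts, cands[[i]])
      flagged <- !f$converged || !is.finite(f$G2)
      dG2 <- f$G2 - cur_fit$G2
      ddf <- f$df - cur_fit$df
      p <- if (flagged || ddf <= 0) NA_real_
           else stats::pchisq(max(dG2, 0), ddf, lower.tail = FALSE)
      list(fit = f, dG2 = dG2, ddf = ddf, p = p, flagged = flagged)
    })
    ps <- vapply(stats_, function(s)
      if (is.na(s$p)) -Inf else s$p, numeric(1))
    best <- which.max(ps)
    s <- stats_[[best]]
    rm_ok <- is.finite(ps[best]) && ps[best] > alpha
    trail <- rbind(trail, data.frame(
      term = .term_label(removable[[best]], dnn),
      delta_G2 = s$dG2, df = s$ddf, p_value = s$p,
      removed = rm_ok, flagged = s$flagged))
    if (!rm_ok) break
    current <- cands[[best]]
    cur_fit <- s$fit
  }
  structure(list(model = current, fit = cur_fit, trail = trail),
            class = "loglin_stepwise")
}

#' Likelihood-ratio comparison of two hierarchical log-linear models
#'
#' The default comparison is the saturated model against the model with
#' all two-way terms but no three-way term — the habitat x phenotype x
#' outcome interaction test.
#'
#' @param counts contingency-table array.
#' @param full,reduced generating classes (lists of index vectors);
#'   defaults as described.
#' @return A list: `lr` (the G^2 difference), `df`, `p_value`, and both
#'   [ipf_fit()]s.
#' @export
loglin_lr_test <- function(counts,
                           full = list(seq_along(dim(as.array(counts)))),
                           reduced = utils::combn(
                             seq_along(dim(as.array(counts))),
                             length(dim(as.array(counts))) - 1,
                             simplify = FALSE)) {
  f <- ipf_fit(counts, full)
  r <- ipf_fit(counts, reduced)
  lr <- r$G2 - f$G2
  df <- r$df - f$df
  if (df <= 0) stop("models are not nested (non-positive df difference)")
  list(lr = lr, df = df,
       p_value = stats::pchisq(max(lr, 0), df, lower.tail = FALSE),
       fit_full = f, fit_reduced = r)
}
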