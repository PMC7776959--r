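#' Supervised admixture-proportion estimate for one individual
#'
#' Maximum-likelihood estimate of the admixture proportion q toward
#' parental pool 1, holding the parental allele frequencies fixed
#' (supervised two-pool model). The per-locus model is
#' `g_l ~ Binomial(2, pi_l)` with `pi_l = q*f1_l + (1-q)*f2_l`; since
#' `pi` is affine in q the log-likelihood is concave and a bounded 1-D
#' optimiser suffices. The standard error comes from the observed Fisher
#' information at the optimum and is `NA` when the optimum sits on the
#' boundary of `[0, 1]`.
#'
#' @param g dosage vector (values 0/1/2 or `NA`). If named, entries are
#'   matched to `freqs$locus_id`; otherwise positions must align.
#' @param freqs a [parental_frequencies()] object (or data.frame with
#'   `f1`, `f2`).
#' @param min_loci minimum usable (non-missing, frequency-known) loci.
#' @param tol optimiser tolerance on q.
#' @return A list of class `ancestry_estimate`: `q`, `se`, `loglik`,
#'   `n_loci_used`.
#' @export
estimate_q <- function(g, freqs, min_loci = 50, tol = 1e-6) {
  al <- .align_loci(g, freqs)
  g <- al$g; f1 <- al$f1; f2 <- al$f2
  use <- !is.na(g)
  if (!any(use)) stop("all loci missing: cannot estimate q")
  if (sum(use) < min_loci)
    stop(sprintf("only %d usable loci (< min_loci = %d)", sum(use), min_loci))
  g <- g[use]; f1 <- f1[use]; f2 <- f2[use]
  ll <- function(q) {
    pi <- q * f1 + (1 - q) * f2
    pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
    sum(g * log(pi) + (2 - g) * log1p(-pi))
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = tol)
  cand_q <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, ll(0), ll(1))
  best <- which.max(cand_ll)
  qhat <- cand_q[best]; llhat <- cand_ll[best]
  se <- NA_real_
  if (qhat > tol && qhat < 1 - tol) {
    d <- f1 - f2
    pi <- qhat * f1 + (1 - qhat) * f2
    info <- sum(d^2 * (g / pi^2 + (2 - g) / (1 - pi)^2))
    if (is.finite(info) && info > 0) se <- 1 / sqrt(info)
  }
  structure(list(q = qhat, se = se, loglik = llhat, n_loci_used = length(g)),
            class = "ancestry_estimate")
}

.align_loci <- function(g, freqs) {
  if (!is.null(names(g))) {
    idx <- match(freqs$locus_id, names(g))
    ok <- !is.na(idx)
    list(g = as.numeric(g[idx[ok]]), f1 = freqs$f1[ok], f2 = freqs$f2[ok])
  } else {
    if (length(g) != nrow(freqs))
      stop("unnamed dosage vector must match the frequency table length")
    list(g = as.numeric(g), f1 = freqs$f1, f2 = freqs$f2)
  }
}

#' Ancestry estimates for every individual in a genotype matrix
#'
#' Individuals with fewer than `min_loci` usable loci are flagged: their
#' estimates are `NA` and a warning lists them.
#'
#' @inheritParams estimate_q
#' @param G a [genotype_matrix()].
#' @return A data.frame with columns `sample_id`, `q`, `se`, `loglik`,
#'   `n_loci_used`.
#' @export
estimate_ancestry <- function(G, freqs, min_loci = 50, tol = 1e-6) {
  res <- lapply(rownames(G), function(id) {
    g <- G[id, ]
    names(g) <- colnames(G)
    n_use <- sum(!is.na(g[freqs$locus_id]))
    if (n_use < min_loci)
      return(data.frame(sample_id = id, q = NA_real_, se = NA_real_,
                        loglik = NA_real_, n_loci_used = n_use))
    e <- estimate_q(g, freqs, min_loci = min_loci, tol = tol)
    data.frame(sample_id = id, q = e$q, se = e$se, loglik = e$loglik,
               n_loci_used = e$n_loci_used)
  })
  out <- do.call(rbind, res)
  flagged <- out$sample_id[is.na(out$q)]
  if (length(flagged))
    warning(length(flagged), " individual(s) below the usable-locus ",
            "threshold excluded: ",
            paste(utils::head(flagged, 5), collapse = ", "))
  out
}

#' Correlation between genetic and morphological admixture indices
#'
#' Pearson correlation with a two-sided p-value, on complete pairs.
#'
#' @param q numeric vector (e.g. admixture proportions).
#' @param m numeric vector (e.g. morphological hybrid indices), same order.
#' @return A list with `r`, `p_value`, `n`.
#' @export
genotype_morphology_correlation <- function(q, m) {
  if (length(q) != length(m)) stop("q and m must be paired")
  ok <- stats::complete.cases(q, m)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  q <- q[ok]; m <- m[ok]
  if (stats::sd(q) == 0 || stats::sd(m) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(q, m, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
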