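#' Genotype probability under a hybrid-zone category
#'
#' Standard two-generation category model: a class c has an allele-origin
#' distribution w(c) over (both alleles from pool 1, one from each pool,
#' both from pool 2) — see [hz_origin_weights]. Then
#' `P(g | c) = sum_z w_z(c) * P(g | z)` with `P(g | both-P1) =
#' Binom(g; 2, f1)`, `P(g | both-P2) = Binom(g; 2, f2)` and for the
#' one-each state `P(2) = f1*f2`, `P(1) = f1*(1-f2) + (1-f1)*f2`,
#' `P(0) = (1-f1)*(1-f2)`.
#'
#' @param g dosage value(s) in `{0, 1, 2}`.
#' @param f1,f2 parental frequencies of the counted allele, strictly
#'   inside (0, 1) (shrink upstream; exact 0/1 is a contract error).
#' @param cls one of `"P1","P2","F1","F2","BC1","BC2"`.
#' @return Probability vector, one entry per locus.
#' @examples
#' class_genotype_prob(1, 0.9, 0.1, "F1")  # 0.82
#' @export
class_genotype_prob <- function(g, f1, f2, cls) {
  if (!cls %in% hz_classes) stop("unknown class: ", cls)
  if (any(f1 <= 0 | f1 >= 1 | f2 <= 0 | f2 >= 1))
    stop("parental frequencies must lie strictly in (0,1); apply shrinkage")
  if (any(!g %in% 0:2)) stop("g must be 0, 1 or 2")
  w <- hz_origin_weights[cls, ]
  p_both1 <- stats::dbinom(g, 2, f1)
  p_both2 <- stats::dbinom(g, 2, f2)
  p_one <- ifelse(g == 2, f1 * f2,
                  ifelse(g == 1, f1 * (1 - f2) + (1 - f1) * f2,
                         (1 - f1) * (1 - f2)))
  unname(w[1] * p_both1 + w[2] * p_one + w[3] * p_both2)
}

#' Classify one individual into a parental or hybrid category
#'
#' Per-class log-likelihood summed over usable loci, combined with a
#' prior (uniform by default) in log space; the posterior is normalised
#' with log-sum-exp. Ties are broken by the deterministic preference
#' order P1, P2, F1, F2, BC1, BC2 with a warning — an exact tie means the
#' loci carry no information for the choice.
#'
#' @inheritParams estimate_q
#' @param prior named or positional six-vector of prior class
#'   probabilities, summing to 1.
#' @return A list of class `class_assignment`: `best_class`, `posterior`
#'   (named six-vector), `loglik_by_class`, `n_loci_used`.
#' @export
classify <- function(g, freqs, prior = rep(1 / 6, 6), min_loci = 50) {
  if (length(prior) != 6 || abs(sum(prior) - 1) > 1e-6)
    stop("prior must be a six-vector summing to 1")
  if (all(prior == 0)) stop("degenerate prior")
  if (is.null(names(prior))) names(prior) <- hz_classes
  al <- .align_loci(g, freqs)
  use <- !is.na(al$g)
  if (sum(use) < min_loci)
    stop(sprintf("only %d usable loci (< min_loci = %d)", sum(use), min_loci))
  g <- al$g[use]; f1 <- al$f1[use]; f2 <- al$f2[use]
  ll <- vapply(hz_classes, function(cl)
    sum(log(class_genotype_prob(g, f1, f2, cl))), numeric(1))
  lp <- ll + log(prior[hz_classes])
  lp[prior[hz_classes] == 0] <- -Inf
  m <- max(lp)
  post <- exp(lp - (m + log(sum(exp(lp - m)))))
  top <- which(lp >= max(lp) - 1e-9)  # tolerance absorbs float jitter in ties
  if (length(top) > 1)
    warning("tied classes (", paste(hz_classes[top], collapse = ", "),
            "); preferring ", hz_classes[top[1]])
  structure(list(best_class = hz_classes[top[1]], posterior = post,
                 loglik_by_class = ll, n_loci_used = length(g)),
            class = "class_assignment")
}

#' Classify every individual in a genotype matrix
#'
#' @inheritParams classify
#' @param G a [genotype_matrix()].
#' @return A data.frame with `sample_id`, `best_class`, `n_loci_used`,
#'   and one posterior column per class (`post_P1`, ...). Individuals
#'   below the usable-locus threshold get `NA` with a warning.
#' @export
classify_all <- function(G, freqs, prior = rep(1 / 6, 6), min_loci = 50) {
  res <- lapply(rownames(G), function(id) {
    g <- G[id, ]; names(g) <- colnames(G)
    n_use <- sum(!is.na(g[freqs$locus_id]))
    if (n_use < min_loci) {
      post <- rep(NA_real_, 6)
    } else {
      a <- classify(g, freqs, prior = prior, min_loci = min_loci)
      post <- unname(a$posterior)
    }
    df <- data.frame(sample_id = id,
                     best_class = if (n_use < min_loci) NA_character_ else
                       a$best_class,
                     n_loci_used = n_use)
    df[paste0("post_", hz_classes)] <- as.list(post)
    df
  })
  out <- do.call(rbind, res)
  flagged <- out$sample_id[is.na(out$best_class)]
  if (length(flagged))
    warning(length(flagged), " individual(s) below the usable-locus ",
            "threshold excluded from classification")
  out
}

#' Hybrid-zone composition by habitat
#'
#' Per-habitat proportions of parental, F1 and later-generation (F2/BC)
#' individuals among classified samples; "hybrid" covers F1, F2, BC1, BC2.
#' Habitats with zero classified samples are omitted with a message.
#'
#' @param assignments data.frame from [classify_all()] (needs
#'   `sample_id`, `best_class`).
#' @param S a [sample_frame()].
#' @return A data.frame with one row per habitat: `n`, `n_parental`,
#'   `n_F1`, `n_later` (F2 + backcrosses), `hybrid_frac`,
#'   `f1_frac_of_hybrids`.
#' @export
zone_composition <- function(assignments, S) {
  df <- merge(assignments, S[, c("sample_id", "habitat")], by = "sample_id")
  df <- df[!is.na(df$best_class), ]
  out <- lapply(.habitats, function(h) {
    d <- df[df$habitat == h, ]
    if (!nrow(d)) {
      message("habitat '", h, "' has no classified samples; omitted")
      return(NULL)
    }
    n_par <- sum(d$best_class %in% c("P1", "P2"))
    n_f1 <- sum(d$best_class == "F1")
    n_later <- sum(d$best_class %in% c("F2", "BC1", "BC2"))
    n_hyb <- n_f1 + n_later
    data.frame(habitat = h, n = nrow(d), n_parental = n_par, n_F1 = n_f1,
               n_later = n_later, hybrid_frac = n_hyb / nrow(d),
               f1_frac_of_hybrids = if (n_hyb) n_f1 / n_hyb else NA_real_)
  })
  do.call(rbind, out)
}
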