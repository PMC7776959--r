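#' Leaf-morphometric hybrid index per individual
#'
#' A scaled and centred principal component analysis over all leaves;
#' axis-1 scores are averaged per individual and then mapped affinely so
#' the parental reference centroids sit exactly at `-anchor` (pool 1) and
#' `+anchor` (pool 2). Averaging before or after the affine map is
#' equivalent; we average raw scores. Constant measurement columns are
#' dropped with a warning (they carry no shape information and break
#' scaling).
#'
#' @param M a [morph_table()].
#' @param S a [sample_frame()] containing the parental reference roles.
#' @param anchor half-distance between parental centroids on the index
#'   scale (default 2, so the conventional hybrid window is (-1, 1)).
#' @return A data.frame of class `hybrid_index` with `sample_id`,
#'   `index`, `n_leaves`; the axis-1 variance fraction is attached as
#'   attribute `"pc1_var_frac"`.
#' @export
leaf_pca_index <- function(M, S, anchor = 2) {
  M <- morph_table(M, samples = S)
  meas <- setdiff(names(M), c("sample_id", "leaf_id"))
  if (length(meas) < 2) stop("need at least 2 measurement columns")
  X <- as.matrix(M[meas])
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant measurement column(s): ",
            paste(meas[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 1) stop("no informative measurement columns")
  if (nrow(X) < 3) stop("need at least 3 leaves")
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  sc1 <- pr$x[, 1]
  per_sample <- tapply(sc1, M$sample_id, mean)
  ids <- names(per_sample)
  role <- S$role[match(ids, S$sample_id)]
  c1 <- mean(per_sample[role == "reference_P1"])
  c2 <- mean(per_sample[role == "reference_P2"])
  if (!is.finite(c1) || !is.finite(c2))
    stop("both parental reference centroids are required")
  if (abs(c2 - c1) < 1e-12)
    stop("parental centroids coincide: index undefined")
  mid <- (c1 + c2) / 2
  index <- (per_sample - mid) / (c2 - mid) * anchor
  out <- data.frame(sample_id = ids, index = as.numeric(index),
                    n_leaves = as.integer(table(M$sample_id)[ids]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pc1_var_frac") <- unname(pr$sdev[1]^2 / sum(pr$sdev^2))
  class(out) <- c("hybrid_index", "data.frame")
  out
}

#' Progeny hybridization rate with Wilson interval
#'
#' Fraction of seedlings whose hybrid index falls strictly inside the
#' hybrid window (default (-1, 1) on the +/-2-anchored index scale),
#' with a Wilson score 95% confidence interval.
#'
#' @param indices numeric hybrid indices of scored seedlings.
#' @param lower,upper open-interval bounds of the hybrid window.
#' @param conf confidence level (default 0.95).
#' @return A list: `rate`, `ci` (length-2), `n`, `n_hybrid`.
#' @export
progeny_hybrid_rate <- function(indices, lower = -1, upper = 1,
                                conf = 0.95) {
  indices <- indices[!is.na(indices)]
  n <- length(indices)
  if (n < 1) stop("need at least one scored seedling")
  k <- sum(indices > lower & indices < upper)
  ci <- suppressWarnings(stats::prop.test(k, n, conf.level = conf,
                                          correct = FALSE))$conf.int
  list(rate = k / n, ci = as.numeric(ci), n = n, n_hybrid = k)
}

#' Simulate a leaf morphometry table tied to ancestry
#'
#' Generates `k` shape descriptors plus an area column whose expectations
#' move linearly between parental phenotypes with the individual's
#' ancestry, with leaf-level Gaussian noise — the structure the PCA index
#' assumes (one dominant axis aligned with ancestry).
#'
#' @param q named ancestry vector (names are sample ids).
#' @param leaves_per_plant leaves measured per individual.
#' @param k number of shape descriptors beside area.
#' @param noise_sd leaf-level standard deviation of each descriptor.
#' @param seed optional seed.
#' @return A [morph_table()].
#' @export
simulate_morphology <- function(q, leaves_per_plant = 5, k = 3,
                                noise_sd = 0.4, seed = NULL) {
  if (is.null(names(q))) stop("q must be named by sample id")
  if (!is.null(seed)) set.seed(seed)
  n <- length(q)
  ids <- rep(names(q), each = leaves_per_plant)
  qq <- rep(q, each = leaves_per_plant)
  # parental trait poles: area larger in pool 1, descriptors alternate sign
  area <- 120 + 80 * qq + stats::rnorm(length(qq), 0, 25)
  area <- pmax(area, 1)
  shp <- sapply(seq_len(k), function(j) {
    pole <- (-1)^j * 2
    pole * (2 * qq - 1) + stats::rnorm(length(qq), 0, noise_sd)
  })
  colnames(shp) <- paste0("shape", seq_len(k))
  morph_table(data.frame(sample_id = ids,
                         leaf_id = paste0(ids, "_leaf",
                                          rep(seq_len(leaves_per_plant), n)),
                         area_mm2 = area, shp,
                         stringsAsFactors = FALSE))
}
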