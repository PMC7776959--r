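#' Sigmoid (tanh) cline expectation
#'
#' `p(x) = pmin + (pmax - pmin) * (1 + tanh(2 (x - center) / width)) / 2`.
#' `width` is the inverse of the maximum slope of the scaled cline, the
#' conventional geographic cline width.
#'
#' @param x position(s), meters from the ecotone midline.
#' @param center cline centre (m).
#' @param width cline width (m), > 0.
#' @param pmin,pmax tail levels (values approached at -Inf / +Inf).
#' @return Expected ancestry at `x`.
#' @export
cline_expected <- function(x, center, width, pmin, pmax) {
  pmin + (pmax - pmin) * (1 + tanh(2 * (x - center) / width)) / 2
}

#' Bin individuals into fixed-width transect bands
#'
#' Bands are anchored on the ecotone midline (position 0): band k covers
#' `(k*w, (k+1)*w]`-style half-open intervals via `floor(x / w)`. Empty
#' bands are dropped; band means are plain averages of member ancestries.
#'
#' @param q ancestry values, one per individual.
#' @param positions transect positions (m), same order.
#' @param band_width band width in meters (default 10).
#' @return A data.frame of class `band_series` with `band_center`,
#'   `mean_q`, `n`; member ancestries are kept in attribute `"members"`
#'   (a list, one vector per band) for bootstrap resampling.
#' @export
bin_transect <- function(q, positions, band_width = 10) {
  if (!length(q)) stop("no samples to bin")
  if (length(q) != length(positions)) stop("q and positions must be paired")
  if (band_width <= 0) stop("band_width must be > 0")
  if (any(!is.finite(positions))) stop("positions must be finite")
  ok <- !is.na(q)
  q <- q[ok]; positions <- positions[ok]
  if (!length(q)) stop("no samples with non-missing ancestry")
  idx <- floor(positions / band_width)
  members <- split(q, idx)
  centers <- (as.numeric(names(members)) + 0.5) * band_width
  out <- data.frame(band_center = centers,
                    mean_q = vapply(members, mean, numeric(1)),
                    n = lengths(members))
  out <- out[order(out$band_center), ]
  rownames(out) <- NULL
  attr(out, "members") <- members[order(centers)]
  attr(out, "band_width") <- band_width
  class(out) <- c("band_series", "data.frame")
  out
}

# Weighted least squares of y on the tanh shape S(x; c, w): the tails enter
# linearly (p = a + b*S), so for fixed (c, w) the profile solution is a 2x2
# weighted regression. Returns the weighted SSE and the implied tails.
.cline_profile <- function(cw, x, y, n) {
  S <- (1 + tanh(2 * (x - cw[1]) / exp(cw[2]))) / 2
  sw <- sum(n)
  sS <- sum(n * S); sy <- sum(n * y)
  sSS <- sum(n * S * S); sSy <- sum(n * S * y)
  den <- sSS - sS^2 / sw
  if (den < 1e-12) {
    a <- sy / sw; b <- 0
  } else {
    b <- (sSy - sS * sy / sw) / den
    a <- (sy - b * sS) / sw
  }
  r <- y - (a + b * S)
  list(sse = sum(n * r^2), a = a, b = b)
}

.cline_sse4 <- function(par, x, y, n) {
  # par = (center, log width, left tail, right tail)
  p <- cline_expected(x, par[1], exp(par[2]), par[3], par[4])
  sum(n * (y - p)^2)
}

.cline_binll4 <- function(par, x, succ, trials) {
  p <- cline_expected(x, par[1], exp(par[2]), par[3], par[4])
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(succ * log(p) + (trials - succ) * log1p(-p))
}

#' Profiled Gaussian log-likelihood of a band series under cline parameters
#'
#' Band means are modelled as Normal with variance `sigma^2 / n_b`;
#' `sigma^2` is profiled out. Useful for comparing parameter sets on the
#' same data (e.g. fitted vs generating values).
#'
#' @param bands a [bin_transect()] result.
#' @param center,width,pmin,pmax cline parameters; `pmin`/`pmax` are the
#'   left/right tail levels in transect order.
#' @return Log-likelihood (numeric scalar).
#' @export
cline_loglik <- function(bands, center, width, pmin, pmax) {
  y <- bands$mean_q; n <- bands$n; x <- bands$band_center
  p <- cline_expected(x, center, width, pmin, pmax)
  B <- length(y)
  s2 <- sum(n * (y - p)^2) / B
  if (s2 <= 0) s2 <- 1e-12
  -0.5 * sum(log(2 * pi * s2 / n)) - B / 2
}

.cline_profile_sse <- function(cw, x, y, n) .cline_profile(cw, x, y, n)$sse

.fit_cline_once <- function(x, y, n, starts) {
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(starts[k, ], .cline_profile_sse, x = x, y = y, n = n,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  pr <- .cline_profile(best$par, x, y, n)
  par4 <- c(best$par[1], best$par[2],
            min(max(pr$a, 0), 1), min(max(pr$a + pr$b, 0), 1))
  span <- diff(range(x))
  pol <- stats::optim(par4, .cline_sse4, x = x, y = y, n = n,
                      method = "L-BFGS-B",
                      lower = c(min(x) - span, log(1e-3), 0, 0),
                      upper = c(max(x) + span, log(100 * span), 1, 1),
                      control = list(maxit = 500, factr = 1e4))
  pol
}

#' Fit a tanh geographic cline to a band series
#'
#' Maximum likelihood under a Gaussian band-mean error model (variance
#' `sigma^2 / n` with `sigma^2` profiled, i.e. weighted least squares), or
#' a binomial pseudo-count model (`2n` trials, `round(2n * mean_q)`
#' successes). Multistart (8 starts: centres at the position quintiles
#' crossed with widths span/10 and span/3) guards against the flat ridges
#' typical of tanh fits; a boxed quasi-Newton polish frees the tails
#' within `[0, 1]`. The bootstrap confidence interval for the width
#' resamples individuals within bands.
#'
#' @param bands a [bin_transect()] result (>= 5 bands spanning both tails).
#' @param error_model `"normal"` (default) or `"binomial"`.
#' @param boot bootstrap replicates for the width CI (0 to skip;
#'   default 500). Requires band membership (present when `bands` came
#'   from [bin_transect()]).
#' @param conf confidence level for the percentile interval.
#' @param seed optional seed for the bootstrap.
#' @return A list of class `cline_fit`: `center`, `width`, `pmin`,
#'   `pmax` (sorted tail levels), `rising` (TRUE if ancestry increases
#'   with position), `loglik`, `ci_width` (percentile CI or `NA`s),
#'   `error_model`, `n_bands`.
#' @export
fit_cline <- function(bands, error_model = c("normal", "binomial"),
                      boot = 500, conf = 0.95, seed = NULL) {
  error_model <- match.arg(error_model)
  if (nrow(bands) < 5) stop("need at least 5 bands to fit a cline")
  x <- bands$band_center; y <- bands$mean_q; n <- bands$n
  span <- diff(range(x))
  if (span <= 0) stop("bands must span a positive distance")
  cs <- stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  ws <- log(c(span / 10, span / 3))
  starts <- as.matrix(expand.grid(center = cs, logw = ws))

  fit1 <- function(yy) {
    pol <- .fit_cline_once(x, yy, n, starts)
    if (error_model == "binomial") {
      trials <- 2 * n
      succ <- round(trials * yy)
      pol <- stats::optim(pol$par, .cline_binll4, x = x, succ = succ,
                          trials = trials, method = "L-BFGS-B",
                          lower = c(min(x) - span, log(1e-3), 1e-9, 1e-9),
                          upper = c(max(x) + span, log(100 * span),
                                    1 - 1e-9, 1 - 1e-9),
                          control = list(maxit = 500))
    }
    pol$par
  }
  par <- fit1(y)
  mk <- function(par) {
    tails <- sort(c(par[3], par[4]))
    list(center = unname(par[1]), width = unname(exp(par[2])),
         pmin = tails[1], pmax = tails[2], rising = par[4] >= par[3])
  }
  est <- mk(par)
  ll <- if (error_model == "normal")
    cline_loglik(bands, par[1], exp(par[2]), par[3], par[4])
  else -.cline_binll4(par, x, round(2 * n * y), 2 * n)

  ci <- c(NA_real_, NA_real_)
  members <- attr(bands, "members")
  if (boot > 0 && !is.null(members)) {
    if (!is.null(seed)) set.seed(seed)
    wb <- numeric(boot)
    for (b in seq_len(boot)) {
      yb <- vapply(members, function(v)
        mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      ob <- stats::optim(par, .cline_sse4, x = x, y = yb, n = n,
                         method = "L-BFGS-B",
                         lower = c(min(x) - span, log(1e-3), 0, 0),
                         upper = c(max(x) + span, log(100 * span), 1, 1),
                         control = list(maxit = 200, factr = 1e5))
      wb[b] <- exp(ob$par[2])
    }
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(wb, c(alpha, 1 - alpha)))
  }
  structure(c(est, list(loglik = ll, ci_width = ci,
                        error_model = error_model, n_bands = nrow(bands))),
            class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf(paste0("tanh cline fit (%s error model, %d bands)\n",
                     "  center %.1f m, width %.1f m",
                     " [95%% CI %.1f, %.1f]\n  tails %.3f / %.3f (%s)\n"),
              x$error_model, x$n_bands, x$center, x$width,
              x$ci_width[1], x$ci_width[2], x$pmin, x$pmax,
              if (x$rising) "rising" else "falling"))
  invisible(x)
}

#' Predicted ancestry from a fitted cline
#' @param object a [fit_cline()] result.
#' @param x positions (m).
#' @param ... unused.
#' @return Predicted ancestry values.
#' @export
predict.cline_fit <- function(object, x, ...) {
  tails <- if (object$rising) c(object$pmin, object$pmax)
           else c(object$pmax, object$pmin)
  cline_expected(x, object$center, object$width, tails[1], tails[2])
}
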