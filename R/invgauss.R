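#' Inverse-Gaussian (Wald) density, shape/location/scale form
#'
#' Density of the three-parameter inverse-Gaussian family used to
#' summarize RT distributions: a standard inverse Gaussian with mean
#' `shape` and shape parameter 1, shifted by `location` and stretched by
#' `scale` (the parameter that literally reflects the width of the
#' distribution).
#'
#' @param x Quantiles.
#' @param shape Dimensionless shape (mean of the standardized variable).
#' @param location Shift in ms. Default 0.
#' @param scale Multiplicative stretch in ms. Default 1.
#' @param log Return log density.
#' @return Density values (0 for `x <= location`).
#' @export
dinvgauss <- function(x, shape, location = 0, scale = 1, log = FALSE) {
  stopifnot(shape > 0, scale > 0)
  y <- (x - location) / scale
  ld <- ifelse(y > 0,
               -log(scale) - 0.5 * (log(2 * pi) + 3 * log(pmax(y, 1e-300))) -
                 (y - shape)^2 / (2 * shape^2 * pmax(y, 1e-300)),
               -Inf)
  if (log) ld else exp(ld)
}

#' Inverse-Gaussian random deviates
#'
#' Michael-Schucany-Haas transformation method for the standardized
#' variable, then shifted and stretched.
#'
#' @param n Number of draws.
#' @inheritParams dinvgauss
#' @return Numeric vector of draws.
#' @export
rinvgauss <- function(n, shape, location = 0, scale = 1) {
  stopifnot(shape > 0, scale > 0)
  # standard IG(mu = shape, lambda = 1)
  nu <- stats::rnorm(n)^2
  mu <- shape
  x <- mu + mu^2 * nu / 2 - (mu / 2) * sqrt(4 * mu * nu + mu^2 * nu^2)
  u <- runif(n)
  x <- ifelse(u <= mu / (mu + x), x, mu^2 / x)
  location + scale * x
}

ig_loglik <- function(x, shape, location, scale) {
  sum(dinvgauss(x, shape, location, scale, log = TRUE))
}

# Moment-matching start at a given location: two-parameter Wald MLE of
# x - loc mapped into (shape, scale).
ig_start <- function(x, loc) {
  y <- x - loc
  mu <- mean(y)
  lam <- 1 / mean(1 / y - 1 / mu)
  c(shape = mu / lam, scale = lam)
}

#' Maximum-likelihood inverse-Gaussian fit
#'
#' Fits the three-parameter shape/location/scale inverse-Gaussian family
#' to a vector of (correct-trial) RTs by numerical maximum likelihood,
#' multi-started from moment estimates at several candidate locations
#' (the location is bounded below the sample minimum). Fitting is refused
#' (flagged, not errored) when fewer than `min_n` observations are
#' available.
#'
#' @param rts Positive RT vector.
#' @param min_n Minimum cell size. Default 10.
#' @param location Optional fixed location; when `NULL` (default) the
#'   location is estimated.
#' @return A list of class `invgauss_fit`: `shape`, `location`, `scale`,
#'   `loglik`, `n`, `refused`.
#' @export
fit_inverse_gaussian <- function(rts, min_n = 10, location = NULL) {
  n <- length(rts)
  if (n < min_n)
    return(structure(list(shape = NA_real_, location = NA_real_,
                          scale = NA_real_, loglik = NA_real_, n = n,
                          refused = TRUE),
                     class = "invgauss_fit"))
  if (any(rts <= 0))
    stop_searchddm("RTs must be positive", "searchddm_data_error")
  if (var(rts) == 0)
    stop_searchddm("degenerate RT vector (zero variance)",
                   "searchddm_data_error")
  mn <- min(rts)
  fits <- list()
  if (is.null(location)) {
    for (loc0 in c(0, 0.5 * mn, 0.9 * mn)) {
      st <- ig_start(rts, loc0)
      if (!all(is.finite(st)) || any(st <= 0)) next
      par0 <- c(log(st["shape"]), log(mn - loc0), log(st["scale"]))
      opt <- tryCatch(optim(par0, function(p) {
        -ig_loglik(rts, exp(p[1]), mn - exp(p[2]), exp(p[3]))
      }, method = "Nelder-Mead",
      control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value))
        fits[[length(fits) + 1]] <-
          list(shape = unname(exp(opt$par[1])),
               location = unname(mn - exp(opt$par[2])),
               scale = unname(exp(opt$par[3])), loglik = -opt$value)
    }
  } else {
    if (location >= mn)
      stop_searchddm("fixed location must lie below min(rts)",
                     "searchddm_data_error")
    st <- ig_start(rts, location)
    opt <- optim(log(st), function(p) {
      -ig_loglik(rts, exp(p[1]), location, exp(p[2]))
    }, method = "Nelder-Mead", control = list(maxit = 500, reltol = 1e-10))
    fits[[1]] <- list(shape = unname(exp(opt$par[1])), location = location,
                      scale = unname(exp(opt$par[2])), loglik = -opt$value)
  }
  if (length(fits) == 0)
    stop_searchddm("inverse-Gaussian fit did not converge",
                   "searchddm_analysis_error")
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  structure(c(best, list(n = n, refused = FALSE)), class = "invgauss_fit")
}

#' Two-parameter Wald fit (closed form)
#'
#' Classical mean/shape maximum-likelihood estimators of the unshifted
#' Wald distribution: `mu = mean(x)`, `1/lambda = mean(1/x - 1/mu)`.
#' Retained as a closed-form cross-check of the numerical three-parameter
#' fit.
#'
#' @param rts Positive RT vector.
#' @return A list with `mu`, `lambda`, and the equivalent
#'   shape/scale parameterization (`shape = mu/lambda`, `scale = lambda`).
#' @export
fit_wald <- function(rts) {
  if (any(rts <= 0))
    stop_searchddm("RTs must be positive", "searchddm_data_error")
  mu <- mean(rts)
  lambda <- 1 / mean(1 / rts - 1 / mu)
  list(mu = mu, lambda = lambda, shape = mu / lambda, scale = lambda)
}

#' Width comparison of Both- vs Non-Color-Match RT distributions
#'
#' Fits the inverse-Gaussian scale (width) parameter to each
#' participant's correct RTs in the Both-Color-Match and Non-Color-Match
#' conditions and compares the paired scales with a classical t-test and
#' a default (JZS) Bayes factor, reporting BF01 — evidence for equally
#' wide distributions. Participants lacking a usable fit in either
#' condition are dropped with a message.
#'
#' @param trials Filtered trial table.
#' @param min_n Minimum correct trials per cell. Default 10.
#' @param r Cauchy prior scale. Default `sqrt(2)/2`.
#' @return A list of class `width_comparison`: per-participant `pairs`
#'   (`scale_both`, `scale_non`), `n`, `t`, `df`, `p`, `bf01`, `bf10`,
#'   `direction`.
#' @export
width_comparison <- function(trials, min_n = 10, r = sqrt(2) / 2) {
  view <- correct_rt_view(trials)
  ids <- unique(view$participant_id)
  rows <- lapply(ids, function(id) {
    both <- view$rts[view$participant_id == id &
                       view$condition == "BothColorMatch"][[1]]
    non <- view$rts[view$participant_id == id &
                      view$condition == "NonColorMatch"][[1]]
    fb <- fit_inverse_gaussian(both, min_n = min_n)
    fn <- fit_inverse_gaussian(non, min_n = min_n)
    if (fb$refused || fn$refused) {
      message("width_comparison: dropping participant ", id,
              " (cell below minimum size)")
      return(NULL)
    }
    data.frame(participant_id = id, scale_both = fb$scale,
               scale_non = fn$scale,
               sd_both = fb$scale * sqrt(fb$shape^3),
               sd_non = fn$scale * sqrt(fn$shape^3))
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) < 2)
    stop_searchddm("fewer than 2 participants with both cells fitted",
                   "searchddm_analysis_error")
  d <- pairs$scale_both - pairs$scale_non
  if (sd(d) == 0) {
    t_res <- list(t = 0, df = nrow(pairs) - 1, p = 1)
  } else {
    t_res <- paired_t(d)
  }
  bf <- jzs_bf(t_res$t, n = nrow(pairs), r = r)
  structure(list(pairs = pairs, n = nrow(pairs), t = t_res$t,
                 df = t_res$df, p = t_res$p, bf01 = bf$bf01,
                 bf10 = bf$bf10,
                 direction = if (mean(d) >= 0) "both wider" else
                   "non wider"),
            class = "width_comparison")
}
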