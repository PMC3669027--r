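#' Parameter probability density function specifications
#'
#' A `pdf_spec` describes one of the three distribution families used to
#' represent vital-rate uncertainty: uniform (survival, fecundity),
#' triangular (longevity, egg-case survival) and truncated logistic (age at
#' maturity). Degenerate supports (e.g. `min == max`) are allowed and give a
#' point mass, which is how deterministic scenarios are expressed.
#'
#' @param kind one of `"uniform"`, `"triangular"`, `"truncated_logistic"`.
#' @param ... kind-specific parameters: `min`, `max` (uniform);
#'   `min`, `mode`, `max` (triangular); `location`, `scale`, `lower`,
#'   `upper` (truncated logistic).
#' @return an object of class `pdf_spec`.
#' @examples
#' pdf_spec("triangular", min = 13, mode = 14, max = 20)
#' pdf_spec("uniform", min = 0.6, max = 0.91)
#' @export
pdf_spec <- function(kind = c("uniform", "triangular", "truncated_logistic"),
                     ...) {
  kind <- match.arg(kind)
  p <- list(...)
  need <- switch(kind,
    uniform = c("min", "max"),
    triangular = c("min", "mode", "max"),
    truncated_logistic = c("location", "scale", "lower", "upper"))
  missing <- setdiff(need, names(p))
  if (length(missing) > 0L) {
    stop("pdf_spec('", kind, "') requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- lapply(p[need], as.numeric)
  if (any(vapply(p, function(x) length(x) != 1L || !is.finite(x), logical(1L)))) {
    stop("all pdf_spec parameters must be finite scalars", call. = FALSE)
  }
  ok <- switch(kind,
    uniform = p$min <= p$max,
    triangular = p$min <= p$mode && p$mode <= p$max,
    truncated_logistic = p$lower < p$upper && p$scale >= 0)
  if (!ok) stop("invalid parameters for ", kind, " pdf_spec", call. = FALSE)
  structure(c(list(kind = kind), p), class = "pdf_spec")
}

#' @export
print.pdf_spec <- function(x, ...) {
  p <- unlist(x[-1L])
  cat("<pdf_spec ", x$kind, ": ",
      paste(names(p), signif(p, 6), sep = " = ", collapse = ", "), ">\n",
      sep = "")
  invisible(x)
}

#' Sample from a parameter PDF
#'
#' Draws from the distribution described by a [pdf_spec()] using the global
#' random number stream (`set.seed()` gives reproducibility). The triangular
#' family is sampled by inverse-CDF transform; the truncated logistic by
#' rejection from the untruncated logistic, which is exact and efficient at
#' the mild truncations that arise for maturity ogives.
#'
#' @param spec a [pdf_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n`, always within the spec's support.
#' @examples
#' set.seed(1)
#' sample_pdf(pdf_spec("triangular", min = 13, mode = 14, max = 20), 5)
#' @export
sample_pdf <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "pdf_spec"), n >= 0L)
  if (n == 0L) return(numeric(0L))
  switch(spec$kind,
    uniform = if (spec$min == spec$max) rep(spec$min, n) else
      stats::runif(n, spec$min, spec$max),
    triangular = rtriangular(n, spec$min, spec$mode, spec$max),
    truncated_logistic = rlogis_truncated(n, spec$location, spec$scale,
                                          spec$lower, spec$upper))
}

# inverse-CDF triangular sampler; degenerate supports collapse to the mode
rtriangular <- function(n, min, mode, max) {
  if (min == max) return(rep(mode, n))
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

# rejection sampler for the truncated logistic; scale 0 is a point mass at
# the location clamped into [lower, upper]
rlogis_truncated <- function(n, location, scale, lower, upper,
                             max_tries = 1000L) {
  if (scale == 0) return(rep(min(max(location, lower), upper), n))
  accept <- stats::plogis(upper, location, scale) -
    stats::plogis(lower, location, scale)
  if (accept <= 0) {
    stop("truncation interval [", lower, ", ", upper,
         "] has no probability mass under logistic(", location, ", ", scale,
         ")", call. = FALSE)
  }
  out <- numeric(0L)
  tries <- 0L
  while (length(out) < n && tries < max_tries) {
    m <- ceiling((n - length(out)) / max(accept, 0.01)) + 10L
    x <- stats::rlogis(m, location, scale)
    out <- c(out, x[x >= lower & x <= upper])
    tries <- tries + 1L
  }
  if (length(out) < n) {
    stop("rejection sampling failed for truncated logistic", call. = FALSE)
  }
  out[seq_len(n)]
}

#' Logistic scale from a 95% confidence interval
#'
#' The age-at-maturity PDF is a logistic centred on the median age at 50%
#' maturity; its scale is chosen so that the untruncated distribution has
#' its 2.5th and 97.5th percentiles at the reported confidence bounds:
#' `s = (ci_high - ci_low) / (2 log 39)`, since the logistic 97.5% quantile
#' sits `s log(0.975/0.025) = s log 39` above the location.
#'
#' @param ci_low,ci_high lower and upper 95% confidence bounds (years).
#' @return the logistic scale parameter (years).
#' @examples
#' logistic_scale_from_ci(16.2, 19.2) # ~0.409
#' @export
logistic_scale_from_ci <- function(ci_low, ci_high) {
  if (!is.finite(ci_low) || !is.finite(ci_high) || ci_high <= ci_low) {
    stop("confidence interval must have positive width", call. = FALSE)
  }
  (ci_high - ci_low) / (2 * log(39))
}

#' Plausible longevity bounds from ageing precision
#'
#' Widens a maximum observed age into a plausible longevity interval:
#' the lower bound shrinks the observed maximum by the ageing error
#' (`tmax (1 - E)`, with `E` the index of average percent error of the age
#' determinations), and the upper bound inflates it
#' (`c tmax (1 + E)`, with `c >= 1` an extension constant, default 1.4,
#' acknowledging that the absolute oldest individuals are unlikely to have
#' been sampled). Both bounds are rounded to whole years. For the packaged
#' Bering Sea species the published interval bounds are stored verbatim;
#' this helper parameterizes new species.
#'
#' @param tmax maximum observed age (years), > 0.
#' @param iape index of average percent error (dimensionless, in `[0, 1)`).
#' @param c extension constant, >= 1.
#' @return named numeric vector `c(lower, upper)` in years, with
#'   `lower <= tmax <= upper`.
#' @examples
#' longevity_bounds(32, 0, 1.4)     # c(32, 45)
#' longevity_bounds(14, 0.07, 1.4)  # c(13, 21)
#' @export
longevity_bounds <- function(tmax, iape, c = 1.4) {
  stopifnot(is.finite(tmax), tmax > 0, is.finite(iape), iape >= 0, iape < 1,
            is.finite(c), c >= 1)
  lower <- round(tmax * (1 - iape))
  upper <- round(c * tmax * (1 + iape))
  if (lower > tmax || upper < tmax || lower > upper) {
    stop("longevity bounds invert around tmax = ", tmax, call. = FALSE)
  }
  c(lower = lower, upper = upper)
}
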