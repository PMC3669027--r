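#' Pearson correlation with t-test
#'
#' Product-moment correlation between two trait vectors with the exact
#' t-transform significance test: `t = r sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom, two-tailed.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with non-zero
#'   variance.
#' @return an object of class `correlation_result`: list with `r_p`, `n`,
#'   `t_stat`, `p_value`, `df`.
#' @examples
#' pearson_with_t_test(c(1, 2, 3), c(6, 4, 5)) # r = -0.5
#' @export
pearson_with_t_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(r_p = r, n = n, t_stat = t_stat, p_value = p, df = df),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r_p = %.3f, n = %d, t = %.3f, P = %.3f\n",
              x$r_p, x$n, x$t_stat, x$p_value))
  invisible(x)
}

#' Ratio of age at maturity to longevity
#'
#' The proportion of the lifespan devoted to maturation; an inverse proxy
#' for the relative reproductive lifespan (`1 -` this ratio).
#'
#' @param alpha age at maturity (years), `0 < alpha <= omega`.
#' @param omega longevity (years).
#' @return `alpha / omega`, in (0, 1].
#' @examples
#' maturity_longevity_ratio(27.5, 36.75) # ~0.75
#' @export
maturity_longevity_ratio <- function(alpha, omega) {
  stopifnot(all(alpha > 0), all(omega > 0))
  if (any(alpha > omega)) {
    stop("age at maturity cannot exceed longevity", call. = FALSE)
  }
  alpha / omega
}

#' Correlates of population growth rate across an assemblage
#'
#' Pearson correlation (with t-test) of published finite population growth
#' rates against each candidate life-history correlate — the maturity to
#' longevity ratio, maximum total length, and depth-range midpoint —
#' optionally restricted to the Alaskan assemblage subset.
#'
#' @param records comparative data.frame from [load_comparative_table()].
#' @param group `"all"` or `"alaskan"`.
#' @return data.frame with one row per trait: `trait`, `r_p`, `n`,
#'   `t_stat`, `p_value`.
#' @examples
#' comp <- load_comparative_table(
#'   system.file("extdata", "high_latitude_skates.csv",
#'               package = "skatedemog"))
#' run_correlate_suite(comp, "all")
#' @export
run_correlate_suite <- function(records, group = c("all", "alaskan")) {
  group <- match.arg(group)
  stopifnot(is.data.frame(records))
  df <- if (group == "alaskan") records[records$group == "alaskan", ] else
    records
  if (nrow(df) < 3L) {
    stop("fewer than 3 species after filtering (n = ", nrow(df), ")",
         call. = FALSE)
  }
  traits <- c(alpha_omega_ratio = "alpha_omega_ratio",
              tl_max_cm = "tl_max_cm", depth_mid_m = "depth_mid_m")
  rows <- lapply(names(traits), function(tr) {
    ct <- pearson_with_t_test(df$lambda_pub, df[[traits[[tr]]]])
    data.frame(trait = tr, r_p = ct$r_p, n = ct$n, t_stat = ct$t_stat,
               p_value = ct$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
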