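#' Draw one Monte Carlo realization of a species' vital rates
#'
#' Produces a complete set of vital rates for one replicate of the
#' probabilistic matrix model:
#'
#' * longevity `omega`: triangular draw, rounded to the nearest whole year
#'   (annual age classes);
#' * age at maturity `alpha`: truncated-logistic draw (location `alpha50`,
#'   scale from the 95% CI, truncated to the record's bounds by rejection),
#'   rounded and clamped to `[1, omega]`;
#' * per-age annual survival: uniform draws — one per age class in `"iid"`
#'   mode, a single shared draw in `"correlated"` mode — after which the
#'   first two post-hatching age classes are multiplied by 0.5 and 0.75 to
#'   represent extra early-life mortality;
#' * per-age fecundity: uniform draws (iid or shared as above), set to zero
#'   below `alpha` (knife-edge maturity) and halved at `alpha` (only half
#'   of the cohort reproduces during its maturation year);
#' * egg-case annual survival `l_e`: triangular draw.
#'
#' `"iid"` treats vital-rate uncertainty as independent among age classes;
#' `"correlated"` is the opposite extreme of perfect correlation (one draw
#' of `S` and one of `m` applied to every class). Draws use the global RNG;
#' the per-replicate RNG call sequence is fixed (omega, alpha, survival,
#' fecundity, egg case), so a given seed reproduces draws exactly.
#'
#' @param record a [species_record()].
#' @param mode `"iid"` or `"correlated"`.
#' @param fixed optional named list to pin `omega` and/or `alpha` at a
#'   given value (used by the univariate sensitivity analysis); a pinned
#'   parameter consumes no random draws.
#' @return an object of class `vital_rate_draw`: list with integer `omega`
#'   and `alpha`, numeric `survival` and `fecundity` vectors of length
#'   `omega` (index 1 = first post-hatching year), scalar
#'   `eggcase_survival`, and `mode`.
#' @examples
#' rec <- species_record("demo", 13, 14, 20, 9.2, 8.7, 9.7, 8, 10,
#'                       16, 52, 0.65, 0.81, 0.98, 0.60, 0.91)
#' set.seed(42)
#' draw_vital_rates(rec, "iid")
#' @export
draw_vital_rates <- function(record, mode = c("iid", "correlated"),
                             fixed = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "skate_species"))
  if (record$alpha_trunc_low > record$alpha_trunc_high) {
    stop("empty maturity truncation interval for '", record$species_name,
         "'", call. = FALSE)
  }

  omega <- if (!is.null(fixed$omega)) {
    as.integer(round(fixed$omega))
  } else {
    as.integer(round(rtriangular(1L, record$omega_min, record$omega_mode,
                                 record$omega_max)))
  }
  if (omega < 1L) stop("drawn longevity below one year", call. = FALSE)

  alpha <- if (!is.null(fixed$alpha)) {
    as.integer(round(fixed$alpha))
  } else {
    scale <- if (record$alpha_ci_high > record$alpha_ci_low) {
      logistic_scale_from_ci(record$alpha_ci_low, record$alpha_ci_high)
    } else 0
    as.integer(round(rlogis_truncated(1L, record$alpha50, scale,
                                      record$alpha_trunc_low,
                                      record$alpha_trunc_high)))
  }
  alpha <- max(1L, min(alpha, omega))

  n_s <- if (mode == "iid") omega else 1L
  survival <- if (record$survival_min == record$survival_max) {
    rep(record$survival_min, n_s)
  } else {
    stats::runif(n_s, record$survival_min, record$survival_max)
  }
  if (mode == "correlated") survival <- rep(survival, omega)
  survival[1L] <- survival[1L] * 0.5
  if (omega >= 2L) survival[2L] <- survival[2L] * 0.75

  fecundity <- if (record$fecundity_min == record$fecundity_max) {
    rep(record$fecundity_min, n_s)
  } else {
    stats::runif(n_s, record$fecundity_min, record$fecundity_max)
  }
  if (mode == "correlated") fecundity <- rep(fecundity, omega)
  fecundity[seq_len(omega) < alpha] <- 0
  fecundity[alpha] <- fecundity[alpha] / 2

  eggcase <- rtriangular(1L, record$eggcase_min, record$eggcase_mode,
                         record$eggcase_max)

  structure(list(omega = omega, alpha = alpha, survival = survival,
                 fecundity = fecundity, eggcase_survival = eggcase,
                 mode = mode, species_name = record$species_name),
            class = "vital_rate_draw")
}

#' @export
print.vital_rate_draw <- function(x, ...) {
  cat("<vital_rate_draw> ", x$species_name, " (", x$mode, ")\n",
      "  omega = ", x$omega, " yr, alpha = ", x$alpha, " yr, l_e = ",
      signif(x$eggcase_survival, 4), "\n",
      "  survival  [", paste(signif(utils::head(x$survival, 4), 3),
                             collapse = ", "),
      if (x$omega > 4L) ", ..." else "", "]\n",
      "  fecundity [", paste(signif(utils::head(x$fecundity, 4), 3),
                             collapse = ", "),
      if (x$omega > 4L) ", ..." else "", "]\n", sep = "")
  invisible(x)
}
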