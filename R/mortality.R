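#' Indirect natural mortality estimators
#'
#' Estimates the instantaneous natural mortality rate `M` (yr^-1) from
#' life-history parameters, for species without catch-at-age data. Methods:
#'
#' * `hoenig_all_taxa`: longevity regression `ln M = 1.46 - 1.01 ln(tmax)`.
#' * `hoenig_fish`: longevity regression `ln M = 1.44 - 0.982 ln(tmax)`.
#' * `jensen_alpha`: maturity form `M = 1.65 / alpha50`.
#' * `jensen_k15`: growth form `M = 1.5 k`.
#' * `jensen_k16`: growth form `M = 1.6 k`.
#' * `chen_watanabe`: age-specific `M_x` from the von Bertalanffy
#'   parameters `k` and `t0`; declining with age up to the senescence age
#'   `tM = t0 - (1/k) log(1 - exp(k t0))` and following a quadratic
#'   expansion of the survival curve beyond it.
#'
#' The first five give a single population-wide rate; `chen_watanabe`
#' returns one rate per requested age. Annual survival is `S = exp(-M)`.
#'
#' @param method estimator name (see above).
#' @param record a [species_record()] supplying the method's inputs
#'   (`tmax_observed` for the Hoenig forms, `alpha50` for `jensen_alpha`,
#'   `growth_k` (+ `growth_t0`) for the growth forms).
#' @param ages integer vector of ages (years), required for
#'   `chen_watanabe`.
#' @return an object of class `mortality_estimate`: list with `method`,
#'   `m_values` (instantaneous rate(s), yr^-1), `s_values` (`exp(-m)`), and
#'   `ages` (for the age-specific method).
#' @examples
#' rec <- species_record("demo", 13, 14, 20, 9.2, 8.7, 9.7, 8, 10,
#'                       16, 52, 0.65, 0.81, 0.98, 0.60, 0.91,
#'                       tmax_observed = 14)
#' estimate_mortality("hoenig_all_taxa", rec) # M ~ 0.30
#' estimate_mortality("jensen_alpha", rec)    # M ~ 0.18
#' @export
estimate_mortality <- function(method = c("hoenig_all_taxa", "hoenig_fish",
                                          "jensen_alpha", "jensen_k15",
                                          "jensen_k16", "chen_watanabe"),
                               record, ages = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(record, "skate_species"))
  need <- function(field) {
    v <- record[[field]]
    if (is.null(v) || !is.finite(v)) {
      stop("estimate_mortality('", method, "') requires field '", field,
           "' in the species record", call. = FALSE)
    }
    v
  }
  m <- switch(method,
    hoenig_all_taxa = exp(1.46 - 1.01 * log(need("tmax_observed"))),
    hoenig_fish = exp(1.44 - 0.982 * log(need("tmax_observed"))),
    jensen_alpha = 1.65 / need("alpha50"),
    jensen_k15 = 1.5 * need("growth_k"),
    jensen_k16 = 1.6 * need("growth_k"),
    chen_watanabe = {
      if (is.null(ages)) {
        stop("estimate_mortality('chen_watanabe') requires 'ages'",
             call. = FALSE)
      }
      chen_watanabe_m(ages, need("growth_k"), need("growth_t0"))
    })
  if (any(m <= 0)) {
    stop("method '", method, "' produced a non-positive mortality rate",
         call. = FALSE)
  }
  structure(list(method = method, m_values = m, s_values = exp(-m),
                 ages = if (method == "chen_watanabe") as.integer(ages)),
            class = "mortality_estimate")
}

# Chen & Watanabe (1989) age-specific natural mortality from von
# Bertalanffy k and t0 (t0 < 0 for a senescence age to exist).
chen_watanabe_m <- function(ages, k, t0) {
  stopifnot(k > 0, all(is.finite(ages)))
  tm <- if (t0 < 0) -(1 / k) * log(1 - exp(k * t0)) + t0 else Inf
  a0 <- 1 - exp(-k * (tm - t0))
  a1 <- k * exp(-k * (tm - t0))
  a2 <- -0.5 * k^2 * exp(-k * (tm - t0))
  vapply(ages, function(t) {
    denom <- if (t <= tm) {
      1 - exp(-k * (t - t0))
    } else {
      a0 + a1 * (t - tm) + a2 * (t - tm)^2
    }
    if (!is.finite(denom) || denom <= 0) {
      stop("chen_watanabe mortality undefined at age ", t,
           " (non-positive denominator)", call. = FALSE)
    }
    k / denom
  }, numeric(1L))
}

#' @export
print.mortality_estimate <- function(x, ...) {
  cat("<mortality_estimate ", x$method, ">\n", sep = "")
  if (length(x$m_values) == 1L) {
    cat("  M = ", signif(x$m_values, 4), " yr^-1,  S = ",
        signif(x$s_values, 4), " yr^-1\n", sep = "")
  } else {
    cat("  age-specific M over ", length(x$m_values), " ages; range ",
        signif(min(x$m_values), 3), "-", signif(max(x$m_values), 3),
        " yr^-1\n", sep = "")
  }
  invisible(x)
}

#' Convert instantaneous mortality to annual survival
#'
#' @param m instantaneous mortality rate(s), yr^-1, non-negative.
#' @return `exp(-m)`, in (0, 1].
#' @examples
#' mortality_to_survival(0.13) # ~0.88
#' @export
mortality_to_survival <- function(m) {
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("mortality rates must be finite and non-negative", call. = FALSE)
  }
  exp(-m)
}

#' Annual survival range across indirect estimators
#'
#' Applies the requested estimators to one species and returns the extreme
#' annual survival values, the range used as the uniform survival PDF when
#' parameterizing the matrix model. Age-specific methods contribute every
#' per-age value. Methods whose inputs are missing from the record are
#' skipped; if none is computable an error is raised.
#'
#' @param record a [species_record()].
#' @param methods estimator names (see [estimate_mortality()]).
#' @param ages ages for `chen_watanabe` (default `1:round(omega_mode)`).
#' @return named numeric vector `c(s_min, s_max)`.
#' @export
survival_range <- function(record,
                           methods = c("hoenig_all_taxa", "hoenig_fish",
                                       "jensen_alpha", "jensen_k15",
                                       "jensen_k16", "chen_watanabe"),
                           ages = NULL) {
  stopifnot(inherits(record, "skate_species"), length(methods) > 0L)
  if (is.null(ages)) ages <- seq_len(round(record$omega_mode))
  s_all <- numeric(0L)
  for (m in methods) {
    est <- tryCatch(
      estimate_mortality(m, record, ages = ages),
      error = function(e) NULL)
    if (!is.null(est)) s_all <- c(s_all, est$s_values)
  }
  if (length(s_all) == 0L) {
    stop("no requested mortality method is computable for '",
         record$species_name, "'", call. = FALSE)
  }
  c(s_min = min(s_all), s_max = max(s_all))
}

#' Indirect mortality table for a set of species
#'
#' Tabulates `M` and `S` for every scalar method and species, one row per
#' method x species combination (the shape of a standard mortality-methods
#' comparison table). Values are reported at full precision; round only for
#' presentation.
#'
#' @param records list of [species_record()]s.
#' @param methods scalar estimator names.
#' @return data.frame with columns `method`, `species`, `M`, `S`.
#' @export
mortality_table <- function(records,
                            methods = c("hoenig_all_taxa", "hoenig_fish",
                                        "jensen_alpha", "jensen_k15",
                                        "jensen_k16")) {
  rows <- list()
  for (m in methods) {
    for (rec in records) {
      est <- tryCatch(estimate_mortality(m, rec), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, species = rec$species_name,
        M = if (is.null(est)) NA_real_ else est$m_values,
        S = if (is.null(est)) NA_real_ else est$s_values,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
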