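#' Survivorship schedule from a vital-rate draw
#'
#' Cumulative survivorship `l_x` from the per-age annual survival vector:
#' `l_0 = 1` and `l_x = l_{x-1} S_x`. Length is `omega + 1` (indices are
#' ages 0..omega).
#'
#' @param draw a [draw_vital_rates()] result.
#' @return non-increasing numeric vector of length `omega + 1`, `l[1] = 1`.
#' @export
survivorship_schedule <- function(draw) {
  stopifnot(inherits(draw, "vital_rate_draw"))
  cumprod(c(1, draw$survival))
}

#' Birth-flow survival probabilities
#'
#' With reproduction spread continuously over each annual time step
#' (birth-flow), the matrix survival probability averages individuals
#' entering and leaving a class:
#' `P_i = (l_i + l_{i+1}) / (l_{i-1} + l_i)`,
#' for the `omega - 1` interior age-class transitions.
#'
#' @param l survivorship vector from [survivorship_schedule()] (ages
#'   `0..omega`).
#' @return numeric vector `P` of length `length(l) - 2`, each in (0, 1).
#' @examples
#' birth_flow_survival(c(1, 0.9, 0.3, 0.1)) # 0.6316, 0.3333
#' @export
birth_flow_survival <- function(l) {
  stopifnot(is.numeric(l), length(l) >= 2L, l[1] == 1, all(l > 0 | l == 0))
  n <- length(l) - 2L
  if (n < 1L) return(numeric(0L))
  i <- seq_len(n)
  denom <- l[i] + l[i + 1L]
  if (any(denom == 0)) {
    stop("zero denominator in birth-flow survival (survivorship hit zero)",
         call. = FALSE)
  }
  (l[i + 1L] + l[i + 2L]) / denom
}

#' Birth-flow fertility coefficients
#'
#' Fertility for a birth-flow population: offspring production averaged
#' over the time step and discounted by survival of the egg-case stage for
#' half a period,
#' `F_i = sqrt(l_e) (m_i + P_i m_{i+1}) / 2`,
#' with `m_{omega+1} = 0` for the final class. The egg case is not an
#' explicit matrix class; its annual survival `l_e` enters the model only
#' here, so its influence is contained in the fertility elasticities.
#'
#' @param draw a [draw_vital_rates()] result (supplies `m` and `l_e`).
#' @param P birth-flow survival vector from [birth_flow_survival()]
#'   computed from the same draw.
#' @return non-negative numeric vector of length `omega`.
#' @export
birth_flow_fertility <- function(draw, P) {
  stopifnot(inherits(draw, "vital_rate_draw"),
            length(P) == draw$omega - 1L)
  m <- draw$fecundity
  m_next <- c(m[-1L], 0)
  p_half <- c(P, 0) # P_omega pairs with m_{omega+1} = 0, so any value works
  sqrt(draw$eggcase_survival) * (m + p_half * m_next) / 2
}

#' Assemble the birth-flow Leslie projection matrix
#'
#' Builds the `omega x omega` age-classified projection matrix for one
#' vital-rate draw: birth-flow fertilities on the first row, birth-flow
#' survival probabilities on the subdiagonal, zero elsewhere (individuals
#' do not survive past age `omega`).
#'
#' @param draw a [draw_vital_rates()] result.
#' @return a `projection_matrix`: base matrix with attributes `alpha`
#'   (age at maturity of the draw) and `species_name`.
#' @export
assemble_matrix <- function(draw) {
  stopifnot(inherits(draw, "vital_rate_draw"))
  l <- survivorship_schedule(draw)
  P <- birth_flow_survival(l)
  Fv <- birth_flow_fertility(draw, P)
  n <- draw$omega
  a <- matrix(0, n, n)
  a[1L, ] <- Fv
  if (n >= 2L) a[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- P
  structure(a, alpha = draw$alpha, species_name = draw$species_name,
            class = c("projection_matrix", class(a)))
}

#' Eigen-analysis of a projection matrix
#'
#' The finite annual rate of population increase `lambda` is the dominant
#' eigenvalue; the stable age distribution `w` and reproductive value `v`
#' are the associated right and left eigenvectors. Errors if no fertility
#' is positive or the dominant eigenvalue is not real and strictly largest
#' in modulus (imprimitive or reducible matrix).
#'
#' @param a a square non-negative matrix (typically [assemble_matrix()]).
#' @return list with `lambda` (> 0), `w` (normalized to sum 1) and `v`
#'   (normalized so `v[1] = 1`), both elementwise non-negative.
#' @export
eigen_analysis <- function(a) {
  a <- unclass(a)
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (any(a < 0)) stop("projection matrix must be non-negative", call. = FALSE)
  if (all(a[1L, ] <= 0)) {
    stop("no positive fertility: the matrix has no reproduction and no ",
         "meaningful dominant eigenvalue", call. = FALSE)
  }
  ev <- eigen(a)
  mods <- Mod(ev$values)
  k <- which.max(mods)
  lam <- ev$values[k]
  others <- if (length(mods) > 1L) max(mods[-k]) else 0
  if (abs(Im(lam)) > 1e-9 * max(1, mods[k]) ||
      others >= mods[k] * (1 - 1e-9)) {
    stop("dominant eigenvalue is not unique and real: matrix appears ",
         "imprimitive or reducible", call. = FALSE)
  }
  lam <- Re(lam)
  if (lam <= 0) stop("dominant eigenvalue is not positive", call. = FALSE)
  w <- Re(ev$vectors[, k])
  if (sum(w) < 0) w <- -w
  if (any(w < -1e-8 * max(abs(w)))) {
    stop("right eigenvector has mixed signs: matrix is not primitive",
         call. = FALSE)
  }
  w <- pmax(w, 0)
  w <- w / sum(w)
  evl <- eigen(t(a))
  kl <- which.max(Mod(evl$values))
  v <- Re(evl$vectors[, kl])
  if (v[1L] == 0) stop("reproductive value of the first class is zero",
                       call. = FALSE)
  v <- v / v[1L]
  v <- pmax(v, 0)
  list(lambda = lam, w = w, v = v)
}

#' Derived demographic statistics
#'
#' From the matrix-consistent schedules — survivorship through the matrix
#' survival probabilities (`lm_1 = 1`, `lm_x = prod(P_1..P_{x-1})`) and the
#' fertility coefficients `F_x` — computes:
#'
#' * net reproductive rate `R0 = sum_x lm_x F_x` (expected lifetime female
#'   offspring per female recruit);
#' * cohort generation time `mu1 = sum_x x lm_x F_x / R0` (mean age of the
#'   mothers of a cohort's offspring);
#' * stable-age generation time
#'   `Abar = sum_x x lambda^-x lm_x F_x / sum_x lambda^-x lm_x F_x`
#'   (mean age of mothers at the stable age distribution);
#' * rate of increase per generation `rT = log(R0)`.
#'
#' At the dominant eigenvalue the discounted schedule satisfies the
#' Euler-Lotka identity `sum_x lambda^-x lm_x F_x = 1`.
#'
#' @param a a [assemble_matrix()] projection matrix.
#' @param lambda its dominant eigenvalue from [eigen_analysis()].
#' @return list with `r0`, `rt`, `mu1`, `abar`.
#' @export
demographic_statistics <- function(a, lambda) {
  a <- unclass(a)
  stopifnot(is.matrix(a), nrow(a) == ncol(a), lambda > 0)
  n <- nrow(a)
  Fv <- a[1L, ]
  P <- if (n >= 2L) a[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] else
    numeric(0L)
  lm <- cumprod(c(1, P))
  x <- seq_len(n)
  r0 <- sum(lm * Fv)
  if (r0 <= 0) stop("net reproductive rate is zero: no reproduction",
                    call. = FALSE)
  disc <- lambda^(-x) * lm * Fv
  list(r0 = r0,
       rt = log(r0),
       mu1 = sum(x * lm * Fv) / r0,
       abar = sum(x * disc) / sum(disc))
}

#' Elasticity matrix of the population growth rate
#'
#' Proportional sensitivities of `lambda` to the matrix entries:
#' `e_ij = (a_ij / lambda) v_i w_j / <w, v>`. Entries are zero wherever
#' `a_ij = 0` and sum to one over the matrix.
#'
#' @param a projection matrix.
#' @param eig result of [eigen_analysis()] on `a` (or `NULL` to compute).
#' @return matrix of elasticities, same dimension as `a`.
#' @export
elasticity_matrix <- function(a, eig = NULL) {
  if (is.null(eig)) eig <- eigen_analysis(a)
  a <- unclass(a)
  denom <- sum(eig$w * eig$v)
  if (denom == 0) stop("degenerate eigenvectors: <w, v> = 0", call. = FALSE)
  (a / eig$lambda) * outer(eig$v, eig$w) / denom
}

#' Elasticity category sums
#'
#' Partitions the elasticity matrix into the three life-cycle categories:
#' fertility (first row, which also carries egg-case survival), juvenile
#' survival (subdiagonal transitions out of age classes younger than
#' `alpha`) and adult survival (remaining subdiagonal transitions). The
#' three sums partition the total elasticity of one.
#'
#' @param e elasticity matrix from [elasticity_matrix()].
#' @param alpha age at maturity (years / age-class index).
#' @return named numeric vector `c(e_fertility, e_juvenile, e_adult)`.
#' @export
elasticity_categories <- function(e, alpha) {
  stopifnot(is.matrix(e), nrow(e) == ncol(e))
  n <- nrow(e)
  if (alpha < 1L || alpha > n) {
    stop("alpha (", alpha, ") outside the matrix dimension (", n, ")",
         call. = FALSE)
  }
  i <- seq_len(n - 1L)
  sub <- if (n >= 2L) e[cbind(i + 1L, i)] else numeric(0L)
  c(e_fertility = sum(e[1L, ]),
    e_juvenile = sum(sub[i < alpha]),
    e_adult = sum(sub[i >= alpha]))
}

#' Compensatory increase required to offset a vital-rate decrease
#'
#' Using elasticities as exchange rates on `lambda`, the proportional
#' increase in one vital-rate category needed to compensate a proportional
#' decrease in another is `decrement_pct * e_decreased / e_increased`.
#'
#' @param e_decreased elasticity of the category that decreases.
#' @param e_increased elasticity of the category that must compensate.
#' @param decrement_pct size of the decrease, in percent.
#' @return required increase, in percent.
#' @examples
#' compensation_ratio(0.8, 0.2, 10) # a 40% increase is needed
#' @export
compensation_ratio <- function(e_decreased, e_increased, decrement_pct = 10) {
  stopifnot(e_decreased > 0, decrement_pct >= 0)
  if (e_increased <= 0) {
    stop("compensation impossible: the compensating category has no ",
         "elasticity", call. = FALSE)
  }
  decrement_pct * e_decreased / e_increased
}

#' Full demographic output for one vital-rate draw
#'
#' Convenience wrapper running the complete per-replicate pipeline:
#' assemble the birth-flow matrix, eigen-analysis, derived statistics and
#' elasticity sums.
#'
#' @param draw a [draw_vital_rates()] result.
#' @param full if `TRUE` also return the matrix, eigenvectors and the full
#'   elasticity matrix.
#' @return an object of class `demographic_output`: list with `lambda`,
#'   `r` (`log(lambda)`), `r0`, `rt`, `mu1`, `abar`, `e_fertility`,
#'   `e_juvenile`, `e_adult` (and, with `full = TRUE`, `matrix`, `w`, `v`,
#'   `elasticity`).
#' @export
demographic_output <- function(draw, full = FALSE) {
  a <- assemble_matrix(draw)
  eig <- eigen_analysis(a)
  stats <- demographic_statistics(a, eig$lambda)
  e <- elasticity_matrix(a, eig)
  cats <- elasticity_categories(e, draw$alpha)
  out <- c(list(lambda = eig$lambda, r = log(eig$lambda)), stats,
           as.list(cats))
  if (full) {
    out$matrix <- a
    out$w <- eig$w
    out$v <- eig$v
    out$elasticity <- e
  }
  structure(out, class = "demographic_output")
}

#' @export
print.demographic_output <- function(x, ...) {
  cat("<demographic_output>\n",
      sprintf("  lambda = %.4f yr^-1 (r = %.4f)\n", x$lambda, x$r),
      sprintf("  R0 = %.3f, rT = %.3f, mu1 = %.2f yr, Abar = %.2f yr\n",
              x$r0, x$rt, x$mu1, x$abar),
      sprintf("  elasticities: fertility %.3f, juvenile %.3f, adult %.3f\n",
              x$e_fertility, x$e_juvenile, x$e_adult), sep = "")
  invisible(x)
}
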