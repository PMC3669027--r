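# shared fixtures and independent oracles

bering_records <- function() {
  suppressWarnings(
    load_species_records(skatedemog_example("bering_sea_skates.csv")))
}

comparative_table <- function() {
  load_comparative_table(skatedemog_example("high_latitude_skates.csv"))
}

# a record whose PDFs are all point masses, so every draw is identical
point_record <- function(omega = 3, alpha = 2, s = 0.8, m = 20, le = 1,
                         name = "point") {
  suppressWarnings(species_record(
    name,
    omega_min = omega, omega_mode = omega, omega_max = omega,
    alpha50 = alpha, alpha_ci_low = alpha, alpha_ci_high = alpha + 1e-9,
    alpha_trunc_low = alpha - 0.25, alpha_trunc_high = alpha + 0.25,
    fecundity_min = m, fecundity_max = m,
    eggcase_min = le, eggcase_mode = le, eggcase_max = le,
    survival_min = s, survival_max = s,
    tmax_observed = omega))
}

taranetzi_record <- function() bering_records()[["Bathyraja taranetzi"]]

# power iteration: independent route to the dominant eigenpair
power_iteration <- function(a, tol = 1e-13, max_iter = 100000L) {
  x <- rep(1, nrow(a))
  lam <- 0
  for (i in seq_len(max_iter)) {
    y <- a %*% x
    lam_new <- max(abs(y))
    y <- y / lam_new
    if (max(abs(y - x)) < tol) {
      return(list(lambda = lam_new, w = as.numeric(y / sum(y))))
    }
    x <- y
    lam <- lam_new
  }
  list(lambda = lam_new, w = as.numeric(y / sum(y)))
}

# central-difference elasticities, independent of the eigenvector formula
fd_elasticity <- function(a, h = 1e-7) {
  lam0 <- power_iteration(a)$lambda
  e <- matrix(0, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] == 0) next
      d <- h * a[i, j]
      ap <- a; ap[i, j] <- a[i, j] + d
      am <- a; am[i, j] <- a[i, j] - d
      dlam <- (power_iteration(ap)$lambda - power_iteration(am)$lambda) /
        (2 * d)
      e[i, j] <- dlam * a[i, j] / lam0
    }
  }
  e
}

# small random Leslie matrix, always primitive (at least the last two
# classes are fertile, so the fertile classes are consecutive)
random_leslie <- function(n, mature_from = 2L) {
  mature_from <- min(mature_from, n - 1L)
  f <- numeric(n)
  f[mature_from:n] <- runif(n - mature_from + 1L, 0.5, 5)
  p <- runif(n - 1L, 0.3, 0.95)
  a <- matrix(0, n, n)
  a[1L, ] <- f
  a[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- p
  a
}
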