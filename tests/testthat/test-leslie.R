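# hand-evaluated 3x3 case used throughout: omega 3, alpha 2, point rates
# S = 0.8 (juvenile-reduced to 0.4, 0.6), m = 20 (0, 10, 20), l_e = 1
degenerate_draw <- function() {
  set.seed(1)
  draw_vital_rates(point_record(), "iid")
}

test_that("survivorship is the cumulative product of annual survival", {
  d <- degenerate_draw()
  expect_equal(survivorship_schedule(d), c(1, 0.4, 0.24, 0.192))
  set.seed(5)
  d2 <- draw_vital_rates(taranetzi_record(), "iid")
  l <- survivorship_schedule(d2)
  expect_identical(l[1L], 1)
  expect_length(l, d2$omega + 1L)
  expect_true(all(diff(l) <= 0))
})

test_that("birth-flow survival averages individuals entering and leaving", {
  # geometric survivorship telescopes back to the constant rate
  expect_equal(birth_flow_survival(c(1, 0.5, 0.25, 0.125)), c(0.5, 0.5))
  s <- 0.87
  expect_equal(birth_flow_survival(cumprod(c(1, rep(s, 6)))), rep(s, 5))
  # direct evaluation
  expect_equal(birth_flow_survival(c(1, 0.9, 0.3, 0.1)),
               c((0.9 + 0.3) / (1 + 0.9), (0.3 + 0.1) / (0.9 + 0.3)))
})

test_that("birth-flow fertility averages offspring and discounts the egg stage", {
  mk <- function(s, m, le, alpha = 1L) {
    structure(list(omega = length(m), alpha = alpha, survival = s,
                   fecundity = m, eggcase_survival = le, mode = "iid",
                   species_name = "hand"), class = "vital_rate_draw")
  }
  # l_e = 1, m = (0, 2, 2), P = (0.5, 0.5) -> F = (0.5, 1.5, 1.0)
  d <- mk(c(0.5, 0.5, 0.5), c(0, 2, 2), 1)
  expect_equal(birth_flow_fertility(d, c(0.5, 0.5)), c(0.5, 1.5, 1.0))
  # zero egg-case survival kills all fertility
  d0 <- mk(c(0.5, 0.5, 0.5), c(0, 2, 2), 0)
  expect_equal(birth_flow_fertility(d0, c(0.5, 0.5)), c(0, 0, 0))
  # sqrt(l_e) discount: 0.9 * (0 + 0.6 * 10) / 2 = 2.7
  d2 <- mk(c(0.7, 0.7), c(0, 10), 0.81)
  expect_equal(birth_flow_fertility(d2, 0.6)[1L], 2.7)
})

test_that("the assembled matrix matches the hand-evaluated schedules", {
  a <- assemble_matrix(degenerate_draw())
  P <- c(0.64 / 1.4, 0.432 / 0.64)
  Fv <- c((0 + P[1] * 10) / 2, (10 + P[2] * 20) / 2, 20 / 2)
  expected <- matrix(0, 3, 3)
  expected[1, ] <- Fv
  expected[cbind(2:3, 1:2)] <- P
  expect_equal(unclass(a), expected, ignore_attr = TRUE)
  expect_identical(attr(a, "alpha"), 2L)
  # dimension always equals the drawn longevity
  set.seed(2)
  d <- draw_vital_rates(taranetzi_record(), "iid")
  expect_identical(dim(assemble_matrix(d)), c(d$omega, d$omega))
})

test_that("eigen-analysis returns the dominant eigenpair", {
  # 1x1: the matrix entry itself
  e1 <- eigen_analysis(matrix(2.5, 1, 1))
  expect_equal(e1$lambda, 2.5)
  expect_equal(e1$w, 1)
  expect_equal(e1$v, 1)

  # 3x3 with known characteristic polynomial
  a <- matrix(c(0.5, 1.5, 1.0,
                0.5, 0, 0,
                0, 0.5, 0), 3, 3, byrow = TRUE)
  roots <- polyroot(c(-0.25, -0.75, -0.5, 1)) # l^3 - 0.5l^2 - 0.75l - 0.25
  lam_poly <- max(Re(roots[abs(Im(roots)) < 1e-9]))
  eg <- eigen_analysis(a)
  expect_equal(eg$lambda, lam_poly, tolerance = 1e-9)
  expect_equal(eg$lambda, 1.256, tolerance = 1e-3)
  expect_equal(sum(eg$w), 1)
  expect_equal(eg$v[1L], 1)

  # independent power-iteration oracle on random Leslie matrices
  set.seed(42)
  for (n in c(2, 4, 6, 9)) {
    a <- random_leslie(n)
    expect_equal(eigen_analysis(a)$lambda, power_iteration(a)$lambda,
                 tolerance = 1e-10)
  }
})

test_that("eigen-analysis rejects degenerate matrices", {
  expect_error(eigen_analysis(matrix(c(0, 0.5, 0, 0), 2, 2)),
               "no positive fertility")
  # pure cycle: three eigenvalues of equal modulus
  cyc <- matrix(c(0, 0, 2, 0.5, 0, 0, 0, 0.5, 0), 3, 3, byrow = TRUE)
  expect_error(eigen_analysis(cyc), "imprimitive")
  expect_error(eigen_analysis(matrix(c(1, -0.1, 0.5, 0), 2, 2)),
               "non-negative")
})

test_that("derived statistics match hand-computed schedules", {
  a <- matrix(c(0.5, 1.5, 1.0,
                0.5, 0, 0,
                0, 0.5, 0), 3, 3, byrow = TRUE)
  lam <- eigen_analysis(a)$lambda
  st <- demographic_statistics(a, lam)
  # lm = (1, 0.5, 0.25); F = (0.5, 1.5, 1.0)
  expect_equal(st$r0, 0.5 + 0.75 + 0.25)
  expect_equal(st$rt, log(1.5))
  expect_equal(st$mu1, (0.5 + 1.5 + 0.75) / 1.5)
  # at lambda = 1 the discount vanishes and abar equals mu1
  st1 <- demographic_statistics(a, 1)
  expect_equal(st1$abar, st1$mu1)

  # a single reproductive age is both generation times
  b <- matrix(0, 3, 3)
  b[1, 3] <- 4
  b[2, 1] <- 0.5
  b[3, 2] <- 0.5
  stb <- demographic_statistics(b, 1.2)
  expect_equal(stb$r0, 4 * 0.25)
  expect_equal(stb$mu1, 3)
  expect_equal(stb$abar, 3)
  expect_equal(stb$rt, log(1))

  expect_error(demographic_statistics(matrix(c(0, 0.5, 0, 0), 2, 2), 1),
               "no reproduction")
})

test_that("the Euler-Lotka identity holds at the computed growth rate", {
  set.seed(8)
  rec <- taranetzi_record()
  for (i in 1:20) {
    d <- draw_vital_rates(rec, "iid")
    a <- assemble_matrix(d)
    lam <- eigen_analysis(a)$lambda
    n <- nrow(a)
    P <- a[cbind(2:n, 1:(n - 1))]
    lm <- cumprod(c(1, P))
    expect_lt(abs(sum(lam^(-(1:n)) * lm * a[1, ]) - 1), 1e-8)
  }
})

test_that("lambda never decreases when a vital rate increases", {
  set.seed(13)
  for (i in 1:15) {
    a <- random_leslie(sample(3:7, 1))
    lam <- eigen_analysis(a)$lambda
    nz <- which(a > 0, arr.ind = TRUE)
    pick <- nz[sample(nrow(nz), 1), ]
    a2 <- a
    a2[pick[1], pick[2]] <- a2[pick[1], pick[2]] * 1.05
    expect_gte(eigen_analysis(a2)$lambda, lam)
  }
})

test_that("lambda and R0 sit on the same side of replacement", {
  set.seed(21)
  rec <- taranetzi_record()
  for (i in 1:15) {
    d <- draw_vital_rates(rec, "iid")
    a <- assemble_matrix(d)
    lam <- eigen_analysis(a)$lambda
    st <- demographic_statistics(a, lam)
    expect_identical(sign(lam - 1), sign(st$r0 - 1))
  }
})

test_that("elasticities sum to one and match finite differences", {
  expect_equal(elasticity_matrix(matrix(3, 1, 1)), matrix(1, 1, 1))
  set.seed(31)
  for (n in c(3, 4, 6)) {
    a <- random_leslie(n)
    e <- elasticity_matrix(a)
    expect_lt(abs(sum(e) - 1), 1e-8)
    expect_true(all(e[a == 0] == 0))
    expect_equal(e, fd_elasticity(a), tolerance = 1e-5)
  }
})

test_that("elasticity categories partition the total", {
  set.seed(17)
  d <- draw_vital_rates(taranetzi_record(), "iid")
  a <- assemble_matrix(d)
  e <- elasticity_matrix(a)
  cats <- elasticity_categories(e, d$alpha)
  expect_lt(abs(sum(cats) - 1), 1e-8)
  # all classes mature: no juvenile transitions
  expect_equal(unname(elasticity_categories(e, 1)["e_juvenile"]), 0)
  # maturity at the final class: no adult transitions
  expect_equal(unname(elasticity_categories(e, nrow(a))["e_adult"]), 0)
  expect_error(elasticity_categories(e, nrow(a) + 1), "outside")
})

test_that("compensation ratios scale elasticities as exchange rates", {
  expect_equal(compensation_ratio(0.2, 0.2, 10), 10)
  expect_equal(compensation_ratio(0.8, 0.2, 10), 40)
  expect_error(compensation_ratio(0.8, 0, 10), "impossible")
})

test_that("a draw with no reproduction cannot grow", {
  d <- structure(list(omega = 4L, alpha = 2L,
                      survival = c(0.4, 0.6, 0.8, 0.8),
                      fecundity = c(0, 0, 0, 0), eggcase_survival = 0.9,
                      mode = "iid", species_name = "sterile"),
                 class = "vital_rate_draw")
  a <- assemble_matrix(d)
  expect_error(eigen_analysis(a), "no positive fertility")
})
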