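test_that("factorial decomposition equals exhaustive enumeration", {
  set.seed(31)
  uf <- matrix(rbinom(12 * 25, 1, 0.5), 12, 25)
  um <- matrix(rbinom(9 * 25, 1, 0.5), 9, 25)
  a <- rnorm(25); d <- rnorm(25, 0, 0.5)
  arch <- structure(list(q = 1:25, a = a, d = d, qd = integer(0), scale = 1),
                    class = "trait_arch")
  dec <- factorial_decomposition(uf, um, arch)
  oracle <- enumerate_factorial(uf, um, a, d)
  expect_equal(dec$mu, oracle$mu, tolerance = 1e-9)
  expect_equal(dec$gca_f, oracle$gca_f, tolerance = 1e-9)
  expect_equal(dec$gca_m, oracle$gca_m, tolerance = 1e-9)
  expect_equal(dec$var_g, oracle$var_g, tolerance = 1e-9)
  expect_equal(dec$var_gca_f, oracle$var_gca_f, tolerance = 1e-9)
  expect_equal(dec$var_gca_m, oracle$var_gca_m, tolerance = 1e-9)
  expect_equal(dec$var_sca, oracle$var_sca, tolerance = 1e-9)
  # variance identity of the two-way layout
  expect_equal(dec$var_g,
               dec$var_gca_f + dec$var_gca_m + dec$var_sca, tolerance = 1e-9)
})

test_that("a purely additive trait has zero SCA variance", {
  set.seed(32)
  uf <- matrix(rbinom(10 * 30, 1, 0.5), 10, 30)
  um <- matrix(rbinom(10 * 30, 1, 0.5), 10, 30)
  arch <- structure(list(q = 1:30, a = rnorm(30), d = rep(0, 30),
                         qd = integer(0), scale = 1), class = "trait_arch")
  dec <- factorial_decomposition(uf, um, arch)
  expect_equal(dec$var_sca, 0, tolerance = 1e-12)
  expect_equal(dec$tau, 0, tolerance = 1e-9)
})

test_that("heterozygous factorial parents are rejected", {
  h1 <- matrix(0L, 3, 5); h2 <- matrix(1L, 3, 5)
  pop <- new_population(h1, h2, status = "S0", validate = FALSE)
  arch <- structure(list(q = 1:5, a = rnorm(5), d = rnorm(5),
                         qd = integer(0), scale = 1), class = "trait_arch")
  expect_error(factorial_decomposition(pop, pop, arch), "homozygous")
})

test_that("genic variances implement the closed-form expressions", {
  # single-locus toys, hand-evaluated
  arch1 <- structure(list(q = 1L, a = 2, d = 1, qd = integer(0), scale = 1),
                     class = "trait_arch")
  g <- genic_variances(p_f = 0.5, p_m = 0.5, arch1)
  # gcaF = p(1-p) [a - (2p_m - 1) d]^2 = 0.25 * 4 = 1, symmetric
  expect_equal(g$gca_f, 1)
  expect_equal(g$gca_m, 1)
  # sca = 4 p_f(1-p_f) p_m(1-p_m) d^2 = 4 * 0.25 * 0.25 * 1 = 0.25
  expect_equal(g$sca, 0.25)
  expect_equal(g$g, 2.25)
  # a fixed locus on one side contributes no gca variance on that side
  g2 <- genic_variances(p_f = 1, p_m = 0.5, arch1)
  expect_equal(g2$gca_f, 0)
  expect_equal(g2$sca, 0)
  # gcaM = p_m(1-p_m) [a - (2 p_f - 1) d]^2 = 0.25 * (2 - 1)^2
  expect_equal(g2$gca_m, 0.25)
})

test_that("genic variances match the factorial under linkage equilibrium", {
  # unlinked, independently drawn loci: genetic and genic variances agree
  # in expectation; use a large factorial for a tight Monte-Carlo check
  set.seed(33)
  n <- 400; m <- 80
  pf <- runif(m, 0.2, 0.8); pm <- runif(m, 0.2, 0.8)
  uf <- matrix(rbinom(n * m, 1, rep(pf, each = n)), n, m)
  um <- matrix(rbinom(n * m, 1, rep(pm, each = n)), n, m)
  arch <- structure(list(q = 1:m, a = rnorm(m), d = rnorm(m, 0.3, 0.3),
                         qd = integer(0), scale = 1), class = "trait_arch")
  dec <- factorial_decomposition(uf, um, arch)
  gen <- genic_variances(colMeans(uf), colMeans(um), arch)
  rat <- genic_ratios(dec, gen)
  expect_equal(rat$gca, 1, tolerance = 0.15)
  expect_equal(rat$g, 1, tolerance = 0.15)
})

test_that("Eq. 5 closed form gives the published checked value", {
  expect_equal(round(analytic_rg_tc_gca(tau = 0.45, phi = 1), 2), 0.62)
  # limiting cases
  expect_equal(analytic_rg_tc_gca(0, 1), 1)
  expect_equal(analytic_rg_tc_gca(0.45, 0),
               sqrt((1 - 0.45) / (1 - 0.45)))  # phi = 0: r = 1
  # single-cross tester lies between inbred and population tester
  expect_gt(analytic_rg_tc_gca(0.45, 0.5), analytic_rg_tc_gca(0.45, 1))
  expect_equal(rgca_tc(0.5, 0.45, 1), 0.5 * analytic_rg_tc_gca(0.45, 1))
})

test_that("expected drift loss reproduces the published percentages", {
  expect_equal(round(expected_drift_loss(20, 4)), 10)       # ~10% per cycle
  expect_equal(expected_drift_loss(20, 4), 9.6312, tolerance = 1e-4)
  expect_equal(expected_drift_loss(20, 4, squared = TRUE), 18.3347,
               tolerance = 1e-3)                            # SCA variant
})

test_that("modified Rogers distance is scaled to [0, 1]", {
  expect_equal(modified_rogers_distance(c(1, 1), c(0, 0)), 1)
  expect_equal(modified_rogers_distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  # one fixed-opposite locus plus one identical locus: sqrt(mean(c(1, 0)))
  expect_equal(modified_rogers_distance(c(1, 0.5), c(0, 0.5)),
               sqrt(1 / 2))
})

test_that("prediction accuracy handles degenerate inputs", {
  expect_equal(prediction_accuracy(1:10, 1:10), 1)
  expect_true(is.na(prediction_accuracy(rep(1, 5), rnorm(5))))
  expect_equal(prediction_accuracy(1:10, c(10:1), subset = 1:5),
               cor(1:5, 10:6))
})

test_that("cumulative gain is the mean difference to the baseline", {
  b <- list(mu = 0.2)
  s <- list(mu = 1.7)
  expect_equal(cumulative_gain(s, b), 1.5)
})
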