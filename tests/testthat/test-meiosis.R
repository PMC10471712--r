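test_that("a homozygous parent transmits its haplotype unchanged", {
  map <- even_map(n_chr = 2, total_cM = 300, n_markers = 50)
  h <- matrix(rep(c(0L, 1L), each = 25), 1, 50)
  pop <- new_population(h, h, status = "DH")
  set.seed(1)
  for (i in 1:20) expect_equal(recombine_gamete(pop, 1, map), drop(h))
})

test_that("recombination fractions follow the Haldane map function", {
  # one chromosome, three markers at 0, 0 and 50 cM
  map <- genetic_map(c(1, 1, 1), c(0, 0, 50))
  h1 <- matrix(c(0L, 0L, 0L), 1)
  h2 <- matrix(c(1L, 1L, 1L), 1)
  pop <- new_population(h1, h2, status = "S0", validate = FALSE)
  n <- 1e5
  set.seed(42)
  gam <- t(replicate(n, recombine_gamete(pop, 1, map)))
  # 0 cM apart: never recombine
  expect_equal(mean(gam[, 1] != gam[, 2]), 0)
  # 50 cM apart: Haldane r = 0.5 (1 - exp(-1)) = 0.3161
  r_exp <- 0.5 * (1 - exp(-1))
  se <- sqrt(r_exp * (1 - r_exp) / n)
  expect_lt(abs(mean(gam[, 2] != gam[, 3]) - r_exp), 3 * se)
})

test_that("loose linkage approaches free recombination", {
  map <- genetic_map(c(1, 1), c(0, 300))  # 3 Morgans apart
  pop <- new_population(matrix(c(0L, 0L), 1), matrix(c(1L, 1L), 1),
                        status = "S0", validate = FALSE)
  n <- 1e5
  set.seed(7)
  gam <- t(replicate(n, recombine_gamete(pop, 1, map)))
  r_exp <- 0.5 * (1 - exp(-6))
  se <- sqrt(r_exp * (1 - r_exp) / n)
  expect_lt(abs(mean(gam[, 1] != gam[, 2]) - r_exp), 3 * se)
})

test_that("chromosomes segregate independently", {
  map <- genetic_map(c(1, 2), c(0, 0))
  pop <- new_population(matrix(c(0L, 0L), 1), matrix(c(1L, 1L), 1),
                        status = "S0", validate = FALSE)
  n <- 1e5
  set.seed(11)
  gam <- t(replicate(n, recombine_gamete(pop, 1, map)))
  r <- mean(gam[, 1] != gam[, 2])
  se <- sqrt(0.25 / n)
  expect_lt(abs(r - 0.5), 3 * se)
})

test_that("DH production doubles one gamete into a homozygous line", {
  map <- even_map(n_chr = 1, total_cM = 100, n_markers = 20)
  set.seed(2)
  h1 <- matrix(rbinom(20, 1, 0.5), 1)
  h2 <- matrix(rbinom(20, 1, 0.5), 1)
  pop <- new_population(h1, h2, status = "S0", validate = FALSE)
  dh <- make_dh(pop, 1, map)
  expect_identical(dh$h1, dh$h2)
  expect_equal(dh$status, "DH")
  all_dh <- rrgsim:::make_dh_all(
    new_population(rbind(h1, h1), rbind(h2, h2),
                   status = "S0", validate = FALSE), map)
  expect_equal(n_ind(all_dh), 2)
  expect_identical(all_dh$h1, all_dh$h2)
})

test_that("crossing excludes selfing and random pairing needs even input", {
  map <- even_map(n_chr = 1, total_cM = 100, n_markers = 10)
  pop <- new_population(matrix(0L, 4, 10), matrix(0L, 4, 10), status = "DH")
  expect_error(cross(pop, 2, 2, map), "selfing")
  expect_error(random_pairing(1:5), "even")
  set.seed(1)
  pr <- random_pairing(1:8)
  expect_equal(sort(c(pr)), 1:8)  # every id used exactly once
  expect_true(all(pr[, 1] != pr[, 2]))
})

test_that("half-diallel mating design has the documented counts", {
  map <- even_map(n_chr = 1, total_cM = 100, n_markers = 10)
  set.seed(3)
  units <- new_population(matrix(rbinom(200, 1, .5), 20, 10),
                          matrix(rbinom(200, 1, .5), 20, 10),
                          status = "S0", validate = FALSE)
  prog <- half_diallel_progeny(units, progeny_per_mating = 5, map = map)
  plan <- attr(prog, "cross_plan")
  expect_equal(nrow(unique(plan)), 190)  # choose(20, 2) matings
  expect_equal(n_ind(prog), 950)         # 190 x 5 progeny
  expect_true(all(plan$parent1 != plan$parent2))
  # n_total overrides the per-mating count but keeps all matings
  prog2 <- half_diallel_progeny(units, map = map, n_total = 950)
  expect_equal(n_ind(prog2), 950)
  expect_equal(nrow(unique(attr(prog2, "cross_plan"))), 190)
})
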