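test_that("configurations validate their arguments", {
  expect_s3_class(rrgs_config(), "rrgs_config")
  expect_error(rrgs_config(n_sel_dh = 39))          # odd selection count
  expect_error(rrgs_config(n_ts = 1000))            # TS larger than candidates
  expect_error(rrgs_config(h2 = 0))
  cfg <- desk_config(n_cycles = 2)
  expect_equal(cfg$n_cycles, 2)
  expect_equal(cfg$n_candidates, 950)
})

test_that("child seeds are deterministic and distinct across streams", {
  s1 <- rrgsim:::child_seeds(42)
  s2 <- rrgsim:::child_seeds(42)
  expect_identical(s1, s2)
  expect_false(any(duplicated(s1)))
  expect_true(all(c("founders", "panel", "effects", "hs", "fs") %in%
                  names(s1)))
  expect_false(any(s1 == rrgsim:::child_seeds(43)[names(s1)]))
})

test_that("select_top picks the highest scores with a stable tie-break", {
  expect_equal(select_top(c(1, 5, 3, 5, 2), 2), c(2, 4))
  expect_equal(select_top(rep(0, 6), 3), 1:3)
  expect_error(select_top(1:3, 5))
})

test_that("the base population initialises to the documented state", {
  cfg <- smoke_config()
  base <- init_rrgs_base(cfg, seed = 7)
  expect_equal(n_ind(base$pop_f), cfg$n_candidates)
  expect_equal(n_ind(base$pop_m), cfg$n_candidates)
  expect_identical(base$pop_f$h1, base$pop_f$h2)  # DH
  # trait scaled to unit factorial variance
  dec <- factorial_decomposition(base$pop_f, base$pop_m, base$arch)
  expect_equal(dec$var_g, 1, tolerance = 1e-10)
  # fixed error variance from h2
  expect_equal(base$sigma2_e, (1 - cfg$h2) / cfg$h2)
  # QTL panel and prediction panel R are disjoint
  expect_length(intersect(base$arch$q, base$arch$r), 0)
  # reproducible
  base2 <- init_rrgs_base(cfg, seed = 7)
  expect_identical(base$pop_f$h1, base2$pop_f$h1)
  expect_identical(base$arch$a, base2$arch$a)
})

test_that("one scheme replicate has the documented log structure", {
  cfg <- smoke_config()
  base <- init_rrgs_base(cfg, seed = 11)
  lg <- run_scheme(base, cfg, "HS", seed = 12)
  # 1 + subcycles rows per cycle
  expect_equal(nrow(lg), cfg$n_cycles * (cfg$subcycles + 1))
  expect_equal(lg$s[lg$t == 1], 0:cfg$subcycles)
  # baseline: zero gain and unit variance at C_1,0
  expect_equal(lg$sum_dg[1], 0)
  expect_equal(lg$var_g[1], 1, tolerance = 1e-10)
  # variance identity holds in every logged factorial
  expect_equal(lg$var_g, lg$var_gca_f + lg$var_gca_m + lg$var_sca,
               tolerance = 1e-8)
  # tau consistent with its components
  expect_equal(lg$tau, 100 * lg$var_sca / lg$var_g, tolerance = 1e-8)
  # genetic distance and training diagnostics only logged at s = 0
  expect_true(all(is.na(lg$mrd[lg$s > 0])))
  expect_true(all(!is.na(lg$mrd[lg$s == 0])))
  # reproducibility of the full trajectory
  lg2 <- run_scheme(base, cfg, "HS", seed = 12)
  expect_equal(lg, lg2)
  # a different seed gives a different trajectory
  lg3 <- run_scheme(base, cfg, "HS", seed = 13)
  expect_false(isTRUE(all.equal(lg$sum_dg, lg3$sum_dg)))
})

test_that("both methods run on one shared base and are paired by replicate", {
  cfg <- smoke_config()
  sim <- run_rrgs(cfg, methods = c("HS", "FS"), replicates = 2, seed = 21)
  expect_s3_class(sim, "rrgs_sim")
  expect_setequal(unique(sim$method), c("HS", "FS"))
  expect_equal(nrow(sim),
               2 * 2 * cfg$n_cycles * (cfg$subcycles + 1))
  # the baseline C_1,0 factorial is identical across methods within a
  # replicate (shared base population and trait)
  b_hs <- sim$mu[sim$method == "HS" & sim$t == 1 & sim$s == 0]
  b_fs <- sim$mu[sim$method == "FS" & sim$t == 1 & sim$s == 0]
  expect_equal(b_hs, b_fs, tolerance = 1e-12)
  # identical re-run
  sim2 <- run_rrgs(cfg, methods = c("HS", "FS"), replicates = 2, seed = 21)
  expect_equal(sim$sum_dg, sim2$sum_dg)
})

test_that("the initial tester is a plausible top genotype", {
  cfg <- smoke_config()
  base <- init_rrgs_base(cfg, seed = 31)
  set.seed(1)
  idx <- choose_initial_tester(base$pop_m, base$pop_f, base$arch,
                               sigma2_e = 0)
  # with sigma2_e = 0 the choice is the true-GCA argmax of the sampled 100
  u_m <- base$pop_m$h1[, base$arch$q]
  u_f <- base$pop_f$h1[, base$arch$q]
  gca_m <- rowMeans(rrgsim:::factorial_values(u_m, u_f, base$arch$a,
                                              base$arch$d))
  expect_gte(gca_m[idx], quantile(gca_m, 0.9))
})
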