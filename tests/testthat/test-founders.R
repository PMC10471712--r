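test_that("generate_founder_pools yields two divergent panels on one map", {
  fp <- generate_founder_pools(145, 111, maize_like_map(2000),
                               divergence_generations = 30,
                               effective_size = 50, seed = 1)
  expect_s3_class(fp$F, "founder_panel")
  expect_s3_class(fp$M, "founder_panel")
  expect_equal(ncol(fp$F$haplo), ncol(fp$M$haplo))
  expect_equal(nrow(fp$F$haplo), 145)
  expect_equal(nrow(fp$M$haplo), 111)
  expect_identical(fp$F$map$marker, fp$M$map$marker)
  pf <- colMeans(fp$F$haplo)
  pm <- colMeans(fp$M$haplo)
  expect_gt(mean(abs(pf - pm)), 0)
  # no marker monomorphic in both pools jointly
  joint <- colSums(fp$F$haplo) + colSums(fp$M$haplo)
  expect_true(all(joint > 0 & joint < 145 + 111))
  # reproducible under the same seed
  fp2 <- generate_founder_pools(145, 111, maize_like_map(2000),
                                divergence_generations = 30,
                                effective_size = 50, seed = 1)
  expect_identical(fp$F$haplo, fp2$F$haplo)
})

test_that("sample_base_population respects size, homozygosity and cap", {
  panel <- toy_panel(n_lines = 20, n_markers = 60)
  pop <- sample_base_population(panel, n = 100, max_gametes_per_founder = 12,
                                seed = 3)
  expect_equal(n_ind(pop), 100)
  expect_identical(pop$h1, pop$h2)  # DH lines
  usage <- attr(pop, "founder_usage")
  expect_true(all(usage <= 12))
  expect_equal(sum(usage), 200)  # two parental gametes per S0
})

test_that("founder gamete-usage cap holds per role over many seeded runs", {
  panel <- toy_panel(n_lines = 10, n_markers = 40)
  for (s in 1:100) {
    pop <- sample_base_population(panel, n = 30,
                                  max_gametes_per_founder = 4, seed = s)
    expect_true(all(attr(pop, "founder_usage") <= 4))
  }
})

test_that("infeasible gamete caps error; the reference sizes are feasible", {
  small <- toy_panel(n_lines = 18, n_markers = 40)
  expect_error(sample_base_population(small, n = 950,
                                      max_gametes_per_founder = 12),
               "infeasible")
  pop <- sample_base_population(small, n = 950,
                                max_gametes_per_founder = 55, seed = 1)
  expect_equal(n_ind(pop), 950)
  expect_true(all(attr(pop, "founder_usage") <= 55))
  big <- toy_panel(n_lines = 145, n_markers = 40)
  pop2 <- sample_base_population(big, n = 950,
                                 max_gametes_per_founder = 12, seed = 1)
  expect_equal(n_ind(pop2), 950)
  expect_true(all(attr(pop2, "founder_usage") <= 12))
})

test_that("no S0 cross is a selfing", {
  panel <- toy_panel(n_lines = 6, n_markers = 40)
  for (s in 1:20) {
    pairs <- local({
      set.seed(s)
      rrgsim:::draw_founder_pairs(6, 15, 3)
    })
    expect_true(all(pairs[, 1] != pairs[, 2]))
  }
})

test_that("founder panels round-trip through the text format", {
  panel <- toy_panel(n_lines = 5, n_markers = 30, pool = "M")
  gpath <- tempfile(fileext = ".tsv")
  mpath <- tempfile(fileext = ".tsv")
  write_founder_panel(panel, gpath, mpath)
  back <- load_founders(gpath, mpath, pool = "M")
  expect_equal(unname(back$haplo), unname(panel$haplo))
  expect_equal(back$map$marker, panel$map$marker)
  expect_equal(back$map$pos_cM, panel$map$pos_cM)
})

test_that("loader rejects or imputes heterozygous calls and unmapped markers", {
  panel <- toy_panel(n_lines = 4, n_markers = 10)
  gpath <- tempfile(fileext = ".tsv")
  mpath <- tempfile(fileext = ".tsv")
  write_founder_panel(panel, gpath, mpath)
  g <- read.table(gpath, header = TRUE, sep = "\t", check.names = FALSE)
  g[2, 3] <- 1  # heterozygous dosage
  write.table(g, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_founders(gpath, mpath), "heterozygous")
  imp <- load_founders(gpath, mpath, het = "missing")
  expect_true(all(imp$haplo %in% 0:1))
  # a genotype column absent from the map is an error
  mp <- read.table(mpath, header = TRUE, sep = "\t")
  write.table(mp[-1, ], mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_founders(gpath, mpath), "absent")
})

test_that("nucleotide-coded genotypes use the lexicographic reference rule", {
  gpath <- tempfile(fileext = ".tsv")
  mpath <- tempfile(fileext = ".tsv")
  writeLines(c("line\tm1\tm2", "L1\tAA\tCC", "L2\tTT\tCC", "L3\tTT\tGG"),
             gpath)
  writeLines(c("marker\tchr\tpos_cM", "m1\t1\t0", "m2\t1\t10"), mpath)
  panel <- load_founders(gpath, mpath)
  # m1: T > A lexicographically, so TT = 1; m2: G > C, so GG = 1
  expect_equal(unname(panel$haplo[, 1]), c(0L, 1L, 1L))
  expect_equal(unname(panel$haplo[, 2]), c(0L, 0L, 1L))
})
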