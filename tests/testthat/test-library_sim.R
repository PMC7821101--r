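test_that("library composition reproduces the screen library arithmetic", {
  lib <- build_library(481, 63, 10, 22)
  expect_length(lib$genes, 544)
  expect_equal(nrow(lib$sgrnas), 6092)  # 481*10 + 63*20 + 22
  expect_equal(length(unlist(lib$tss_map)), 481 + 2 * 63)
  expect_equal(sum(lib$sgrnas$gene == "NONTARGETING"), 22)
  expect_false(anyDuplicated(lib$sgrnas$sgrna_id) > 0)
  # every targeting sgRNA maps to exactly one TSS
  targ <- lib$sgrnas[lib$sgrnas$gene != "NONTARGETING", ]
  expect_true(all(!is.na(targ$tss)))
  expect_true(all(table(targ$tss) == 10))

  expect_equal(nrow(build_library(1, 0, 1, 0)$sgrnas), 1)
  ctrl_only <- build_library(0, 0, 0, 22)
  expect_length(ctrl_only$genes, 0)
  expect_equal(nrow(ctrl_only$sgrnas), 22)

  expect_error(build_library(-1, 0, 10, 22), "n_single_tss_genes")
})

test_that("population simulation honors infection and penetrance rates", {
  lib <- build_library(20, 0, 10, 22)
  hit <- lib$genes[1:4]
  effic <- stats::setNames(rep(1, nrow(lib$sgrnas)), lib$sgrnas$sgrna_id)
  eff <- effect_model(lib, hit_genes = hit, penetrance = 0.8,
                      efficacy = effic)
  pop <- simulate_population(lib, eff, 100000, infected_fraction = 0.125,
                             seed = 7)
  # binomial 99% CI around the infected fraction
  f <- mean(!is.na(pop$sgrna_id))
  expect_lt(abs(f - 0.125), 2.576 * sqrt(0.125 * 0.875 / 100000))
  # phenotype fraction among hit-sgRNA cells within binomial 99% CI of 0.8
  hits <- pop$is_hit_sgrna
  ph <- mean(pop$true_phenotype[hits])
  expect_lt(abs(ph - 0.8), 2.576 * sqrt(0.8 * 0.2 / sum(hits)))
  # single sgRNA per infected cell, none for uninfected
  expect_true(all(is.na(pop$sgrna_id) == is.na(pop$gene)))

  # degenerate penetrance values
  eff0 <- effect_model(lib, hit_genes = hit, penetrance = 0,
                       efficacy = effic)
  pop0 <- simulate_population(lib, eff0, 5000, seed = 1)
  expect_equal(sum(pop0$true_phenotype[pop0$is_hit_sgrna]), 0)
  eff1 <- effect_model(lib, hit_genes = hit, penetrance = 1,
                       efficacy = effic, effect_size = 10)
  pop1 <- simulate_population(lib, eff1, 5000, seed = 1)
  expect_true(all(pop1$true_phenotype[pop1$is_hit_sgrna]))
})

test_that("fixed seed gives a bit-identical population", {
  lib <- build_library(5, 1, 10, 5)
  eff <- effect_model(lib, hit_genes = lib$genes[1], seed = 3)
  p1 <- simulate_population(lib, eff, 2000, seed = 11)
  p2 <- simulate_population(lib, eff, 2000, seed = 11)
  expect_identical(p1, p2)
  p3 <- simulate_population(lib, eff, 2000, seed = 12)
  expect_false(identical(p1$area_um2, p3$area_um2))
})

test_that("nontargeting cells keep the baseline area distribution", {
  lib <- build_library(0, 0, 0, 22)
  pop <- simulate_population(lib, NULL, 10000, seed = 5)
  ba <- baseline_area_default()
  lp <- optenrich:::.lnorm_pars(ba[["mean"]], ba[["sd"]])
  ks <- suppressWarnings(
    stats::ks.test(pop$area_um2, stats::plnorm, lp$meanlog, lp$sdlog))
  expect_gt(ks$p.value, 0.01)
  # the top-0.5% of the baseline sits at the 1,000 um^2 screening threshold
  expect_equal(stats::qlnorm(0.995, lp$meanlog, lp$sdlog), 1000,
               tolerance = 1e-6)
})

test_that("uniform draw keeps sgRNA representation within 3-fold at 200x", {
  lib <- build_library(100, 0, 10, 0)
  pop <- simulate_population(lib, NULL, 200 * 1000, seed = 2)
  counts <- table(pop$sgrna_id)
  expect_length(counts, 1000)
  expect_lt(max(counts) / min(counts), 3)
})

test_that("BFP reporter separates infected from uninfected cells", {
  lib <- build_library(5, 0, 10, 2)
  pop <- simulate_population(lib, NULL, 20000, infected_fraction = 0.5,
                             seed = 9)
  inf <- !is.na(pop$sgrna_id)
  expect_gt(mean(pop$bfp_ln[inf]), mean(pop$bfp_ln[!inf]) + 1.5)
  # the 7.6 gate separates the two populations well
  expect_gt(mean(pop$bfp_ln[inf] > 7.6), 0.95)
  expect_gt(mean(pop$bfp_ln[!inf] <= 7.6), 0.95)
})

test_that("empty library cannot be infected and library TSV round-trips", {
  lib0 <- build_library(0, 0, 0, 0)
  expect_error(simulate_population(lib0, NULL, 10, infected_fraction = 0.5),
               "empty library")
  lib <- build_library(3, 1, 4, 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, path)
  lib2 <- read_library(path)
  expect_identical(lib2$sgrnas$sgrna_id, lib$sgrnas$sgrna_id)
  expect_identical(lib2$genes, lib$genes)
  expect_equal(lib2$n_nontargeting, 5)
})
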