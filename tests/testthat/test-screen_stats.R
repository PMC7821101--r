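test_that("phenotypic scores follow the pinned epsilon convention", {
  lib <- toy_library()
  nt <- c("NT1", "NT2")
  tab <- count_table(lib, s = c(A1 = 8, NT1 = 1, NT2 = 1),
                     r = c(A1 = 2, NT1 = 1, NT2 = 1))
  sc <- phenotypic_scores(tab, "s", "r", nt)
  expect_equal(sc$epsilon[sc$sgrna_id == "A1"], log2(9 / 3),
               tolerance = 1e-12)
  # identical columns give epsilon 0 everywhere
  tab2 <- count_table(lib, s = c(A1 = 5, NT1 = 3, NT2 = 7),
                      r = c(A1 = 5, NT1 = 3, NT2 = 7))
  expect_true(all(phenotypic_scores(tab2, "s", "r", nt)$epsilon == 0))
  # depth-normalization identity: doubling both columns changes nothing
  tab3 <- count_table(lib, s = c(A1 = 16, NT1 = 2, NT2 = 2),
                      r = c(A1 = 4, NT1 = 2, NT2 = 2))
  sc3 <- phenotypic_scores(tab3, "s", "r", nt, pseudocount = 2)
  sc1 <- phenotypic_scores(tab, "s", "r", nt, pseudocount = 1)
  expect_equal(sc3$epsilon, sc1$epsilon, tolerance = 1e-12)
  # nontargeting median is exactly 0 after centering
  set.seed(10)
  lib2 <- build_library(30, 0, 10, 22)
  ids <- lib2$sgrnas$sgrna_id
  tabr <- count_table(lib2,
    s = stats::setNames(as.integer(rmultinom(1, 1e5, rep(1, 322))), ids),
    r = stats::setNames(as.integer(rmultinom(1, 1e5, rep(1, 322))), ids))
  scr <- phenotypic_scores(tabr, "s", "r", nontargeting_ids(lib2))
  expect_equal(stats::median(scr$epsilon[scr$gene == "NONTARGETING"]), 0)
  expect_error(phenotypic_scores(tab, "s", "s", nt), "differ")
  tab0 <- count_table(lib, s = c(A1 = 0, NT1 = 0, NT2 = 0),
                      r = c(A1 = 1, NT1 = 1, NT2 = 1))
  expect_error(phenotypic_scores(tab0, "s", "r", nt), "zero total")
})

test_that("run averaging is the arithmetic mean and reduces variance", {
  lib <- toy_library()
  mk <- function(e) data.frame(sgrna_id = c("A1", "NT1", "NT2"),
                               gene = lib$sgrnas$gene, tss = lib$sgrnas$tss,
                               epsilon = e)
  expect_equal(average_runs(list(mk(c(1, 0, 0))))$epsilon, c(1, 0, 0))
  expect_equal(average_runs(list(mk(c(2, 0, 0)), mk(c(0, 0, 0))))$epsilon,
               c(1, 0, 0))
  expect_equal(average_runs(rep(list(mk(c(1, 1, 1))), 4))$epsilon,
               c(1, 1, 1))
  bad <- mk(c(1, 0, 0)); bad$sgrna_id <- c("B1", "NT1", "NT2")
  expect_error(average_runs(list(mk(c(1, 0, 0)), bad)), "mismatched")
  # Monte-Carlo: averaging four runs shrinks the per-sgRNA spread
  set.seed(22)
  lib2 <- build_library(10, 0, 10, 22)
  ids <- lib2$sgrnas$sgrna_id
  nt <- nontargeting_ids(lib2)
  one_run <- function() {
    tab <- count_table(lib2,
      s = stats::setNames(as.integer(rmultinom(1, 5e4, rep(1, 122))), ids),
      r = stats::setNames(as.integer(rmultinom(1, 5e4, rep(1, 122))), ids))
    phenotypic_scores(tab, "s", "r", nt)
  }
  singles <- one_run()
  averaged <- average_runs(replicate(4, one_run(), simplify = FALSE))
  expect_lt(stats::var(averaged$epsilon), stats::var(singles$epsilon))
})

test_that("grouping partitions sgRNAs and is deterministic per seed", {
  sc <- data.frame(sgrna_id = sprintf("s%d", 1:6), gene = "X",
                   tss = "X_T1", epsilon = c(1, 2, 3, 4, 5, 6))
  g1 <- group_scores(sc, 1, "random", seed = 1)
  expect_equal(sort(g1$epsilon), sort(sc$epsilon))
  g2 <- group_scores(sc, 2, "random", seed = 1)
  expect_equal(nrow(g2), 3)
  expect_equal(sum(g2$epsilon * 2), sum(sc$epsilon))
  expect_identical(g2, group_scores(sc, 2, "random", seed = 1))
  expect_error(group_scores(sc, 7, "random"), "exceeds")
  # leftovers are dropped
  expect_equal(nrow(group_scores(sc, 4, "random", seed = 2)), 1)
  expect_equal(group_scores(sc, 2, "by_tss")$epsilon, mean(sc$epsilon))
})

test_that("Mann-Whitney p matches exhaustive enumeration for small groups", {
  expect_equal(tss_pvalue(c(3, 4, 5), c(0, 1, 2)), 0.1, tolerance = 1e-12)
  expect_equal(mw_enum_p(c(3, 4, 5), c(0, 1, 2)), 0.1, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(3:8, 1)
    x <- stats::rnorm(n1); y <- stats::rnorm(n2)
    expect_equal(tss_pvalue(x, y), mw_enum_p(x, y), tolerance = 1e-9)
  }
  # equal multisets sit at the null center
  x <- c(1, 2, 3)
  expect_equal(optenrich:::mw_u(x, x), length(x)^2 / 2)
  expect_gt(tss_pvalue(c(1, 2, 3, 4), c(4, 3, 2, 1)), 0.9)
  # degenerate all-tied input
  expect_equal(tss_pvalue(rep(2, 5), rep(2, 9)), 1)
  expect_error(tss_pvalue(numeric(), 1:3), "non-empty")
})

test_that("tied inputs follow the tie-corrected normal convention", {
  set.seed(15)
  for (i in 1:25) {
    x <- sample(0:3, sample(3:5, 1), replace = TRUE)
    y <- sample(0:3, sample(4:8, 1), replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE)$p.value)
    if (is.finite(ref)) expect_equal(tss_pvalue(x, y), ref,
                                     tolerance = 1e-9)
  }
  # at screen-scale group sizes the approximation tracks a brute-force
  # permutation of the group labels within Monte-Carlo error
  set.seed(25)
  x <- sample(seq(0, 2, by = 0.25), 10, replace = TRUE)
  y <- sample(seq(0, 2, by = 0.25), 22, replace = TRUE)
  comb <- c(x, y)
  dev <- abs(optenrich:::mw_u(x, y) - 110)
  perm <- replicate(20000, {
    ix <- sample(32, 10)
    abs(optenrich:::mw_u(comb[ix], comb[-ix]) - 110)
  })
  p_mc <- mean(perm >= dev - 1e-9)
  expect_lt(abs(tss_pvalue(x, y) - p_mc),
            0.02 + 3 * sqrt(p_mc * (1 - p_mc) / 20000))
})

test_that("vectorized TSS scoring equals the scalar test and reference", {
  set.seed(16)
  lib <- build_library(40, 5, 10, 22)
  sc <- data.frame(sgrna_id = lib$sgrnas$sgrna_id, gene = lib$sgrnas$gene,
                   tss = lib$sgrnas$tss,
                   epsilon = round(stats::rnorm(nrow(lib$sgrnas)), 1))
  nt <- nontargeting_ids(lib)
  tss <- score_tss(sc, nt)
  expect_equal(nrow(tss), 50)
  nt_eps <- sc$epsilon[sc$sgrna_id %in% nt]
  for (t in sample(tss$tss, 12)) {
    member <- sc$epsilon[!is.na(sc$tss) & sc$tss == t]
    expect_equal(tss$p_value[tss$tss == t], tss_pvalue(member, nt_eps),
                 tolerance = 1e-12)
    ref <- suppressWarnings(stats::wilcox.test(member, nt_eps)$p.value)
    expect_equal(tss$p_value[tss$tss == t], ref, tolerance = 1e-9)
    expect_equal(tss$epsilon[tss$tss == t], mean(member), tolerance = 1e-12)
  }
})

test_that("eta combines severity and significance multiplicatively", {
  expect_equal(eta(2, exp(-3)), 6)
  expect_equal(eta(5, 1), 0)
  expect_equal(eta(0, 0.001), 0)
  expect_error(eta(1, 0), "p must be")
  expect_error(eta(1, 1.5), "p must be")
  set.seed(18)
  eps <- sort(stats::runif(20, 0, 5))
  expect_true(all(diff(eta(eps, 0.01)) > 0))
  ps <- sort(stats::runif(20, 0.001, 1), decreasing = TRUE)
  expect_true(all(diff(eta(2, ps)) >= 0))
  expect_true(all(eta(stats::rnorm(50), stats::runif(50, 0.01, 1)) >= 0))
})

test_that("simulated negatives score like genes and match the null", {
  lib <- build_library(481, 63, 10, 22)
  nt <- nontargeting_ids(lib)
  # zero-epsilon library: everything degenerate
  sc0 <- data.frame(sgrna_id = lib$sgrnas$sgrna_id, gene = lib$sgrnas$gene,
                    tss = lib$sgrnas$tss, epsilon = 0)
  sn0 <- simulated_negatives(sc0, nt, 10, n_draws = 2, seed = 1)
  expect_equal(nrow(sn0), 2 * 609)  # floor(6092 / 10) per draw
  expect_true(all(sn0$epsilon == 0))
  expect_true(all(sn0$p_value == 1))
  expect_true(all(sn0$eta == 0))
  # null screen: gene eta and simulated-negative eta indistinguishable
  set.seed(19)
  sc <- sc0; sc$epsilon <- stats::rnorm(nrow(sc))
  tss <- score_tss(sc, nt)
  sn <- simulated_negatives(sc, nt, 10, n_draws = 10, seed = 2)
  genes <- collapse_genes(tss)
  ks <- suppressWarnings(stats::ks.test(genes$eta, sn$eta))
  expect_gt(ks$p.value, 0.01)
  expect_identical(sn, simulated_negatives(sc, nt, 10, n_draws = 10,
                                           seed = 2))
})

test_that("eFDR follows the counting definition and is monotone", {
  expect_equal(efdr(1.5, c(5, 4, 1), c(2, 0.5)), 1 / 3)
  expect_equal(efdr(3, c(5, 4, 1), c(2, 0.5)), 0)
  expect_equal(efdr(10, c(5, 4, 1), c(2, 0.5)), 0)  # 0/0 defined as 0
  # ties at the cutoff are not positives (strict inequality)
  expect_equal(efdr(2, c(5, 4, 1), c(2, 0.5)), 0)
  ec <- efdr_curve(c(5, 4, 1), c(2, 0.5), target = 0.5)
  expect_true(all(diff(ec$curve$efdr) <= 0))
  expect_true(all(ec$curve$efdr >= ec$curve$efdr_raw - 1e-12))
  # draw scaling: 3 draws of the same null scale the exceedance back down
  expect_equal(efdr(1.5, c(5, 4, 1), rep(c(2, 0.5), 3), n_draws = 3), 1 / 3)
  # cutoff above every simulated negative gives zero eFDR and calls hits
  ec2 <- efdr_curve(c(5, 4, 1), c(2, 0.5), target = 0.001)
  expect_equal(ec2$cutoff, 2)
  expect_equal(ec2$hits, c(TRUE, TRUE, FALSE))
  expect_error(efdr_curve(numeric(), 1), "non-empty")
})

test_that("gene collapse takes the strongest TSS and hit calls respect eta", {
  tss <- data.frame(gene = c("A", "A", "B"), tss = c("A_T1", "A_T2", "B_T1"),
                    n_sgrnas = 10, epsilon = c(1, 3, 0.5),
                    p_value = c(0.01, 0.001, 0.5),
                    eta = c(1 * -log(0.01), 3 * -log(0.001),
                            0.5 * -log(0.5)))
  genes <- collapse_genes(tss)
  expect_equal(nrow(genes), 2)
  expect_equal(genes$tss[genes$gene == "A"], "A_T2")
  sn <- data.frame(draw = 1, group = 1:2, epsilon = 0, p_value = 1,
                   eta = c(2, 0.1))
  attr(sn, "n_draws") <- 1
  res <- call_hits(tss, sn, target = 0.5)
  expect_true(res$genes$hit[res$genes$gene == "A"])
  expect_true(all(res$genes$eta[res$genes$hit] > res$cutoff))
})

test_that("efficacy subsetting keeps controls and halves targeting rows", {
  lib <- build_library(10, 2, 10, 22)
  tab <- count_table(lib)
  top <- subset_by_efficacy(tab, lib, "top5")
  expect_equal(sum(top$gene == "NONTARGETING"), 22)
  expect_equal(sum(top$gene != "NONTARGETING"), (10 + 2 * 2) * 5)
  sup <- subset_by_efficacy(tab, lib, "supp5")
  expect_equal(nrow(top) + nrow(sup), nrow(tab) + 22)
})

test_that("count tables round-trip as TSV and reject bad input", {
  lib <- build_library(3, 0, 4, 2)
  ids <- lib$sgrnas$sgrna_id
  tab <- count_table(lib, a = stats::setNames(seq_along(ids), ids))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path, seed = 1, config_hash = "abc")
  back <- read_count_table(path)
  expect_equal(back$count_a, tab$count_a)
  expect_equal(back$sgrna_id, tab$sgrna_id)
  expect_error(count_table(lib, a = rep(-1L, length(ids))), "negative")
  expect_equal(hit_rate(15, 544), 100 * 15 / 544)
})
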