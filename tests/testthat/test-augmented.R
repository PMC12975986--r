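test_that("the worked adjustment example reproduces by hand", {
  fb <- worked_fieldbook()          # block check means 11 and 14
  adj <- adjust_means(fb)
  expect_equal(unname(adj$block_effects[, "Y"]), c(-1.5, 1.5))
  expect_equal(sum(adj$block_effects[, "Y"]), 0)
  expect_equal(adj$means["G2", "Y"], 18.5)   # 20 observed in block 2
  expect_equal(adj$means["G1", "Y"], 16.5)
  expect_equal(unname(adj$check_means[, "Y"]), c(11, 14))
})

test_that("equal block check means leave test observations untouched", {
  plots <- data.frame(plot = 1:6, block = rep(1:2, each = 3),
                      accession = c("Ck", "Ck", "G1", "Ck", "Ck", "G2"),
                      role = c("check", "check", "test")[c(1, 1, 3, 1, 1, 3)],
                      Y = c(5, 7, 11, 6, 6, 13), stringsAsFactors = FALSE)
  fb <- field_book(plots, trait_descriptors("Y", "quantitative"))
  adj <- adjust_means(fb)
  expect_equal(unname(adj$block_effects[, "Y"]), c(0, 0))
  expect_equal(adj$means["G1", "Y"], 11)
  expect_equal(adj$means["G2", "Y"], 13)
})

test_that("noise-free synthetic data is recovered exactly after adjustment", {
  cfg <- small_config(n_test = 40, n_blocks = 4, ve = c(0, 0, 0))
  sim <- generate_collection(cfg)       # block effects present, no error
  adj <- adjust_means(sim$fieldbook)
  mu <- setNames(cfg$traits$mean, cfg$traits$trait)
  for (tr in cfg$traits$trait) {
    truth <- mu[[tr]] + sim$truth[rownames(adj$means), tr]
    expect_equal(unname(adj$means[, tr]), unname(truth), tolerance = 1e-10)
    expect_equal(unname(adj$ve[[tr]]), 0, tolerance = 1e-18)
  }
})

test_that("adjustment is idempotent once block effects are removed", {
  sim <- generate_collection(small_config(n_test = 30, n_blocks = 3))
  fb <- sim$fieldbook
  adj <- adjust_means(fb)
  pl2 <- fb$plots
  for (tr in adj$traits) {
    pl2[[tr]] <- pl2[[tr]] - adj$block_effects[pl2$block, tr]
  }
  adj2 <- adjust_means(field_book(pl2, fb$descriptors))
  expect_lt(max(abs(adj2$block_effects)), 1e-10)
})

test_that("ANOVA strata match the least-squares oracle on random designs", {
  for (seed in 1:8) {
    fb <- random_small_fieldbook(seed)
    an <- abd_anova(fb)
    tab <- an$tables$Y
    fit <- lm(Y ~ factor(block) + factor(accession), data = fb$plots)
    oracle <- anova(fit)
    expect_equal(tab$ss[tab$source == "block"],
                 oracle["factor(block)", "Sum Sq"], tolerance = 1e-8)
    expect_equal(tab$ss[tab$source == "treatment"],
                 oracle["factor(accession)", "Sum Sq"], tolerance = 1e-8)
    expect_equal(tab$ss[tab$source == "error"],
                 oracle["Residuals", "Sum Sq"], tolerance = 1e-8)
    expect_equal(tab$df[tab$source == "error"], oracle["Residuals", "Df"])
    # decomposition: component strata add to the corrected total
    expect_equal(sum(tab$ss[tab$source %in% c("block", "treatment", "error")]),
                 attr(tab, "ss_total"), tolerance = 1e-8)
    expect_equal(sum(tab$ss[tab$source %in%
                              c("checks", "tests", "checks_vs_tests")]),
                 tab$ss[tab$source == "treatment"], tolerance = 1e-8)
  }
})

test_that("degenerate and small designs give the textbook error stratum", {
  # b=2 blocks, c=2 checks, one rep: error df = (2-1)(2-1) = 1
  fb <- worked_fieldbook()
  an <- abd_anova(fb)
  expect_equal(an$tables$Y$df[an$tables$Y$source == "error"], 1L)
  # constant checks: zero error
  pl <- fb$plots
  pl$Y[pl$role == "check"] <- 9
  an0 <- abd_anova(field_book(pl, fb$descriptors))
  expect_equal(an0$tables$Y$ss[an0$tables$Y$source == "error"], 0)
  expect_equal(unname(an0$ve[["Y"]]), 0)
  # fewer than two checks: no error stratum
  one <- pl[pl$accession != "CkB", ]
  expect_error(abd_anova(field_book(one, fb$descriptors)), "at least 2 checks")
})

test_that("adjusted means track the truth better as error shrinks", {
  mse <- vapply(c(9, 3, 0.5), function(ve) {
    cfg <- small_config(n_test = 80, n_blocks = 4, ve = c(ve, ve, ve),
                        seed = 7)
    sim <- generate_collection(cfg)
    adj <- adjust_means(sim$fieldbook)
    truth <- cfg$traits$mean[1] + sim$truth[rownames(adj$means), "T1"]
    mean((adj$means[, "T1"] - truth)^2)
  }, numeric(1))
  expect_true(all(diff(mse) < 0))
})

test_that("critical differences follow the Federer formulas", {
  fb <- worked_fieldbook()
  an <- abd_anova(fb)
  # synthetic ANOVA shell with controlled Ve
  shell <- an
  shell$ve[] <- 4; shell$error_df[] <- 1
  cd <- critical_differences(shell, alpha = 0.05)
  t1 <- qt(0.975, 1)                        # 12.706
  expect_equal(cd$cd_test_test_same_block, t1 * sqrt(8), tolerance = 1e-6)
  expect_equal(cd$cd_check_check, t1 * sqrt(2 * 4 / 2), tolerance = 1e-6)
  expect_equal(cd$cd_test_test_diff_block, t1 * sqrt(2 * 4 * 3 / 2),
               tolerance = 1e-6)
  expect_equal(cd$cd_test_check, t1 * sqrt(4 * (1 + 1/2 + 1/2 + 1/4)),
               tolerance = 1e-6)
  shell$ve[] <- 0
  expect_true(all(critical_differences(shell)[, 2:5] == 0))
  # monotone in Ve at fixed df
  shell$ve[] <- 9
  cd9 <- critical_differences(shell)
  expect_true(all(cd9[, 2:5] > cd[, 2:5] - 1e-12))
})

test_that("promising accessions are detected against the best check", {
  fb <- worked_fieldbook()
  adj <- adjust_means(fb)
  an <- abd_anova(fb)
  cd <- critical_differences(an)
  # nobody beats the best check by more than the CD here
  expect_equal(nrow(identify_promising(adj, cd, "Y")), 0L)
  # plant an extreme genotype
  pl <- fb$plots
  pl$Y[pl$accession == "G2"] <- 100
  adj2 <- adjust_means(field_book(pl, fb$descriptors))
  hits <- identify_promising(adj2, cd, "Y")
  expect_equal(hits$accession[1L], "G2")
  expect_error(identify_promising(adj, cd, "NOPE"), "unknown trait")
})

test_that("a planted extreme genotype is recovered from synthetic data", {
  cfg <- small_config(n_test = 60, n_blocks = 3, seed = 12)
  sim <- generate_collection(cfg)
  pl <- sim$fieldbook$plots
  target <- sim$fieldbook$tests[1L]
  pl$T1[pl$accession == target] <- pl$T1[pl$accession == target] + 100
  fb <- field_book(pl, sim$fieldbook$descriptors)
  adj <- adjust_means(fb)
  cd <- critical_differences(abd_anova(fb))
  hits <- identify_promising(adj, cd, "T1")
  expect_equal(hits$accession[1L], target)
})

test_that("Bartlett homogeneity screening matches the textbook formula", {
  # equal variances: statistic ~ 0, p ~ 1
  eq <- bartlett_homogeneity(rep(2.5, 4), rep(20, 4))
  expect_lt(unname(eq$statistic), 1e-10)
  expect_gt(eq$p.value, 0.999)
  # extreme heterogeneity
  het <- bartlett_homogeneity(c(1, 100), c(50, 50))
  expect_lt(het$p.value, 0.001)
  # hand-evaluated k=2 case: Ve=(2,8), df=(10,10)
  k <- 2; ve <- c(2, 8); df <- c(10, 10)
  pooled <- sum(df * ve) / sum(df)
  M <- sum(df) * log(pooled) - sum(df * log(ve))
  C <- 1 + (sum(1 / df) - 1 / sum(df)) / (3 * (k - 1))
  res <- bartlett_homogeneity(ve, df)
  expect_equal(unname(res$statistic), M / C, tolerance = 1e-12)
  expect_error(bartlett_homogeneity(c(1, -1), c(5, 5)), "positive")
  expect_error(bartlett_homogeneity(3, 5), "at least 2")
})
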