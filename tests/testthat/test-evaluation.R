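test_that("summary statistics handle degenerate and simple shapes", {
  s <- summary_stats(data.frame(x = c(4, 4, 4, 4)))
  expect_equal(s$sd, 0)
  expect_equal(s$iqr, 0)
  expect_true(is.na(s$skewness))
  s2 <- summary_stats(data.frame(x = 1:4))
  expect_equal(s2$skewness, 0, tolerance = 1e-12)
  s3 <- summary_stats(data.frame(x = c(1, 2, 3, 4, 100)))
  expect_gt(s3$skewness, 0)
  expect_equal(s2$cv, 100 * sd(1:4) / mean(1:4))
  expect_error(summary_stats(data.frame(x = 1)), ">= 2")
})

test_that("the identity core is the fixed point of every quality index", {
  sim <- generate_collection(small_config(n_test = 80, seed = 17))
  tr <- accession_traits(sim$fieldbook)
  hu <- hu_indices(tr, tr)
  expect_equal(as.numeric(hu), c(0, 0, 100, 100))
  cov <- class_coverage(tr, tr, sim$fieldbook$descriptors)
  expect_equal(unname(cov), c(100, 1))
  d <- gower_matrix(tr, sim$fieldbook$descriptors)
  expect_equal(unname(core_objective(d, rownames(tr))["a_ne"]), 0)
  bt <- distribution_tests(tr$T1, tr$T1)
  expect_equal(bt$statistic[bt$test == "t"], 0)
  expect_equal(bt$statistic[bt$test == "ks"], 0)
  expect_equal(bt$statistic[bt$test == "kl_distance"], 0)
  expect_true(all(bt$p_value[bt$test %in% c("t", "levene", "wilcoxon", "ks")] >
                    0.99))
})

test_that("Hu indices reproduce constructed range and CV patterns", {
  # two traits, core ranges 50% and 100% of the collection: CR = 75
  ec <- data.frame(a = seq(0, 10, length.out = 21),
                   b = seq(0, 10, length.out = 21))
  rownames(ec) <- sprintf("G%02d", 1:21)
  cc <- ec[6:16, ]           # range 5 on both
  cc$b <- seq(0, 10, length.out = 11)
  expect_equal(unname(hu_indices(ec, cc)["cr"]), 75)
  # hollowing out the middle keeps ranges but inflates CVs: CR 100, VR > 100
  keep <- c(1:4, 18:21)
  cc2 <- ec[keep, ]
  hu2 <- hu_indices(ec, cc2)
  expect_equal(unname(hu2["cr"]), 100)
  expect_gt(unname(hu2["vr"]), 100)
})

test_that("class coverage counts collection classes found in the core", {
  ec <- data.frame(s = letters[c(1:10)], row.names = sprintf("G%02d", 1:10),
                   stringsAsFactors = FALSE)
  cc <- ec[1:7, , drop = FALSE]
  cov <- class_coverage(ec, cc)
  expect_equal(unname(cov["coverage"]), 70)
  expect_equal(unname(cov["phenotype_ratio"]), 0.7)
  # dropping the only carrier of one state lowers the retained ratio
  sim <- generate_collection(small_config(n_test = 60, seed = 19))
  tr <- accession_traits(sim$fieldbook)
  counts <- table(tr$SC)
  rare <- names(counts)[which.min(counts)]
  cc2 <- tr[tr$SC != rare, ]
  cov2 <- class_coverage(tr, cc2, sim$fieldbook$descriptors)
  expect_lt(unname(cov2["phenotype_ratio"]), 1)
})

test_that("Shannon indices follow the definitions", {
  u <- shannon_diversity(c(50, 50))
  expect_equal(unname(u["h_prime"]), log(2), tolerance = 1e-12)
  expect_equal(unname(u["j_prime"]), 1)
  expect_equal(unname(shannon_diversity(c(10, 0, 0), k = 3)["h_prime"]), 0)
  expect_equal(unname(shannon_diversity(c(1, 1, 1, 1, 1))["h_max"]), log(5))
  expect_error(shannon_diversity(10, k = 1), "at least 2")
  # J' in [0,1], H' <= Hmax on random tables; J' = 1 iff uniform
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:9, 1)
    cnt <- rmultinom(1, 200, prob = runif(k))[, 1]
    if (sum(cnt > 0) == 0) next
    s <- shannon_diversity(cnt, k)
    expect_true(s["j_prime"] >= 0 && s["j_prime"] <= 1)
    expect_lte(s[["h_prime"]], s[["h_max"]] + 1e-12)
  }
  expect_lt(unname(shannon_diversity(c(190, 5, 5))["j_prime"]), 1)
})

test_that("sign tests use the exact binomial on non-tied traits", {
  s <- sign_tests(c(1, 2, 3, 4), c(2, 1, 4, 3))    # 2 up, 2 down
  expect_equal(s$p_value, 1)
  s2 <- sign_tests(rep(0, 7), rep(1, 7))            # 7 up, 0 down
  expect_equal(s2$p_value, 2 * 0.5^7, tolerance = 1e-12)
  s3 <- sign_tests(c(1, 2), c(1, 2))
  expect_true(s3$undefined)
  expect_true(is.na(s3$p_value))
})

test_that("the Mantel test is exact on identical matrices and reproducible", {
  set.seed(11)
  x <- matrix(rnorm(400), 20)
  m1 <- cor(x)
  mt <- mantel_test(m1, m1, permutations = 199, seed = 4)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_lte(mt$p_value, 1 / (199 + 1) + 1e-12)
  m2 <- cor(matrix(rnorm(400), 20))
  a <- mantel_test(m1, m2, permutations = 199, seed = 4)
  b <- mantel_test(m1, m2, permutations = 199, seed = 4)
  expect_identical(a$p_value, b$p_value)
  expect_lt(abs(a$r), 0.9)
  expect_error(mantel_test(diag(3), diag(3)), "constant")
})

test_that("the distribution battery matches independent formula oracles", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  bt <- distribution_tests(x, y)
  # Welch t by direct formula
  tval <- (mean(x) - mean(y)) / sqrt(var(x) / 5 + var(y) / 5)
  expect_equal(bt$statistic[bt$test == "t"], tval, tolerance = 1e-12)
  # Newman-Keuls two-group studentized range on pooled variance
  s2 <- (4 * var(x) + 4 * var(y)) / 8
  q <- abs(mean(x) - mean(y)) / sqrt(s2 / 2 * (1 / 5 + 1 / 5))
  expect_equal(bt$statistic[bt$test == "newman_keuls"], q, tolerance = 1e-12)
  expect_equal(bt$p_value[bt$test == "newman_keuls"],
               ptukey(q, 2, 8, lower.tail = FALSE), tolerance = 1e-12)
  # gross separation is detected by every location test
  far <- distribution_tests(1:10, 101:110)
  expect_lt(far$p_value[far$test == "t"], 1e-6)
  expect_lt(far$p_value[far$test == "ks"], 1e-3)
  expect_gt(far$statistic[far$test == "kl_distance"], 1)
})

test_that("the two-sample Anderson-Darling matches its reference values", {
  # frozen from an independent evaluation of the Scholz-Stephens statistic
  set.seed(5)
  x <- round(rnorm(30, 10, 2), 3)
  y <- round(rnorm(25, 11, 3), 3)
  ad <- germcore:::ad_two_sample(x, y)
  expect_equal(ad$statistic, 2.4601868, tolerance = 1e-6)
  expect_lt(abs(ad$p_value - 0.0318), 0.005)
})

test_that("KS and AD p-values are near-uniform under the null", {
  set.seed(2024)
  pk <- pa <- numeric(200)
  for (i in 1:200) {
    x <- rnorm(40); y <- rnorm(40)
    bt <- distribution_tests(x, y)
    pk[i] <- bt$p_value[bt$test == "ks"]
    pa[i] <- bt$p_value[bt$test == "anderson_darling"]
  }
  expect_gt(mean(pk > 0.5), 0.35)
  expect_lt(mean(pk < 0.05), 0.12)
  expect_lt(mean(pa < 0.05), 0.12)
  expect_gt(mean(pa), 0.35)
})

test_that("Q-Q data sits on the expected lines", {
  x <- rnorm(50)
  qq <- qq_data(x, x)
  expect_equal(qq$ec, qq$cc)
  qq2 <- qq_data(x, 2 * x)
  expect_equal(qq2$cc, 2 * qq2$ec, tolerance = 1e-12)
  qq3 <- qq_data(rnorm(30), rnorm(80))
  expect_equal(nrow(qq3), 30L)
})
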