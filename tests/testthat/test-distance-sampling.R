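test_that("Gower distances reproduce hand arithmetic", {
  tr <- data.frame(q = c(0, 5, 10), s = c("a", "b", "a"),
                   row.names = c("A", "B", "C"), stringsAsFactors = FALSE)
  d <- gower_matrix(tr)
  expect_equal(d["A", "C"], 1 * 0.5 + 0 * 0.5)   # |0-10|/10 and matching state
  expect_equal(d["A", "B"], (0.5 + 1) / 2)        # 0.5 quantitative + mismatch
  expect_equal(d["A", "A"], 0)
  one <- gower_matrix(data.frame(q = c(0, 10), row.names = c("A", "B")))
  expect_equal(one["A", "B"], 1)
})

test_that("Gower matrices satisfy the metric-range invariants", {
  sim <- generate_collection(small_config(n_test = 60, seed = 13))
  tr <- accession_traits(sim$fieldbook)
  d <- gower_matrix(tr, sim$fieldbook$descriptors)
  expect_true(isSymmetric(unname(d)))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  expect_true(all(d >= 0 & d <= 1))
  # constant trait dropped with warning; all-constant errors
  tr$CONST <- 1
  expect_warning(gower_matrix(tr), "constant trait")
  expect_error(suppressWarnings(
    gower_matrix(data.frame(a = c(1, 1), b = c("x", "x"),
                            row.names = c("A", "B")))),
    "constant")
})

test_that("objective values match hand enumeration on a 1-D instance", {
  d <- as.matrix(dist(c(A = 0, B = 1, C = 3)))
  ob <- core_objective(d, c("A", "C"))
  expect_equal(unname(ob["e_ne"]), 3)          # mean(3, 3)
  expect_equal(unname(ob["a_ne"]), mean(c(0, 1, 0)))
  expect_equal(unname(ob["e_e"]), 3)
  # whole collection: perfect representation
  expect_equal(unname(core_objective(d, c("A", "B", "C"))["a_ne"]), 0)
  # a pair: E-NE = E-E = their distance
  ob2 <- core_objective(d, c("A", "B"))
  expect_equal(unname(ob2["e_ne"]), unname(ob2["e_e"]))
  expect_error(core_objective(d, character()), "non-empty")
})

test_that("the optimizer finds the known optima of tiny instances", {
  pts <- c(G1 = 0, G2 = 1, G3 = 2, G4 = 10, G5 = 11)
  d <- as.matrix(dist(pts))
  en <- optimize_core(d, 2, w_en = 1, w_an = 0, seed = 1, budget = 500,
                      restarts = 5)
  expect_setequal(en$ids, c("G1", "G5"))      # max pairwise distance 11
  an <- optimize_core(d, 1, w_en = 0, w_an = 1, seed = 1, budget = 500,
                      restarts = 5)
  expect_equal(an$ids, "G3")                   # the medoid
  all5 <- optimize_core(d, 5, w_en = 1, w_an = 0, seed = 1)
  expect_setequal(all5$ids, names(pts))
  forced <- optimize_core(d, 2, w_en = 1, w_an = 0, forced = "G3",
                          seed = 1, budget = 500, restarts = 5)
  expect_true("G3" %in% forced$ids)
  expect_error(optimize_core(d, 9, 1, 0), "exceeds")
  expect_error(optimize_core(d, 2, w_en = 0.7, w_an = 0.6), "equal 1")
})

test_that("identical seeds give identical cores for every sampler", {
  sim <- generate_collection(small_config(n_test = 50, seed = 21))
  tr <- accession_traits(sim$fieldbook)
  d <- gower_matrix(tr, sim$fieldbook$descriptors)
  for (w in list(c(1, 0), c(0, 1), c(0.5, 0.5))) {
    a <- optimize_core(d, 8, w[1], w[2], seed = 5, budget = 1000, restarts = 5)
    b <- optimize_core(d, 8, w[1], w[2], seed = 5, budget = 1000, restarts = 5)
    expect_identical(a$ids, b$ids)
  }
  expect_identical(powercore_sample(tr, sim$fieldbook$descriptors, 8)$ids,
                   powercore_sample(tr, sim$fieldbook$descriptors, 8)$ids)
  expect_identical(pcss_sample(tr, 8)$ids, pcss_sample(tr, 8)$ids)
})

test_that("local search attains the exhaustive optimum on small instances", {
  set.seed(424)
  for (case in 1:12) {
    n <- sample(6:12, 1)
    k <- sample(2:4, 1)
    d <- as.matrix(dist(matrix(runif(n * 2), n)))
    dimnames(d) <- list(sprintf("A%02d", 1:n), sprintf("A%02d", 1:n))
    w <- sample(c(0, 0.5, 1), 1)
    core <- optimize_core(d, k, w_en = w, w_an = 1 - w, seed = case,
                          budget = 1000, restarts = 20)
    val <- germcore:::core_weighted_value(d, core$ids, w, 1 - w,
                                          core$normalization)
    best <- exhaustive_best(d, k, w, 1 - w, core$normalization)
    expect_gte(val, best$value - 1e-9)
  }
})

test_that("the EN weight trades diversity against representativeness", {
  sim <- generate_collection(small_config(n_test = 150, n_blocks = 5,
                                          seed = 33))
  tr <- accession_traits(sim$fieldbook)
  d <- gower_matrix(tr, sim$fieldbook$descriptors,
                    subset = c("T1", "T2", "T3"))
  ws <- c(0, 0.25, 0.5, 0.75, 1)
  obs <- t(vapply(ws, function(w) {
    core <- optimize_core(d, 15, w_en = w, w_an = 1 - w, seed = 3,
                          budget = 5000, restarts = 10)
    core$objective[c("e_ne", "a_ne")]
  }, numeric(2)))
  expect_true(all(diff(obs[, 1]) > -1e-9))   # E-NE non-decreasing in w_EN
  expect_true(all(diff(obs[, 2]) > -1e-9))   # A-NE non-decreasing in w_EN
})

test_that("greedy class coverage behaves like hand-traced PowerCore", {
  # one qualitative trait with three states: any size-3 core covers them all
  tr <- data.frame(s = c("A", "A", "B", "C", "C"),
                   row.names = sprintf("G%d", 1:5), stringsAsFactors = FALSE)
  core <- powercore_sample(tr, size = 3)
  expect_equal(core$extras$coverage, 100)
  expect_setequal(unique(tr[core$ids, "s"]), c("A", "B", "C"))
  # a three-class accession is taken before one-class accessions
  tr2 <- data.frame(x = c("a", "a", "b", "c"), y = c("p", "q", "p", "p"),
                    z = c("m", "n", "m", "m"),
                    row.names = sprintf("G%d", 1:4), stringsAsFactors = FALSE)
  # G2 covers (a, q, n): the only accession covering 3 still-rare classes
  core2 <- powercore_sample(tr2, size = 2)
  expect_true("G2" %in% core2$ids)
  # hand-traceable instance: six classes, two per accession, so three
  # accessions are needed and greedy reaches full coverage with exactly three
  tr3 <- data.frame(
    a = c("x", "y", "x", "y", "z"),
    b = c("p", "p", "q", "q", "r"),
    row.names = sprintf("G%d", 1:5), stringsAsFactors = FALSE)
  core3 <- powercore_sample(tr3, size = 3)
  expect_equal(core3$size, 3L)
  expect_equal(core3$extras$coverage, 100)
})

test_that("PCSS ranks accessions by principal-component contribution", {
  set.seed(7)
  base <- matrix(rnorm(40), 20, 2)
  tr <- as.data.frame(cbind(base, base + matrix(rnorm(40, sd = 0.1), 20, 2)))
  names(tr) <- c("t1", "t2", "t3", "t4")
  rownames(tr) <- sprintf("G%02d", 1:20)
  # an accession sitting exactly at the centroid scores zero
  tr["G01", ] <- colMeans(tr[-1, ])
  core <- pcss_sample(tr, 19)
  expect_false("G01" %in% core$ids[1])
  expect_lt(core$extras$contribution[["G01"]],
            min(core$extras$contribution[setdiff(rownames(tr), "G01")]))
  # a gross outlier is selected first at size 1
  tr["G20", ] <- 50
  core1 <- pcss_sample(tr, 1)
  expect_equal(core1$ids, "G20")
})

test_that("geographic enforcement restores missing groups at least cost", {
  pts <- c(A1 = 0, A2 = 0.1, B1 = 5, B2 = 5.1, C1 = 10, C2 = 10.1)
  d <- as.matrix(dist(pts))
  passport <- data.frame(accession = names(pts),
                         group = rep(c("a", "b", "c"), each = 2),
                         stringsAsFactors = FALSE)
  core <- germcore:::new_core_set(c("A1", "A2", "B1"), method = "en100",
                                  w_en = 1, w_an = 0)
  fixed <- enforce_geography(core, passport, d)
  expect_equal(fixed$size, 3L)
  expect_setequal(unname(fixed$extras$groups_covered), c("a", "b", "c"))
  # matches the exhaustive best group-covering triple
  combs <- combn(names(pts), 3)
  ok <- apply(combs, 2, function(ids)
    length(unique(passport$group[match(ids, passport$accession)])) == 3)
  vals <- apply(combs[, ok, drop = FALSE], 2, function(ids)
    germcore:::core_weighted_value(d, ids, 1, 0, NULL))
  best <- max(vals)
  got <- germcore:::core_weighted_value(d, fixed$ids, 1, 0, NULL)
  expect_equal(got, best, tolerance = 1e-9)
  # already-covered cores are untouched
  full <- germcore:::new_core_set(c("A1", "B1", "C1"), method = "en100",
                                  w_en = 1, w_an = 0)
  expect_identical(enforce_geography(full, passport, d)$ids, full$ids)
  # infeasible when groups outnumber slots
  tiny <- germcore:::new_core_set(c("A1", "B1"), method = "en100",
                                  w_en = 1, w_an = 0)
  expect_error(enforce_geography(tiny, passport, d), "infeasible")
})
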