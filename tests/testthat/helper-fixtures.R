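# shared fixtures, all built in code

# two blocks, two checks once each, block check means 11 and 14
worked_fieldbook <- function() {
  plots <- data.frame(
    plot = 1:6,
    block = c(1, 1, 1, 2, 2, 2),
    accession = c("CkA", "CkB", "G1", "CkA", "CkB", "G2"),
    role = c("check", "check", "test", "check", "check", "test"),
    Y = c(10, 12, 15, 12, 16, 20),
    stringsAsFactors = FALSE)
  desc <- trait_descriptors("Y", "quantitative", "g")
  field_book(plots, desc)
}

small_config <- function(n_test = 120, n_blocks = 6, seed = 42,
                         vg = c(9, 4, 25), ve = c(3, 2, 10),
                         block_sd = NULL, correlation = NULL,
                         qualitative = NULL) {
  synth_config(
    n_test = n_test, n_blocks = n_blocks,
    checks = c("C1", "C2", "C3"), reps_per_check = 2,
    traits = data.frame(trait = c("T1", "T2", "T3"),
                        mean = c(50, 10, 100), vg = vg, ve = ve,
                        stringsAsFactors = FALSE),
    correlation = correlation, block_sd = block_sd,
    qualitative = qualitative, seed = seed)
}

# random small field book for ANOVA oracle checks
random_small_fieldbook <- function(seed) {
  set.seed(seed)
  b <- sample(2:4, 1)
  ck <- sprintf("C%d", seq_len(sample(2:3, 1)))
  r <- sample(1:2, 1)
  n_test <- sample(b:(3 * b), 1)
  layout <- plan_abd_layout(n_test, b, ck, reps = r, seed = seed)
  layout$Y <- round(rnorm(nrow(layout), 20, 4), 3)
  field_book(layout, trait_descriptors("Y", "quantitative"))
}

# exhaustive maximizer of the weighted EN/AN objective
exhaustive_best <- function(d, k, w_en, w_an, normalization = NULL) {
  combs <- combn(rownames(d), k)
  vals <- apply(combs, 2, function(ids)
    germcore:::core_weighted_value(d, ids, w_en, w_an, normalization))
  list(value = max(vals), ids = sort(combs[, which.max(vals)]))
}

# heavier shared state for the acceptance suite: one fixed-seed collection
# of 1000 test accessions under the default trait structure, its Gower
# matrix and the EN100 / AN100 cores at the 10% size
acceptance_cache <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (!is.null(acceptance_cache$run)) return(acceptance_cache$run)
  cfg <- synth_config(n_test = 1000, n_blocks = 50, seed = 1)
  sim <- generate_collection(cfg)
  adj <- adjust_means(sim$fieldbook)
  traits <- accession_traits(sim$fieldbook, adj)
  quant <- names(traits)[vapply(traits, is.numeric, logical(1L))]
  d <- gower_matrix(traits, sim$fieldbook$descriptors, subset = quant)
  en <- optimize_core(d, 100, w_en = 1, w_an = 0, seed = 1)
  an <- optimize_core(d, 100, w_en = 0, w_an = 1, seed = 1)
  acceptance_cache$run <- list(sim = sim, adj = adj, traits = traits,
                               d = d, en = en, an = an)
  acceptance_cache$run
}
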