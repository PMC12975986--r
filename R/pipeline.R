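#' Pipeline configuration
#'
#' Bundles every choice of the end-to-end study replica: the input (a
#' synthetic-collection configuration or field-book/descriptor/passport
#' files), the core size (default 10% of the collection), the sampling
#' methods to run, objective weights for the weighted strategies, the
#' significance level, Mantel permutations, search effort and the master
#' seed.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param synth a [synth_config()] (synthetic mode).
#' @param fieldbook_path,descriptor_path,passport_path input files (files mode).
#' @param size core size; `NULL` means 10% of the test accessions (rounded).
#' @param methods subset of `c("powercore", "pcss", "en100", "an100",
#'   "en50an50")`.
#' @param alpha significance level for evaluation tests.
#' @param permutations Mantel permutations.
#' @param budget,restarts local-search effort (see [optimize_core()]).
#' @param enforce_groups apply [enforce_geography()] when passport groups are
#'   available.
#' @param seed master seed; every stochastic stage derives a named sub-seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            synth = synth_config(),
                            fieldbook_path = NULL, descriptor_path = NULL,
                            passport_path = NULL, size = NULL,
                            methods = c("powercore", "pcss", "en100",
                                        "an100", "en50an50"),
                            alpha = 0.05, permutations = 999L,
                            budget = 50000L, restarts = 20L,
                            enforce_groups = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, c("powercore", "pcss", "en100", "an100",
                                  "en50an50"), several.ok = TRUE)
  if (!is.null(size) && size < 2L) stop("core size must be >= 2")
  structure(list(mode = mode, synth = synth, fieldbook_path = fieldbook_path,
                 descriptor_path = descriptor_path,
                 passport_path = passport_path, size = size,
                 methods = methods, alpha = alpha,
                 permutations = as.integer(permutations),
                 budget = as.integer(budget), restarts = as.integer(restarts),
                 enforce_groups = enforce_groups, seed = seed),
            class = "pipeline_config")
}

#' Run the full characterization and core-selection pipeline
#'
#' Simulates or loads a collection, computes block-adjusted means, the
#' augmented-design ANOVA and genetic variability parameters, builds the
#' Gower distance matrix, samples one core per requested method, evaluates
#' every core against the collection (Hu indices, class coverage, objective
#' values, Shannon table, sign tests, Mantel test), and designates the best
#' core: maximize E-NE among the cores passing the quality gate
#' (`MD% < 20` and `CR% > 80`), ties broken by higher class coverage then
#' higher VR%; when no core passes the gate the E-NE maximum is chosen and
#' flagged. The distribution-test battery is run for the chosen core.
#' Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_bundle` list with every artifact (field book, adjusted
#'   means, variability table, distance matrix, cores, evaluations, chosen
#'   core and a stage log).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    msg
  }
  if (config$mode == "synthetic") {
    note("simulate: n_test=", config$synth$n_test, " blocks=",
         config$synth$n_blocks, " seed=", config$synth$seed)
    sim <- generate_collection(config$synth)
    fb <- sim$fieldbook
    passport <- sim$passport
    truth <- sim$truth
  } else {
    note("load: ", config$fieldbook_path)
    fb <- load_collection(config$fieldbook_path, config$descriptor_path)
    passport <- if (!is.null(config$passport_path))
      load_passport(config$passport_path) else NULL
    truth <- NULL
  }
  note("adjust: ", length(fb$tests), " tests, ", fb$n_blocks, " blocks")
  adj <- adjust_means(fb)
  anova <- abd_anova(fb)
  vars <- withCallingHandlers(
    variability_params(adj),
    warning = function(w) {
      note("warning(variability): ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  traits <- accession_traits(fb, adj)
  quant <- quantitative_traits(fb$descriptors)
  d <- gower_matrix(traits, fb$descriptors, subset = intersect(quant, names(traits)))
  size <- config$size
  if (is.null(size)) size <- max(2L, round(0.10 * nrow(traits)))
  note("distance: gower on ", length(intersect(quant, names(traits))),
       " quantitative traits; core size ", size)

  cores <- list()
  for (m in config$methods) {
    seed_m <- substream_seed(config$seed, paste0("method_", m))
    core <- switch(m,
      powercore = powercore_sample(traits, fb$descriptors, size, seed = seed_m),
      pcss = pcss_sample(traits, size),
      en100 = optimize_core(d, size, w_en = 1, w_an = 0, seed = seed_m,
                            budget = config$budget, restarts = config$restarts),
      an100 = optimize_core(d, size, w_en = 0, w_an = 1, seed = seed_m,
                            budget = config$budget, restarts = config$restarts),
      en50an50 = optimize_core(d, size, w_en = 0.5, w_an = 0.5, seed = seed_m,
                               budget = config$budget,
                               restarts = config$restarts))
    if (config$enforce_groups && !is.null(passport)) {
      core <- enforce_geography(core, passport, d)
    }
    core$objective <- core_objective(d, core$ids)
    cores[[m]] <- core
    note("sample[", m, "]: E-NE=", round(core$objective[["e_ne"]], 4),
         " A-NE=", round(core$objective[["a_ne"]], 4))
  }

  evaluations <- lapply(cores, function(core)
    evaluate_core(traits, core, fb$descriptors, d,
                  alpha = config$alpha, permutations = config$permutations,
                  seed = config$seed))
  comparison <- do.call(rbind, lapply(names(evaluations), function(m) {
    ev <- evaluations[[m]]
    data.frame(method = m, e_ne = ev$objective[["e_ne"]],
               a_ne = ev$objective[["a_ne"]], e_e = ev$objective[["e_e"]],
               md = ev$hu[["md"]], vd = ev$hu[["vd"]], cr = ev$hu[["cr"]],
               vr = ev$hu[["vr"]], coverage = ev$coverage[["coverage"]],
               phenotype_ratio = ev$coverage[["phenotype_ratio"]],
               sign_mean_p = ev$sign_mean$p_value,
               sign_var_p = ev$sign_variance$p_value,
               mantel_r = ev$mantel$r, mantel_p = ev$mantel$p_value,
               stringsAsFactors = FALSE)
  }))

  gate <- comparison$md < 20 & comparison$cr > 80
  pool <- if (any(gate)) comparison[gate, ] else comparison
  pool <- pool[order(-pool$e_ne, -pool$coverage, -pool$vr), ]
  chosen <- pool$method[1L]
  note("select: ", chosen, if (any(gate)) " (passes MD<20 & CR>80 gate)"
       else " (no core passed the gate; E-NE maximum)")

  cc_ids <- cores[[chosen]]$ids
  battery <- lapply(intersect(quant, names(traits)), function(tr)
    cbind(trait = tr, distribution_tests(traits[[tr]], traits[cc_ids, tr])))
  battery <- do.call(rbind, battery)

  structure(list(config = config, fieldbook = fb, passport = passport,
                 truth = truth, adjusted = adj, anova = anova,
                 variability = vars, traits = traits, distance = d,
                 cores = cores, evaluations = evaluations,
                 comparison = comparison, chosen = chosen,
                 gate_passed = any(gate), battery = battery, log = log),
            class = "pipeline_bundle")
}

#' Evaluate one core set against its collection
#'
#' @param traits accession x trait table of the collection.
#' @param core a `core_set` (or accession id vector).
#' @param descriptors the [trait_descriptors()].
#' @param d distance matrix over the collection.
#' @param alpha significance level.
#' @param permutations Mantel permutations.
#' @param seed seed for the Mantel permutation stream.
#' @return List with `hu`, `coverage`, `objective`, `shannon` (EC and CC),
#'   `sign_mean`, `sign_variance`, `mantel`, `stats_ec`, `stats_cc`.
#' @export
evaluate_core <- function(traits, core, descriptors, d, alpha = 0.05,
                          permutations = 999L, seed = 1L) {
  ids <- if (inherits(core, "core_set")) core$ids else as.character(core)
  cc <- traits[ids, , drop = FALSE]
  hu <- hu_indices(traits, cc, alpha = alpha)
  cov <- class_coverage(traits, cc, descriptors)
  ob <- core_objective(d, ids)
  qual <- intersect(qualitative_traits(descriptors), names(traits))
  shan <- if (length(qual)) {
    ec_s <- shannon_indices(traits[, qual, drop = FALSE], descriptors)
    cc_s <- shannon_indices(cc[, qual, drop = FALSE], descriptors)
    merge(ec_s, cc_s, by = c("trait", "k", "h_max"),
          suffixes = c("_ec", "_cc"))
  } else NULL
  st_ec <- summary_stats(traits)
  st_cc <- summary_stats(cc)
  sg_m <- sign_tests(st_ec$mean, st_cc$mean)
  sg_v <- sign_tests(st_ec$sd^2, st_cc$sd^2)
  quant_cols <- names(traits)[vapply(traits, is.numeric, logical(1L))]
  mt <- if (length(quant_cols) >= 3L) {
    r_ec <- correlation_matrix(traits[, quant_cols, drop = FALSE])$r
    r_cc <- correlation_matrix(cc[, quant_cols, drop = FALSE])$r
    mantel_test(r_ec, r_cc, permutations = permutations, seed = seed)
  } else list(r = NA_real_, p_value = NA_real_)
  list(hu = hu, coverage = cov, objective = ob, shannon = shan,
       sign_mean = sg_m, sign_variance = sg_v, mantel = mt,
       stats_ec = st_ec, stats_cc = st_cc)
}

#' Write a pipeline run bundle to disk
#'
#' Emits the study-shaped CSV tables (variability parameters, summary
#' statistics for collection and chosen core, the method comparison table,
#' Shannon diversity table, PCA tables for collection and core, per-method
#' core lists), a machine-readable `summary.json`, and a stage log.
#' Idempotent: re-running on the same bundle reproduces identical files.
#'
#' @param bundle a [run_pipeline()] result.
#' @param path output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  paths <- character()
  wr <- function(obj, name) {
    fp <- file.path(path, name)
    write.csv(obj, fp, row.names = FALSE)
    paths <<- c(paths, fp)
  }
  wr(bundle$variability, "variability.csv")
  chosen_ids <- bundle$cores[[bundle$chosen]]$ids
  wr(bundle$evaluations[[bundle$chosen]]$stats_ec, "summary_stats_collection.csv")
  wr(bundle$evaluations[[bundle$chosen]]$stats_cc, "summary_stats_core.csv")
  wr(bundle$comparison, "core_comparison.csv")
  if (!is.null(bundle$evaluations[[bundle$chosen]]$shannon)) {
    wr(bundle$evaluations[[bundle$chosen]]$shannon, "shannon_diversity.csv")
  }
  quant <- names(bundle$traits)[vapply(bundle$traits, is.numeric, logical(1L))]
  pca_ec <- pca_traits(bundle$traits[, quant, drop = FALSE])
  pca_cc <- pca_traits(bundle$traits[chosen_ids, quant, drop = FALSE])
  pca_tab <- function(p) data.frame(
    component = seq_along(p$eigenvalues), eigenvalue = p$eigenvalues,
    sdev = p$sdev, variance_pct = p$variance_share,
    cumulative_pct = p$cumulative_share)
  wr(pca_tab(pca_ec), "pca_collection.csv")
  wr(pca_tab(pca_cc), "pca_core.csv")
  wr(bundle$battery, "distribution_tests_core.csv")
  for (m in names(bundle$cores)) {
    fp <- file.path(path, paste0("core_", m, ".csv"))
    save_core_list(bundle$cores[[m]], fp)
    paths <- c(paths, fp)
  }
  summary <- list(
    chosen = bundle$chosen, gate_passed = bundle$gate_passed,
    seed = bundle$config$seed,
    n_collection = nrow(bundle$traits),
    core_size = length(chosen_ids),
    comparison = bundle$comparison)
  jp <- file.path(path, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, jp)
  lp <- file.path(path, "run.log")
  writeLines(c(sprintf("seed=%s methods=%s size=%d", bundle$config$seed,
                       paste(names(bundle$cores), collapse = ","),
                       length(chosen_ids)),
               bundle$log), lp)
  invisible(c(paths, lp))
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("pipeline_bundle:", nrow(x$traits), "accessions,",
      length(x$cores), "core methods\n")
  cat("chosen core:", x$chosen,
      if (x$gate_passed) "(quality gate passed)" else "(gate not passed)", "\n")
  comp <- x$comparison
  for (cn in c("e_ne", "a_ne", "e_e")) comp[[cn]] <- round(comp[[cn]], 4)
  for (cn in c("md", "vd", "cr", "vr")) comp[[cn]] <- round(comp[[cn]], 2)
  print(comp)
  invisible(x)
}
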