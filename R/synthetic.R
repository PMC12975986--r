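#' Configuration for the synthetic collection generator
#'
#' Builds the generative parameters for a stand-in germplasm collection laid
#' out in an augmented block design: the layout (test count, blocks, checks
#' and their replication), per-trait genotypic and error variance components
#' with an optional genotypic correlation matrix, block-effect standard
#' deviations, qualitative descriptor-state frequencies, and geographic group
#' probabilities. The defaults emulate a national-genebank mungbean trial:
#' 3903 test accessions in 50 blocks with 5 checks repeated twice per block,
#' 21 quantitative traits whose means, phenotypic variances and heritabilities
#' follow the published trait table shipped in `inst/extdata`, and 7
#' qualitative traits with 29 descriptor states in total.
#'
#' @param n_test number of unreplicated test accessions.
#' @param n_blocks number of blocks (>= 2).
#' @param checks character vector of check labels.
#' @param reps_per_check replicate plots of each check in every block.
#' @param traits data frame with columns `trait`, `mean`, `vg`, `ve` for the
#'   quantitative traits; `NULL` uses the packaged reference trait table
#'   (Vp = SD^2, Vg = h2 * Vp).
#' @param correlation genotypic correlation matrix (unit diagonal, symmetric
#'   PSD) across quantitative traits; `NULL` means independent traits.
#' @param block_sd per-trait block-effect standard deviation; `NULL` defaults
#'   to `0.5 * sqrt(ve)` per trait, a moderate field heterogeneity.
#' @param qualitative named list of state-probability vectors (names become
#'   qualitative trait names, probability names the descriptor states);
#'   `NULL` uses the packaged 7 descriptor traits with geometric-decay
#'   frequencies.
#' @param groups named numeric vector of geographic-group probabilities.
#' @param seed master seed; layout, genotype, block and error draws use
#'   deterministic named substreams so one component can change without
#'   perturbing the others.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_test = 3903, n_blocks = 50,
                         checks = c("Virat", "Samrat", "IPM2-14", "SML-668", "MH-421"),
                         reps_per_check = 2, traits = NULL, correlation = NULL,
                         block_sd = NULL, qualitative = NULL,
                         groups = c(north = 0.3, south = 0.25, east = 0.2,
                                    west = 0.15, exotic = 0.1),
                         seed = 1L) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  if (!length(checks)) stop("design error: at least one check is required")
  if (is.null(traits)) {
    ref <- reference_trait_table()
    vp <- ref$sd^2
    vg <- (ref$h2 / 100) * vp
    traits <- data.frame(trait = ref$trait, mean = ref$mean,
                         vg = vg, ve = vp - vg, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("trait", "mean", "vg", "ve") %in% names(traits)))
  if (any(traits$vg < 0) || any(traits$ve < 0)) stop("variances must be >= 0")
  p <- nrow(traits)
  if (is.null(correlation)) correlation <- diag(p)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8)) ||
      any(abs(diag(correlation) - 1) > 1e-8)) {
    stop("correlation matrix must be symmetric with unit diagonal")
  }
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("correlation matrix must be positive semi-definite")
  }
  if (is.null(block_sd)) block_sd <- 0.5 * sqrt(traits$ve)
  block_sd <- rep_len(block_sd, p)
  if (is.null(qualitative)) qualitative <- default_qualitative_states()
  for (nm in names(qualitative)) {
    pr <- qualitative[[nm]]
    if (abs(sum(pr) - 1) > 1e-6) stop("state probabilities for '", nm,
                                      "' must sum to 1")
    if (length(pr) < 2) stop("qualitative trait '", nm, "' needs >= 2 states")
  }
  if (abs(sum(groups) - 1) > 1e-6) groups <- groups / sum(groups)
  structure(list(n_test = as.integer(n_test), n_blocks = as.integer(n_blocks),
                 checks = checks, reps_per_check = as.integer(reps_per_check),
                 traits = traits, correlation = correlation,
                 block_sd = block_sd, qualitative = qualitative,
                 groups = groups, seed = seed),
            class = "synth_config")
}

reference_trait_table <- function() {
  path <- system.file("extdata", "mungbean_trait_reference.csv",
                      package = "germcore")
  read.csv(path, stringsAsFactors = FALSE)
}

default_qualitative_states <- function() {
  path <- system.file("extdata", "mungbean_descriptors.csv", package = "germcore")
  d <- read_descriptors(path)
  qual <- d[d$kind == "qualitative", ]
  out <- lapply(seq_len(nrow(qual)), function(i) {
    st <- qual$states[[i]]
    w <- 0.55^(seq_along(st) - 1)
    setNames(w / sum(w), st)
  })
  names(out) <- qual$trait
  out
}

#' Plan an augmented block design layout
#'
#' Distributes `n_test` unreplicated test entries across `n_blocks` blocks as
#' evenly as possible (block test counts differ by at most one) and places
#' every check `reps` times in every block, randomizing assignment and plot
#' order within block by `seed`.
#'
#' @param n_test number of test entries.
#' @param n_blocks number of blocks.
#' @param checks check labels.
#' @param reps replicates of each check per block.
#' @param seed integer seed (deterministic layout).
#' @param test_ids optional test accession ids (default `G0001`, ...).
#' @return Data frame with columns `plot`, `block`, `accession`, `role`.
#' @export
plan_abd_layout <- function(n_test, n_blocks, checks, reps = 1, seed = 1L,
                            test_ids = NULL) {
  if (!length(checks)) stop("design error: at least one check is required")
  if (n_test < n_blocks) stop("need at least one test entry per block")
  if (is.null(test_ids)) {
    test_ids <- sprintf("G%04d", seq_len(n_test))
  }
  stopifnot(length(test_ids) == n_test)
  set.seed(substream_seed(seed, "layout"))
  shuffled <- sample(test_ids)
  sizes <- rep(n_test %/% n_blocks, n_blocks)
  extra <- n_test %% n_blocks
  if (extra > 0) sizes[sample.int(n_blocks, extra)] <- sizes[1L] + 1L
  idx <- split(shuffled, rep(seq_len(n_blocks), sizes))
  rows <- lapply(seq_len(n_blocks), function(j) {
    acc <- c(idx[[j]], rep(checks, each = reps))
    role <- c(rep("test", length(idx[[j]])),
              rep("check", length(checks) * reps))
    ord <- sample(length(acc))
    data.frame(block = j, accession = acc[ord], role = role[ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$plot <- seq_len(nrow(out))
  out[, c("plot", "block", "accession", "role")]
}

#' Generate a synthetic collection with known genotypic truth
#'
#' Simulates a field book under the additive model
#' `observation = trait mean + genotypic value + block effect + plot error`:
#' genotypic values are drawn once per accession from a correlated
#' multivariate normal (identical across a check's replicate plots and
#' blocks), block effects are i.i.d. normal scaled per trait, and plot errors
#' are independent normal with variance `ve`. Qualitative states and
#' geographic groups are accession attributes drawn from the configured
#' frequency vectors.
#'
#' @param config a [synth_config()].
#' @return A list with elements `fieldbook` (a validated [field_book()]),
#'   `truth` (per-accession true genotypic values, per trait), `block_effects`
#'   (block x trait matrix of true effects, per-trait scaled), and `passport`
#'   (accession, group).
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tr <- config$traits
  p <- nrow(tr)
  layout <- plan_abd_layout(config$n_test, config$n_blocks, config$checks,
                            config$reps_per_check, seed = config$seed)
  acc <- c(sprintf("G%04d", seq_len(config$n_test)), config$checks)
  n_acc <- length(acc)

  set.seed(substream_seed(config$seed, "genotype"))
  sigma <- diag(sqrt(tr$vg), p) %*% config$correlation %*% diag(sqrt(tr$vg), p)
  g <- MASS::mvrnorm(n_acc, mu = rep(0, p), Sigma = sigma)
  dimnames(g) <- list(acc, tr$trait)

  set.seed(substream_seed(config$seed, "block"))
  u <- rnorm(config$n_blocks)
  beta <- outer(u, config$block_sd)          # block x trait
  dimnames(beta) <- list(seq_len(config$n_blocks), tr$trait)

  set.seed(substream_seed(config$seed, "error"))
  n_plots <- nrow(layout)
  err <- matrix(rnorm(n_plots * p), n_plots, p) %*% diag(sqrt(tr$ve), p)
  colnames(err) <- tr$trait

  obs <- matrix(rep(tr$mean, each = n_plots), n_plots, p) +
    g[layout$accession, , drop = FALSE] +
    beta[layout$block, , drop = FALSE] + err
  colnames(obs) <- tr$trait

  set.seed(substream_seed(config$seed, "qualitative"))
  qual <- lapply(config$qualitative, function(pr) {
    sample(names(pr), n_acc, replace = TRUE, prob = pr)
  })
  qual <- as.data.frame(qual, stringsAsFactors = FALSE)
  if (ncol(qual)) rownames(qual) <- acc

  set.seed(substream_seed(config$seed, "groups"))
  grp <- sample(names(config$groups), n_acc, replace = TRUE,
                prob = config$groups)
  # guarantee every group has at least one member among tests
  missing_groups <- setdiff(names(config$groups), grp[seq_len(config$n_test)])
  if (length(missing_groups) && config$n_test >= length(config$groups)) {
    grp[seq_along(missing_groups)] <- missing_groups
  }

  plots <- cbind(layout, as.data.frame(obs, stringsAsFactors = FALSE))
  for (nm in names(qual)) plots[[nm]] <- qual[plots$accession, nm]

  descriptors <- trait_descriptors(
    trait = c(tr$trait, names(config$qualitative)),
    kind = c(rep("quantitative", p), rep("qualitative", length(config$qualitative))),
    unit = rep("", p + length(config$qualitative)),
    states = c(vector("list", p), lapply(config$qualitative, names))
  )
  fb <- field_book(plots, descriptors, location = "synthetic",
                   year = NA)
  list(fieldbook = fb,
       truth = as.data.frame(g),
       block_effects = beta,
       passport = data.frame(accession = acc, group = grp,
                             stringsAsFactors = FALSE),
       config = config)
}
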