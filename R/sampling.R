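#' Core-versus-collection objective values
#'
#' The three Odong-style distance criteria of a candidate core: `e_ne`, the
#' mean distance from each entry to its nearest other entry (diversity);
#' `a_ne`, the mean distance from each accession of the collection to its
#' nearest entry (representativeness; entries contribute zero); and `e_e`,
#' the mean pairwise distance between entries.
#'
#' @param d symmetric distance matrix with accession ids as dimnames.
#' @param core accession ids (or integer indices) of the core entries.
#' @return Named numeric vector `c(e_ne, a_ne, e_e)`.
#' @export
core_objective <- function(d, core) {
  idx <- core_indices(d, core)
  if (!length(idx)) stop("core must be non-empty")
  k <- length(idx)
  sub <- d[, idx, drop = FALSE]
  a_ne <- mean(apply(sub, 1L, min))
  if (k >= 2L) {
    dd <- d[idx, idx, drop = FALSE]
    diag(dd) <- Inf
    e_ne <- mean(apply(dd, 1L, min))
    e_e <- mean(dd[upper.tri(dd)])
  } else {
    e_ne <- NA_real_
    e_e <- NA_real_
  }
  c(e_ne = e_ne, a_ne = a_ne, e_e = e_e)
}

core_indices <- function(d, core) {
  if (inherits(core, "core_set")) core <- core$ids
  if (is.character(core)) {
    idx <- match(core, rownames(d))
    if (anyNA(idx)) stop("core id(s) not in distance matrix: ",
                         paste(core[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(core)
    if (any(idx < 1L | idx > nrow(d))) stop("core index out of range")
  }
  if (anyDuplicated(idx)) stop("duplicate core entries")
  idx
}

#' Weighted entry/accession-to-nearest-entry core optimization
#'
#' Selects a core of the requested size by random-descent local search over
#' the single-swap neighborhood, maximizing
#' `w_en * norm(E-NE) - w_an * norm(A-NE)`: E-NE (diversity) is rewarded,
#' A-NE (representativeness, smaller is better) is penalized. Each objective
#' is normalized by its range over an ensemble of random cores so the two
#' live on a common scale. `w_en = 1` gives the EN100 strategy, `w_an = 1`
#' AN100, and equal weights EN50:AN50. Forced accessions are never swapped
#' out; the search is deterministic given `seed` and stops after `budget`
#' consecutive non-improving proposals (per restart).
#'
#' @param d symmetric distance matrix with accession ids as dimnames.
#' @param size core size (>= 1; `size = n` returns the whole collection).
#' @param w_en,w_an non-negative objective weights summing to 1.
#' @param forced accession ids that must be in the core.
#' @param seed integer seed.
#' @param budget consecutive non-improving proposals before a restart stops.
#' @param restarts number of random restarts.
#' @param ensemble random cores used to normalize the two objectives.
#' @param method label recorded on the result (defaults to the weight
#'   pattern: `en100`, `an100` or `en50an50`).
#' @return A `core_set` with ids (ascending), objective values, weights,
#'   seed, and the normalization ranges used.
#' @export
optimize_core <- function(d, size, w_en = 1, w_an = 0, forced = character(),
                          seed = 1L, budget = 50000L, restarts = 20L,
                          ensemble = 200L, method = NULL) {
  n <- nrow(d)
  if (size > n) stop("core size exceeds collection size")
  if (size < 1L) stop("core size must be >= 1")
  if (w_en < 0 || w_an < 0) stop("objective weights must be non-negative")
  if (abs(w_en + w_an - 1) > 1e-8) stop("w_en + w_an must equal 1")
  ids <- rownames(d)
  forced <- as.character(forced)
  fidx <- match(forced, ids)
  if (anyNA(fidx)) stop("forced id(s) not in collection: ",
                        paste(forced[is.na(fidx)], collapse = ", "))
  if (length(fidx) > size) stop("more forced accessions than core slots")
  if (is.null(method)) {
    method <- if (w_en == 1) "en100" else if (w_an == 1) "an100"
              else if (w_en == 0.5) "en50an50"
              else sprintf("en%san%s", round(100 * w_en), round(100 * w_an))
  }
  if (size == n) {
    core <- new_core_set(ids = sort(ids), method = method, w_en = w_en,
                         w_an = w_an, forced = forced, seed = seed)
    core$objective <- core_objective(d, core$ids)
    return(core)
  }
  dm <- unname(as.matrix(d))
  set.seed(substream_seed(seed, "core_norm"))
  free <- setdiff(seq_len(n), fidx)
  ens <- replicate(ensemble, {
    m <- c(fidx, sample(free, size - length(fidx)))
    cpp_core_objective(dm, m - 1L)[1:2]
  })
  rng_en <- diff(range(ens[1L, ]))
  rng_an <- diff(range(ens[2L, ]))
  a_en <- if (is.finite(rng_en) && rng_en > 0) w_en / rng_en else w_en
  a_an <- if (is.finite(rng_an) && rng_an > 0) w_an / rng_an else w_an

  best <- NULL
  best_obj <- -Inf
  set.seed(substream_seed(seed, "core_search"))
  for (rs in seq_len(restarts)) {
    init <- c(fidx, sample(free, size - length(fidx)))
    res <- cpp_local_search(dm, init - 1L,
                            as.integer(fidx - 1L), a_en, a_an,
                            as.integer(budget), as.integer(budget) * 20L)
    if (res$objective > best_obj + 1e-12) {
      best_obj <- res$objective
      best <- res$members + 1L
    }
  }
  core <- new_core_set(ids = sort(ids[best]), method = method, w_en = w_en,
                       w_an = w_an, forced = forced, seed = seed,
                       normalization = list(range_en = rng_en, range_an = rng_an))
  core$objective <- core_objective(d, core$ids)
  core
}

core_weighted_value <- function(d, ids, w_en, w_an, normalization = NULL) {
  ob <- core_objective(d, ids)
  e <- if (is.na(ob["e_ne"])) 0 else ob[["e_ne"]]
  a <- ob[["a_ne"]]
  if (!is.null(normalization)) {
    if (normalization$range_en > 0) e <- e / normalization$range_en
    if (normalization$range_an > 0) a <- a / normalization$range_an
  }
  w_en * e - w_an * a
}

#' PowerCore-style greedy class-coverage sampling
#'
#' Approximates the advanced-M coverage strategy with a fixed core size:
#' quantitative traits are discretized into Sturges-rule classes on the
#' collection, qualitative descriptor states are classes as-is, and entries
#' are added greedily to cover the most still-uncovered classes (ties go to
#' the accession covering the rarest class, then the lowest id). Once every
#' class is covered, the remaining slots are filled by maximin
#' (E-NE-maximizing) greedy additions on the Gower distance.
#'
#' @param traits accession x trait data frame.
#' @param descriptors optional [trait_descriptors()].
#' @param size core size.
#' @param seed recorded for provenance (the sampler is deterministic).
#' @return A `core_set` (method `powercore`) whose `extras$coverage` reports
#'   the percentage of collection classes present in the core.
#' @export
powercore_sample <- function(traits, descriptors = NULL, size, seed = 1L) {
  stopifnot(size >= 1L, size <= nrow(traits))
  M <- class_membership(traits, descriptors)
  ids <- rownames(traits)
  class_freq <- colSums(M)
  selected <- integer()
  uncovered <- which(class_freq > 0)
  avail <- rep(TRUE, nrow(M))
  while (length(selected) < size && length(uncovered)) {
    gains <- M[, uncovered, drop = FALSE] %*% rep(1, length(uncovered))
    gains[!avail] <- -1
    gmax <- max(gains)
    if (gmax <= 0) break
    cand <- which(gains == gmax)
    if (length(cand) > 1L) {
      rarest <- vapply(cand, function(i) {
        cls <- uncovered[M[i, uncovered]]
        min(class_freq[cls])
      }, numeric(1L))
      cand <- cand[rarest == min(rarest)]
      cand <- cand[order(ids[cand])]
    }
    pick <- cand[1L]
    selected <- c(selected, pick)
    avail[pick] <- FALSE
    uncovered <- uncovered[!M[pick, uncovered]]
  }
  if (length(selected) < size) {
    d <- gower_matrix(traits, descriptors)
    dm <- unname(d)
    if (!length(selected)) {
      selected <- which.max(rowSums(dm))
      avail[selected] <- FALSE
    }
    mind <- apply(dm[, selected, drop = FALSE], 1L, min)
    while (length(selected) < size) {
      mind[!avail] <- -1
      cand <- which(mind == max(mind))
      cand <- cand[order(ids[cand])]
      pick <- cand[1L]
      selected <- c(selected, pick)
      avail[pick] <- FALSE
      mind <- pmin(mind, dm[, pick])
    }
  }
  covered <- colSums(M[selected, , drop = FALSE]) > 0
  present <- class_freq > 0
  core <- new_core_set(ids = sort(ids[selected]), method = "powercore",
                       w_en = NA_real_, w_an = NA_real_, seed = seed,
                       extras = list(coverage = 100 * sum(covered & present) /
                                       sum(present)))
  core
}

# accession x class logical membership matrix (Sturges bins + states)
class_membership <- function(traits, descriptors = NULL) {
  if (is.null(descriptors)) {
    kinds <- ifelse(vapply(traits, is.numeric, logical(1L)),
                    "quantitative", "qualitative")
  } else {
    kinds <- setNames(descriptors$kind, descriptors$trait)[names(traits)]
  }
  n <- nrow(traits)
  cols <- list()
  for (tr in names(traits)) {
    x <- traits[[tr]]
    if (kinds[[tr]] == "quantitative") {
      rng <- suppressWarnings(range(x, na.rm = TRUE))
      if (!all(is.finite(rng)) || diff(rng) == 0) next
      nb <- ceiling(log2(sum(!is.na(x))) + 1)
      breaks <- seq(rng[1L], rng[2L], length.out = nb + 1L)
      bin <- findInterval(x, breaks, rightmost.closed = TRUE)
      m <- matrix(FALSE, n, nb)
      ok <- !is.na(bin) & bin >= 1L & bin <= nb
      m[cbind(which(ok), bin[ok])] <- TRUE
      colnames(m) <- paste0(tr, ".bin", seq_len(nb))
    } else {
      st <- sort(unique(stats::na.omit(as.character(x))))
      if (!length(st)) next
      m <- outer(as.character(x), st, `==`)
      m[is.na(m)] <- FALSE
      colnames(m) <- paste0(tr, ".", st)
    }
    cols[[tr]] <- m
  }
  M <- do.call(cbind, cols)
  rownames(M) <- rownames(traits)
  M
}

#' Principal component score sampling (PCSS)
#'
#' Runs a correlation-matrix PCA on the standardized quantitative traits,
#' retains the components with eigenvalue above one, scores each accession by
#' the sum over retained components of its squared standardized score
#' weighted by the component's variance share, and keeps the `size` highest
#' contributions (ties broken by ascending accession id). Deterministic.
#'
#' @param traits accession x trait data frame (quantitative columns used).
#' @param size core size.
#' @return A `core_set` (method `pcss`) with per-accession contributions in
#'   `extras$contribution`.
#' @export
pcss_sample <- function(traits, size) {
  stopifnot(size >= 1L, size <= nrow(traits))
  num <- traits[, vapply(traits, is.numeric, logical(1L)), drop = FALSE]
  if (ncol(num) < 2L) stop("PCSS needs at least 2 quantitative traits")
  pca <- pca_traits(num)
  lambda <- pca$eigenvalues
  retained <- which(lambda > 1)
  if (!length(retained)) retained <- 1L
  share <- lambda[retained] / length(lambda)
  contrib <- as.numeric(pca$scores[, retained, drop = FALSE]^2 %*% share)
  names(contrib) <- rownames(traits)
  ord <- order(-contrib, rownames(traits))
  sel <- ord[seq_len(size)]
  new_core_set(ids = sort(rownames(traits)[sel]), method = "pcss",
               w_en = NA_real_, w_an = NA_real_, seed = NA,
               extras = list(contribution = contrib))
}

#' Enforce geographic-group coverage on a core set
#'
#' For every geographic group present in the collection but absent from the
#' core, swaps in the group member whose insertion (paired with the removal
#' of the least damaging non-forced entry) best preserves the core's weighted
#' EN/AN objective, keeping the core size unchanged. Removals never uncover
#' another group represented only once.
#'
#' @param core a `core_set`.
#' @param passport passport data frame (`accession`, `group`).
#' @param d distance matrix over the collection.
#' @return The adjusted `core_set`, with `extras$groups_covered` recording
#'   the groups represented.
#' @export
enforce_geography <- function(core, passport, d) {
  stopifnot(inherits(core, "core_set"))
  grp <- setNames(passport$group, passport$accession)
  grp <- grp[intersect(names(grp), rownames(d))]
  groups <- sort(unique(stats::na.omit(grp)))
  if (length(groups) > core$size) {
    stop("infeasible: more geographic groups (", length(groups),
         ") than core slots (", core$size, ")")
  }
  w_en <- if (is.na(core$w_en)) 1 else core$w_en
  w_an <- if (is.na(core$w_an)) 0 else core$w_an
  ids <- core$ids
  for (g in groups) {
    have <- grp[ids]
    if (g %in% have) next
    members_in <- sort(names(grp)[!is.na(grp) & grp == g])
    members_in <- setdiff(members_in, ids)
    if (!length(members_in)) stop("group '", g, "' has no collection member")
    counts <- table(have[!is.na(have)])
    removable <- ids[!(ids %in% core$forced)]
    removable <- removable[is.na(have[removable]) |
                             counts[have[removable]] > 1L]
    if (!length(removable)) stop("no removable entry to make room for group '",
                                 g, "'")
    best_val <- -Inf; best_pair <- NULL
    for (a in members_in) {
      for (r in removable) {
        cand <- c(setdiff(ids, r), a)
        val <- core_weighted_value(d, cand, w_en, w_an, core$normalization)
        if (val > best_val + 1e-12) {
          best_val <- val
          best_pair <- c(a, r)
        }
      }
    }
    ids <- sort(c(setdiff(ids, best_pair[2L]), best_pair[1L]))
  }
  out <- new_core_set(ids = ids, method = core$method, w_en = core$w_en,
                      w_an = core$w_an, forced = core$forced,
                      seed = core$seed, normalization = core$normalization,
                      extras = c(core$extras,
                                 list(groups_covered = sort(unique(
                                   stats::na.omit(grp[ids]))))))
  out$objective <- core_objective(d, ids)
  out
}
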