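#' Per-trait summary statistics
#'
#' Minimum, maximum, mean, SD, CV%, interquartile range (linear-interpolation
#' quantiles), adjusted Fisher-Pearson skewness and excess kurtosis for every
#' numeric trait column.
#'
#' @param values data frame (or matrix) of per-trait samples.
#' @return Data frame with one row per trait.
#' @export
summary_stats <- function(values) {
  values <- as.data.frame(values)
  num <- values[, vapply(values, is.numeric, logical(1L)), drop = FALSE]
  rows <- lapply(names(num), function(tr) {
    x <- num[[tr]][!is.na(num[[tr]])]
    n <- length(x)
    if (n < 2L) stop("need >= 2 non-missing values for trait '", tr, "'")
    m <- mean(x); s <- sd(x)
    cv <- if (abs(m) > .Machine$double.eps) 100 * s / m else NA_real_
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    if (s > 0) {
      z <- (x - m) / (s * sqrt((n - 1) / n))   # population-scaled
      g1 <- mean(z^3)
      skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
      kurt <- mean(z^4) - 3
    } else {
      skew <- NA_real_
      kurt <- NA_real_
    }
    data.frame(trait = tr, n = n, min = min(x), max = max(x), mean = m,
               sd = s, cv = cv, iqr = q[2L] - q[1L], skewness = skew,
               kurtosis = kurt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hu core-quality indices (MD%, VD%, CR%, VR%)
#'
#' Percentage of traits whose core and collection means differ significantly
#' (two-sample t test, `MD%`), percentage with significantly different
#' variances (variance-ratio F test, `VD%`), mean ratio of core-to-collection
#' trait ranges (`CR%`) and of coefficients of variation (`VR%`). A good core
#' conventionally has `MD% < 20` and `CR% > 80`.
#'
#' @param ec collection accession x trait table (quantitative columns used).
#' @param cc core accession x trait table (same traits; core is a subset).
#' @param alpha significance level for the component tests (default 0.05).
#' @return Named numeric vector `c(md, vd, cr, vr)` (percent scale), with the
#'   per-trait detail in the `"detail"` attribute.
#' @export
hu_indices <- function(ec, cc, alpha = 0.05) {
  ec <- as.data.frame(ec); cc <- as.data.frame(cc)
  quant <- names(ec)[vapply(ec, is.numeric, logical(1L))]
  quant <- intersect(quant, names(cc))
  if (!length(quant)) stop("no shared quantitative traits")
  keep <- character(); md <- vd <- logical(); crr <- vrr <- numeric()
  for (tr in quant) {
    x <- ec[[tr]][!is.na(ec[[tr]])]
    y <- cc[[tr]][!is.na(cc[[tr]])]
    rng <- diff(range(x))
    if (rng == 0) {
      warning("zero collection range for trait '", tr, "'; excluded")
      next
    }
    keep <- c(keep, tr)
    identical_samples <- length(x) == length(y) && all(sort(x) == sort(y))
    if (identical_samples || (sd(x) == 0 && sd(y) == 0)) {
      md <- c(md, FALSE); vd <- c(vd, FALSE)
    } else {
      md <- c(md, t.test(x, y)$p.value < alpha)
      vd <- c(vd, var.test(x, y)$p.value < alpha)
    }
    crr <- c(crr, diff(range(y)) / rng)
    cv_ec <- 100 * sd(x) / mean(x)
    cv_cc <- 100 * sd(y) / mean(y)
    vrr <- c(vrr, cv_cc / cv_ec)
  }
  if (!length(keep)) stop("no usable traits")
  out <- c(md = 100 * mean(md), vd = 100 * mean(vd),
           cr = 100 * mean(crr), vr = 100 * mean(vrr))
  attr(out, "detail") <- data.frame(trait = keep, mean_diff = md,
                                    var_diff = vd, range_ratio = crr,
                                    cv_ratio = vrr, stringsAsFactors = FALSE)
  out
}

#' Class coverage and phenotype-retained ratio
#'
#' Classes are built on the collection (Sturges bins for quantitative traits,
#' descriptor states for qualitative ones); coverage is the percentage of
#' those classes represented in the core, and the phenotype-retained ratio is
#' the fraction of qualitative descriptor states of the collection that
#' survive in the core.
#'
#' @param ec collection accession x trait table.
#' @param cc core accession x trait table (same columns).
#' @param descriptors optional [trait_descriptors()].
#' @return Named vector `c(coverage, phenotype_ratio)`.
#' @export
class_coverage <- function(ec, cc, descriptors = NULL) {
  M <- class_membership(ec, descriptors)
  idx <- match(rownames(cc), rownames(ec))
  if (anyNA(idx)) stop("core accessions must be a subset of the collection")
  present <- colSums(M) > 0
  covered <- colSums(M[idx, , drop = FALSE]) > 0
  coverage <- 100 * sum(covered & present) / sum(present)
  if (is.null(descriptors)) {
    qual <- names(ec)[!vapply(ec, is.numeric, logical(1L))]
  } else {
    qual <- intersect(qualitative_traits(descriptors), names(ec))
  }
  if (length(qual)) {
    st_ec <- sum(vapply(qual, function(tr)
      length(unique(stats::na.omit(ec[[tr]]))), numeric(1L)))
    st_cc <- sum(vapply(qual, function(tr)
      length(unique(stats::na.omit(cc[[tr]]))), numeric(1L)))
    ratio <- st_cc / st_ec
  } else {
    ratio <- NA_real_
  }
  c(coverage = coverage, phenotype_ratio = ratio)
}

#' Shannon diversity, evenness and maximum diversity
#'
#' For a vector of descriptor-state counts: `H' = -sum p_i ln p_i` over the
#' observed states, `H_max = ln k` where `k` is the number of possible states
#' declared by the descriptor (not the observed support), and the evenness
#' `J' = H'/H_max`.
#'
#' @param counts non-negative state counts (at least one positive).
#' @param k number of possible descriptor states (>= 2); defaults to
#'   `length(counts)`.
#' @return Named vector `c(h_prime, j_prime, h_max)`.
#' @export
shannon_diversity <- function(counts, k = length(counts)) {
  if (k < 2) stop("a descriptor needs at least 2 states")
  if (any(counts < 0) || sum(counts) <= 0) stop("counts must be >= 0 with a positive total")
  p <- counts[counts > 0] / sum(counts)
  h <- -sum(p * log(p))
  hmax <- log(k)
  c(h_prime = h, j_prime = h / hmax, h_max = hmax)
}

#' Shannon evenness from diversity and its maximum
#'
#' @param h_prime Shannon diversity H'.
#' @param h_max maximum diversity ln(k).
#' @return `h_prime / h_max`.
#' @export
shannon_evenness <- function(h_prime, h_max) h_prime / h_max

#' Shannon diversity table for the qualitative traits of a collection
#'
#' @param traits accession x trait table (qualitative columns used).
#' @param descriptors a [trait_descriptors()] declaring the possible states
#'   per trait (sets `k` and hence `H_max`); when absent, `k` is the observed
#'   number of states.
#' @return Data frame `trait`, `k`, `h_prime`, `j_prime`, `h_max`.
#' @export
shannon_indices <- function(traits, descriptors = NULL) {
  traits <- as.data.frame(traits)
  if (is.null(descriptors)) {
    qual <- names(traits)[!vapply(traits, is.numeric, logical(1L))]
    kk <- setNames(vapply(qual, function(tr)
      length(unique(stats::na.omit(traits[[tr]]))), numeric(1L)), qual)
  } else {
    qual <- intersect(qualitative_traits(descriptors), names(traits))
    kk <- setNames(vapply(qual, function(tr)
      length(descriptors$states[descriptors$trait == tr][[1L]]), numeric(1L)),
      qual)
  }
  if (!length(qual)) stop("no qualitative traits")
  rows <- lapply(qual, function(tr) {
    cnt <- table(traits[[tr]])
    s <- shannon_diversity(as.numeric(cnt), k = kk[[tr]])
    data.frame(trait = tr, k = kk[[tr]], h_prime = s[["h_prime"]],
               j_prime = s[["j_prime"]], h_max = s[["h_max"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sign tests for core-versus-collection means and variances
#'
#' Counts the traits where the core statistic exceeds the collection
#' statistic and applies the exact two-sided binomial sign test (ties are
#' dropped; all ties yields an undefined flag).
#'
#' @param ec_stats,cc_stats per-trait statistic vectors (same trait order),
#'   e.g. the `mean` or `sd` column of [summary_stats()].
#' @return List with `n_plus`, `n_minus`, `p_value` (NA if all tied) and
#'   `undefined`.
#' @export
sign_tests <- function(ec_stats, cc_stats) {
  stopifnot(length(ec_stats) == length(cc_stats))
  diffs <- cc_stats - ec_stats
  diffs <- diffs[!is.na(diffs)]
  n_plus <- sum(diffs > 0)
  n_minus <- sum(diffs < 0)
  if (n_plus + n_minus == 0L) {
    return(list(n_plus = 0L, n_minus = 0L, p_value = NA_real_,
                undefined = TRUE))
  }
  p <- binom.test(n_plus, n_plus + n_minus, 0.5)$p.value
  list(n_plus = n_plus, n_minus = n_minus, p_value = p, undefined = FALSE)
}

#' Mantel test between two trait correlation matrices
#'
#' Pearson correlation of the off-diagonal elements under simultaneous
#' row/column permutation (one-sided p, `(1 + #(r* >= r)) / (permutations + 1)`).
#'
#' @param m1,m2 square symmetric matrices on the same trait index.
#' @param permutations number of label permutations (>= 99).
#' @param seed integer seed (permutation stream).
#' @return List with `r`, `p_value` and `permutations`.
#' @export
mantel_test <- function(m1, m2, permutations = 999L, seed = 1L) {
  stopifnot(nrow(m1) == ncol(m1), all(dim(m1) == dim(m2)))
  if (permutations < 99L) stop("use at least 99 permutations")
  off1 <- m1[lower.tri(m1)]
  off2 <- m2[lower.tri(m2)]
  if (sd(off1) == 0 || sd(off2) == 0) {
    stop("constant off-diagonal elements; Mantel r undefined")
  }
  lt <- lower.tri(m1)
  r_obs <- cor(m1[lt], m2[lt])
  set.seed(substream_seed(seed, "mantel"))
  n <- nrow(m1)
  hits <- 0L
  for (b in seq_len(permutations)) {
    p <- sample.int(n)
    mp <- m2[p, p]
    if (cor(m1[lt], mp[lt]) >= r_obs - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p_value = (hits + 1) / (permutations + 1),
       permutations = permutations)
}

#' Two-sample distribution comparison battery
#'
#' Welch t test, Newman-Keuls studentized-range comparison of the two means
#' on the pooled variance (the two-group degenerate case), Brown-Forsythe
#' (median-centered) Levene test, two-sided Wilcoxon rank-sum with normal
#' approximation, two-sample Kolmogorov-Smirnov, two-sample Anderson-Darling
#' (Scholz-Stephens), and a symmetrized Kullback-Leibler distance over shared
#' Sturges histogram bins with additive smoothing.
#'
#' @param ec_values,cc_values numeric samples (>= 5 observations each).
#' @return Data frame `test`, `statistic`, `p_value` (KL has no p-value).
#' @export
distribution_tests <- function(ec_values, cc_values) {
  x <- ec_values[!is.na(ec_values)]
  y <- cc_values[!is.na(cc_values)]
  if (length(x) < 5L || length(y) < 5L) {
    return(data.frame(test = c("t", "newman_keuls", "levene", "wilcoxon",
                               "ks", "anderson_darling", "kl_distance"),
                      statistic = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE))
  }
  degenerate <- sd(x) == 0 && sd(y) == 0
  if (degenerate) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- t.test(x, y)
  }
  nk <- newman_keuls_two(x, y)
  lv <- levene_bf(x, y)
  wx <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  ks <- suppressWarnings(ks.test(x, y))
  ad <- ad_two_sample(x, y)
  kl <- kl_distance(x, y)
  data.frame(
    test = c("t", "newman_keuls", "levene", "wilcoxon", "ks",
             "anderson_darling", "kl_distance"),
    statistic = c(unname(tt$statistic), nk$statistic, lv$statistic,
                  unname(wx$statistic), unname(ks$statistic), ad$statistic,
                  kl),
    p_value = c(tt$p.value, nk$p_value, lv$p_value, wx$p.value, ks$p.value,
                ad$p_value, NA_real_),
    stringsAsFactors = FALSE)
}

# studentized-range comparison of two means on pooled variance
newman_keuls_two <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  s2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  if (s2 == 0) return(list(statistic = 0, p_value = 1))
  se <- sqrt(s2 / 2 * (1 / n1 + 1 / n2))
  q <- abs(mean(x) - mean(y)) / se
  list(statistic = q, p_value = ptukey(q, 2, df, lower.tail = FALSE))
}

# Brown-Forsythe: one-way ANOVA on absolute deviations from group medians
levene_bf <- function(x, y) {
  z <- c(abs(x - median(x)), abs(y - median(y)))
  g <- factor(rep(c("ec", "cc"), c(length(x), length(y))))
  if (sd(z) == 0) return(list(statistic = 0, p_value = 1))
  res <- car::leveneTest(c(x, y), g, center = stats::median)
  list(statistic = res[1L, "F value"], p_value = res[1L, "Pr(>F)"])
}

# two-sample Anderson-Darling (Scholz-Stephens A2kN, continuous version),
# standardized and converted to p through the published critical-value
# surface (quadratic interpolation on the logistic scale).
ad_two_sample <- function(x, y) {
  k <- 2L
  ns <- c(length(x), length(y))
  N <- sum(ns)
  pooled <- sort(c(x, y))
  z <- pooled[-N]                      # first N-1 order statistics
  a2 <- 0
  samples <- list(x, y)
  for (i in 1:2) {
    M <- vapply(z, function(v) sum(samples[[i]] <= v), numeric(1L))
    j <- seq_len(N - 1L)
    a2 <- a2 + (1 / ns[i]) * sum((N * M - j * ns[i])^2 / (j * (N - j)))
  }
  a2 <- a2 / N
  H <- sum(1 / ns)
  h <- sum(1 / seq_len(N - 1L))
  ii <- seq_len(N - 2L)
  g <- sum(vapply(ii, function(i) sum(1 / ((N - i) * seq(i + 1L, N - 1L))),
                  numeric(1L)))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * H + 4 * h
  dd <- (2 * h + 6) * k^2 - 4 * h * k
  var_a2 <- (a * N^3 + b * N^2 + cc * N + dd) / ((N - 1) * (N - 2) * (N - 3))
  tstat <- (a2 - (k - 1)) / sqrt(var_a2)
  list(statistic = tstat, p_value = ad_pvalue(tstat, k - 1L))
}

ad_pvalue <- function(t, m) {
  alphas <- c(0.25, 0.10, 0.05, 0.025, 0.01)
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396)
  tm <- b0 + b1 / sqrt(m) + b2 / m
  lp <- log(alphas / (1 - alphas))
  fit <- lm(lp ~ tm + I(tm^2))
  pred <- sum(coef(fit) * c(1, t, t^2))
  p <- exp(pred) / (1 + exp(pred))
  min(max(p, 0), 1)
}

# symmetrized discrete KL divergence over shared Sturges bins
kl_distance <- function(x, y) {
  pooled <- c(x, y)
  nb <- ceiling(log2(length(pooled)) + 1)
  rng <- range(pooled)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1L], rng[2L], length.out = nb + 1L)
  cx <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nb)
  cy <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE), nb)
  eps <- 1 / (2 * length(pooled))
  p <- (cx + eps) / sum(cx + eps)
  q <- (cy + eps) / sum(cy + eps)
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}

#' Matched quantiles for a Q-Q comparison
#'
#' Quantiles of both samples at the common probability grid
#' `(i - 0.5) / n`, `n = min(sample sizes)`.
#'
#' @param ec_values,cc_values numeric samples (>= 2 each).
#' @return Data frame `prob`, `ec`, `cc` with `n` rows.
#' @export
qq_data <- function(ec_values, cc_values) {
  x <- ec_values[!is.na(ec_values)]
  y <- cc_values[!is.na(cc_values)]
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  n <- min(length(x), length(y))
  probs <- (seq_len(n) - 0.5) / n
  data.frame(prob = probs, ec = quantile(x, probs, names = FALSE),
             cc = quantile(y, probs, names = FALSE))
}
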