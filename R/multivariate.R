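#' Correlation-matrix PCA of quantitative traits
#'
#' PCA on the standardized traits (correlation matrix), so the eigenvalues
#' sum to the number of traits and each component's variance share is
#' `100 * lambda / p`. Missing values are imputed by the trait mean with a
#' warning; constant traits are dropped with a warning. Loading signs are
#' fixed so the largest-magnitude loading of each component is positive.
#'
#' @param traits accession x trait data frame (numeric columns used).
#' @return A `pca_result` list: `eigenvalues`, `sdev`, `loadings`
#'   (trait x component), `scores` (accession x component),
#'   `variance_share`, `cumulative_share`, `n_traits`.
#' @export
pca_traits <- function(traits) {
  traits <- as.data.frame(traits)
  num <- traits[, vapply(traits, is.numeric, logical(1L)), drop = FALSE]
  if (ncol(num) < 2L) stop("PCA needs at least 2 quantitative traits")
  for (tr in names(num)) {
    if (anyNA(num[[tr]])) {
      warning("imputing missing values of '", tr, "' by the trait mean")
      num[[tr]][is.na(num[[tr]])] <- mean(num[[tr]], na.rm = TRUE)
    }
  }
  keep <- vapply(num, function(x) sd(x) > 0, logical(1L))
  if (any(!keep)) warning("dropping constant trait(s): ",
                          paste(names(num)[!keep], collapse = ", "))
  num <- num[, keep, drop = FALSE]
  p <- ncol(num)
  if (p < 2L) stop("fewer than 2 non-constant traits")
  pc <- prcomp(num, center = TRUE, scale. = TRUE)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  lambda <- pc$sdev^2
  share <- pc_variance_share(lambda, p)
  structure(list(eigenvalues = lambda, sdev = pc$sdev, loadings = load,
                 scores = scores, variance_share = share,
                 cumulative_share = cumsum(share), n_traits = p),
            class = "pca_result")
}

#' Variance share of a principal component
#'
#' For correlation-matrix PCA the eigenvalues sum to the number of traits, so
#' a component's explained variability is `100 * lambda / p` percent.
#'
#' @param lambda eigenvalue(s).
#' @param p number of traits entering the PCA.
#' @return Percentage share(s).
#' @export
pc_variance_share <- function(lambda, p) 100 * lambda / p

#' @export
print.pca_result <- function(x, ...) {
  k <- min(6L, length(x$eigenvalues))
  cat("pca_result:", x$n_traits, "traits,", nrow(x$scores), "accessions\n")
  tab <- rbind(eigenvalue = x$eigenvalues[1:k],
               `variance %` = x$variance_share[1:k],
               `cumulative %` = x$cumulative_share[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, 2))
  invisible(x)
}

#' Agglomerative hierarchical clustering of accessions
#'
#' @param d distance matrix (e.g. [gower_matrix()], possibly Euclidean on
#'   standardized traits).
#' @param linkage `"ward"` (ward.D2), `"average"` or `"complete"`.
#' @return A `dendrogram_result`: the `hclust` tree, the linkage label and
#'   helpers [cut_dendrogram()] / [dendrogram_newick()].
#' @export
hier_cluster <- function(d, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  if (nrow(as.matrix(d)) < 2L) stop("need at least 2 accessions")
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[linkage]
  hc <- hclust(as.dist(d), method = method)
  structure(list(hclust = hc, linkage = linkage), class = "dendrogram_result")
}

#' Flat cluster labels from a dendrogram
#'
#' @param dendro a [hier_cluster()] result.
#' @param k requested number of clusters.
#' @return Named integer vector of cluster labels.
#' @export
cut_dendrogram <- function(dendro, k) {
  stopifnot(inherits(dendro, "dendrogram_result"))
  cutree(dendro$hclust, k = k)
}

#' Newick export of a dendrogram
#'
#' @param dendro a [hier_cluster()] result.
#' @param path optional file path; when `NULL` the newick string is returned.
#' @return The newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "dendrogram_result"))
  phy <- ape::as.phylo(dendro$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}

#' Pearson correlation matrix with per-pair p-values
#'
#' Pairwise-complete Pearson correlations with two-sided t-based p-values;
#' pairs involving a constant trait are flagged undefined (NA).
#'
#' @param traits accession x trait data frame (numeric columns used).
#' @return List with `r` (correlation matrix, unit diagonal) and `p`.
#' @export
correlation_matrix <- function(traits) {
  num <- as.data.frame(traits)
  num <- num[, vapply(num, is.numeric, logical(1L)), drop = FALSE]
  if (nrow(num) < 3L) stop("need at least 3 accessions")
  p <- ncol(num)
  r <- suppressWarnings(cor(num, use = "pairwise.complete.obs"))
  diag(r) <- 1
  pv <- matrix(NA_real_, p, p, dimnames = dimnames(r))
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      ok <- complete.cases(num[[i]], num[[j]])
      n <- sum(ok)
      rij <- r[i, j]
      if (is.na(rij) || n < 3L) next
      tstat <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
      pv[i, j] <- pv[j, i] <- 2 * pt(-abs(tstat), n - 2)
    }
  }
  diag(pv) <- 0
  list(r = r, p = pv)
}
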