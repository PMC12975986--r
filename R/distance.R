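#' Accession-level trait table
#'
#' Assembles the accession x trait table that distance computation and core
#' sampling consume: block-adjusted means for the quantitative traits and the
#' accession-level descriptor state for the qualitative traits, for the test
#' accessions of a field book.
#'
#' @param fb a validated [field_book()].
#' @param adj an [adjust_means()] result for `fb` (computed if missing).
#' @return Data frame with accession ids as row names.
#' @export
accession_traits <- function(fb, adj = NULL) {
  stopifnot(inherits(fb, "field_book"))
  if (is.null(adj)) adj <- adjust_means(fb)
  out <- as.data.frame(adj$means)
  qual <- intersect(qualitative_traits(fb$descriptors), names(fb$plots))
  if (length(qual)) {
    tp <- fb$plots[fb$plots$role == "test", c("accession", qual)]
    tp <- tp[!duplicated(tp$accession), , drop = FALSE]
    rownames(tp) <- tp$accession
    for (tr in qual) out[[tr]] <- tp[rownames(out), tr]
  }
  out
}

#' Gower (or Euclidean) distance matrix on mixed trait data
#'
#' Pairwise dissimilarities between accessions: Gower's coefficient averages
#' range-normalized absolute differences for quantitative traits and 0/1
#' mismatch indicators for qualitative traits, with pairwise deletion of
#' missing values and renormalization over the traits observed in both
#' accessions; entries lie in \[0, 1\]. The Euclidean option standardizes the
#' quantitative traits and ignores qualitative ones.
#'
#' @param traits accession x trait data frame (row names = accession ids),
#'   e.g. from [accession_traits()].
#' @param descriptors optional [trait_descriptors()]; when absent, numeric
#'   columns are treated as quantitative and the rest as qualitative.
#' @param subset optional trait names to restrict to.
#' @param metric `"gower"` (default) or `"euclidean"`.
#' @return A symmetric n x n matrix with zero diagonal, accession ids as
#'   dimnames and a `"metric"` attribute.
#' @export
gower_matrix <- function(traits, descriptors = NULL, subset = NULL,
                         metric = c("gower", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(traits), nrow(traits) >= 2L)
  if (!is.null(subset)) {
    miss <- setdiff(subset, names(traits))
    if (length(miss)) stop("unknown trait(s): ", paste(miss, collapse = ", "))
    traits <- traits[, subset, drop = FALSE]
  }
  if (any(rowSums(!is.na(traits)) == 0L)) {
    stop("accession(s) with all-missing trait values: ",
         paste(rownames(traits)[rowSums(!is.na(traits)) == 0L], collapse = ", "))
  }
  if (is.null(descriptors)) {
    kinds <- ifelse(vapply(traits, is.numeric, logical(1L)),
                    "quantitative", "qualitative")
  } else {
    kinds <- setNames(descriptors$kind, descriptors$trait)[names(traits)]
  }
  df <- traits
  keep <- rep(TRUE, ncol(df))
  for (i in seq_along(df)) {
    if (kinds[i] == "quantitative") {
      rng <- suppressWarnings(diff(range(df[[i]], na.rm = TRUE)))
      if (!is.finite(rng) || rng == 0) {
        warning("dropping constant trait '", names(df)[i], "'")
        keep[i] <- FALSE
      }
    } else {
      df[[i]] <- factor(df[[i]])
      if (nlevels(df[[i]]) < 2L) {
        warning("dropping constant trait '", names(df)[i], "'")
        keep[i] <- FALSE
      }
    }
  }
  df <- df[, keep, drop = FALSE]
  if (!ncol(df)) stop("all traits are constant; no distance is defined")
  if (metric == "gower") {
    d <- cluster::daisy(df, metric = "gower", warnBin = FALSE,
                        warnAsym = FALSE, warnConst = FALSE)
  } else {
    num <- df[, kinds[keep] == "quantitative", drop = FALSE]
    if (!ncol(num)) stop("euclidean metric needs quantitative traits")
    d <- dist(scale(as.matrix(num)))
  }
  m <- as.matrix(d)
  diag(m) <- 0
  dimnames(m) <- list(rownames(traits), rownames(traits))
  attr(m, "metric") <- metric
  m
}
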