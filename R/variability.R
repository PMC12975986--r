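#' Broad-sense heritability from the two coefficients of variation
#'
#' Algebraic identity `h2 = 100 * (GCV / PCV)^2`, the internal consistency
#' relation between the genotypic and phenotypic coefficients of variation
#' and broad-sense heritability (both CVs share the same mean, so the mean
#' cancels and only the variance ratio remains).
#'
#' @param gcv,pcv genotypic and phenotypic coefficients of variation (%).
#' @return Heritability on the 0-100 scale.
#' @export
h2_from_cv <- function(gcv, pcv) 100 * (gcv / pcv)^2

#' Expected genetic advance under truncation selection
#'
#' `GA = k * sqrt(Vp) * h2/100` with `sqrt(Vp)` recovered from the phenotypic
#' coefficient of variation as `PCV * mean / 100`.
#'
#' @param k standardized selection differential (2.063 for 5% selection).
#' @param h2 broad-sense heritability (%).
#' @param pcv phenotypic coefficient of variation (%).
#' @param mean trait mean.
#' @return Genetic advance in trait units.
#' @export
genetic_advance <- function(k, h2, pcv, mean) k * (h2 / 100) * (pcv * mean / 100)

#' Genetic gain as a percentage of the trait mean
#'
#' @param ga genetic advance in trait units.
#' @param mean trait mean.
#' @return `100 * ga / mean`.
#' @export
gg_from_ga <- function(ga, mean) 100 * ga / mean

#' Categorize a variability parameter
#'
#' Conventional three-level labels: heritability is Low below 30%, Medium in
#' \[30, 60\], High above 60%; GCV/PCV, genetic advance and genetic gain are
#' Low below 10, Medium in \[10, 20\], High above 20. Boundaries are closed
#' on the lower side (a value of exactly 30 is Medium).
#'
#' @param value non-negative parameter value.
#' @param parameter one of `"h2"`, `"gcv_pcv"`, `"ga"`, `"gg"`.
#' @return `"Low"`, `"Medium"` or `"High"` (vectorized over `value`).
#' @export
categorize_param <- function(value, parameter = c("h2", "gcv_pcv", "ga", "gg")) {
  parameter <- match.arg(parameter)
  if (any(value < 0, na.rm = TRUE)) stop("parameter value must be >= 0")
  cuts <- if (parameter == "h2") c(30, 60) else c(10, 20)
  out <- ifelse(value < cuts[1L], "Low",
                ifelse(value <= cuts[2L], "Medium", "High"))
  out
}

#' Genetic variability parameters per trait
#'
#' Computes, for every quantitative trait, the phenotypic variance `Vp`
#' (variance of the adjusted test means), the error variance attached to an
#' adjusted mean, the genotypic variance `Vg = Vp - Ve_adj` (floored at zero
#' with a warning when the error variance exceeds the phenotypic variance),
#' the genotypic and phenotypic coefficients of variation, broad-sense
#' heritability, genetic advance and genetic gain, and their category labels.
#'
#' The variance of an adjusted test value exceeds `Vg + Ve` by the
#' block-effect estimation variance `Ve/(r*c)` (c checks, r replicates per
#' block). With `ve_inflation = TRUE` (default) that term is removed from the
#' phenotypic variance (`Vp = var(adjusted means) - Ve/(rc)`) and the
#' genotypic variance is `Vg = Vp - Ve`, so the decomposition `Vp = Vg + Ve`
#' holds exactly and the heritability estimator is unbiased on adjusted
#' data; `FALSE` uses the raw adjusted-mean variance as `Vp`.
#'
#' @param adj an [adjust_means()] result.
#' @param k standardized selection differential (default 2.063, 5% selection).
#' @param ve_inflation account for block-adjustment error variance (default
#'   TRUE).
#' @return A `variability` data frame with one row per trait: `mean`, `vp`,
#'   `vg`, `ve`, `gcv`, `pcv`, `h2`, `ga`, `gg`, the category columns and a
#'   `vg_floored` flag.
#' @export
variability_params <- function(adj, k = 2.063, ve_inflation = TRUE) {
  stopifnot(inherits(adj, "adjusted_means"))
  if (nrow(adj$means) < 3L) stop("need at least 3 test accessions")
  adj_var <- if (ve_inflation) 1 / (adj$design$r * adj$design$c) else 0
  rows <- lapply(adj$traits, function(tr) {
    x <- adj$means[, tr]
    m <- mean(x, na.rm = TRUE)
    ve <- adj$ve[[tr]]
    vp <- max(var(x, na.rm = TRUE) - ve * adj_var, 0)
    vg <- vp - ve
    floored <- FALSE
    if (is.finite(vg) && vg < 0) {
      warning("Vg floored at 0 for trait '", tr, "' (Ve > Vp)")
      vg <- 0
      floored <- TRUE
    }
    if (!is.finite(m) || abs(m) < .Machine$double.eps) {
      warning("zero mean for trait '", tr, "': CV-based parameters undefined")
      return(data.frame(trait = tr, mean = m, vp = vp, vg = vg, ve = ve,
                        gcv = NA_real_, pcv = NA_real_, h2 = 100 * vg / vp,
                        ga = NA_real_, gg = NA_real_,
                        gcv_category = NA_character_, pcv_category = NA_character_,
                        h2_category = NA_character_, ga_category = NA_character_,
                        gg_category = NA_character_, vg_floored = floored,
                        stringsAsFactors = FALSE))
    }
    gcv <- 100 * sqrt(vg) / m
    pcv <- 100 * sqrt(vp) / m
    h2 <- 100 * vg / vp
    ga <- genetic_advance(k, h2, pcv, m)
    gg <- gg_from_ga(ga, m)
    data.frame(trait = tr, mean = m, vp = vp, vg = vg, ve = ve,
               gcv = gcv, pcv = pcv, h2 = h2, ga = ga, gg = gg,
               gcv_category = categorize_param(gcv, "gcv_pcv"),
               pcv_category = categorize_param(pcv, "gcv_pcv"),
               h2_category = categorize_param(h2, "h2"),
               ga_category = categorize_param(ga, "ga"),
               gg_category = categorize_param(gg, "gg"),
               vg_floored = floored, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("variability", "data.frame")
  out
}
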