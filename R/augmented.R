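#' Block-adjusted entry means for an augmented block design
#'
#' Implements the classical check-based adjustment: for every quantitative
#' trait the block effect is the block's check mean minus the grand check
#' mean, each test entry's observation is corrected by its block effect, and
#' a check's adjusted mean is its raw mean across blocks. Block effects sum
#' to zero by construction. The plot-level error variance `ve` is estimated
#' from the residuals of the additive block + check fit on all check plots
#' (degrees of freedom `b*c*r - b - c + 1`, which reduces to the classical
#' `(b-1)(c-1)` when each check appears once per block).
#'
#' @param fb a validated [field_book()] with at least one check in every block.
#' @return An `adjusted_means` object: `means` (test accession x trait matrix
#'   of adjusted means), `check_means`, `block_effects` (block x trait),
#'   `ve`, `error_df`, `grand_mean` (of test adjusted means) and the design
#'   summary (`b` blocks, `c` checks, `r` replicates per check per block).
#' @export
adjust_means <- function(fb) {
  stopifnot(inherits(fb, "field_book"))
  if (!length(fb$checks)) stop("design error: field book has no check plots")
  quant <- quantitative_traits(fb$descriptors)
  quant <- intersect(quant, names(fb$plots))
  if (!length(quant)) stop("no quantitative traits in field book")
  plots <- fb$plots
  blocks <- sort(unique(plots$block))
  b <- length(blocks); cches <- fb$checks; cc <- length(cches)
  r <- fb$reps_per_check
  is_check <- plots$role == "check"
  tests <- fb$tests

  means <- matrix(NA_real_, length(tests), length(quant),
                  dimnames = list(tests, quant))
  check_means <- matrix(NA_real_, cc, length(quant),
                        dimnames = list(cches, quant))
  block_eff <- matrix(NA_real_, b, length(quant),
                      dimnames = list(blocks, quant))
  ve <- edf <- grand <- setNames(numeric(length(quant)), quant)

  for (tr in quant) {
    y <- plots[[tr]]
    yc <- y[is_check]
    blk_c <- plots$block[is_check]
    chk_c <- plots$accession[is_check]
    grand_check <- mean(yc, na.rm = TRUE)
    bm <- tapply(yc, factor(blk_c, levels = blocks), mean, na.rm = TRUE)
    eff <- bm - grand_check
    block_eff[, tr] <- eff
    cm <- tapply(yc, factor(chk_c, levels = cches), mean, na.rm = TRUE)
    check_means[, tr] <- cm
    # additive two-way residuals on check plots -> plot-scale error variance
    resid <- yc - cm[chk_c] - bm[as.character(blk_c)] + grand_check
    df_err <- sum(!is.na(yc)) - b - cc + 1L
    ve[tr] <- if (df_err > 0) sum(resid^2, na.rm = TRUE) / df_err else NA_real_
    edf[tr] <- df_err
    it <- !is_check
    adj <- y[it] - eff[as.character(plots$block[it])]
    means[plots$accession[it], tr] <- adj
    grand[tr] <- mean(adj, na.rm = TRUE)
  }
  structure(list(means = means, check_means = check_means,
                 block_effects = block_eff, ve = ve, error_df = edf,
                 grand_mean = grand,
                 design = list(b = b, c = cc, r = r, n_test = length(tests)),
                 traits = quant),
            class = "adjusted_means")
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat("adjusted_means:", nrow(x$means), "test accessions x", ncol(x$means),
      "traits;", x$design$b, "blocks,", x$design$c, "checks x", x$design$r, "\n")
  cat("error variance (Ve) per trait:\n")
  print(round(x$ve, 4))
  invisible(x)
}

#' Augmented block design ANOVA
#'
#' Per-trait analysis of variance for Federer's augmented RCBD at plot level:
#' blocks (ignoring treatments), treatments adjusted for blocks — partitioned
#' into checks, tests (from adjusted values) and checks-vs-tests — and the
#' error stratum estimated from the check plots (residual of the additive
#' block + check fit). The strata are additive: the component sums of squares
#' add up to the corrected total.
#'
#' @param fb a validated [field_book()] with at least two checks.
#' @return An `abd_anova` object: per-trait ANOVA tables (`source`, `df`,
#'   `ss`, `ms`, `f`, `p`), plus `ve`, `error_df` and the design summary.
#' @export
abd_anova <- function(fb) {
  stopifnot(inherits(fb, "field_book"))
  if (length(fb$checks) < 2L) {
    stop("error stratum undefined: at least 2 checks are required")
  }
  adj <- adjust_means(fb)
  quant <- adj$traits
  plots <- fb$plots
  blocks <- sort(unique(plots$block))
  b <- adj$design$b; cc <- adj$design$c; r <- adj$design$r
  n_test <- adj$design$n_test
  is_check <- plots$role == "check"

  tables <- list()
  for (tr in quant) {
    y <- plots[[tr]]
    ok <- !is.na(y)
    N <- sum(ok)
    grand <- mean(y[ok])
    ss_total <- sum((y[ok] - grand)^2)
    bm <- tapply(y[ok], factor(plots$block[ok], levels = blocks), mean)
    nj <- tapply(y[ok], factor(plots$block[ok], levels = blocks), length)
    ss_block <- sum(nj * (bm - grand)^2)
    # error: residual of additive block + check fit on check plots
    yc <- y[is_check & ok]
    chk <- plots$accession[is_check & ok]
    blk <- plots$block[is_check & ok]
    gch <- mean(yc)
    cmn <- tapply(yc, chk, mean)
    bmn <- tapply(yc, factor(blk, levels = blocks), mean)
    res <- yc - cmn[chk] - bmn[as.character(blk)] + gch
    ss_error <- sum(res^2)
    df_error <- length(yc) - b - cc + 1L
    ss_treat <- ss_total - ss_block - ss_error
    ss_checks <- sum(tapply(yc, chk, length) * (cmn - gch)^2)
    adj_t <- adj$means[, tr]
    ss_tests <- sum((adj_t - mean(adj_t, na.rm = TRUE))^2, na.rm = TRUE)
    ss_cvt <- ss_treat - ss_checks - ss_tests
    df <- c(block = b - 1L, treatment = cc + n_test - 1L,
            checks = cc - 1L, tests = n_test - 1L, checks_vs_tests = 1L,
            error = df_error)
    ss <- c(ss_block, ss_treat, ss_checks, ss_tests, ss_cvt, ss_error)
    ms <- ss / df
    mse <- ms[["error"]]
    f <- ms / mse
    f[["error"]] <- NA_real_
    p <- ifelse(is.na(f), NA_real_, pf(f, df, df_error, lower.tail = FALSE))
    tables[[tr]] <- data.frame(
      source = c("block", "treatment", "checks", "tests",
                 "checks_vs_tests", "error"),
      df = as.integer(df), ss = ss, ms = ms, f = as.numeric(f),
      p = as.numeric(p), row.names = NULL)
    attr(tables[[tr]], "ss_total") <- ss_total
  }
  structure(list(tables = tables, ve = adj$ve, error_df = adj$error_df,
                 design = adj$design, traits = quant),
            class = "abd_anova")
}

#' @export
print.abd_anova <- function(x, ...) {
  cat("abd_anova:", length(x$traits), "traits;", x$design$b, "blocks,",
      x$design$c, "checks x", x$design$r, "\n")
  tr <- x$traits[1L]
  cat("first trait (", tr, "):\n", sep = "")
  tab <- x$tables[[tr]]
  tab$ss <- signif(tab$ss, 5); tab$ms <- signif(tab$ms, 5)
  tab$f <- signif(tab$f, 4); tab$p <- signif(tab$p, 3)
  print(tab)
  invisible(x)
}

#' Critical differences for an augmented block design
#'
#' Federer's four comparison standard errors, each multiplied by the
#' two-sided t critical value on the error degrees of freedom:
#' check-check `sqrt(2 Ve / b)`, test-test within a block `sqrt(2 Ve)`,
#' test-test across blocks `sqrt(2 Ve (c + 1) / c)`, and test-check
#' `sqrt(Ve (1 + 1/b + 1/c + 1/(bc)))`.
#'
#' @param anova an [abd_anova()] result (or an [adjust_means()] result).
#' @param alpha significance level (default 0.05).
#' @return Data frame with one row per trait and the four CD columns.
#' @export
critical_differences <- function(anova, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  ve <- anova$ve
  edf <- anova$error_df
  b <- anova$design$b; cc <- anova$design$c
  if (any(edf <= 0)) stop("error degrees of freedom must be positive")
  tcrit <- qt(1 - alpha / 2, edf)
  data.frame(
    trait = names(ve),
    cd_check_check = tcrit * sqrt(2 * ve / b),
    cd_test_test_same_block = tcrit * sqrt(2 * ve),
    cd_test_test_diff_block = tcrit * sqrt(2 * ve * (cc + 1) / cc),
    cd_test_check = tcrit * sqrt(ve * (1 + 1 / b + 1 / cc + 1 / (b * cc))),
    alpha = alpha, row.names = NULL, stringsAsFactors = FALSE)
}

#' Identify promising accessions by critical difference
#'
#' Flags test accessions whose adjusted mean beats the best check mean by
#' more than the test-check critical difference, in the requested direction,
#' sorted by decreasing margin.
#'
#' @param adj an [adjust_means()] result.
#' @param cd a [critical_differences()] table.
#' @param trait quantitative trait name.
#' @param direction `"higher"` (default) or `"lower"`.
#' @return Data frame `accession`, `adjusted_mean`, `best_check`, `margin`.
#' @export
identify_promising <- function(adj, cd, trait, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (!trait %in% colnames(adj$means)) stop("unknown trait: ", trait)
  cdr <- cd$cd_test_check[cd$trait == trait]
  x <- adj$means[, trait]
  cm <- adj$check_means[, trait]
  if (direction == "higher") {
    best <- max(cm, na.rm = TRUE)
    margin <- x - best - cdr
  } else {
    best <- min(cm, na.rm = TRUE)
    margin <- best - x - cdr
  }
  sel <- which(!is.na(margin) & margin > 0)
  sel <- sel[order(margin[sel], decreasing = TRUE)]
  data.frame(accession = rownames(adj$means)[sel],
             adjusted_mean = unname(x[sel]),
             best_check = rep(best, length(sel)),
             margin = unname(margin[sel]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bartlett's test for homogeneity of error variances across environments
#'
#' Textbook Bartlett chi-square statistic computed from per-environment error
#' variances and their degrees of freedom (as produced by per-environment
#' augmented-design ANOVAs).
#'
#' @param ve numeric vector of error variances (one per environment, > 0).
#' @param df degrees of freedom for each variance (>= 1).
#' @return An object of class `htest` with the statistic, df and p-value.
#' @export
bartlett_homogeneity <- function(ve, df) {
  if (length(ve) < 2L) stop("need error variances from at least 2 environments")
  if (any(ve <= 0)) stop("error variances must be positive")
  if (any(df < 1)) stop("each degrees of freedom must be >= 1")
  k <- length(ve)
  pooled <- sum(df * ve) / sum(df)
  M <- sum(df) * log(pooled) - sum(df * log(ve))
  C <- 1 + (sum(1 / df) - 1 / sum(df)) / (3 * (k - 1))
  stat <- M / C
  pval <- pchisq(stat, k - 1, lower.tail = FALSE)
  structure(list(statistic = c(`Bartlett's K-squared` = stat),
                 parameter = c(df = k - 1), p.value = pval,
                 method = "Bartlett test of homogeneity of error variances",
                 data.name = paste(k, "environments")),
            class = "htest")
}
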