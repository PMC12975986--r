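#' Trait descriptor set
#'
#' A descriptor set declares, for every trait recorded in a field book,
#' whether it is quantitative or qualitative, its unit, and (for qualitative
#' traits) the ordered list of descriptor states.
#'
#' @param trait character vector of unique trait names.
#' @param kind character vector, `"quantitative"` or `"qualitative"`.
#' @param unit character vector of units (may be empty strings).
#' @param states list of character vectors of descriptor states; must be
#'   empty for quantitative traits and have at least two states for
#'   qualitative traits.
#' @return A `trait_descriptors` data frame with one row per trait.
#' @examples
#' trait_descriptors(
#'   trait = c("PH", "SC"),
#'   kind = c("quantitative", "qualitative"),
#'   unit = c("cm", ""),
#'   states = list(character(), c("green", "yellow"))
#' )
#' @export
trait_descriptors <- function(trait, kind, unit = rep("", length(trait)),
                              states = vector("list", length(trait))) {
  trait <- as.character(trait)
  kind <- match.arg(kind, c("quantitative", "qualitative"), several.ok = TRUE)
  kind <- rep_len(kind, length(trait))
  if (anyDuplicated(trait)) {
    stop("duplicate trait names in descriptor set: ",
         paste(unique(trait[duplicated(trait)]), collapse = ", "))
  }
  states <- lapply(states, function(s) as.character(s %||% character()))
  for (i in seq_along(trait)) {
    if (kind[i] == "qualitative" && length(states[[i]]) < 2L) {
      stop("qualitative trait '", trait[i], "' needs at least 2 descriptor states")
    }
    if (kind[i] == "quantitative" && length(states[[i]]) > 0L) {
      stop("quantitative trait '", trait[i], "' must not declare descriptor states")
    }
  }
  out <- data.frame(trait = trait, kind = kind, unit = as.character(unit),
                    stringsAsFactors = FALSE)
  out$states <- states
  class(out) <- c("trait_descriptors", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a trait descriptor table
#'
#' Expects a CSV with columns `trait`, `kind`, `unit`, `states`; states are
#' `"|"`-separated for qualitative traits and empty for quantitative ones.
#'
#' @param path path to the descriptor CSV.
#' @return A [trait_descriptors()] object.
#' @export
read_descriptors <- function(path) {
  if (!file.exists(path)) stop("descriptor file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("trait", "kind", "states")
  if (!all(need %in% names(d))) {
    stop("descriptor file must have columns: ", paste(need, collapse = ", "))
  }
  d$states[is.na(d$states)] <- ""
  states <- lapply(strsplit(d$states, "|", fixed = TRUE),
                   function(s) s[nzchar(s)])
  trait_descriptors(d$trait, d$kind, d$unit %||% rep("", nrow(d)), states)
}

quantitative_traits <- function(descriptors) {
  descriptors$trait[descriptors$kind == "quantitative"]
}

qualitative_traits <- function(descriptors) {
  descriptors$trait[descriptors$kind == "qualitative"]
}

#' Construct and validate a field book
#'
#' A field book holds the plot-level observations of one augmented block
#' design trial: each plot has a block, an accession, a role (`check`
#' replicated in every block, or `test` appearing exactly once) and one
#' column per trait.
#'
#' @param plots data frame with columns `plot`, `block`, `accession`, `role`
#'   and one column per descriptor trait.
#' @param descriptors a [trait_descriptors()] set covering every trait column.
#' @param location,year environment labels.
#' @return A validated `field_book` object.
#' @export
field_book <- function(plots, descriptors, location = "unspecified", year = NA) {
  stopifnot(is.data.frame(plots))
  core_cols <- c("plot", "block", "accession", "role")
  miss <- setdiff(core_cols, names(plots))
  if (length(miss)) stop("field book missing columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(plots), c(core_cols, descriptors$trait))
  if (length(extra)) {
    stop("unknown trait column(s) not in descriptor set: ",
         paste(extra, collapse = ", "))
  }
  plots$role <- tolower(trimws(as.character(plots$role)))
  bad_role <- setdiff(unique(plots$role), c("check", "test"))
  if (length(bad_role)) stop("invalid role value(s): ", paste(bad_role, collapse = ", "))
  plots$block <- as.integer(plots$block)
  if (!is_contiguous(plots$block)) stop("block ids must form a contiguous set")
  for (tr in intersect(descriptors$trait, names(plots))) {
    kind <- descriptors$kind[descriptors$trait == tr]
    if (kind == "quantitative") {
      v <- plots[[tr]]
      if (!is.numeric(v)) {
        suppressWarnings(num <- as.numeric(as.character(v)))
        bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
        if (length(bad)) {
          stop("non-numeric value '", v[bad[1L]], "' in quantitative trait '",
               tr, "' at plot ", plots$plot[bad[1L]])
        }
        plots[[tr]] <- num
      }
    } else {
      plots[[tr]] <- as.character(plots[[tr]])
      st <- descriptors$states[descriptors$trait == tr][[1L]]
      bad <- setdiff(stats::na.omit(unique(plots[[tr]])), st)
      if (length(bad)) {
        stop("unknown descriptor state(s) for '", tr, "': ",
             paste(bad, collapse = ", "))
      }
    }
  }
  blocks <- sort(unique(plots$block))
  checks <- sort(unique(plots$accession[plots$role == "check"]))
  if (length(checks)) {
    tab <- table(factor(plots$accession[plots$role == "check"], levels = checks),
                 factor(plots$block[plots$role == "check"], levels = blocks))
    reps <- max(tab)
    off <- which(tab != reps, arr.ind = TRUE)
    if (nrow(off)) {
      stop("design error: check '", checks[off[1L, 1L]],
           "' does not appear ", reps, " time(s) in block ", blocks[off[1L, 2L]])
    }
  } else {
    reps <- 0L
  }
  test_counts <- table(plots$accession[plots$role == "test"])
  if (length(test_counts) && any(test_counts != 1L)) {
    stop("design error: test accession(s) appearing more than once: ",
         paste(names(test_counts)[test_counts != 1L], collapse = ", "))
  }
  structure(
    list(plots = plots, descriptors = descriptors,
         environment = list(location = location, year = year),
         checks = checks, reps_per_check = as.integer(reps),
         n_blocks = length(blocks),
         tests = sort(unique(plots$accession[plots$role == "test"]))),
    class = "field_book")
}

#' @export
print.field_book <- function(x, ...) {
  cat("field_book:", nrow(x$plots), "plots,", x$n_blocks, "blocks,",
      length(x$tests), "test accessions,", length(x$checks), "checks (x",
      x$reps_per_check, "per block)\n")
  cat("traits:", sum(x$descriptors$kind == "quantitative"), "quantitative,",
      sum(x$descriptors$kind == "qualitative"), "qualitative\n")
  cat("environment:", x$environment$location,
      if (!is.na(x$environment$year)) x$environment$year else "", "\n")
  invisible(x)
}

#' Load a field book and its descriptors from CSV files
#'
#' Reads a plot-level field book (`plot`, `block`, `accession`, `role`, one
#' column per trait; missing values as `NA`) together with its trait
#' descriptor table, and validates the augmented design layout. Repeated rows
#' with the same plot id are treated as intra-plot replicate measurements and
#' averaged (quantitative traits) unless `average_replicates = FALSE`.
#'
#' @param fieldbook_path path to the field book CSV.
#' @param descriptor_path path to the descriptor CSV.
#' @param average_replicates average repeated rows per plot id (default TRUE).
#' @param location,year environment labels recorded on the result.
#' @return A validated [field_book()].
#' @export
load_collection <- function(fieldbook_path, descriptor_path,
                            average_replicates = TRUE,
                            location = "unspecified", year = NA) {
  if (!file.exists(fieldbook_path)) stop("field book not found: ", fieldbook_path)
  descriptors <- read_descriptors(descriptor_path)
  raw <- read.csv(fieldbook_path, stringsAsFactors = FALSE, na.strings = "NA",
                  check.names = FALSE)
  if (average_replicates && anyDuplicated(raw$plot)) {
    quant <- intersect(quantitative_traits(descriptors), names(raw))
    qual <- intersect(qualitative_traits(descriptors), names(raw))
    for (tr in quant) {
      v <- raw[[tr]]
      if (!is.numeric(v)) {
        suppressWarnings(num <- as.numeric(as.character(v)))
        bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
        if (length(bad)) {
          stop("non-numeric value '", v[bad[1L]], "' in quantitative trait '",
               tr, "' at plot ", raw$plot[bad[1L]])
        }
        raw[[tr]] <- num
      }
    }
    agg <- lapply(split(raw, raw$plot), function(g) {
      out <- g[1L, , drop = FALSE]
      for (tr in quant) out[[tr]] <- mean(g[[tr]], na.rm = TRUE)
      for (tr in qual) {
        u <- stats::na.omit(unique(g[[tr]]))
        out[[tr]] <- if (length(u)) u[1L] else NA_character_
      }
      out
    })
    raw <- do.call(rbind, agg)
    rownames(raw) <- NULL
  }
  field_book(raw, descriptors, location = location, year = year)
}

#' Write a field book back to CSV
#'
#' Companion writer for [load_collection()]; round-trips plots, roles and
#' trait values losslessly.
#'
#' @param fb a [field_book()].
#' @param path output CSV path.
#' @export
save_field_book <- function(fb, path) {
  stopifnot(inherits(fb, "field_book"))
  write.csv(fb$plots, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Load passport records
#'
#' Reads a CSV with columns `accession`, `group` (geographic group) and an
#' optional `origin`. Accession ids must be unique.
#'
#' @param path path to the passport CSV.
#' @return Data frame of passport records.
#' @export
load_passport <- function(path) {
  if (!file.exists(path)) stop("passport file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"accession" %in% names(d)) stop("passport file needs an 'accession' column")
  if (anyDuplicated(d$accession)) {
    stop("duplicate accession id(s) in passport file: ",
         paste(unique(d$accession[duplicated(d$accession)]), collapse = ", "))
  }
  if ("group" %in% names(d) && any(!is.na(d$group) & !nzchar(d$group))) {
    stop("empty group label in passport file")
  }
  d
}

#' Save a core set membership list
#'
#' Writes the accession ids of a core set as CSV preceded by a provenance
#' comment header (`# method=... w_en=... w_an=... size=... seed=...`), and
#' [read_core_list()] restores it losslessly.
#'
#' @param core a `core_set` object (see [optimize_core()]).
#' @param path output path.
#' @export
save_core_list <- function(core, path) {
  stopifnot(inherits(core, "core_set"))
  if (!length(core$ids)) stop("cannot save an empty core set")
  hdr <- sprintf("# method=%s w_en=%s w_an=%s size=%d seed=%s",
                 core$method, format(core$w_en), format(core$w_an),
                 length(core$ids), format(core$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "accession"), con)
  writeLines(as.character(core$ids), con)
  invisible(path)
}

#' Read a core set membership list written by [save_core_list()]
#'
#' @param path path to the core list file.
#' @return A `core_set` object.
#' @export
read_core_list <- function(path) {
  if (!file.exists(path)) stop("core list not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  ids <- body[-1L]
  meta <- list(method = "unknown", w_en = NA_real_, w_an = NA_real_, seed = NA)
  if (length(hdr)) {
    kv <- regmatches(hdr[1L], gregexpr("[a-z_]+=[^ ]+", hdr[1L]))[[1L]]
    for (pair in kv) {
      parts <- strsplit(pair, "=", fixed = TRUE)[[1L]]
      meta[[parts[1L]]] <- parts[2L]
    }
  }
  new_core_set(ids = ids, method = meta$method,
               w_en = suppressWarnings(as.numeric(meta$w_en)),
               w_an = suppressWarnings(as.numeric(meta$w_an)),
               seed = suppressWarnings(as.numeric(meta$seed)))
}

new_core_set <- function(ids, method, w_en = NA_real_, w_an = NA_real_,
                         forced = character(), seed = NA, objective = NULL,
                         normalization = NULL, extras = list()) {
  stopifnot(!anyDuplicated(ids))
  structure(list(ids = as.character(ids), method = method,
                 w_en = w_en, w_an = w_an, forced = as.character(forced),
                 seed = seed, size = length(ids), objective = objective,
                 normalization = normalization, extras = extras),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat("core_set:", x$size, "accessions, method =", x$method)
  if (!is.na(x$w_en)) cat(sprintf(" (w_EN=%.2f, w_AN=%.2f)", x$w_en, x$w_an))
  cat("\n")
  if (!is.null(x$objective)) {
    cat(sprintf("  E-NE=%.4f  A-NE=%.4f  E-E=%.4f\n",
                x$objective["e_ne"], x$objective["a_ne"], x$objective["e_e"]))
  }
  cat("  ids:", paste(head(x$ids, 8L), collapse = ", "),
      if (x$size > 8L) "..." else "", "\n")
  invisible(x)
}
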