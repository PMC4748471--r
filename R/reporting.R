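#' Summarize a mapping result
#'
#' Aggregates per-concept outcomes into coverage counts and fractions, level
#' histograms (full resolution plus the conventional bins: lexical 1/2/3+,
#' logical 1..4/5+), and the lexical-by-logical level cross-tabulation.
#'
#' @param result A `mapping_result`.
#' @param digits Decimal places for the reported percentage columns
#'   (counts stay exact; percentages use round-half-even).
#' @return Object of class `mapping_report`: list with `counts`,
#'   `fractions`, `percent`, `lexical_levels`, `logical_levels`,
#'   `lexical_levels_binned`, `logical_levels_binned`, `crosstab`, `total`.
#' @export
summarize_mappings <- function(result, digits = 1) {
  cats <- result$categories
  lv <- c("complete", "both", "lexical_only", "logical_only", "unmapped")
  counts <- table(factor(cats$category, levels = lv))
  counts <- stats::setNames(as.integer(counts), lv)
  total <- nrow(cats)
  counts <- c(counts,
              partial_lexical = counts[["both"]] + counts[["lexical_only"]],
              partial_logical = counts[["both"]] + counts[["logical_only"]],
              partial_any = counts[["both"]] + counts[["lexical_only"]] +
                counts[["logical_only"]],
              mapped_any = total - counts[["unmapped"]])
  fractions <- if (total > 0) counts / total else counts * 0

  hist_of <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(stats::setNames(integer(), character()))
    tab <- table(factor(x, levels = seq_len(max(x))))
    stats::setNames(as.integer(tab), names(tab))
  }
  bin_levels <- function(h, cut) {
    if (!length(h)) return(stats::setNames(integer(), character()))
    lev <- as.integer(names(h))
    lab <- ifelse(lev >= cut, paste0(cut, "+"), as.character(lev))
    out <- tapply(h, lab, sum)
    ord <- order(as.integer(sub("\\+", "", names(out))))
    stats::setNames(as.integer(out[ord]), names(out)[ord])
  }
  lex_h <- hist_of(cats$lexical_level)
  log_h <- hist_of(cats$logical_level)

  structure(list(
    total = total,
    counts = counts,
    fractions = fractions,
    percent = round(100 * fractions, digits),
    lexical_levels = lex_h,
    logical_levels = log_h,
    lexical_levels_binned = bin_levels(lex_h, 3L),
    logical_levels_binned = bin_levels(log_h, 5L),
    crosstab = level_crosstab(result)
  ), class = "mapping_report")
}

#' @export
summary.mapping_result <- function(object, ...) summarize_mappings(object, ...)

#' @export
print.mapping_report <- function(x, ...) {
  cat("<mapping_report> ", x$total, " source concepts\n", sep = "")
  for (nm in c("complete", "both", "lexical_only", "logical_only",
               "unmapped")) {
    cat(sprintf("  %-13s %6d  (%s%%)\n", nm, x$counts[[nm]],
                format(x$percent[[nm]])))
  }
  invisible(x)
}

#' Cross-tabulate partial-mapping levels
#'
#' Cell (i, j) counts source concepts with a partial lexical mapping at
#' level i and a partial logical mapping at level j; a "none" row and column
#' hold concepts carrying only one kind. The grand total equals the number
#' of concepts lacking a complete mapping.
#'
#' @param result A `mapping_result`.
#' @return Integer matrix with labeled "none" margins; row names are lexical
#'   levels, column names logical levels.
#' @export
level_crosstab <- function(result) {
  cats <- result$categories
  cats <- cats[cats$category != "complete", , drop = FALSE]
  lex_max <- max(c(cats$lexical_level, 1L), na.rm = TRUE)
  log_max <- max(c(cats$logical_level, 1L), na.rm = TRUE)
  rlab <- c(as.character(seq_len(lex_max)), "none")
  clab <- c(as.character(seq_len(log_max)), "none")
  rw <- ifelse(is.na(cats$lexical_level), "none",
               as.character(cats$lexical_level))
  cl <- ifelse(is.na(cats$logical_level), "none",
               as.character(cats$logical_level))
  tab <- table(factor(rw, levels = rlab), factor(cl, levels = clab))
  m <- matrix(as.integer(tab), nrow = length(rlab),
              dimnames = list(lexical_level = rlab, logical_level = clab))
  m
}

#' Draw a reproducible sample of partial mappings for manual review
#'
#' `mode = "fraction"` draws `floor(fraction * n)` of the per-concept
#' partial lexical mappings uniformly without replacement; `mode =
#' "per_level"` draws `min(per_level, available)` partial logical mappings
#' from each level stratum. The seed is mandatory and the draw never
#' disturbs the caller's RNG state.
#'
#' @param result A `mapping_result`.
#' @param mode `"fraction"` (lexical) or `"per_level"` (logical).
#' @param seed Integer seed (required; no implicit global randomness).
#' @param fraction Sampling fraction for `"fraction"` mode.
#' @param per_level Stratum size for `"per_level"` mode.
#' @return data.frame of sampled per-concept mappings (source_id, level,
#'   target_ids).
#' @export
draw_review_sample <- function(result, mode = c("fraction", "per_level"),
                               seed, fraction = 0.10, per_level = 25L) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("an explicit seed is required")
  df <- if (mode == "fraction") result$partial_lexical else
    result$partial_logical
  if (!nrow(df)) {
    return(data.frame(source_id = character(), level = integer(),
                      target_ids = character(), stringsAsFactors = FALSE))
  }
  per_concept <- do.call(rbind, lapply(
    split(df, df$source_id), function(d) {
      data.frame(source_id = d$source_id[1], level = d$level[1],
                 target_ids = paste(sort_c(unique(d$target_id)),
                                    collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  per_concept <- per_concept[order(per_concept$source_id, method = "radix"),
                             , drop = FALSE]
  rownames(per_concept) <- NULL
  with_seed(seed, {
    if (mode == "fraction") {
      m <- floor(fraction * nrow(per_concept))
      idx <- sort(sample.int(nrow(per_concept), m))
      per_concept[idx, , drop = FALSE]
    } else {
      picked <- lapply(split(seq_len(nrow(per_concept)), per_concept$level),
                       function(idx) {
                         m <- min(per_level, length(idx))
                         sort(idx[sample.int(length(idx), m)])
                       })
      out <- per_concept[unlist(picked, use.names = FALSE), , drop = FALSE]
      rownames(out) <- NULL
      out
    }
  })
}

#' Write a mapping report as JSON
#'
#' Serializes counts, fractions, level histograms and the cross-tab;
#' [read_report()] reloads it with identical counts.
#'
#' @param report A `mapping_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    total = report$total,
    counts = as.list(report$counts),
    fractions = as.list(report$fractions),
    lexical_levels = as.list(report$lexical_levels),
    logical_levels = as.list(report$logical_levels),
    crosstab = list(
      rows = rownames(report$crosstab),
      cols = colnames(report$crosstab),
      cells = lapply(seq_len(nrow(report$crosstab)), function(i)
        as.list(report$crosstab[i, ]))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reload a JSON mapping report
#'
#' @param path Path written by [write_report()].
#' @return List with `total`, `counts`, `lexical_levels`, `logical_levels`,
#'   `crosstab` (integer matrix).
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  m <- do.call(rbind, lapply(x$crosstab$cells, function(r)
    vapply(r, as.integer, integer(1))))
  dimnames(m) <- list(lexical_level = unlist(x$crosstab$rows),
                      logical_level = unlist(x$crosstab$cols))
  list(
    total = as.integer(x$total),
    counts = vapply(x$counts, as.integer, integer(1)),
    lexical_levels = vapply(x$lexical_levels, as.integer, integer(1)),
    logical_levels = vapply(x$logical_levels, as.integer, integer(1)),
    crosstab = m
  )
}

#' Write summary rows as TSV
#'
#' @param report A `mapping_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  df <- data.frame(metric = names(report$counts),
                   count = as.integer(report$counts),
                   percent = as.numeric(report$percent[names(report$counts)]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the level cross-tab as TSV with labeled margins
#'
#' @param report A `mapping_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crosstab_tsv <- function(report, path) {
  m <- report$crosstab
  df <- data.frame(lexical_level = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
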