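# Accessors for the published genome-scale screen tables shipped with the
# package.  These counts are inputs (printed results of a proteome-wide
# screen whose raw variant corpus is not redistributable); the package's
# reporting functions recompute all derived percentages and tests from
# them.

#' Published proteome-screen count tables
#'
#' Returns the shipped per-level sweep counts (variant calls of each type
#' at each specificity option), the per-type class breakdown at the 70%
#' specificity option, and the cohort totals (number of screened variants
#' per class).
#'
#' @return `list(sweep, class_counts, totals)` of data.frames; `totals` is
#'   a named numeric vector.
#' @export
reported_screen <- function() {
  p <- function(f) system.file("extdata", f, package = "sumovar")
  sweep <- utils::read.delim(p("reported_sweep_counts.tsv"),
                             stringsAsFactors = FALSE)
  cls <- utils::read.delim(p("reported_class_counts.tsv"),
                           stringsAsFactors = FALSE)
  tot <- utils::read.delim(p("reported_cohort_totals.tsv"),
                           stringsAsFactors = FALSE)
  totals <- stats::setNames(tot$value, tot$quantity)
  list(sweep = sweep, class_counts = cls, totals = totals)
}

#' Percentage breakdown of a sweep-count row
#'
#' Recomputes, for one specificity level, the share of each variant-effect
#' type among all screened variants and among all called variants.
#'
#' @param sweep sweep-count data.frame (see [reported_screen()] or
#'   [sweep_report()]).
#' @param n_variants total number of screened variants.
#' @param level which level row to use.
#' @return Named numeric vector of percentages (two decimals):
#'   `type_I_pct`, `type_II_pct`, `type_III_pct`, `total_pct` (of all
#'   variants) and `type_III_share` (of all calls).
#' @export
sweep_percentages <- function(sweep, n_variants, level = "default") {
  row <- sweep[sweep$level == level, , drop = FALSE]
  if (nrow(row) != 1L) stop(sprintf("no unique row for level '%s'", level),
                            call. = FALSE)
  total <- row$type_I_all + row$type_II_all + row$type_III
  c(type_I_pct = pct(row$type_I_all, n_variants),
    type_II_pct = pct(row$type_II_all, n_variants),
    type_III_pct = pct(row$type_III, n_variants),
    total_pct = pct(total, n_variants),
    type_III_share = pct(row$type_III, total))
}
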