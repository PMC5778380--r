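# Target annotation of series and scaffolds, and the summary statistics of
# an extraction run (series/compound coverage, single- vs multi-site
# categories, single- vs multi-target breakdown).

#' Annotate analog series with target information
#'
#' The target set of a series is the union of its members' annotations; a
#' series is single-target when exactly one target remains, multi-target
#' for more than one. Scaffolds derived afterwards inherit the series
#' target set, so multi-target activity is captured at scaffold level.
#'
#' @param seriesSet an \linkS4class{AnalogSeriesSet}.
#' @param compounds the annotated \linkS4class{CompoundSet} (see
#'   \code{\link{setCompoundTargets}}).
#' @param activity optional activity data.frame (\code{compound_id,
#'   target_id}) applied to \code{compounds} first.
#' @return the AnalogSeriesSet with per-series target slots filled.
#' @export
annotateSeries <- function(seriesSet, compounds, activity = NULL) {
  if (!is.null(activity)) compounds <- setCompoundTargets(compounds, activity)
  tg <- compoundTargets(compounds)
  seriesSet@series <- lapply(seriesSet@series, function(s) {
    s@targets <- sort(unique(unlist(tg[s@members], use.names = FALSE)))
    s
  })
  seriesSet
}

#' Summary statistics of an extraction run
#'
#' Computes the series/scaffold statistics reported for analog-series
#' extractions: series counts and sizes, the three scaffold categories
#' (single-site series whose scaffold already qualified as the unique core
#' before reduction, single-site series rescued by redundant-core
#' reduction, multi-site series), compound and series coverage by accepted
#' scaffolds, target counts, and the single-/multi-target breakdown.
#' Percentages are computed against the number of series (series-based
#' rows) or the number of compounds participating in series (compound-based
#' rows), rounded half-up to one decimal.
#'
#' @param seriesSet an \linkS4class{AnalogSeriesSet} (annotated if target
#'   statistics are wanted).
#' @param scaffolds list of \linkS4class{ASBScaffold} from
#'   \code{\link{deriveScaffolds}}.
#' @param compounds optional \linkS4class{CompoundSet} for the total
#'   compound count.
#' @return an object of class \code{ASBStatsReport} (a list; see fields in
#'   the vignette), with a printed table layout.
#' @export
summarizeSeries <- function(seriesSet, scaffolds, compounds = NULL) {
  stopifnot(length(scaffolds) == length(seriesSet))
  sizes <- vapply(seriesSet@series, length, integer(1))
  n_series <- length(seriesSet)
  n_in_series <- sum(sizes)
  status <- vapply(scaffolds, function(s) s@status, character(1))
  nsites <- vapply(scaffolds, function(s) s@nSites, integer(1))
  gener <- vapply(scaffolds, function(s) s@generation, character(1))
  targets_of <- lapply(seriesSet@series, function(s) s@targets)
  cat_of <- ifelse(status != "ok", "excluded",
                   ifelse(nsites >= 2, "multi_site",
                          ifelse(gener == "first", "single_site_first",
                                 "single_site_second")))
  cat_stats <- function(sel) {
    list(
      n_series = sum(sel),
      pct_series = pctOf(sum(sel), n_series),
      n_compounds = sum(sizes[sel]),
      pct_compounds = pctOf(sum(sizes[sel]), n_in_series),
      size_min = if (any(sel)) min(sizes[sel]) else 0L,
      size_max = if (any(sel)) max(sizes[sel]) else 0L,
      size_mean = if (any(sel)) .round1(mean(sizes[sel])) else 0,
      mean_sites = if (any(sel)) .round1(mean(nsites[sel])) else 0,
      n_targets = length(unique(unlist(targets_of[sel], use.names = FALSE))))
  }
  ok <- status == "ok"
  n_annotated <- sum(lengths(targets_of) > 0)
  n_single_t <- sum(lengths(targets_of) == 1)
  report <- list(
    n_compounds = if (!is.null(compounds)) length(compounds) else NA_integer_,
    n_series = n_series,
    n_compounds_in_series = n_in_series,
    n_singletons = length(seriesSet@singletons),
    series_size_min = if (n_series) min(sizes) else 0L,
    series_size_max = if (n_series) max(sizes) else 0L,
    series_size_mean = if (n_series) .round1(mean(sizes)) else 0,
    mean_substitution_sites = if (any(ok)) .round1(mean(nsites[ok])) else 0,
    categories = list(
      all = cat_stats(rep(TRUE, n_series)),
      single_site_first = cat_stats(cat_of == "single_site_first"),
      single_site_second = cat_stats(cat_of == "single_site_second"),
      multi_site = cat_stats(cat_of == "multi_site")),
    n_scaffolds = sum(ok),
    n_first_generation = sum(ok & gener == "first"),
    n_second_generation = sum(ok & gener == "second"),
    n_compounds_covered = sum(sizes[ok]),
    pct_series_covered = pctOf(sum(ok), n_series),
    pct_compounds_covered = pctOf(sum(sizes[ok]), n_in_series),
    n_targets = length(unique(unlist(targets_of, use.names = FALSE))),
    n_annotated_series = n_annotated,
    n_single_target_series = n_single_t,
    n_multi_target_series = n_annotated - n_single_t,
    exclusions = c(
      ambiguous_mapping = sum(status == "ambiguous_mapping"),
      multi_scaffold_required = sum(status == "multi_scaffold_required")))
  class(report) <- "ASBStatsReport"
  report
}

#' @export
print.ASBStatsReport <- function(x, ...) {
  fmt <- function(n, p) sprintf("%d (%.1f%%)", n, p)
  cat("Analog series statistics\n")
  cat(sprintf("  compounds (distinct):        %s\n",
              ifelse(is.na(x$n_compounds), "-", x$n_compounds)))
  cat(sprintf("  series:                      %d\n", x$n_series))
  cat(sprintf("  compounds in series:         %d  (singletons: %d)\n",
              x$n_compounds_in_series, x$n_singletons))
  cat(sprintf("  series size:                 %d-%d (mean %.1f)\n",
              x$series_size_min, x$series_size_max, x$series_size_mean))
  cat("  category                  series          compounds     mean sites\n")
  for (nm in c("single_site_first", "single_site_second", "multi_site")) {
    cs <- x$categories[[nm]]
    cat(sprintf("  %-24s  %-14s  %-12s  %.1f\n", nm,
                fmt(cs$n_series, cs$pct_series),
                fmt(cs$n_compounds, cs$pct_compounds), cs$mean_sites))
  }
  cat(sprintf("  ASB scaffolds:               %d (first gen: %d, second gen: %d)\n",
              x$n_scaffolds, x$n_first_generation, x$n_second_generation))
  cat(sprintf("  series coverage:             %.1f%%\n", x$pct_series_covered))
  cat(sprintf("  compound coverage:           %.1f%%\n", x$pct_compounds_covered))
  cat(sprintf("  targets:                     %d\n", x$n_targets))
  cat(sprintf("  single-/multi-target series: %d / %d\n",
              x$n_single_target_series, x$n_multi_target_series))
  if (sum(x$exclusions) > 0)
    cat(sprintf("  excluded: %d ambiguous_mapping, %d multi_scaffold_required\n",
                x$exclusions[["ambiguous_mapping"]],
                x$exclusions[["multi_scaffold_required"]]))
  invisible(x)
}
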