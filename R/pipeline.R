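# One-call pipeline: standardize -> fragment -> RMMP network -> series ->
# scaffolds -> statistics, with optional artifact output.

#' Run the full analog-series / ASB-scaffold pipeline
#'
#' Standardizes and de-duplicates the input compounds, enumerates
#' retrosynthetic single-cut fragmentations, builds the RMMP network,
#' extracts analog series as its disjoint clusters, derives one ASB
#' scaffold (or reasoned exclusion) per series, and computes the summary
#' statistics. Deterministic: two runs on identical inputs produce
#' identical artifacts.
#'
#' @param input a path to a SMILES file, a data.frame with columns
#'   \code{id, smiles}, or a \linkS4class{CompoundSet}.
#' @param activity optional activity table (path to CSV or data.frame with
#'   \code{compound_id, target_id}).
#' @param restriction a \linkS4class{SizeRestriction}.
#' @param rules retrosynthetic rule subset (default: all).
#' @param keepStereo,neutralize standardization flags (see
#'   \code{\link{standardizeSmiles}}).
#' @param outDir optional output directory for the artifact files
#'   (fragments.tsv, edges.tsv, series.json, scaffolds.tsv, rgroups/,
#'   stats.json, singletons.txt).
#' @param verbose log stage counts via \code{message}.
#' @return invisible list with elements \code{compounds, cuts, rmmps,
#'   seriesSet, scaffolds, stats}.
#' @examples
#' bm <- generateBenchmark(nSeries = 1, sitesDistribution = c("1" = 1),
#'                         nDecoys = 1, seed = 1)
#' res <- runPipeline(bm$compounds, activity = bm$activity, verbose = FALSE)
#' res$stats$n_series
#' @export
runPipeline <- function(input, activity = NULL,
                        restriction = sizeRestriction(),
                        rules = recapRuleNames(),
                        keepStereo = TRUE, neutralize = TRUE,
                        outDir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  if (is.character(input) && length(input) == 1) input <- readSmilesFile(input)
  if (is(input, "CompoundSet")) {
    compounds <- input
    n_raw <- length(input)
  } else {
    stopifnot(is.data.frame(input), all(c("id", "smiles") %in% names(input)))
    n_raw <- nrow(input)
    compounds <- compoundSet(input$smiles, input$id,
                             keepStereo = keepStereo, neutralize = neutralize)
  }
  if (is.character(activity)) activity <- readActivityCsv(activity)
  if (!is.null(activity)) compounds <- setCompoundTargets(compounds, activity)
  say("compounds: ", n_raw, " read, ", length(compounds),
      " after duplicate merging")
  cuts <- enumerateCuts(compounds, rules = rules)
  say("fragmentations: ", nrow(cuts), " records, ",
      length(unique(cuts$core)), " distinct cores")
  rmmps <- enumerateRMMPs(cuts, restriction)
  say("RMMPs: ", nrow(rmmps))
  seriesSet <- extractSeries(rmmps, compounds)
  seriesSet <- annotateSeries(seriesSet, compounds)
  say("analog series: ", length(seriesSet), "; singletons: ",
      length(seriesSingletons(seriesSet)))
  scaffolds <- deriveScaffolds(seriesSet, compounds, cuts)
  status <- vapply(scaffolds, function(s) s@status, character(1))
  gen <- vapply(scaffolds, function(s) s@generation, character(1))
  say("scaffolds: ", sum(status == "ok"), " (first generation: ",
      sum(status == "ok" & gen == "first"), ", second generation: ",
      sum(status == "ok" & gen == "second"), "); excluded: ",
      sum(status != "ok"))
  stats <- summarizeSeries(seriesSet, scaffolds, compounds)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeFragmentsTsv(cuts, file.path(outDir, "fragments.tsv"))
    writeEdgesTsv(rmmps, file.path(outDir, "edges.tsv"))
    writeSeriesJson(seriesSet, compounds, file.path(outDir, "series.json"))
    writeScaffoldsTsv(scaffolds, file.path(outDir, "scaffolds.tsv"))
    writeRGroupTables(scaffolds, file.path(outDir, "rgroups"))
    writeLines(seriesSingletons(seriesSet),
               file.path(outDir, "singletons.txt"))
    jsonlite::write_json(unclass(stats), file.path(outDir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("artifacts written to ", outDir)
  }
  invisible(list(compounds = compounds, cuts = cuts, rmmps = rmmps,
                 seriesSet = seriesSet, scaffolds = scaffolds,
                 stats = stats))
}
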