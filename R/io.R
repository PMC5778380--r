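# File formats: SMILES files (.smi), activity CSV, and the TSV/JSON
# artifacts of a pipeline run.

#' Read a SMILES file
#'
#' One record per line: structure, whitespace, identifier (an identifier is
#' generated from the line number when absent). Lines starting with
#' \code{#} and blank lines are ignored. Unparsable structures raise an
#' error naming the offending line.
#'
#' @param path file path.
#' @return data.frame with columns \code{id, smiles} (raw, not yet
#'   standardized).
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep))
    return(data.frame(id = character(0), smiles = character(0)))
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  smiles <- vapply(fields, `[`, character(1), 1L)
  id <- vapply(seq_along(fields), function(i) {
    if (length(fields[[i]]) >= 2) fields[[i]][2] else sprintf("L%d", keep[i])
  }, character(1))
  bad <- which(!isValidSmiles(smiles))
  if (length(bad))
    stop("unparsable SMILES at line ", keep[bad[1]], ": '",
         smiles[bad[1]], "'")
  if (anyDuplicated(id))
    stop("duplicate identifiers in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  data.frame(id = id, smiles = smiles)
}

#' Write a SMILES file
#'
#' @param x data.frame with columns \code{id, smiles}.
#' @param path file path.
#' @export
writeSmilesFile <- function(x, path) {
  writeLines(paste(x$smiles, x$id), path)
  invisible(path)
}

#' Read an activity table
#'
#' CSV with header \code{compound_id,target_id}, one row per
#' compound-target pair.
#'
#' @param path file path.
#' @return data.frame with the two columns as character.
#' @export
readActivityCsv <- function(path) {
  act <- utils::read.csv(path, colClasses = "character")
  if (!all(c("compound_id", "target_id") %in% names(act)))
    stop("activity CSV needs columns compound_id,target_id")
  act[, c("compound_id", "target_id")]
}

#' Write pipeline artifacts
#'
#' @param cuts fragmentation records from \code{\link{enumerateCuts}}.
#' @param path output TSV path.
#' @export
writeFragmentsTsv <- function(cuts, path) {
  tab <- cuts[, c("parent_id", "rule", "core", "substituent")]
  names(tab)[2] <- "rule_id"
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFragmentsTsv
#' @param rmmps RMMP records from \code{\link{enumerateRMMPs}}.
#' @export
writeEdgesTsv <- function(rmmps, path) {
  edges <- unique(rmmps[, c("compound_a", "compound_b")])
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize analog series to JSON
#'
#' Stores members, member structures, RMMP edges, qualifying cores and the
#' MMS decomposition of every series, plus the singleton audit, so that
#' downstream stages can run from the file alone.
#'
#' @param seriesSet an \linkS4class{AnalogSeriesSet}.
#' @param compounds a \linkS4class{CompoundSet} (for member structures).
#' @param path output path.
#' @export
writeSeriesJson <- function(seriesSet, compounds, path) {
  smi <- structures(compounds)
  payload <- list(
    series = lapply(seriesSet@series, function(s) list(
      id = s@id,
      members = s@members,
      structures = as.list(smi[s@members]),
      targets = s@targets,
      cores = s@cores,
      rmmps = s@rmmps,
      mms = lapply(decomposeMMS(s), function(m)
        list(core = m$core, members = names(m$subs),
             substituents = unname(m$subs))))),
    singletons = seriesSet@singletons)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read analog series back from JSON
#'
#' @param path path written by \code{\link{writeSeriesJson}}.
#' @return list with \code{seriesSet} (\linkS4class{AnalogSeriesSet}) and
#'   \code{structures} (named character vector).
#' @export
readSeriesJson <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  structures <- character(0)
  series <- vector("list", length(payload$series))
  for (k in seq_along(payload$series)) {
    rec <- payload$series[[k]]
    rmmps <- do.call(rbind, lapply(rec$rmmps, function(r)
      data.frame(core = r$core, compound_a = r$compound_a,
                 compound_b = r$compound_b, sub_a = r$sub_a,
                 sub_b = r$sub_b, core_ha = as.integer(r$core_ha),
                 sub_a_ha = as.integer(r$sub_a_ha),
                 sub_b_ha = as.integer(r$sub_b_ha))))
    series[[k]] <- new("AnalogSeries", id = rec$id,
                       members = unlist(rec$members),
                       rmmps = rmmps,
                       cores = unlist(rec$cores),
                       targets = as.character(unlist(rec$targets)))
    structures <- c(structures, unlist(rec$structures))
  }
  list(seriesSet = new("AnalogSeriesSet", series = series,
                       singletons = as.character(unlist(payload$singletons))),
       structures = structures[!duplicated(names(structures))])
}

#' Write the scaffold table
#'
#' One row per series: scaffold structure, site count, generation, member
#' count, target annotation and status (accepted or exclusion reason).
#'
#' @param scaffolds list of \linkS4class{ASBScaffold}.
#' @param path output TSV path.
#' @export
writeScaffoldsTsv <- function(scaffolds, path) {
  tab <- scaffoldTable(scaffolds)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate scaffold results
#'
#' @param scaffolds list of \linkS4class{ASBScaffold}.
#' @return data.frame with one row per series.
#' @export
scaffoldTable <- function(scaffolds) {
  data.frame(
    series_id = vapply(scaffolds, function(s) s@seriesId, character(1)),
    scaffold = vapply(scaffolds, function(s) s@structure, character(1)),
    n_sites = vapply(scaffolds, function(s) s@nSites, integer(1)),
    generation = vapply(scaffolds, function(s) s@generation, character(1)),
    member_count = vapply(scaffolds, function(s) length(s@members), integer(1)),
    n_targets = vapply(scaffolds, function(s) length(s@targets), integer(1)),
    targets = vapply(scaffolds, function(s)
      paste(s@targets, collapse = ";"), character(1)),
    status = vapply(scaffolds, function(s) s@status, character(1)))
}

#' Write per-series R-group tables
#'
#' @param scaffolds list of \linkS4class{ASBScaffold}.
#' @param dir output directory (one TSV per accepted scaffold).
#' @export
writeRGroupTables <- function(scaffolds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in scaffolds) {
    if (s@status != "ok") next
    tab <- cbind(compound_id = rownames(s@rgroups), s@rgroups)
    utils::write.table(tab, file.path(dir, paste0(s@seriesId, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
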