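#' @import methods
#' @exportMethod show
NULL

#' SizeRestriction: substituent size limits for RMMP generation
#'
#' Exchanged substituents of a matched molecular pair are restricted to the
#' modification sizes typically seen within analog series: the shared core
#' must be at least \code{coreToSubRatio} times as large (in heavy atoms) as
#' the larger exchanged substituent, no substituent may exceed
#' \code{maxSubHeavy} heavy atoms, and the two exchanged substituents may
#' differ by at most \code{maxDiffHeavy} heavy atoms.
#'
#' @slot coreToSubRatio numeric(1), minimum core/substituent heavy-atom ratio.
#' @slot maxSubHeavy numeric(1), maximum substituent heavy atoms.
#' @slot maxDiffHeavy numeric(1), maximum heavy-atom difference between the
#'   exchanged substituents.
#' @aliases SizeRestriction
#' @exportClass SizeRestriction
setClass("SizeRestriction", representation(
  coreToSubRatio = "numeric",
  maxSubHeavy = "numeric",
  maxDiffHeavy = "numeric"
))

setValidity("SizeRestriction", function(object) {
  v <- c(object@coreToSubRatio, object@maxSubHeavy, object@maxDiffHeavy)
  if (length(v) != 3 || any(!is.finite(v)) || any(v <= 0))
    return("all three size-restriction values must be strictly positive")
  TRUE
})

#' Construct a SizeRestriction
#'
#' Defaults follow the transformation-size-restriction convention used for
#' analog-series extraction; all three values are configurable.
#'
#' @param coreToSubRatio minimum core-to-substituent heavy-atom ratio.
#' @param maxSubHeavy maximum heavy atoms per exchanged substituent.
#' @param maxDiffHeavy maximum heavy-atom difference between exchanged
#'   substituents.
#' @return a \linkS4class{SizeRestriction} object.
#' @examples
#' sizeRestriction()
#' sizeRestriction(coreToSubRatio = 1.5)
#' @export
sizeRestriction <- function(coreToSubRatio = 2, maxSubHeavy = 13,
                            maxDiffHeavy = 8) {
  new("SizeRestriction", coreToSubRatio = as.numeric(coreToSubRatio),
      maxSubHeavy = as.numeric(maxSubHeavy),
      maxDiffHeavy = as.numeric(maxDiffHeavy))
}

setMethod("show", "SizeRestriction", function(object) {
  cat("SizeRestriction: core >= ", object@coreToSubRatio,
      " x max(sub), sub <= ", object@maxSubHeavy,
      " heavy atoms, |diff| <= ", object@maxDiffHeavy, "\n", sep = "")
})

#' CompoundSet: standardized, de-duplicated compounds
#'
#' Container for a set of small molecules with opaque identifiers, canonical
#' structures, heavy-atom counts and (possibly empty) target annotation
#' sets. Construction standardizes each structure (largest organic
#' component, charge neutralization where a neutral form exists, optional
#' stereo stripping) and merges duplicates: compounds with identical
#' canonical structure become one record whose ids are recorded as aliases
#' and whose target sets are unioned.
#'
#' @slot id character, primary identifier per compound.
#' @slot structure character, canonical SMILES per compound.
#' @slot heavyAtoms integer, non-hydrogen atom counts.
#' @slot targets list of character vectors, target ids per compound.
#' @slot aliases list of character vectors, all input ids merged into each
#'   record (including the primary id).
#' @aliases CompoundSet
#' @exportClass CompoundSet
setClass("CompoundSet", representation(
  id = "character",
  structure = "character",
  heavyAtoms = "integer",
  targets = "list",
  aliases = "list"
))

setValidity("CompoundSet", function(object) {
  n <- length(object@id)
  if (length(object@structure) != n || length(object@heavyAtoms) != n ||
      length(object@targets) != n || length(object@aliases) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@id)) return("duplicate compound ids")
  if (anyDuplicated(object@structure)) return("duplicate canonical structures")
  if (n > 0 && any(object@heavyAtoms < 1)) return("heavyAtoms must be >= 1")
  TRUE
})

#' @describeIn CompoundSet number of (distinct) compounds.
#' @param x a CompoundSet.
#' @export
setMethod("length", "CompoundSet", function(x) length(x@id))

#' Compound identifiers
#' @param object a \linkS4class{CompoundSet}.
#' @return character vector of primary ids.
#' @export
compoundIds <- function(object) object@id

#' Canonical structures
#' @param object a \linkS4class{CompoundSet}.
#' @return character vector of canonical SMILES.
#' @export
structures <- function(object) stats::setNames(object@structure, object@id)

#' Target annotations per compound
#' @param object a \linkS4class{CompoundSet}.
#' @return named list of character vectors.
#' @export
compoundTargets <- function(object) stats::setNames(object@targets, object@id)

setMethod("show", "CompoundSet", function(object) {
  cat("CompoundSet with ", length(object), " compounds\n", sep = "")
  n_ann <- sum(lengths(object@targets) > 0)
  cat("  annotated: ", n_ann, "; heavy atoms: ",
      if (length(object)) paste0(min(object@heavyAtoms), "-",
                                 max(object@heavyAtoms)) else "-", "\n",
      sep = "")
  if (length(object)) {
    k <- min(3L, length(object))
    for (i in seq_len(k))
      cat("  ", object@id[i], "  ", object@structure[i], "\n", sep = "")
    if (length(object) > k) cat("  ...\n")
  }
})

#' AnalogSeries: one connected component of the RMMP network
#'
#' @slot id series identifier.
#' @slot members character, ids of the member compounds (>= 2).
#' @slot rmmps data.frame of the RMMP relationships among members (columns
#'   \code{core, compound_a, compound_b, sub_a, sub_b, core_ha, sub_a_ha,
#'   sub_b_ha}).
#' @slot cores character, all qualifying RMMP cores of the series.
#' @slot targets character, union of member target annotations (filled by
#'   \code{\link{annotateSeries}}).
#' @aliases AnalogSeries
#' @exportClass AnalogSeries
setClass("AnalogSeries", representation(
  id = "character",
  members = "character",
  rmmps = "data.frame",
  cores = "character",
  targets = "character"
))

setValidity("AnalogSeries", function(object) {
  if (length(object@members) < 2) return("an analog series needs >= 2 members")
  edge_ids <- unique(c(object@rmmps$compound_a, object@rmmps$compound_b))
  if (!setequal(edge_ids, object@members))
    return("RMMP endpoints do not match the member set")
  TRUE
})

#' @describeIn AnalogSeries number of member compounds.
#' @param x an AnalogSeries.
#' @export
setMethod("length", "AnalogSeries", function(x) length(x@members))

#' Series members
#' @param object an \linkS4class{AnalogSeries}.
#' @return character vector of member compound ids.
#' @export
seriesMembers <- function(object) object@members

#' Qualifying RMMP cores of a series
#' @param object an \linkS4class{AnalogSeries}.
#' @return character vector of core fragment SMILES.
#' @export
seriesCores <- function(object) object@cores

setMethod("show", "AnalogSeries", function(object) {
  cat("AnalogSeries ", object@id, ": ", length(object@members),
      " members, ", nrow(object@rmmps), " RMMPs, ",
      length(object@cores), " cores\n", sep = "")
})

#' AnalogSeriesSet: all analog series of a compound set
#'
#' The disjoint clusters of the RMMP network, plus the compounds that
#' participate in no RMMP (singletons, kept for coverage denominators).
#'
#' @slot series list of \linkS4class{AnalogSeries}.
#' @slot singletons character, ids of compounds outside every series.
#' @aliases AnalogSeriesSet
#' @exportClass AnalogSeriesSet
setClass("AnalogSeriesSet", representation(
  series = "list",
  singletons = "character"
))

#' @describeIn AnalogSeriesSet number of series.
#' @param x an AnalogSeriesSet.
#' @export
setMethod("length", "AnalogSeriesSet", function(x) length(x@series))

#' @describeIn AnalogSeriesSet extract one series.
#' @param i index.
#' @export
setMethod("[[", "AnalogSeriesSet", function(x, i) x@series[[i]])

#' Singleton compounds (no RMMP partner)
#' @param object an \linkS4class{AnalogSeriesSet}.
#' @return character vector of compound ids.
#' @export
seriesSingletons <- function(object) object@singletons

setMethod("show", "AnalogSeriesSet", function(object) {
  sizes <- vapply(object@series, length, integer(1))
  cat("AnalogSeriesSet: ", length(object), " series (sizes ",
      if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-",
      "), ", length(object@singletons), " singletons\n", sep = "")
})

#' ASBScaffold: the unique scaffold of an analog series
#'
#' One scaffold (or a reasoned exclusion) per analog series. Accepted
#' scaffolds carry numbered attachment points \code{[1*]..[n*]}, a
#' generation tag (\code{"first"} when the series had a unique qualifying
#' core before redundant-core reduction, otherwise \code{"second"}), and
#' the R-group table whose rows regenerate every member exactly.
#'
#' @slot seriesId series identifier.
#' @slot structure canonical scaffold SMILES with numbered attachment
#'   points, or \code{NA} for excluded series.
#' @slot nSites integer, number of substitution sites (0 when excluded).
#' @slot generation \code{"first"} or \code{"second"} (\code{NA} when
#'   excluded).
#' @slot status \code{"ok"}, \code{"ambiguous_mapping"} or
#'   \code{"multi_scaffold_required"}.
#' @slot members character, member compound ids.
#' @slot rgroups data.frame, one row per member, one column per site
#'   (\code{R1..Rn}; hydrogen sentinel \code{"H"}).
#' @slot targets character, target annotations inherited from the series.
#' @aliases ASBScaffold
#' @exportClass ASBScaffold
setClass("ASBScaffold", representation(
  seriesId = "character",
  structure = "character",
  nSites = "integer",
  generation = "character",
  status = "character",
  members = "character",
  rgroups = "data.frame",
  targets = "character"
))

setValidity("ASBScaffold", function(object) {
  if (!object@status %in% c("ok", "ambiguous_mapping", "multi_scaffold_required"))
    return("unknown status")
  if (object@status == "ok") {
    if (is.na(object@structure)) return("accepted scaffold needs a structure")
    if (object@nSites < 1) return("accepted scaffold needs >= 1 site")
  }
  TRUE
})

#' Scaffold structure
#' @param object an \linkS4class{ASBScaffold}.
#' @return canonical scaffold SMILES (or NA when the series was excluded).
#' @export
scaffoldStructure <- function(object) object@structure

#' Number of substitution sites
#' @param object an \linkS4class{ASBScaffold}.
#' @return integer.
#' @export
scaffoldSites <- function(object) object@nSites

#' Scaffold generation tag
#' @param object an \linkS4class{ASBScaffold}.
#' @return \code{"first"} or \code{"second"}.
#' @export
scaffoldGeneration <- function(object) object@generation

#' R-group table of a scaffold
#' @param object an \linkS4class{ASBScaffold}.
#' @return data.frame, members x sites; hydrogen sentinel \code{"H"}.
#' @export
rGroupTable <- function(object) object@rgroups

setMethod("show", "ASBScaffold", function(object) {
  if (object@status == "ok") {
    cat("ASBScaffold [", object@seriesId, "] ", object@structure,
        "\n  sites: ", object@nSites, "; generation: ", object@generation,
        "; members: ", length(object@members),
        if (length(object@targets)) paste0("; targets: ",
                                           paste(object@targets, collapse = ";"))
        else "", "\n", sep = "")
  } else {
    cat("ASBScaffold [", object@seriesId, "] excluded: ", object@status,
        " (", length(object@members), " members)\n", sep = "")
  }
})
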