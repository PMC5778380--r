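# Core indexing, RMMP enumeration, the compound network and its disjoint
# clusters (analog series), and the decomposition of a series into matching
# molecular series (MMSs).

#' Index fragmentations by shared core
#'
#' Groups single-cut fragmentation records by canonical core so that
#' compounds sharing a core can be paired into RMMPs. Within a core, each
#' parent contributes one entry (symmetric duplicate cuts are collapsed
#' deterministically).
#'
#' @param cuts data.frame from \code{\link{enumerateCuts}}.
#' @return named list (by core SMILES) of data.frames with columns
#'   \code{parent_id, substituent, sub_ha, core_ha, core_atom, sub_atom}.
#' @export
indexCores <- function(cuts) {
  if (nrow(cuts) == 0) return(structure(list(), names = character(0)))
  cuts <- cuts[order(cuts$core, cuts$parent_id, cuts$substituent,
                     cuts$core_atom), ]
  cuts <- cuts[!duplicated(cuts[, c("core", "parent_id")]), ]
  split(cuts[, c("parent_id", "substituent", "sub_ha", "core_ha",
                 "core_atom", "sub_atom")],
        cuts$core)
}

#' Enumerate retrosynthetic matched molecular pairs (RMMPs)
#'
#' An RMMP is an unordered pair of distinct compounds that share a
#' retrosynthetic single-cut core and differ by one exchanged substituent
#' pair passing the size restrictions. One row is emitted per compound pair
#' per shared core, in deterministic order.
#'
#' @param cuts data.frame from \code{\link{enumerateCuts}}, or a core index
#'   from \code{\link{indexCores}}.
#' @param restriction a \linkS4class{SizeRestriction}.
#' @return data.frame with columns \code{core, compound_a, compound_b,
#'   sub_a, sub_b, core_ha, sub_a_ha, sub_b_ha}.
#' @export
enumerateRMMPs <- function(cuts, restriction = sizeRestriction()) {
  index <- if (is.data.frame(cuts)) indexCores(cuts) else cuts
  empty <- data.frame(core = character(0), compound_a = character(0),
                      compound_b = character(0), sub_a = character(0),
                      sub_b = character(0), core_ha = integer(0),
                      sub_a_ha = integer(0), sub_b_ha = integer(0))
  if (!length(index)) return(empty)
  out <- list()
  for (core in sort(names(index))) {
    tab <- index[[core]]
    if (nrow(tab) < 2) next
    tab <- tab[order(tab$parent_id), ]
    pairs <- utils::combn(nrow(tab), 2)
    ia <- pairs[1, ]; ib <- pairs[2, ]
    keep <- tab$substituent[ia] != tab$substituent[ib] &
      passesSizeRestriction(tab$core_ha[ia], tab$sub_ha[ia], tab$sub_ha[ib],
                            restriction)
    if (!any(keep)) next
    out[[core]] <- data.frame(
      core = core,
      compound_a = tab$parent_id[ia[keep]],
      compound_b = tab$parent_id[ib[keep]],
      sub_a = tab$substituent[ia[keep]],
      sub_b = tab$substituent[ib[keep]],
      core_ha = tab$core_ha[ia[keep]],
      sub_a_ha = tab$sub_ha[ia[keep]],
      sub_b_ha = tab$sub_ha[ib[keep]])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$core, res$compound_a, res$compound_b), ]
  rownames(res) <- NULL
  res
}

#' Extract analog series from the RMMP network
#'
#' Builds the network whose nodes are compounds and whose edges are pairwise
#' RMMP relationships; each disjoint cluster (connected component) is one
#' analog series. Compounds participating in no RMMP are reported as
#' singletons when the full compound set is supplied.
#'
#' @param rmmps data.frame from \code{\link{enumerateRMMPs}}.
#' @param compounds optional \linkS4class{CompoundSet} (for the singleton
#'   audit and target annotation denominators).
#' @return an \linkS4class{AnalogSeriesSet}.
#' @export
extractSeries <- function(rmmps, compounds = NULL) {
  all_ids <- if (!is.null(compounds)) compoundIds(compounds) else character(0)
  if (nrow(rmmps) == 0)
    return(new("AnalogSeriesSet", series = list(), singletons = sort(all_ids)))
  ids <- sort(unique(c(rmmps$compound_a, rmmps$compound_b)))
  g <- igraph::graph_from_data_frame(
    unique(rmmps[, c("compound_a", "compound_b")]),
    directed = FALSE, vertices = ids)
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  # deterministic series order: by smallest member id
  groups <- groups[order(vapply(groups, min, character(1)))]
  series <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    members <- sort(groups[[k]])
    sel <- rmmps$compound_a %in% members
    sub <- rmmps[sel, , drop = FALSE]
    rownames(sub) <- NULL
    series[[k]] <- new("AnalogSeries",
                       id = sprintf("AS%04d", k),
                       members = members,
                       rmmps = sub,
                       cores = sort(unique(sub$core)),
                       targets = character(0))
  }
  singletons <- sort(setdiff(all_ids, unlist(groups, use.names = FALSE)))
  new("AnalogSeriesSet", series = series, singletons = singletons)
}

#' Decompose an analog series into matching molecular series
#'
#' A matching molecular series (MMS) is the set of two or more analogs that
#' share one RMMP core and are distinguished only at that core's single
#' substitution site. An analog series may consist of several MMSs; each
#' MMS here is the union of the endpoints of the size-restriction-passing
#' RMMPs on one core of the series.
#'
#' @param series an \linkS4class{AnalogSeries}.
#' @return list of MMSs, each a list with elements \code{core} (fragment
#'   SMILES) and \code{subs} (named character vector, member id ->
#'   substituent fragment).
#' @export
decomposeMMS <- function(series) {
  stopifnot(is(series, "AnalogSeries"))
  rm <- series@rmmps
  out <- list()
  for (core in sort(unique(rm$core))) {
    rows <- rm[rm$core == core, , drop = FALSE]
    subs <- c(stats::setNames(rows$sub_a, rows$compound_a),
              stats::setNames(rows$sub_b, rows$compound_b))
    subs <- subs[!duplicated(names(subs))]
    subs <- subs[order(names(subs))]
    if (length(subs) >= 2)
      out[[length(out) + 1L]] <- list(core = core, subs = subs)
  }
  out
}
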