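# Compound standardization on ingest: keep the largest organic component,
# neutralize charges where a neutral form exists, optionally strip stereo.

.neutralize_graph <- function(mol) {
  ch <- mol$atoms$charge
  if (!any(ch != 0L)) return(NULL)
  elem <- mol$atoms$elem
  changed <- FALSE
  for (i in which(ch != 0L)) {
    nb <- mol$nbr[[i]]
    # leave zwitterionic pairs (e.g. nitro, N-oxides) untouched
    if (length(nb) && any(ch[nb] * ch[i] < 0)) next
    bond_sum <- sum(mol$bonds$order[mol$nbrbond[[i]]])
    if (ch[i] == -1L && elem[i] %in% c("O", "S", "N")) {
      ch[i] <- 0L; changed <- TRUE                # anion -> protonated form
    } else if (ch[i] == 1L && elem[i] == "N" && bond_sum < 4 &&
               !mol$atoms$arom[i]) {
      ch[i] <- 0L; changed <- TRUE                # ammonium -> free amine
    }
  }
  if (!changed) return(NULL)
  mol$atoms$charge <- ch
  mol
}

#' Standardize SMILES for analog-series analysis
#'
#' Applies the ingest standardization: keep the largest organic component
#' (salt/solvent stripping), neutralize charges where a neutral form exists
#' (carboxylates, phenolates, protonated amines; zwitterionic groups such as
#' nitro are left intact), optionally strip stereochemistry, and
#' canonicalize.
#'
#' @param smiles character vector of SMILES.
#' @param keepStereo keep stereo descriptors (default TRUE). Fragmentation
#'   and scaffold derivation operate on constitution regardless; this flag
#'   governs the stored canonical structures and hence duplicate merging.
#' @param neutralize neutralize charges where possible (default TRUE).
#' @return character vector of standardized canonical SMILES.
#' @examples
#' standardizeSmiles("CC(=O)[O-].[Na+]")  # -> "CC(=O)O"
#' @export
standardizeSmiles <- function(smiles, keepStereo = TRUE, neutralize = TRUE) {
  vapply(as.character(smiles), function(s) {
    if (!keepStereo) s <- gsub("@", "", gsub("[/\\\\]", "-", s), fixed = FALSE)
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(parts) > 1) {
      ha <- heavyAtomCount(parts)
      organic <- grepl("C|c", parts)
      cand <- if (any(organic)) which(organic) else seq_along(parts)
      s <- parts[cand[order(-ha[cand], parts[cand])][1]]
    }
    s <- canonicalizeSmiles(s)
    if (neutralize) {
      m2 <- .neutralize_graph(.parse_mol(s))
      if (!is.null(m2)) s <- .graph_smiles(m2)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Build a CompoundSet from structures and identifiers
#'
#' Standardizes every structure and merges duplicates: records with the same
#' canonical structure become one compound whose primary id is the first in
#' sorted order, with all input ids kept as aliases and target sets unioned.
#' Duplicate merging is what makes a matched molecular pair a pair of two
#' distinct compounds.
#'
#' @param structure character vector of SMILES.
#' @param id character vector of identifiers (default \code{CPD1..n}).
#' @param targets optional named list (by id) of target id vectors, or an
#'   activity data.frame with columns \code{compound_id, target_id}.
#' @param keepStereo,neutralize passed to \code{\link{standardizeSmiles}}.
#' @return a \linkS4class{CompoundSet}.
#' @examples
#' cs <- compoundSet(c("CC(=O)Nc1ccccc1", "O=C(C)Nc1ccccc1"), c("a", "b"))
#' length(cs)  # 1: the two records are the same compound
#' @export
compoundSet <- function(structure, id = NULL, targets = NULL,
                        keepStereo = TRUE, neutralize = TRUE) {
  structure <- as.character(structure)
  if (is.null(id)) id <- sprintf("CPD%d", seq_along(structure))
  id <- as.character(id)
  stopifnot(length(id) == length(structure))
  if (anyDuplicated(id)) stop("duplicate compound identifiers in input")
  if (is.data.frame(targets)) {
    targets <- split(as.character(targets$target_id),
                     as.character(targets$compound_id))
  }
  std <- standardizeSmiles(structure, keepStereo = keepStereo,
                           neutralize = neutralize)
  ord <- order(id)
  id <- id[ord]; std <- std[ord]
  grp <- split(seq_along(std), std)
  keys <- sort(names(grp))
  rec_id <- character(0); rec_struct <- character(0)
  rec_targets <- list(); rec_aliases <- list()
  for (k in keys) {
    idx <- grp[[k]]
    ids_k <- id[idx]
    rec_id <- c(rec_id, ids_k[1])
    rec_struct <- c(rec_struct, k)
    rec_aliases[[length(rec_aliases) + 1L]] <- ids_k
    tg <- sort(unique(unlist(targets[ids_k], use.names = FALSE)))
    rec_targets[[length(rec_targets) + 1L]] <- if (is.null(tg)) character(0) else tg
  }
  ord2 <- order(rec_id)
  new("CompoundSet",
      id = rec_id[ord2],
      structure = rec_struct[ord2],
      heavyAtoms = heavyAtomCount(rec_struct[ord2]),
      targets = rec_targets[ord2],
      aliases = rec_aliases[ord2])
}

#' Attach target annotations to a CompoundSet
#'
#' @param object a \linkS4class{CompoundSet}.
#' @param activity data.frame with columns \code{compound_id, target_id};
#'   ids matching any alias of a compound are accepted, unknown ids are
#'   skipped with a message.
#' @return the CompoundSet with updated target slots.
#' @export
setCompoundTargets <- function(object, activity) {
  stopifnot(all(c("compound_id", "target_id") %in% names(activity)))
  alias_map <- rep(seq_along(object@aliases), lengths(object@aliases))
  names(alias_map) <- unlist(object@aliases, use.names = FALSE)
  hit <- alias_map[as.character(activity$compound_id)]
  if (anyNA(hit)) {
    unknown <- unique(activity$compound_id[is.na(hit)])
    message("skipping ", length(unknown),
            " activity rows with unknown compound ids")
  }
  ok <- !is.na(hit)
  tg <- split(as.character(activity$target_id[ok]), hit[ok])
  for (k in names(tg))
    object@targets[[as.integer(k)]] <-
      sort(unique(c(object@targets[[as.integer(k)]], tg[[k]])))
  validObject(object)
  object
}
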