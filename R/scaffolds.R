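# Analog series-based (ASB) scaffold derivation: first-generation selection
# of the core shared by all analogs, second-generation redundant-core
# reduction, transfer of substitution sites to shared analogs, multi-site
# scaffold extraction with the decomposition test, R-group tables, and
# Bemis-Murcko scaffolds for comparison.

.structures_of <- function(compounds, ids = NULL) {
  smi <- if (is(compounds, "CompoundSet")) structures(compounds) else compounds
  if (is.null(names(smi))) stop("compound structures must be named by id")
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(smi))
    if (length(missing))
      stop("no structure for compound(s): ", paste(missing, collapse = ", "))
    smi <- smi[ids]
  }
  smi
}

#' Test whether one RMMP core is a structural extension of another
#'
#' \code{big} is a core extension of \code{small} when \code{big} equals
#' \code{small} with its attachment point replaced by a connected fragment
#' that carries \code{big}'s attachment point -- i.e. the smaller core is
#' anchored at the same substitution site inside the larger one. Extensions
#' are classified redundant during second-generation core reduction.
#'
#' @param big,small fragment SMILES, each with one attachment point.
#' @return logical(1). Identical cores are not extensions (strictness).
#' @examples
#' isCoreExtension("[1*]NCC(=O)Nc1ccc2ccccc2c1", "[1*]Nc1ccc2ccccc2c1")
#' @export
isCoreExtension <- function(big, small) {
  big <- canonicalizeSmiles(big); small <- canonicalizeSmiles(small)
  if (big == small) return(FALSE)
  bm <- .parse_mol(big)
  ha_small <- heavyAtomCount(small)
  if (sum(bm$atoms$elem != "*") <= ha_small) return(FALSE)
  d <- .dummy_atoms(bm)
  if (nrow(d) != 1) stop("cores must carry exactly one attachment point")
  sm_label <- .dummy_atoms(.parse_mol(small))$label[1]
  cand <- which(!bm$bonds$ring & bm$bonds$order == 1 &
                  bm$atoms$elem[bm$bonds$a1] != "*" &
                  bm$atoms$elem[bm$bonds$a2] != "*")
  blocks <- character(0)
  for (b in cand) {
    with_d <- .component_from(bm, d$id, blocked = b)
    i <- bm$bonds$a1[b]; j <- bm$bonds$a2[b]
    piece_at <- if (i %in% with_d) j else i
    piece <- .component_from(bm, piece_at, blocked = b)
    if (length(piece) != ha_small) next
    blocks <- c(blocks, .mol_block(bm, piece,
                                   data.frame(at = piece_at, label = sm_label)))
  }
  if (!length(blocks)) return(FALSE)
  any(.blocks_to_smiles(blocks) == small)
}

#' Reduce the cores of an analog series to nonredundant cores
#'
#' Removes every core that is a structural extension (directly or
#' transitively) of another core of the series, keeping the smallest
#' possible core per substitution site; the MMS memberships of removed
#' cores are merged into the retained cores they extend. The retained
#' (nonredundant) cores are pairwise non-extension-related and represent
#' second-generation single-site scaffolds.
#'
#' @param series an \linkS4class{AnalogSeries}.
#' @return list of nonredundant cores, each a list with \code{core}
#'   (fragment SMILES) and \code{members} (sorted member ids).
#' @export
reduceCores <- function(series) {
  mms <- decomposeMMS(series)
  if (!length(mms)) return(list())
  cores <- vapply(mms, function(m) m$core, character(1))
  members <- lapply(mms, function(m) sort(names(m$subs)))
  k <- length(cores)
  ha <- heavyAtomCount(cores)
  ext <- matrix(FALSE, k, k)  # ext[x, y]: core x is an extension of core y
  for (x in seq_len(k)) for (y in seq_len(k)) {
    if (x != y && ha[x] > ha[y]) ext[x, y] <- isCoreExtension(cores[x], cores[y])
  }
  retained <- which(!apply(ext, 1, any))
  out <- list()
  for (y in retained) {
    mem <- members[[y]]
    for (x in which(ext[, y])) mem <- union(mem, members[[x]])
    out[[length(out) + 1L]] <- list(core = cores[y], members = sort(mem))
  }
  out[order(vapply(out, function(z) z$core, character(1)))]
}

#' Transfer substitution sites of nonredundant cores onto the analogs
#'
#' For every analog matched by a nonredundant core, marks the bond between
#' the core's attachment-image atom and the substituent branch (in the
#' analog's canonical-structure atom numbering). Bonds marked by several
#' cores are de-duplicated; an analog matched by one core at several
#' non-equivalent positions (molecular symmetry with differing branches) is
#' flagged ambiguous.
#'
#' @param series an \linkS4class{AnalogSeries}.
#' @param cores list from \code{\link{reduceCores}}.
#' @param cuts fragmentation records of (at least) the series members.
#' @return list with \code{siteBonds}: named list (member id) of data.frames
#'   \code{(a, b)} -- scaffold-side and substituent-side atoms of each
#'   marked bond -- and \code{ambiguous}: character vector of flagged
#'   member ids.
#' @export
mapSites <- function(series, cores, cuts) {
  members <- series@members
  core_smi <- vapply(cores, function(z) z$core, character(1))
  site_bonds <- list()
  ambiguous <- character(0)
  for (m in members) {
    rows <- cuts[cuts$parent_id == m & cuts$core %in% core_smi, , drop = FALSE]
    marks <- data.frame(a = integer(0), b = integer(0))
    for (core in unique(rows$core)) {
      rr <- rows[rows$core == core, , drop = FALSE]
      rr <- rr[order(rr$core_atom, rr$sub_atom), , drop = FALSE]
      if (nrow(rr) > 1 && length(unique(rr$substituent)) > 1) {
        # the core fits this analog at structurally different positions
        ambiguous <- c(ambiguous, m)
        next
      }
      marks <- rbind(marks, data.frame(a = rr$core_atom[1], b = rr$sub_atom[1]))
    }
    key <- paste(pmin(marks$a, marks$b), pmax(marks$a, marks$b))
    marks <- marks[!duplicated(key), , drop = FALSE]
    marks <- marks[order(marks$a, marks$b), , drop = FALSE]
    rownames(marks) <- NULL
    site_bonds[[m]] <- marks
  }
  list(siteBonds = site_bonds, ambiguous = sort(unique(ambiguous)))
}

# split the atoms of mol by the cut bond set and identify the scaffold
# component: the one touching every cut bond at exactly one endpoint.
# Returns list(keep, attach (one scaffold-side atom per cut bond)) or NULL.
.scaffold_component <- function(mol, bond_ids, prefer_atom = NULL) {
  lab <- integer(mol$n)
  cl <- 0L
  for (s in seq_len(mol$n)) {
    if (lab[s] == 0L) {
      cl <- cl + 1L
      lab[.component_from(mol, s, blocked = bond_ids)] <- cl
    }
  }
  e1 <- mol$bonds$a1[bond_ids]; e2 <- mol$bonds$a2[bond_ids]
  cand <- which(vapply(seq_len(cl), function(cc)
    all(xor(lab[e1] == cc, lab[e2] == cc)), logical(1)))
  if (length(cand) > 1 && !is.null(prefer_atom))
    cand <- cand[cand == lab[prefer_atom]]
  if (length(cand) != 1) return(NULL)
  keep <- which(lab == cand)
  attach <- ifelse(lab[e1] == cand, e1, e2)
  list(keep = keep, attach = attach, lab = lab, comp = cand)
}

# H-capped variant of a multi-site scaffold: only sites in `sites` keep
# their attachment dummies
.capped_scaffold <- function(cand_mol, sites) {
  d <- .dummy_atoms(cand_mol)
  drop <- d$id[!d$label %in% sites]
  .graph_smiles(cand_mol, setdiff(seq_len(cand_mol$n), drop))
}

# try to decompose member structure `smi` as candidate scaffold + one
# substituent-or-hydrogen per site; returns named character vector
# (R1..Rn, "H" sentinel) or NULL
.decompose_member <- function(smi, cand_smi, n_sites, cap_cache = new.env()) {
  mol <- .parse_mol(smi)
  cand_mol <- .parse_mol(cand_smi)
  ha_target <- sum(cand_mol$atoms$elem != "*")
  rb <- .recap_bonds(mol)
  if (nrow(rb) == 0) return(NULL)
  key <- paste(pmin(rb$a1, rb$a2), pmax(rb$a1, rb$a2))
  bond_ids <- rb$bond[!duplicated(key)]
  capped <- function(sites) {
    k <- paste(sort(sites), collapse = ",")
    hit <- cap_cache[[k]]
    if (is.null(hit)) {
      hit <- .capped_scaffold(cand_mol, sites)
      assign(k, hit, envir = cap_cache)
    }
    hit
  }
  for (k in seq_len(min(n_sites, length(bond_ids)))) {
    cmb <- utils::combn(length(bond_ids), k)
    for (ci in seq_len(ncol(cmb))) {
      cut <- bond_ids[cmb[, ci]]
      sc <- .scaffold_component(mol, cut)
      scs <- if (is.null(sc)) {
        # a single cut leaves both components eligible; try each
        if (k == 1) {
          lapply(c(mol$bonds$a1[cut], mol$bonds$a2[cut]), function(at)
            .scaffold_component(mol, cut, prefer_atom = at))
        } else list()
      } else list(sc)
      for (sc1 in scs) {
        if (is.null(sc1) || length(sc1$keep) != ha_target) next
        # which sites do the k cut bonds realize? try all injections
        site_sets <- utils::combn(n_sites, k)
        for (si in seq_len(ncol(site_sets))) {
          sites <- site_sets[, si]
          target <- capped(sites)
          for (perm in .perms(k)) {
            lab <- sites[perm]
            got <- .graph_smiles(mol, sc1$keep,
                                 data.frame(at = sc1$attach, label = lab))
            if (got == target) {
              rg <- rep("H", n_sites)
              for (q in seq_len(k)) {
                bnd <- cut[q]
                sub_at <- setdiff(c(mol$bonds$a1[bnd], mol$bonds$a2[bnd]),
                                  sc1$keep)
                piece <- which(sc1$lab == sc1$lab[sub_at])
                rg[lab[q]] <- .graph_smiles(mol, piece,
                                            data.frame(at = sub_at,
                                                       label = lab[q]))
              }
              names(rg) <- sprintf("R%d", seq_len(n_sites))
              return(rg)
            }
          }
        }
      }
    }
  }
  NULL
}

#' Derive the unique ASB scaffold of an analog series
#'
#' Implements the two-generation selection. When redundant-core reduction
#' leaves exactly one nonredundant core and it is produced by a single cut
#' of every member, that core is the scaffold (single substitution site;
#' generation \code{"first"} when it was the unique qualifying core before
#' reduction, \code{"second"} otherwise). Otherwise the substitution sites
#' of all nonredundant cores are transferred onto the analogs; the
#' candidate scaffold is obtained by cutting all marked bonds on an analog
#' carrying the maximal number of distinct sites, and is accepted only if
#' all maximal analogs yield the identical candidate and every member
#' decomposes as candidate plus one substituent-or-hydrogen per site.
#' Series failing these tests are excluded with reason
#' \code{ambiguous_mapping} or \code{multi_scaffold_required} -- never more
#' than one scaffold per series.
#'
#' @param series an \linkS4class{AnalogSeries}.
#' @param compounds a \linkS4class{CompoundSet} or named character vector of
#'   canonical SMILES covering the members.
#' @param cuts optional precomputed \code{\link{enumerateCuts}} records.
#' @return an \linkS4class{ASBScaffold} (status \code{"ok"} or a reasoned
#'   exclusion).
#' @export
deriveScaffold <- function(series, compounds, cuts = NULL) {
  smi <- .structures_of(compounds, series@members)
  if (is.null(cuts)) cuts <- enumerateCuts(smi)
  mcuts <- cuts[cuts$parent_id %in% series@members, , drop = FALSE]
  nr <- reduceCores(series)
  generation <- if (length(series@cores) == 1) "first" else "second"
  excluded <- function(reason) new(
    "ASBScaffold", seriesId = series@id, structure = NA_character_,
    nSites = 0L, generation = NA_character_, status = reason,
    members = series@members, rgroups = data.frame(), targets = series@targets)

  if (length(nr) == 1) {
    core <- nr[[1]]$core
    rows <- mcuts[mcuts$core == core, , drop = FALSE]
    if (all(series@members %in% rows$parent_id)) {
      rows <- rows[order(rows$parent_id, rows$substituent), , drop = FALSE]
      rows <- rows[!duplicated(rows$parent_id), , drop = FALSE]
      rg <- data.frame(R1 = rows$substituent[match(series@members,
                                                   rows$parent_id)],
                       row.names = series@members)
      return(new("ASBScaffold", seriesId = series@id,
                 structure = core, nSites = 1L, generation = generation,
                 status = "ok", members = series@members, rgroups = rg,
                 targets = series@targets))
    }
    return(excluded("multi_scaffold_required"))
  }

  sm <- mapSites(series, nr, mcuts)
  if (length(sm$ambiguous)) return(excluded("ambiguous_mapping"))
  counts <- vapply(sm$siteBonds, nrow, integer(1))
  maxk <- max(counts)
  maximal <- names(counts)[counts == maxk]
  # candidate selection order: lowest canonical structure first
  maximal <- maximal[order(smi[maximal], maximal)]
  candidates <- character(0)
  for (m in maximal) {
    mol <- .parse_mol(smi[[m]])
    marks <- sm$siteBonds[[m]]
    bond_ids <- vapply(seq_len(nrow(marks)), function(r) {
      hit <- which((mol$bonds$a1 == marks$a[r] & mol$bonds$a2 == marks$b[r]) |
                   (mol$bonds$a1 == marks$b[r] & mol$bonds$a2 == marks$a[r]))
      if (length(hit) != 1) stop("marked site bond not found in analog ", m)
      hit
    }, integer(1))
    sc <- .scaffold_component(mol, bond_ids, prefer_atom = marks$a[1])
    if (is.null(sc)) return(excluded("ambiguous_mapping"))
    candidates <- c(candidates,
                    .canonical_site_labeling(mol, sc$keep, sc$attach)$smiles)
  }
  if (length(unique(candidates)) != 1) return(excluded("ambiguous_mapping"))
  cand <- candidates[1]
  n_sites <- maxk
  cap_cache <- new.env(parent = emptyenv())
  rg_rows <- list()
  for (m in series@members) {
    row <- .decompose_member(smi[[m]], cand, n_sites, cap_cache)
    if (is.null(row)) return(excluded("multi_scaffold_required"))
    rg_rows[[m]] <- row
  }
  rg <- as.data.frame(do.call(rbind, rg_rows), stringsAsFactors = FALSE)
  new("ASBScaffold", seriesId = series@id, structure = cand,
      nSites = as.integer(n_sites), generation = generation, status = "ok",
      members = series@members, rgroups = rg, targets = series@targets)
}

#' Derive scaffolds for every series of a set
#'
#' @param seriesSet an \linkS4class{AnalogSeriesSet}.
#' @param compounds a \linkS4class{CompoundSet} or named SMILES vector.
#' @param cuts optional precomputed fragmentation records.
#' @return list of \linkS4class{ASBScaffold}, one per series.
#' @export
deriveScaffolds <- function(seriesSet, compounds, cuts = NULL) {
  if (is.null(cuts)) cuts <- enumerateCuts(.structures_of(compounds))
  lapply(seriesSet@series, deriveScaffold, compounds = compounds, cuts = cuts)
}

#' Build the R-group table of a series against an accepted scaffold
#'
#' Anchored decomposition of every member against the scaffold: at each
#' numbered site either a hydrogen or exactly one substituent branch.
#' Reattaching every row via \code{\link{attachFragments}} reproduces the
#' member set exactly (regeneration closure).
#'
#' @param series an \linkS4class{AnalogSeries}.
#' @param scaffold an \linkS4class{ASBScaffold} with status \code{"ok"}, or
#'   a scaffold SMILES.
#' @param compounds a \linkS4class{CompoundSet} or named SMILES vector.
#' @return data.frame, one row per member, columns \code{R1..Rn}.
#' @export
buildRGroupTable <- function(series, scaffold, compounds) {
  smi <- .structures_of(compounds, series@members)
  struct <- if (is(scaffold, "ASBScaffold")) scaffold@structure else scaffold
  if (is.na(struct)) stop("scaffold was excluded; no R-group table")
  n_sites <- nrow(.dummy_atoms(.parse_mol(struct)))
  cap_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (m in series@members) {
    row <- .decompose_member(smi[[m]], struct, n_sites, cap_cache)
    if (is.null(row))
      stop("member ", m, " does not decompose against the scaffold ",
           "(contract violation)")
    rows[[m]] <- row
  }
  as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
}

#' Bemis-Murcko scaffold of a single compound
#'
#' The compound-based scaffold: all ring systems plus the linker fragments
#' connecting rings, with substituents removed (atoms multiply bonded to
#' the framework, e.g. a linker carbonyl oxygen, are retained). Acyclic
#' molecules have no Bemis-Murcko scaffold.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical scaffold SMILES (\code{NA} for
#'   acyclic molecules).
#' @examples
#' bemisMurckoScaffold("CC(=O)Nc1ccccc1")  # benzene
#' @export
bemisMurckoScaffold <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    mol <- .parse_mol(s)
    ring_atom <- logical(mol$n)
    if (nrow(mol$bonds))
      ring_atom[c(mol$bonds$a1[mol$bonds$ring], mol$bonds$a2[mol$bonds$ring])] <- TRUE
    if (!any(ring_atom)) return(NA_character_)
    keep <- rep(TRUE, mol$n)
    repeat {
      deg <- vapply(seq_len(mol$n), function(i)
        sum(keep[mol$nbr[[i]]]), integer(1))
      prune <- which(keep & !ring_atom & deg <= 1)
      if (!length(prune)) break
      keep[prune] <- FALSE
    }
    # retain atoms attached to the framework by a multiple bond
    repeat {
      add <- which(!keep & vapply(seq_len(mol$n), function(i) {
        bs <- mol$nbrbond[[i]]
        any(mol$bonds$order[bs] >= 2 & keep[mol$nbr[[i]]])
      }, logical(1)))
      if (!length(add)) break
      keep[add] <- TRUE
    }
    .graph_smiles(mol, which(keep))
  }, character(1), USE.NAMES = FALSE)
}
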