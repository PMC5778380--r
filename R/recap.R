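# Retrosynthetic (RECAP) single-cut fragmentation.
#
# A bond is cleavable when it is an acyclic (non-ring) single bond matching
# one of the classical retrosynthetic bond types below. Cleavage of the
# olefin C=C bond -- a double-bond cut -- is incompatible with the
# single-bond attachment grammar used for matched molecular pairs and is
# therefore not part of the catalog (see the methods vignette).

.RECAP_RULES <- c("urea", "amide", "sulfonamide", "ester", "ether",
                  "quaternary_nitrogen", "aromatic_nitrogen_aliphatic_carbon",
                  "lactam_nitrogen_aliphatic_carbon", "amine",
                  "aromatic_carbon_aromatic_carbon")

#' Names of the retrosynthetic bond-cleavage rules
#'
#' @return character vector of rule identifiers, in matching priority order.
#' @export
recapRuleNames <- function() .RECAP_RULES

# classify every acyclic single bond of a molecule; returns a data.frame
# (bond = row id in mol$bonds, a1, a2, rule) with one row per cleavable bond
.recap_bonds <- function(mol, rules = .RECAP_RULES) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(data.frame(bond = integer(0), a1 = integer(0),
                                 a2 = integer(0), rule = character(0)))
  elem <- mol$atoms$elem; arom <- mol$atoms$arom; charge <- mol$atoms$charge
  deg <- lengths(mol$nbr)
  bond_order_sum <- vapply(seq_len(mol$n), function(i)
    sum(mol$bonds$order[mol$nbrbond[[i]]]), numeric(1))
  dbl_to <- function(i, el) {
    bs <- mol$nbrbond[[i]]
    sum(mol$bonds$order[bs] == 2 & elem[mol$nbr[[i]]] == el)
  }
  carbonyl <- vapply(seq_len(mol$n), function(i)
    elem[i] == "C" && !arom[i] && dbl_to(i, "O") >= 1, logical(1))
  sulfonyl <- vapply(seq_len(mol$n), function(i)
    elem[i] == "S" && dbl_to(i, "O") >= 2, logical(1))
  acyl_neighbor <- vapply(seq_len(mol$n), function(i)
    any(carbonyl[mol$nbr[[i]]] | sulfonyl[mol$nbr[[i]]]), logical(1))
  in_ring <- vapply(seq_len(mol$n), function(i)
    any(mol$bonds$ring[mol$nbrbond[[i]]]), logical(1))
  lactam_n <- vapply(seq_len(mol$n), function(i) {
    if (elem[i] != "N" || arom[i] || !in_ring[i]) return(FALSE)
    bs <- mol$nbrbond[[i]]
    any(mol$bonds$ring[bs] & carbonyl[mol$nbr[[i]]])
  }, logical(1))

  classify <- function(i, j) {
    # returns the first matching rule id for the acyclic single bond i-j
    for (r in rules) {
      hit <- switch(r,
        urea = (carbonyl[i] && sum(elem[mol$nbr[[i]]] == "N") >= 2 &&
                  elem[j] == "N") ||
               (carbonyl[j] && sum(elem[mol$nbr[[j]]] == "N") >= 2 &&
                  elem[i] == "N"),
        amide = (carbonyl[i] && elem[j] == "N") ||
                (carbonyl[j] && elem[i] == "N"),
        sulfonamide = (sulfonyl[i] && elem[j] == "N") ||
                      (sulfonyl[j] && elem[i] == "N"),
        ester = (carbonyl[i] && elem[j] == "O" && deg[j] == 2 &&
                   charge[j] == 0L) ||
                (carbonyl[j] && elem[i] == "O" && deg[i] == 2 &&
                   charge[i] == 0L),
        ether = {
          o <- if (elem[i] == "O") i else if (elem[j] == "O") j else 0L
          c_ <- if (o == i) j else i
          o > 0L && !arom[o] && deg[o] == 2 && charge[o] == 0L &&
            elem[c_] == "C" && all(elem[mol$nbr[[o]]] == "C") &&
            !any(carbonyl[mol$nbr[[o]]])
        },
        quaternary_nitrogen = {
          nn <- if (elem[i] == "N" && charge[i] == 1L) i
                else if (elem[j] == "N" && charge[j] == 1L) j else 0L
          nn > 0L && !arom[nn] && deg[nn] == 4 && bond_order_sum[nn] == 4 &&
            all(elem[mol$nbr[[nn]]] == "C")
        },
        aromatic_nitrogen_aliphatic_carbon = {
          nn <- if (elem[i] == "N" && arom[i]) i
                else if (elem[j] == "N" && arom[j]) j else 0L
          cc <- if (nn == i) j else i
          nn > 0L && charge[nn] == 0L && elem[cc] == "C" && !arom[cc] &&
            !carbonyl[cc]
        },
        lactam_nitrogen_aliphatic_carbon = {
          nn <- if (lactam_n[i]) i else if (lactam_n[j]) j else 0L
          cc <- if (nn == i) j else i
          nn > 0L && elem[cc] == "C" && !arom[cc] && !carbonyl[cc]
        },
        amine = {
          nn <- if (elem[i] == "N") i else if (elem[j] == "N") j else 0L
          cc <- if (nn == i) j else i
          nn > 0L && !arom[nn] && charge[nn] == 0L && deg[nn] >= 2 &&
            elem[cc] == "C" && !acyl_neighbor[nn]
        },
        aromatic_carbon_aromatic_carbon =
          elem[i] == "C" && elem[j] == "C" && arom[i] && arom[j],
        FALSE)
      if (isTRUE(hit)) return(r)
    }
    NA_character_
  }

  cand <- which(!mol$bonds$ring & mol$bonds$order == 1 & !mol$bonds$arom)
  res <- lapply(cand, function(b) {
    i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
    if (elem[i] == "*" || elem[j] == "*") return(NULL)
    r <- classify(i, j)
    if (is.na(r)) NULL else data.frame(bond = b, a1 = i, a2 = j, rule = r)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(data.frame(bond = integer(0), a1 = integer(0),
                                      a2 = integer(0), rule = character(0)))
  do.call(rbind, res)
}

#' Enumerate all single-cut retrosynthetic fragmentations
#'
#' Applies the retrosynthetic bond catalog to every acyclic single bond of
#' every compound. Each cleavable bond yields two records -- each fragment
#' serves once as core and once as substituent -- so that cores can later be
#' indexed across the whole compound set. Reattaching core and substituent
#' of any record reproduces the parent structure.
#'
#' @param compounds a \linkS4class{CompoundSet}, or a named character vector
#'   of canonical SMILES.
#' @param rules subset of \code{\link{recapRuleNames}()} to apply.
#' @return data.frame with columns \code{parent_id, rule, core, substituent,
#'   core_ha, sub_ha, core_atom, sub_atom} (the atom columns index the cut
#'   bond in the parent's canonical-structure atom numbering, core side and
#'   substituent side).
#' @examples
#' cs <- compoundSet("CC(=O)Nc1ccc2ccccc2c1", "amide1")
#' enumerateCuts(cs)
#' @export
enumerateCuts <- function(compounds, rules = recapRuleNames()) {
  if (is(compounds, "CompoundSet")) {
    smi <- structures(compounds)
  } else {
    smi <- compounds
    if (is.null(names(smi))) names(smi) <- sprintf("CPD%d", seq_along(smi))
  }
  rules <- match.arg(rules, .RECAP_RULES, several.ok = TRUE)
  out <- vector("list", length(smi))
  for (k in seq_along(smi)) {
    mol <- .parse_mol(smi[[k]])
    rb <- .recap_bonds(mol, rules)
    if (nrow(rb) == 0) next
    blocks <- character(0)
    meta <- list()
    for (r in seq_len(nrow(rb))) {
      pa <- .component_from(mol, rb$a1[r], blocked = rb$bond[r])
      pb <- setdiff(seq_len(mol$n), pa)
      blocks <- c(blocks,
                  .mol_block(mol, pa, data.frame(at = rb$a1[r], label = 1L)),
                  .mol_block(mol, pb, data.frame(at = rb$a2[r], label = 1L)))
      meta[[r]] <- data.frame(rule = rb$rule[r],
                              ha_a = length(pa), ha_b = length(pb),
                              atom_a = rb$a1[r], atom_b = rb$a2[r])
    }
    frags <- .blocks_to_smiles(blocks)
    meta <- do.call(rbind, meta)
    fa <- frags[seq(1, length(frags), by = 2)]
    fb <- frags[seq(2, length(frags), by = 2)]
    out[[k]] <- data.frame(
      parent_id = names(smi)[k],
      rule = rep(meta$rule, 2L),
      core = c(fa, fb),
      substituent = c(fb, fa),
      core_ha = c(meta$ha_a, meta$ha_b),
      sub_ha = c(meta$ha_b, meta$ha_a),
      core_atom = c(meta$atom_a, meta$atom_b),
      sub_atom = c(meta$atom_b, meta$atom_a))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(parent_id = character(0), rule = character(0),
                      core = character(0), substituent = character(0),
                      core_ha = integer(0), sub_ha = integer(0),
                      core_atom = integer(0), sub_atom = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$parent_id, res$core, res$substituent), ]
  rownames(res) <- NULL
  res
}

#' Test the substituent size restrictions
#'
#' True when the shared core is at least \code{coreToSubRatio} times the
#' larger exchanged substituent, both substituents are within
#' \code{maxSubHeavy}, and their heavy-atom difference is within
#' \code{maxDiffHeavy}. Vectorized.
#'
#' @param core_ha,sub_a_ha,sub_b_ha heavy-atom counts of core and exchanged
#'   substituents.
#' @param restriction a \linkS4class{SizeRestriction}.
#' @return logical vector.
#' @examples
#' passesSizeRestriction(11, 3, 5)   # TRUE
#' passesSizeRestriction(7, 3, 5)    # FALSE: core below 2 x 5
#' @export
passesSizeRestriction <- function(core_ha, sub_a_ha, sub_b_ha,
                                  restriction = sizeRestriction()) {
  core_ha >= restriction@coreToSubRatio * pmax(sub_a_ha, sub_b_ha) &
    sub_a_ha <= restriction@maxSubHeavy &
    sub_b_ha <= restriction@maxSubHeavy &
    abs(sub_a_ha - sub_b_ha) <= restriction@maxDiffHeavy
}
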