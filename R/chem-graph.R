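# Internal molecular graph model.
#
# A "mol" is a list with
#   atoms: data.frame(elem, arom, charge, iso)   (one row per heavy atom or
#          attachment dummy "*"; hydrogens are implicit)
#   bonds: data.frame(a1, a2, order, arom, ring) (kekulized orders from SDF,
#          aromaticity flags from MOL2, ring = bond lies on a cycle)
#   nbr / nbrbond: adjacency lists (neighbor atom ids / bond row ids)
# parsed once per distinct SMILES via OpenBabel and cached. All structure
# surgery (cuts, attachment, scaffold pruning) happens on this model; the
# result is serialized back to a V2000 MOL block and canonicalized by
# OpenBabel, so canonical equality is always decided by the same engine.

.parse_counts <- function(line) {
  c(as.integer(substr(line, 1, 3)), as.integer(substr(line, 4, 6)))
}

.parse_mol <- function(smiles) {
  key <- paste0("mol:", smiles)
  hit <- .ob_cache[[key]]
  if (!is.null(hit)) return(hit)
  smiles <- .normalize_attachment_spelling(smiles)
  inp <- paste0(smiles, " m\n")
  sdf <- .ob_convert("SMI", "SDF", inp)
  if (!nzchar(sdf)) stop("unparsable SMILES: '", smiles, "'")
  mol2 <- .ob_convert("SMI", "MOL2", inp)
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  cnt <- .parse_counts(lines[4])
  n <- cnt[1]; nb <- cnt[2]
  at <- lines[4 + seq_len(n)]
  elem <- trimws(substr(at, 32, 34))
  bo <- if (nb > 0) lines[4 + n + seq_len(nb)] else character(0)
  bonds <- data.frame(
    a1 = as.integer(substr(bo, 1, 3)),
    a2 = as.integer(substr(bo, 4, 6)),
    order = as.integer(substr(bo, 7, 9))
  )
  charge <- integer(n)
  iso <- integer(n)
  for (ln in grep("^M  (CHG|ISO)", lines, value = TRUE)) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    k <- as.integer(f[3])
    idx <- as.integer(f[3 + 2 * seq_len(k) - 1])
    val <- as.integer(f[3 + 2 * seq_len(k)])
    if (f[2] == "CHG") charge[idx] <- val else iso[idx] <- val
  }
  # aromaticity from the MOL2 rendering of the same input (atom order is
  # preserved across output formats for a given input molecule)
  arom_atom <- logical(n)
  arom_bond <- logical(nb)
  m2 <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  ai <- grep("^@<TRIPOS>ATOM", m2)
  bi <- grep("^@<TRIPOS>BOND", m2)
  if (length(ai) == 1L) {
    arows <- m2[(ai + 1):(ai + n)]
    atype <- vapply(strsplit(trimws(arows), "[[:space:]]+"),
                    function(f) f[6], character(1))
    arom_atom <- grepl("\\.ar$", atype)
  }
  if (length(bi) == 1L && nb > 0) {
    brows <- m2[(bi + 1):(bi + nb)]
    bf <- strsplit(trimws(brows), "[[:space:]]+")
    for (j in seq_len(nb)) {
      u <- as.integer(bf[[j]][2]); v <- as.integer(bf[[j]][3])
      if (identical(bf[[j]][4], "ar")) {
        # mol2 bond order may be listed in a different sequence; match by pair
        hitb <- which((bonds$a1 == u & bonds$a2 == v) |
                      (bonds$a1 == v & bonds$a2 == u))
        arom_bond[hitb] <- TRUE
        arom_atom[c(u, v)] <- TRUE
      }
    }
  }
  bonds$arom <- arom_bond
  # ring bonds: any bond that is not a bridge of the connectivity graph
  bonds$ring <- logical(nb)
  if (nb > 0) {
    g <- igraph::make_graph(edges = as.vector(t(as.matrix(bonds[, c("a1", "a2")]))),
                            n = n, directed = FALSE)
    br <- igraph::bridges(g)
    bonds$ring[setdiff(seq_len(nb), as.integer(br))] <- TRUE
  }
  atoms <- data.frame(elem = elem, arom = arom_atom, charge = charge, iso = iso)
  # drop explicit hydrogens if OpenBabel emitted any
  if (any(atoms$elem == "H")) {
    keep <- which(atoms$elem != "H")
    remap <- integer(n); remap[keep] <- seq_along(keep)
    bonds <- bonds[bonds$a1 %in% keep & bonds$a2 %in% keep, , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL; rownames(bonds) <- NULL
    n <- nrow(atoms)
  }
  nbr <- rep(list(integer(0)), n)
  nbrbond <- rep(list(integer(0)), n)
  if (nrow(bonds) > 0) {
    for (j in seq_len(nrow(bonds))) {
      u <- bonds$a1[j]; v <- bonds$a2[j]
      nbr[[u]] <- c(nbr[[u]], v); nbrbond[[u]] <- c(nbrbond[[u]], j)
      nbr[[v]] <- c(nbr[[v]], u); nbrbond[[v]] <- c(nbrbond[[v]], j)
    }
  }
  mol <- list(atoms = atoms, bonds = bonds, nbr = nbr, nbrbond = nbrbond,
              n = n, smiles = smiles)
  assign(key, mol, envir = .ob_cache)
  mol
}

# connected component containing `start`, ignoring bonds whose row ids are in
# `blocked`; returns sorted atom ids
.component_from <- function(mol, start, blocked = integer(0)) {
  seen <- logical(mol$n)
  seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    bs <- mol$nbrbond[[v]]
    ok <- !(bs %in% blocked)
    for (w in mol$nbr[[v]][ok]) {
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

# V2000 MOL block for a subset of atoms, with one dummy atom appended per row
# of `dummies` (data.frame at = attachment atom id in `keep`, label = site)
.mol_block <- function(mol, keep = seq_len(mol$n), dummies = NULL) {
  remap <- integer(mol$n)
  remap[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  bsel <- mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep
  bonds <- mol$bonds[bsel, c("a1", "a2", "order"), drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  iso <- atoms$iso; charge <- atoms$charge; elem <- atoms$elem
  if (!is.null(dummies) && nrow(dummies)) {
    for (j in seq_len(nrow(dummies))) {
      elem <- c(elem, "*"); charge <- c(charge, 0L)
      iso <- c(iso, as.integer(dummies$label[j]))
      bonds <- rbind(bonds, data.frame(a1 = remap[dummies$at[j]],
                                       a2 = length(elem), order = 1L))
    }
  }
  na <- length(elem); nbnd <- nrow(bonds)
  hdr <- c("frag", " ASBScaffolds", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nbnd))
  alines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    elem)
  blines <- if (nbnd > 0)
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$order)
  else character(0)
  extra <- character(0)
  for (i in which(charge != 0L))
    extra <- c(extra, sprintf("M  CHG  1 %3d %3d", i, charge[i]))
  for (i in which(iso != 0L))
    extra <- c(extra, sprintf("M  ISO  1 %3d %3d", i, iso[i]))
  paste(c(hdr, alines, blines, extra, "M  END", "$$$$", ""), collapse = "\n")
}

# canonical SMILES for a batch of MOL blocks built by .mol_block (all valid
# by construction, so the multi-record conversion is safe)
.blocks_to_smiles <- function(blocks) {
  if (!length(blocks)) return(character(0))
  out <- .ob_convert("SDF", "CAN", paste(blocks, collapse = ""))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (length(lines) != length(blocks))
    stop("internal error: MOL block conversion lost records")
  vapply(lines, .parse_can_line, character(1), USE.NAMES = FALSE)
}

.graph_smiles <- function(mol, keep = seq_len(mol$n), dummies = NULL) {
  .blocks_to_smiles(.mol_block(mol, keep, dummies))
}

# dummy atoms of a fragment mol: ids and labels (iso 0 treated as label 1)
.dummy_atoms <- function(mol) {
  ids <- which(mol$atoms$elem == "*")
  lab <- mol$atoms$iso[ids]
  lab[lab == 0L] <- 1L
  data.frame(id = ids, label = lab)
}

#' Count heavy atoms
#'
#' Number of non-hydrogen atoms in a molecule or fragment; attachment-point
#' dummies are not counted.
#'
#' @param smiles character vector of SMILES.
#' @return integer vector.
#' @examples
#' heavyAtomCount(c("c1ccccc1", "[1*]C(=O)C"))
#' @export
heavyAtomCount <- function(smiles) {
  vapply(smiles, function(s) {
    m <- .parse_mol(s)
    sum(m$atoms$elem != "*")
  }, integer(1), USE.NAMES = FALSE)
}

#' Attach substituents to a scaffold or core
#'
#' Bonds each substituent fragment to the matching numbered attachment point
#' of \code{core} and returns the canonical SMILES of the assembled molecule.
#' The value \code{"H"} caps a site with hydrogen. For every fragmentation
#' produced by \code{\link{enumerateCuts}}, reattaching core and substituent
#' reproduces the parent structure.
#'
#' @param core fragment SMILES with one or more attachment points
#'   \code{[k*]}.
#' @param substituents character vector of substituent fragments, each
#'   carrying one attachment point whose label matches a core site, or
#'   \code{"H"}. Optionally named by site label.
#' @return canonical SMILES of the assembled molecule.
#' @examples
#' attachFragments("[1*]Nc1ccc2ccccc2c1", "[1*]C(=O)C")
#' @export
attachFragments <- function(core, substituents) {
  cm <- .parse_mol(core)
  cd <- .dummy_atoms(cm)
  if (nrow(cd) == 0) stop("core carries no attachment point: ", core)
  subs <- as.character(substituents)
  # resolve which substituent serves which site
  lab_of <- function(s) {
    if (identical(s, "H") || identical(s, "[H]")) return(NA_integer_)
    d <- .dummy_atoms(.parse_mol(s))
    if (nrow(d) != 1) stop("substituent must carry exactly one attachment point: ", s)
    d$label
  }
  if (!is.null(names(substituents)) && all(nzchar(names(substituents)))) {
    site <- as.integer(names(substituents))
  } else {
    site <- vapply(subs, lab_of, integer(1), USE.NAMES = FALSE)
    if (length(subs) == 1 && is.na(site)) site <- cd$label[1]
  }
  if (anyNA(site) || anyDuplicated(site))
    stop("substituent sites could not be resolved unambiguously")
  if (!all(sort(site) == sort(cd$label)))
    stop("attachment labels of substituents (", paste(sort(site), collapse = ","),
         ") do not match core sites (", paste(sort(cd$label), collapse = ","), ")")
  # assemble combined atom/bond tables
  atoms <- cm$atoms
  bonds <- cm$bonds[, c("a1", "a2", "order")]
  drop_atoms <- integer(0)
  for (j in seq_along(subs)) {
    s <- subs[j]
    cdum <- cd$id[match(site[j], cd$label)]
    cnb <- cm$nbr[[cdum]]
    if (length(cnb) != 1) stop("core attachment point must have one neighbor")
    if (identical(s, "H") || identical(s, "[H]")) {
      drop_atoms <- c(drop_atoms, cdum)
      next
    }
    sm <- .parse_mol(s)
    sd <- .dummy_atoms(sm)
    if (sd$label[1] != site[j])
      stop("attachment label mismatch for substituent '", s, "' at site ", site[j])
    sdum <- sd$id[1]
    snb <- sm$nbr[[sdum]]
    if (length(snb) != 1) stop("substituent attachment point must have one neighbor")
    off <- nrow(atoms)
    atoms <- rbind(atoms, sm$atoms)
    sb <- sm$bonds[, c("a1", "a2", "order")]
    sb$a1 <- sb$a1 + off; sb$a2 <- sb$a2 + off
    bonds <- rbind(bonds, sb)
    bonds <- rbind(bonds, data.frame(a1 = cnb, a2 = snb + off, order = 1L))
    drop_atoms <- c(drop_atoms, cdum, sdum + off)
  }
  keep <- setdiff(seq_len(nrow(atoms)), drop_atoms)
  fake <- list(atoms = atoms, bonds = cbind(bonds, arom = FALSE, ring = FALSE),
               n = nrow(atoms))
  .graph_smiles(fake, keep)
}

# all label assignments (permutations) of 1..k
.perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in .perms(k - 1)) for (i in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = i - 1L)
  }
  out
}

# canonical site numbering: relabel the dummies of a multi-site fragment so
# the canonical SMILES string is lexicographically smallest; deterministic
.canonical_site_labeling <- function(mol, keep, attach_atoms) {
  k <- length(attach_atoms)
  perms <- .perms(k)
  blocks <- vapply(perms, function(p) {
    .mol_block(mol, keep, data.frame(at = attach_atoms, label = p))
  }, character(1))
  smis <- .blocks_to_smiles(blocks)
  best <- order(smis)[1]
  list(smiles = smis[best], labels = perms[[best]])
}
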