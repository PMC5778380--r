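# small shared helpers

# one-decimal rounding, half-up, matching the presentation of series
# statistics tables
.round1 <- function(x) floor(x * 10 + 0.5 + 1e-9) / 10

#' Percentage with table-style rounding
#'
#' \code{100 * num / den}, rounded half-up to one decimal; 0 for an empty
#' denominator.
#'
#' @param num,den numerator and denominator.
#' @return numeric.
#' @examples
#' pctOf(15625, 22015)  # 71.0
#' @export
pctOf <- function(num, den) {
  ifelse(den == 0, 0, .round1(100 * num / den))
}

#' Normalize the site numbering of a multi-site scaffold
#'
#' Relabels the attachment points \code{[k*]} so that the canonical SMILES
#' string is lexicographically smallest; the package-wide deterministic
#' site numbering. Two scaffolds equal up to site renumbering normalize to
#' the identical string.
#'
#' @param smiles scaffold SMILES with one or more attachment points.
#' @return canonical scaffold SMILES with normalized site labels.
#' @export
normalizeScaffoldSites <- function(smiles) {
  vapply(as.character(smiles), function(s) .normalize_scaffold_map(s)$smiles,
         character(1), USE.NAMES = FALSE)
}

# normalization plus the label permutation it applied: map is a named
# integer vector, original site label -> normalized site label
.normalize_scaffold_map <- function(s) {
  mol <- .parse_mol(s)
  d <- .dummy_atoms(mol)
  if (nrow(d) == 0) stop("not a scaffold (no attachment points): ", s)
  attach <- vapply(d$id, function(i) {
    nb <- mol$nbr[[i]]
    if (length(nb) != 1) stop("attachment point must have one neighbor")
    nb
  }, integer(1))
  keep <- setdiff(seq_len(mol$n), d$id)
  lab <- .canonical_site_labeling(mol, keep, attach)
  list(smiles = lab$smiles,
       map = stats::setNames(as.integer(lab$labels),
                             as.character(d$label)))
}
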