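# Low-level OpenBabel bridge. All SMILES canonicalization and format
# conversion goes through ChemmineOB; everything structural above this file
# works on the internal graph model (see chem-graph.R).

.ob_cache <- new.env(parent = emptyenv())

.ob_convert <- function(from, to, text) {
  # OpenBabel writes parse complaints to stderr; an empty/short result is the
  # only programmatic failure signal, handled by callers.
  suppressWarnings(ChemmineOB::convertFormat(from, to, source = text))
}

# Translate the alternative atom-map attachment spelling [*:k] to the
# canonical isotope-label spelling [k*] accepted everywhere in this package.
.normalize_attachment_spelling <- function(x) {
  gsub("\\[\\*:([0-9]+)\\]", "[\\1*]", x)
}

.parse_can_line <- function(line) {
  # OB canonical output is "SMILES\tTITLE\n"
  sub("\t.*$", "", sub("\n$", "", line))
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the canonical form used throughout the package, so
#' that chemically identical inputs map to identical strings. Attachment
#' points are isotope-labeled dummy atoms (\code{[1*]}, \code{[2*]}, ...);
#' the atom-map spelling \code{[*:k]} is accepted and translated on input.
#'
#' @param smiles character vector of SMILES (molecules or fragments).
#' @param onError \code{"stop"} (default) raises an error naming the
#'   offending record; \code{"na"} returns \code{NA} for unparsable input.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalizeSmiles(c("OC(=O)C", "CC(O)=O"))  # identical strings
#' @export
canonicalizeSmiles <- function(smiles, onError = c("stop", "na")) {
  onError <- match.arg(onError)
  smiles <- .normalize_attachment_spelling(as.character(smiles))
  out <- character(length(smiles))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) {
      if (onError == "stop") stop("empty SMILES at position ", i)
      out[i] <- NA_character_
      next
    }
    hit <- .ob_cache[[paste0("can:", s)]]
    if (is.null(hit)) {
      res <- .ob_convert("SMI", "CAN", paste0(s, " m\n"))
      if (!nzchar(res)) {
        if (onError == "stop") stop("unparsable SMILES: '", s, "'")
        out[i] <- NA_character_
        next
      }
      hit <- .parse_can_line(res)
      assign(paste0("can:", s), hit, envir = .ob_cache)
      assign(paste0("can:", hit), hit, envir = .ob_cache)
    }
    out[i] <- hit
  }
  out
}

#' Test whether SMILES strings parse
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
isValidSmiles <- function(smiles) {
  !is.na(canonicalizeSmiles(smiles, onError = "na"))
}

#' Strip stereochemistry from SMILES
#'
#' Removes tetrahedral and double-bond stereo descriptors and
#' re-canonicalizes, giving the constitution-level structure.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical achiral SMILES.
#' @export
stripStereo <- function(smiles) {
  flat <- gsub("@", "", smiles, fixed = TRUE)
  flat <- gsub("[/\\\\]", "-", flat)
  canonicalizeSmiles(flat)
}
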