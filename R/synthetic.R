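# Synthetic benchmark generator: ground-truth analog series assembled from
# scaffold templates whose substituents attach through retrosynthetically
# cleavable linkages (amide, ester, aryl ether, aromatic N-alkyl), plus
# cleavage-free decoy singletons. Every pipeline stage can be validated
# against the recorded ground truth without external data.

# scaffold templates: sprintf patterns with two decoration slots and 1-3
# numbered attachment sites; `chem` names the substituent alphabet per site.
# Templates carry no internal cleavable bond, so the only retrosynthetic
# cuts of a generated member are at (or inside) its substituents.
.TEMPLATES <- list(
  list(sites = 1L, chem = "acyl",
       pattern = "[1*]Nc1ccc2cc(%s)c(%s)cc2c1"),
  list(sites = 1L, chem = "alkoxy",
       pattern = "O=C([1*])c1ccc2cc(%s)c(%s)cc2c1"),
  list(sites = 1L, chem = "nalkyl",
       pattern = "[1*]n1cc(%s)c2cc(%s)ccc21"),
  list(sites = 1L, chem = "aryloxy",
       pattern = "[1*]c1ccc2nc(%s)cc(%s)c2c1"),
  list(sites = 2L, chem = c("acyl", "alkoxy"),
       pattern = "[1*]Nc1c(%s)cc(C(=O)[2*])c(%s)c1"),
  list(sites = 2L, chem = c("acyl", "aryloxy"),
       pattern = "[1*]Nc1cc(%s)c2cc([2*])c(%s)cc2c1"),
  list(sites = 2L, chem = c("nalkyl", "alkoxy"),
       pattern = "[1*]n1c(C(=O)[2*])cc2cc(%s)c(%s)cc21"),
  list(sites = 3L, chem = c("acyl", "alkoxy", "aryloxy"),
       pattern = "[1*]Nc1c(%s)c(C(=O)[2*])cc([3*])c1%s"),
  list(sites = 3L, chem = c("acyl", "alkoxy", "aryloxy"),
       pattern = "[1*]Nc1cc(%s)c2cc(C(=O)[2*])c([3*])c(%s)c2c1"),
  list(sites = 3L, chem = c("nalkyl", "alkoxy", "aryloxy"),
       pattern = "[1*]n1c(C(=O)[2*])cc2cc([3*])c(%s)c(%s)c21")
)

.DECORATIONS <- c("[H]", "C", "F", "Cl", "C(F)(F)F")

# substituent alphabets (heavy atoms 2-5, no internal non-rediscoverable
# chemistry; aryloxy substituents carry the ether oxygen themselves)
.SUB_ALPHABETS <- list(
  acyl   = c("C(=O)C", "C(=O)CC", "C(=O)CCC", "C(=O)C(C)C", "C(=O)C1CC1",
             "C(=O)CC#N"),
  alkoxy = c("OC", "OCC", "OCCC", "OC(C)C", "OCC(C)C", "OC1CC1"),
  aryloxy = c("OC", "OCC", "OCCC", "OC(C)C", "OCC(C)C", "OC1CC1"),
  nalkyl = c("CC", "CCC", "CCCC", "CC(C)C", "C1CC1", "CC1CC1")
)

.DECOY_CORES <- c("c1ccc(%s)cc1", "C1CCC(%s)CC1", "c1ccc2cc(%s)ccc2c1",
                  "C1CCCC(%s)C1", "c1cc(C)cc(%s)c1")
.DECOY_SUBS <- c("C", "CC", "CCC", "CCCC", "C(C)C", "CC(C)C", "C(F)(F)F",
                 "F", "Cl")

# all canonical scaffold variants for a given site count, in deterministic
# order; names carry the template index
.scaffold_pool <- function(sites) {
  pool <- list()
  for (ti in seq_along(.TEMPLATES)) {
    tp <- .TEMPLATES[[ti]]
    if (tp$sites != sites) next
    for (d1 in .DECORATIONS) for (d2 in .DECORATIONS) {
      smi <- sprintf(tp$pattern, d1, d2)
      can <- canonicalizeSmiles(smi, onError = "na")
      if (is.na(can)) stop("invalid scaffold template instance: ", smi)
      pool[[length(pool) + 1L]] <- list(template = ti, structure = can)
    }
  }
  structs <- vapply(pool, function(p) p$structure, character(1))
  pool <- pool[!duplicated(structs)]
  pool[order(vapply(pool, function(p) p$structure, character(1)))]
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a ground-truth benchmark of analog series and decoys
#'
#' Builds analog series from decorated scaffold templates with 1-3
#' substitution sites. Substituents are attached through retrosynthetically
#' cleavable linkages so every cut is rediscoverable, and the scaffolds
#' satisfy the size restrictions against the largest substituent. Members
#' are realized as a connected star sample of the substituent
#' cross-product: one base analog plus single-site variations, never the
#' full cross-product for multi-site series. Decoys carry no cleavable
#' bond, hence share no core with anything and must remain singletons.
#'
#' @param nSeries total number of series.
#' @param sitesDistribution named integer vector, site count -> number of
#'   series (names in \code{"1".."3"}); must sum to \code{nSeries}.
#' @param subsPerSite integer range (length 2), substituents sampled per
#'   site, base included.
#' @param nDecoys number of decoy singletons.
#' @param seed integer seed; the generator is deterministic for a fixed
#'   seed and restores the caller's RNG state.
#' @param annotate also generate a synthetic activity table (single-target
#'   series with probability \code{pSingleTarget}, otherwise 2-4 targets).
#' @param pSingleTarget probability that a series is single-target.
#' @return list with \code{compounds} (data.frame \code{id, smiles}),
#'   \code{activity} (data.frame \code{compound_id, target_id} or NULL) and
#'   \code{truth}: per-series scaffold (site-normalized), substituents,
#'   member structures and R-group rows, decoy ids, and the seed.
#' @examples
#' bm <- generateBenchmark(nSeries = 2, sitesDistribution = c("1" = 1, "2" = 1),
#'                         nDecoys = 2, seed = 7)
#' bm$truth$series[[1]]$scaffold
#' @export
generateBenchmark <- function(nSeries = 50,
                              sitesDistribution = c("1" = 20, "2" = 20,
                                                    "3" = 10),
                              subsPerSite = c(3L, 6L),
                              nDecoys = 30,
                              seed = 42,
                              annotate = TRUE,
                              pSingleTarget = 0.57) {
  stopifnot(nSeries >= 0, nDecoys >= 0, length(subsPerSite) == 2,
            sum(sitesDistribution) == nSeries)
  .with_seed(seed, {
    series <- list()
    compounds <- data.frame(id = character(0), smiles = character(0))
    si <- 0L
    for (sites_chr in names(sitesDistribution)) {
      sites <- as.integer(sites_chr)
      count <- sitesDistribution[[sites_chr]]
      if (count == 0) next
      pool <- .scaffold_pool(sites)
      if (length(pool) < count)
        stop("not enough distinct scaffold variants with ", sites, " site(s)")
      picks <- sample(length(pool), count)
      for (p in picks) {
        si <- si + 1L
        tp <- .TEMPLATES[[pool[[p]]$template]]
        # normalize site numbering up front so the recorded rows attach to
        # the scaffold exactly as the pipeline will report it
        nm <- .normalize_scaffold_map(pool[[p]]$structure)
        scaffold <- nm$smiles
        subs <- vector("list", sites)
        for (j in seq_len(sites)) {
          alpha <- .SUB_ALPHABETS[[tp$chem[j]]]
          krange <- seq(subsPerSite[1], subsPerSite[2])
          k <- krange[sample.int(length(krange), 1)]
          site <- nm$map[[as.character(j)]]
          subs[[site]] <- paste0(sprintf("[%d*]", site),
                                 sample(alpha, min(k, length(alpha))))
        }
        base <- vapply(subs, `[`, character(1), 1L)
        rows <- list(stats::setNames(base, as.character(seq_len(sites))))
        for (j in seq_len(sites)) {
          for (alt in subs[[j]][-1]) {
            combo <- base
            combo[j] <- alt
            rows[[length(rows) + 1L]] <-
              stats::setNames(combo, as.character(seq_len(sites)))
          }
        }
        ids <- sprintf("S%03dM%02d", si, seq_along(rows))
        structs <- vapply(rows, function(r) attachFragments(scaffold, r),
                          character(1))
        compounds <- rbind(compounds, data.frame(id = ids, smiles = structs))
        names(rows) <- ids
        series[[si]] <- list(
          id = sprintf("TRUTH%03d", si),
          sites = sites,
          scaffold = scaffold,
          substituents = subs,
          members = stats::setNames(structs, ids),
          rows = rows)
      }
    }
    decoy_pool <- sort(unique(canonicalizeSmiles(as.vector(vapply(
      .DECOY_CORES, function(core) sprintf(core, .DECOY_SUBS),
      character(length(.DECOY_SUBS)))))))
    if (nDecoys > length(decoy_pool))
      stop("at most ", length(decoy_pool), " distinct decoys available")
    decoys <- if (nDecoys > 0) sort(sample(decoy_pool, nDecoys)) else character(0)
    decoy_ids <- sprintf("DEC%03d", seq_along(decoys))
    if (length(decoys))
      compounds <- rbind(compounds,
                         data.frame(id = decoy_ids, smiles = decoys))
    activity <- NULL
    if (annotate && (nSeries > 0 || nDecoys > 0)) {
      act <- list()
      for (k in seq_along(series)) {
        tg <- sprintf("T%03d", k)
        if (stats::runif(1) >= pSingleTarget && nSeries > 1) {
          extra <- sample(setdiff(seq_len(nSeries), k),
                          sample(1:min(3, nSeries - 1), 1))
          tg <- c(tg, sprintf("T%03d", extra))
        }
        series[[k]]$targets <- sort(tg)
        act[[k]] <- expand.grid(compound_id = names(series[[k]]$members),
                                target_id = tg, stringsAsFactors = FALSE)
      }
      dec_t <- stats::runif(length(decoys)) < 0.5
      if (any(dec_t))
        act[[length(act) + 1L]] <- data.frame(
          compound_id = decoy_ids[dec_t],
          target_id = sprintf("TD%03d", which(dec_t)))
      activity <- do.call(rbind, act)
      rownames(activity) <- NULL
    }
    rownames(compounds) <- NULL
    list(compounds = compounds,
         activity = activity,
         truth = list(series = series, decoys = decoy_ids, seed = seed))
  })
}
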