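# Fixtures and independent oracles used across the suite.
# Fixture structures are built in code; nothing is read from disk.

# --- worked micro-fixtures -------------------------------------------------

# three N-(2-naphthyl) amides differing in the acyl chain + one decoy
fx_three_amides <- function(decoy = TRUE) {
  smi <- c(M1 = "CC(=O)Nc1ccc2ccccc2c1",
           M2 = "CCC(=O)Nc1ccc2ccccc2c1",
           M3 = "CCCC(=O)Nc1ccc2ccccc2c1")
  if (decoy) smi <- c(smi, DEC = "c1ccccc1")
  compoundSet(smi, names(smi))
}

# two-site series: methyl 4-(acylamino)benzoates
fx_two_site <- function() {
  smi <- c(A = "CC(=O)Nc1ccc(C(=O)OC)cc1",
           B = "CCC(=O)Nc1ccc(C(=O)OC)cc1",
           C = "CC(=O)Nc1ccc(C(=O)OCC)cc1")
  compoundSet(smi, names(smi))
}

# redundant-core pair: anthracen-2-yl glycinamides with formyl/acetyl caps
fx_extension <- function() {
  smi <- c(X1 = "O=CNCC(=O)Nc1ccc2cc3ccccc3cc2c1",
           X2 = "CC(=O)NCC(=O)Nc1ccc2cc3ccccc3cc2c1")
  compoundSet(smi, names(smi))
}

run_mini <- function(cs, restriction = sizeRestriction()) {
  cuts <- enumerateCuts(cs)
  rmmps <- enumerateRMMPs(cuts, restriction)
  seriesSet <- extractSeries(rmmps, cs)
  list(cs = cs, cuts = cuts, rmmps = rmmps, seriesSet = seriesSet)
}

# --- cached benchmark runs -------------------------------------------------

.bench_cache <- new.env(parent = emptyenv())

# small benchmark for unit/property tests
small_benchmark <- function() {
  if (is.null(.bench_cache$small)) {
    bm <- generateBenchmark(nSeries = 6,
                            sitesDistribution = c("1" = 2, "2" = 2, "3" = 2),
                            subsPerSite = c(3, 4), nDecoys = 6, seed = 11)
    res <- runPipeline(bm$compounds, activity = bm$activity, verbose = FALSE)
    .bench_cache$small <- list(bm = bm, res = res)
  }
  .bench_cache$small
}

# the full study-condition benchmark (seed 42, 50 series 20/20/10, 3-6
# substituents per site, 30 decoys)
full_benchmark <- function() {
  if (is.null(.bench_cache$full)) {
    bm <- generateBenchmark(nSeries = 50,
                            sitesDistribution = c("1" = 20, "2" = 20,
                                                  "3" = 10),
                            subsPerSite = c(3, 6), nDecoys = 30, seed = 42)
    res <- runPipeline(bm$compounds, activity = bm$activity, verbose = FALSE)
    .bench_cache$full <- list(bm = bm, res = res)
  }
  .bench_cache$full
}

# match each truth series to the derived series with the same member set;
# NA when no exact partition match exists
match_truth_series <- function(truth, seriesSet) {
  vapply(truth$series, function(ts) {
    memb <- sort(names(ts$members))
    hit <- which(vapply(seriesSet@series,
                        function(s) setequal(seriesMembers(s), memb),
                        logical(1)))
    if (length(hit) == 1) hit else NA_integer_
  }, integer(1))
}

# --- independent oracles ---------------------------------------------------

# brute-force RMMP enumeration: for every compound pair, compare every
# single retrosynthetic cut of both and test fragment equality. No core
# index involved.
oracle_rmmps <- function(cs, restriction = sizeRestriction()) {
  smi <- structures(cs)
  ids <- names(smi)
  cuts <- lapply(ids, function(i)
    enumerateCuts(stats::setNames(smi[i], i)))
  names(cuts) <- ids
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    ci <- cuts[[i]]; cj <- cuts[[j]]
    if (nrow(ci) == 0 || nrow(cj) == 0) next
    for (ri in seq_len(nrow(ci))) for (rj in seq_len(nrow(cj))) {
      if (ci$core[ri] != cj$core[rj]) next
      if (ci$substituent[ri] == cj$substituent[rj]) next
      if (!passesSizeRestriction(ci$core_ha[ri], ci$sub_ha[ri],
                                 cj$sub_ha[rj], restriction)) next
      a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
      sa <- if (a == ids[i]) ci$substituent[ri] else cj$substituent[rj]
      sb <- if (a == ids[i]) cj$substituent[rj] else ci$substituent[ri]
      rows[[length(rows) + 1L]] <-
        paste(ci$core[ri], a, b, sa, sb, sep = "\r")
    }
  }
  sort(unique(unlist(rows)))
}

rmmp_keys <- function(rmmps) {
  sort(unique(paste(rmmps$core, rmmps$compound_a, rmmps$compound_b,
                    rmmps$sub_a, rmmps$sub_b, sep = "\r")))
}

# minimal union-find for the component oracle
oracle_components <- function(edges_a, edges_b, ids) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_a))
    parent[[find(edges_a[k])]] <- find(edges_b[k])
  roots <- vapply(ids, find, character(1))
  unname(split(ids, roots))
}

# python/RDKit as an independent chemistry oracle (same image)
rdkit_oracle <- function(script, input_lines) {
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script)),
            input = input_lines, stdout = TRUE, stderr = FALSE))
  if (!is.null(attr(out, "status"))) return(NULL)
  out
}
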