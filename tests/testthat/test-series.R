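# core indexing, RMMP enumeration, network clustering, MMS decomposition

test_that("the core index groups the three naphthyl amides on their shared core", {
  cs <- fx_three_amides(decoy = FALSE)
  idx <- indexCores(enumerateCuts(cs))
  key <- canonicalizeSmiles("[1*]Nc1ccc2ccccc2c1")
  expect_true(key %in% names(idx))
  expect_identical(nrow(idx[[key]]), 3L)
  expect_setequal(idx[[key]]$parent_id, c("M1", "M2", "M3"))
  # empty input -> empty index; single molecule -> single-entry values
  expect_length(indexCores(enumerateCuts(compoundSet(character(0)))), 0L)
  one <- indexCores(enumerateCuts(compoundSet("CC(=O)Nc1ccccc1", "x")))
  expect_true(all(vapply(one, nrow, integer(1)) == 1L))
})

test_that("RMMP enumeration matches the brute-force all-pairs oracle", {
  run <- run_mini(fx_three_amides())
  expect_identical(nrow(run$rmmps), 3L)
  expect_identical(unique(run$rmmps$core),
                   canonicalizeSmiles("[1*]Nc1ccc2ccccc2c1"))
  expect_identical(rmmp_keys(run$rmmps), oracle_rmmps(run$cs))
  # unrelated compounds share no core
  none <- run_mini(compoundSet(c("c1ccccc1", "CC(=O)Nc1ccccc1"),
                               c("a", "b")))
  expect_identical(nrow(none$rmmps), 0L)
})

test_that("duplicate structures merge at ingest and form no pair", {
  cs <- compoundSet(c("CC(=O)Nc1ccccc1", "O=C(C)Nc1ccccc1"), c("a", "b"))
  expect_identical(length(cs), 1L)
  expect_identical(nrow(enumerateRMMPs(enumerateCuts(cs))), 0L)
})

test_that("series are the disjoint clusters of the RMMP network", {
  # two chemically unrelated amide triplets plus a decoy
  smi <- c(M1 = "CC(=O)Nc1ccc2ccccc2c1",
           M2 = "CCC(=O)Nc1ccc2ccccc2c1",
           M3 = "CCCC(=O)Nc1ccc2ccccc2c1",
           Q1 = "CC(=O)Nc1cccc2cccnc12",
           Q2 = "CCC(=O)Nc1cccc2cccnc12",
           DEC = "c1ccccc1")
  run <- run_mini(compoundSet(smi, names(smi)))
  ss <- run$seriesSet
  expect_identical(length(ss), 2L)
  expect_setequal(seriesSingletons(ss), "DEC")
  members <- lapply(seq_len(length(ss)), function(i) seriesMembers(ss[[i]]))
  expect_setequal(unlist(members), c("M1", "M2", "M3", "Q1", "Q2"))
  # agreement with an independent union-find over the edge list
  uf <- oracle_components(run$rmmps$compound_a, run$rmmps$compound_b,
                          sort(unique(c(run$rmmps$compound_a,
                                        run$rmmps$compound_b))))
  expect_identical(sort(vapply(members, function(m)
    paste(sort(m), collapse = ","), character(1))),
    sort(vapply(uf, function(m) paste(sort(m), collapse = ","),
                character(1))))
  # empty RMMP list -> no series
  expect_identical(length(extractSeries(enumerateRMMPs(
    enumerateCuts(compoundSet("c1ccccc1", "z"))))), 0L)
})

test_that("every compound belongs to at most one series (partition property)", {
  run <- small_benchmark()
  ss <- run$res$seriesSet
  all_members <- unlist(lapply(seq_len(length(ss)),
                               function(i) seriesMembers(ss[[i]])))
  expect_identical(anyDuplicated(all_members), 0L)
  expect_length(intersect(all_members, seriesSingletons(ss)), 0L)
  expect_identical(sort(c(all_members, seriesSingletons(ss))),
                   sort(compoundIds(run$res$compounds)))
})

test_that("MMS decomposition yields one single-site sub-series per shared core", {
  # three-amide series: one MMS with all three members
  run <- run_mini(fx_three_amides())
  mms <- decomposeMMS(run$seriesSet[[1]])
  expect_length(mms, 1L)
  expect_setequal(names(mms[[1]]$subs), c("M1", "M2", "M3"))
  # a two-member series is the smallest MMS
  run2 <- run_mini(fx_extension())
  mms2 <- decomposeMMS(run2$seriesSet[[1]])
  expect_true(all(lengths(lapply(mms2, function(m) m$subs)) == 2L))
  # the two-site series decomposes into two MMSs with the expected cores
  run3 <- run_mini(fx_two_site())
  mms3 <- decomposeMMS(run3$seriesSet[[1]])
  expect_length(mms3, 2L)
  cores <- vapply(mms3, function(m) m$core, character(1))
  expect_setequal(cores,
                  canonicalizeSmiles(c("[*:1]Nc1ccc(C(=O)OC)cc1",
                                      "CC(=O)Nc1ccc(C(=O)[*:1])cc1")))
  mem <- lapply(mms3, function(m) sort(names(m$subs)))
  expect_setequal(vapply(mem, paste, character(1), collapse = ","),
                  c("A,B", "A,C"))
  # every RMMP edge of the series is covered by at least one MMS
  covered <- vapply(seq_len(nrow(run3$rmmps)), function(r) {
    any(vapply(mms3, function(m)
      run3$rmmps$core[r] == m$core &&
        all(c(run3$rmmps$compound_a[r], run3$rmmps$compound_b[r]) %in%
              names(m$subs)), logical(1)))
  }, logical(1))
  expect_true(all(covered))
})

test_that("enumeration order is deterministic", {
  cs <- fx_two_site()
  a <- run_mini(cs)
  b <- run_mini(cs)
  expect_identical(a$cuts, b$cuts)
  expect_identical(a$rmmps, b$rmmps)
})
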