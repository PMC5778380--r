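# core reduction, site mapping, scaffold derivation, R-group tables,
# Bemis-Murcko comparison

test_that("core extension is detected as anchored containment at the site", {
  big <- "[1*]NCC(=O)Nc1ccc2cc3ccccc3cc2c1"
  small <- "[1*]Nc1ccc2cc3ccccc3cc2c1"
  expect_true(isCoreExtension(big, small))
  expect_false(isCoreExtension(small, big))
  expect_false(isCoreExtension(big, big))          # extension is strict
  expect_false(isCoreExtension("[1*]Nc1ccccc1", "[1*]Nc1ccccn1"))
  # anchored semantics: the small core sits at a cut bond of the big one,
  # wherever that bond is
  expect_true(isCoreExtension("[1*]NC(=O)c1ccc(C)cc1", "[1*]C"))
})

test_that("redundant cores reduce to the smallest core of the site", {
  run <- run_mini(fx_extension())
  s <- run$seriesSet[[1]]
  expect_identical(length(seriesCores(s)), 2L)
  nr <- reduceCores(s)
  expect_length(nr, 1L)
  expect_identical(nr[[1]]$core,
                   canonicalizeSmiles("[1*]Nc1ccc2cc3ccccc3cc2c1"))
  expect_setequal(nr[[1]]$members, c("X1", "X2"))
  # a single-core series is unchanged
  run1 <- run_mini(fx_three_amides())
  nr1 <- reduceCores(run1$seriesSet[[1]])
  expect_length(nr1, 1L)
  # the two-site series keeps both cores: neither extends the other
  run2 <- run_mini(fx_two_site())
  expect_length(reduceCores(run2$seriesSet[[1]]), 2L)
})

test_that("substitution sites transfer onto shared analogs", {
  run <- run_mini(fx_two_site())
  s <- run$seriesSet[[1]]
  sm <- mapSites(s, reduceCores(s), run$cuts)
  expect_length(sm$ambiguous, 0L)
  counts <- vapply(sm$siteBonds, nrow, integer(1))
  # the shared analog A carries both sites; B and C carry one each
  expect_identical(counts[["A"]], 2L)
  expect_identical(counts[["B"]], 1L)
  expect_identical(counts[["C"]], 1L)
  # a single-MMS series marks exactly one bond per member
  run1 <- run_mini(fx_three_amides())
  s1 <- run1$seriesSet[[1]]
  sm1 <- mapSites(s1, reduceCores(s1), run1$cuts)
  expect_true(all(vapply(sm1$siteBonds, nrow, integer(1)) == 1L))
})

test_that("a symmetric analog with identical branches is not flagged ambiguous", {
  smi <- c(P1 = "CC(=O)Nc1ccc(NC(C)=O)cc1",
           P2 = "CC(=O)Nc1ccc(NC(=O)CC)cc1")
  run <- run_mini(compoundSet(smi, names(smi)))
  expect_identical(length(run$seriesSet), 1L)
  s <- run$seriesSet[[1]]
  sm <- mapSites(s, reduceCores(s), run$cuts)
  expect_length(sm$ambiguous, 0L)
  sc <- deriveScaffold(s, run$cs, run$cuts)
  expect_identical(sc@status, "ok")
})

test_that("single-site scaffolds select the core shared by all analogs", {
  run <- run_mini(fx_three_amides())
  sc <- deriveScaffold(run$seriesSet[[1]], run$cs, run$cuts)
  expect_identical(sc@status, "ok")
  expect_identical(scaffoldStructure(sc),
                   canonicalizeSmiles("[*:1]Nc1ccc2ccccc2c1"))
  expect_identical(scaffoldSites(sc), 1L)
  expect_identical(scaffoldGeneration(sc), "first")
  rg <- rGroupTable(sc)
  expect_identical(rownames(rg), c("M1", "M2", "M3"))
  expect_identical(unname(unlist(rg$R1)),
                   canonicalizeSmiles(c("[1*]C(=O)C", "[1*]C(=O)CC",
                                        "[1*]C(=O)CCC")))
})

test_that("multi-site scaffolds are assembled from transferred sites", {
  run <- run_mini(fx_two_site())
  sc <- deriveScaffold(run$seriesSet[[1]], run$cs, run$cuts)
  expect_identical(sc@status, "ok")
  expect_identical(scaffoldSites(sc), 2L)
  expect_identical(scaffoldGeneration(sc), "second")
  expect_identical(scaffoldStructure(sc),
                   normalizeScaffoldSites("[*:1]Nc1ccc(C([*:2])=O)cc1"))
  # exact regeneration of every member from its R-group row
  rg <- rGroupTable(sc)
  smi <- structures(run$cs)
  for (m in rownames(rg)) {
    subs <- stats::setNames(as.character(rg[m, ]),
                            as.character(seq_len(ncol(rg))))
    expect_identical(attachFragments(scaffoldStructure(sc), subs),
                     unname(smi[m]))
  }
})

test_that("series whose sites map to different remainders are excluded as ambiguous", {
  loose <- sizeRestriction(coreToSubRatio = 0.1, maxSubHeavy = 20,
                           maxDiffHeavy = 15)
  smi <- c(W1 = "CC(=O)NCC", W2 = "CCC(=O)NCC", W3 = "CCC(=O)NCCC")
  cs <- compoundSet(smi, names(smi))
  run <- run_mini(cs, loose)
  expect_identical(length(run$seriesSet), 1L)
  sc <- deriveScaffold(run$seriesSet[[1]], cs, run$cuts)
  expect_identical(sc@status, "ambiguous_mapping")
  expect_identical(scaffoldSites(sc), 0L)
})

test_that("a member that cannot decompose under the shared candidate excludes the series", {
  loose <- sizeRestriction(coreToSubRatio = 0.1, maxSubHeavy = 25,
                           maxDiffHeavy = 25)
  smi <- c(Ma = "CC(=O)Nc1ccc(C(=O)OC)cc1",
           Mb = "CCC(=O)Nc1ccc(C(=O)OC)cc1",
           Mc = "CCC(=O)Nc1ccc(C(=O)OCC)cc1",
           Md = "CCOc1ccccc1C")
  cs <- compoundSet(smi, names(smi))
  run <- run_mini(cs, loose)
  expect_identical(length(run$seriesSet), 1L)
  expect_setequal(seriesMembers(run$seriesSet[[1]]),
                  c("Ma", "Mb", "Mc", "Md"))
  sc <- deriveScaffold(run$seriesSet[[1]], cs, run$cuts)
  expect_identical(sc@status, "multi_scaffold_required")
})

test_that("R-group tables regenerate the member set exactly (closure)", {
  run <- small_benchmark()
  smi <- structures(run$res$compounds)
  ok <- Filter(function(s) s@status == "ok", run$res$scaffolds)
  expect_gt(length(ok), 0)
  for (sc in ok) {
    rg <- rGroupTable(sc)
    expect_setequal(rownames(rg), sc@members)
    rebuilt <- vapply(rownames(rg), function(m)
      attachFragments(scaffoldStructure(sc),
                      stats::setNames(as.character(rg[m, ]),
                                      seq_len(ncol(rg)))), character(1))
    # no extras, no misses
    expect_identical(sort(unname(rebuilt)), sort(unname(smi[sc@members])))
  }
})

test_that("one scaffold per series even when members span several Bemis-Murcko scaffolds", {
  # fused-ring substituent changes the compound-based scaffold but not the
  # series-based one
  smi <- c(F1 = "CC(=O)Nc1ccc2cc(C(=O)OCC3CC3)ccc2c1",
           F2 = "CCC(=O)Nc1ccc2cc(C(=O)OCC3CC3)ccc2c1",
           F3 = "CC(=O)Nc1ccc2cc(C(=O)OCc3ccccc3)ccc2c1")
  cs <- compoundSet(smi, names(smi))
  run <- run_mini(cs)
  expect_identical(length(run$seriesSet), 1L)
  bm <- bemisMurckoScaffold(structures(cs))
  expect_gte(length(unique(bm)), 2L)
  sc <- deriveScaffold(run$seriesSet[[1]], cs, run$cuts)
  expect_identical(sc@status, "ok")
  expect_identical(length(scaffoldStructure(sc)), 1L)
})

test_that("Bemis-Murcko scaffolds keep rings and linkers, drop substituents", {
  expect_identical(bemisMurckoScaffold("CC(=O)Nc1ccccc1"),
                   canonicalizeSmiles("c1ccccc1"))
  expect_identical(bemisMurckoScaffold("c1ccccc1"),
                   canonicalizeSmiles("c1ccccc1"))
  expect_identical(bemisMurckoScaffold("CCCC"), NA_character_)
  # ring-connecting linker (and its carbonyl) survives
  expect_identical(bemisMurckoScaffold("O=C(c1ccccc1)Nc1ccccc1C"),
                   canonicalizeSmiles("O=C(c1ccccc1)Nc1ccccc1"))
})

test_that("Bemis-Murcko agrees with the RDKit implementation on probe molecules", {
  probes <- c("CC(=O)Nc1ccccc1", "CC(=O)Nc1ccc2ccccc2c1",
              "O=C(c1ccccc1)c1ccccc1", "c1ccc(CCc2ccccn2)cc1",
              "CC1CCN(CC1)C(=O)c1ccco1", "Cc1cc(C)c2ccccc2c1")
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.Scaffolds import MurckoScaffold",
    "for line in sys.stdin:",
    "    m = Chem.MolFromSmiles(line.strip())",
    "    print(Chem.MolToSmiles(MurckoScaffold.GetScaffoldForMol(m)))",
    sep = "\n")
  rd <- rdkit_oracle(script, probes)
  expect_identical(bemisMurckoScaffold(probes), canonicalizeSmiles(rd))
})
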