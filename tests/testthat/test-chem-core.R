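# canonicalization, heavy-atom counting, attachment arithmetic,
# standardization and duplicate merging

test_that("canonicalization maps identical compounds to identical strings and is idempotent", {
  # aromatic perception: Kekule and aromatic benzene agree
  expect_identical(canonicalizeSmiles("C1=CC=CC=C1"),
                   canonicalizeSmiles("c1ccccc1"))
  # acetic acid written two ways
  expect_identical(canonicalizeSmiles("OC(=O)C"), canonicalizeSmiles("CC(O)=O"))
  probes <- c("c1ccccc1", "CC(=O)Nc1ccc2ccccc2c1", "[1*]C(=O)C",
              "CCOC(=O)c1ccccc1", "CN1CCCC1=O", "O=S(=O)(N)c1ccccc1")
  can <- canonicalizeSmiles(probes)
  expect_identical(canonicalizeSmiles(can), can)
  # atom-map attachment spelling is accepted and normalized
  expect_identical(canonicalizeSmiles("[*:1]C(=O)C"),
                   canonicalizeSmiles("[1*]C(=O)C"))
})

test_that("canonical equality agrees with an independent canonicalizer (RDKit)", {
  pairs <- list(
    c("OC(=O)C", "CC(O)=O"),
    c("c1ccccc1", "C1=CC=CC=C1"),
    c("CC(=O)Nc1ccc2ccccc2c1", "O=C(C)Nc1ccc2ccccc2c1"),
    c("CCN(CC)CC", "N(CC)(CC)CC"),
    c("CCOC(=O)c1ccccc1", "c1ccccc1C(=O)OCC"),
    c("CC(=O)Nc1ccccc1", "CCC(=O)Nc1ccccc1"),   # different compounds
    c("CCO", "CCN"))                            # different compounds
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "for line in sys.stdin:",
    "    a, b = line.split()",
    "    ca = Chem.MolToSmiles(Chem.MolFromSmiles(a))",
    "    cb = Chem.MolToSmiles(Chem.MolFromSmiles(b))",
    "    print(int(ca == cb))", sep = "\n")
  rd <- rdkit_oracle(script, vapply(pairs, paste, character(1),
                                    collapse = " "))
  mine <- vapply(pairs, function(p)
    as.integer(canonicalizeSmiles(p[1]) == canonicalizeSmiles(p[2])),
    integer(1))
  expect_identical(mine, as.integer(rd))
})

test_that("unparsable input raises an error naming the record", {
  expect_error(canonicalizeSmiles("xyzzy"), "xyzzy")
  expect_identical(canonicalizeSmiles("xyzzy", onError = "na"),
                   NA_character_)
  expect_false(isValidSmiles("C1CC"))
  expect_true(isValidSmiles("C1CC1"))
})

test_that("heavy atoms are counted excluding hydrogens and attachment points", {
  expect_identical(heavyAtomCount("c1ccccc1"), 6L)
  expect_identical(heavyAtomCount("[*]C(=O)C"), 3L)
  # N-acetyl methyl anthranilate analog counted by hand: 14 heavy atoms
  expect_identical(heavyAtomCount("CC(=O)Nc1ccc(C(=O)OC)cc1"), 14L)
  expect_identical(heavyAtomCount("[2*]OCC"), 3L)
})

test_that("attachment reproduces the parent for every cut, both orientations", {
  cs <- fx_two_site()
  cuts <- enumerateCuts(cs)
  expect_gt(nrow(cuts), 0)
  smi <- structures(cs)
  rebuilt <- vapply(seq_len(nrow(cuts)), function(r)
    attachFragments(cuts$core[r], cuts$substituent[r]), character(1))
  expect_identical(rebuilt, unname(smi[cuts$parent_id]))
  # heavy atoms are conserved by cutting
  expect_identical(cuts$core_ha + cuts$sub_ha,
                   unname(heavyAtomCount(smi)[match(cuts$parent_id,
                                                    names(smi))]))
})

test_that("hydrogen capping and label mismatches behave per contract", {
  core <- "[1*]Nc1ccc2ccccc2c1"
  expect_identical(attachFragments(core, "H"),
                   canonicalizeSmiles("Nc1ccc2ccccc2c1"))
  expect_error(attachFragments(core, "[2*]C(=O)C"), "label|site")
  expect_error(attachFragments("CCO", "[1*]C"), "attachment")
  # multi-site assembly with a hydrogen sentinel
  scaf <- "[1*]Nc1ccc(C(=O)[2*])cc1"
  out <- attachFragments(scaf, c("1" = "[1*]C(=O)C", "2" = "H"))
  expect_identical(out, canonicalizeSmiles("CC(=O)Nc1ccc(C=O)cc1"))
})

test_that("standardization strips salts, neutralizes and merges duplicates", {
  expect_identical(standardizeSmiles("CC(=O)[O-].[Na+]"),
                   canonicalizeSmiles("CC(=O)O"))
  expect_identical(standardizeSmiles("CC[NH3+].[Cl-]"),
                   canonicalizeSmiles("CCN"))
  # nitro group is left as the zwitterionic form it was written in
  expect_identical(standardizeSmiles("C[N+](=O)[O-]"),
                   canonicalizeSmiles("C[N+](=O)[O-]"))
  cs <- compoundSet(c("CC(=O)Nc1ccccc1", "O=C(C)Nc1ccccc1", "c1ccccc1"),
                    c("a", "b", "z"),
                    targets = data.frame(compound_id = c("a", "b"),
                                         target_id = c("T1", "T2")))
  expect_identical(length(cs), 2L)
  # merged record unions the targets of both input records
  tg <- compoundTargets(cs)
  expect_identical(tg[["a"]], c("T1", "T2"))
  expect_true(validObject(cs))
})

test_that("stereo handling is configurable at ingest", {
  chiral <- "C[C@H](N)C(=O)O"
  expect_match(standardizeSmiles(chiral, keepStereo = TRUE), "@")
  expect_false(grepl("@", standardizeSmiles(chiral, keepStereo = FALSE)))
  expect_identical(standardizeSmiles(chiral, keepStereo = FALSE),
                   stripStereo(chiral))
})
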