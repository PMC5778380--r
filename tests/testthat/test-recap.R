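# retrosynthetic single-cut enumeration and size restrictions

test_that("molecules without cleavable bonds yield no records", {
  expect_identical(nrow(enumerateCuts(compoundSet("c1ccccc1", "bz"))), 0L)
  expect_identical(nrow(enumerateCuts(compoundSet("CCCC", "bu"))), 0L)
  expect_identical(nrow(enumerateCuts(compoundSet("Cc1ccccc1", "tol"))), 0L)
})

test_that("the amide rule cuts N-acylnaphthalen-2-amine once, two orientations", {
  cuts <- enumerateCuts(compoundSet("CC(=O)Nc1ccc2ccccc2c1", "m"))
  expect_identical(nrow(cuts), 2L)
  expect_identical(unique(cuts$rule), "amide")
  frags <- sort(unique(c(cuts$core, cuts$substituent)))
  expect_identical(frags,
                   sort(canonicalizeSmiles(c("[1*]C(=O)C",
                                             "[1*]Nc1ccc2ccccc2c1"))))
  # each fragment serves once as core and once as substituent
  expect_identical(sort(cuts$core), sort(cuts$substituent))
})

test_that("the ester rule cuts ethyl benzoate at the acyl-oxygen bond only", {
  cuts <- enumerateCuts(compoundSet("CCOC(=O)c1ccccc1", "e"))
  expect_identical(nrow(cuts), 2L)
  expect_identical(unique(cuts$rule), "ester")
  expect_setequal(unique(c(cuts$core, cuts$substituent)),
                  canonicalizeSmiles(c("[1*]OCC", "[1*]C(=O)c1ccccc1")))
})

test_that("each retrosynthetic bond type matches its hand-derived bond set", {
  cases <- list(
    # smiles, expected cleavable bonds, expected rule(s)
    list("CNC(=O)Nc1ccccc1", 2L, "urea"),            # both N-C(=O) bonds
    list("CS(=O)(=O)Nc1ccccc1", 1L, "sulfonamide"),
    list("COc1ccccc1", 2L, "ether"),                 # both C-O bonds of anisole
    list("CNc1ccccc1", 2L, "amine"),                 # N-methyl and N-aryl
    list("c1ccc(-c2ccccc2)cc1", 1L,
         "aromatic_carbon_aromatic_carbon"),
    list("Cn1cccc1", 1L, "aromatic_nitrogen_aliphatic_carbon"),
    list("CCN1CCCC1=O", 1L, "lactam_nitrogen_aliphatic_carbon"),
    list("C[N+](C)(C)Cc1ccccc1", 4L, "quaternary_nitrogen"))
  for (cc in cases) {
    cuts <- enumerateCuts(compoundSet(cc[[1]], "m"))
    expect_identical(nrow(cuts), 2L * cc[[2]],
                     info = paste("bond count for", cc[[1]]))
    expect_identical(unique(cuts$rule), cc[[3]],
                     info = paste("rule for", cc[[1]]))
  }
  # primary amines are not cut; ring bonds (lactam C-N) are never cut
  expect_identical(nrow(enumerateCuts(compoundSet("NCCc1ccccc1", "pa"))), 0L)
  expect_identical(nrow(enumerateCuts(compoundSet("O=C1CCCN1", "lac"))), 0L)
})

test_that("cut bonds are acyclic and every record round-trips", {
  run <- small_benchmark()
  cuts <- run$res$cuts
  smi <- structures(run$res$compounds)
  expect_gt(nrow(cuts), 50)
  # conservation: core + substituent heavy atoms = parent heavy atoms
  ha <- heavyAtomCount(smi)
  expect_identical(cuts$core_ha + cuts$sub_ha,
                   unname(ha[match(cuts$parent_id, names(smi))]))
  # round-trip on a deterministic sample of records
  idx <- seq(1, nrow(cuts), by = max(1L, nrow(cuts) %/% 40))
  rebuilt <- vapply(idx, function(r)
    attachFragments(cuts$core[r], cuts$substituent[r]), character(1))
  expect_identical(rebuilt, unname(smi[cuts$parent_id[idx]]))
  # every fragment carries exactly one attachment point
  expect_true(all(lengths(regmatches(cuts$core,
                                     gregexpr("\\*", cuts$core))) == 1L))
})

test_that("size restrictions implement the three limits", {
  expect_true(passesSizeRestriction(11, 3, 5))
  expect_false(passesSizeRestriction(7, 3, 5))     # core below 2 x 5
  expect_false(passesSizeRestriction(30, 2, 13))   # difference 11 > 8
  expect_false(passesSizeRestriction(30, 14, 14))  # substituent above 13
  # configurable limits
  loose <- sizeRestriction(coreToSubRatio = 1, maxSubHeavy = 20,
                           maxDiffHeavy = 20)
  expect_true(passesSizeRestriction(7, 3, 5, loose))
  expect_error(sizeRestriction(0, 13, 8), "positive")
})

test_that("the rule subset is configurable", {
  cs <- compoundSet("CC(=O)Nc1ccc2ccccc2c1", "m")
  expect_identical(nrow(enumerateCuts(cs, rules = "ester")), 0L)
  expect_identical(nrow(enumerateCuts(cs, rules = c("amide", "ester"))), 2L)
})
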