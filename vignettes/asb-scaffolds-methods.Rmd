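---
title: "Analog series-based scaffolds: model, parameters and design choices"
author: "ASBScaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analog series-based scaffolds: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(ASBScaffolds))
```

## The problem

Medicinal chemistry organizes compounds into *analog series* (ASs): sets of
molecules sharing a core structure and differing by substituents at one or
more sites, typically summarized as an R-group table. The classical
compound-based scaffold (Bemis–Murcko: rings plus ring-connecting linkers)
is defined per molecule, so one series can yield several scaffolds and one
scaffold can mix unrelated series. The analog series-based (ASB) scaffold
flips the perspective: first extract the series objectively from the data,
then derive exactly one scaffold per series, carrying its substitution
sites and the target annotations of its members.

## The model

**RMMPs.** A matched molecular pair (MMP) is two compounds distinguished
only by an exchange at a single site, represented as a shared core plus an
exchanged substituent pair. Here the decomposition is restricted to
*retrosynthetic* single cuts (RECAP-type bond classes), giving RMMPs: the
exchange corresponds to a plausible chemical transformation rather than an
arbitrary bond deletion. The cleavable bond classes implemented are amide,
ester, amine, urea, ether, quaternary nitrogen, aromatic
nitrogen–aliphatic carbon, lactam nitrogen–aliphatic carbon, aromatic
carbon–aromatic carbon and sulfonamide, applied to acyclic single bonds
only. The classical catalog also contains an olefin C=C cleavage; that is
a double-bond cut, which cannot be expressed in the single-bond
core-plus-substituent algebra this method is built on (a cut fragment
carries exactly one single-bond attachment point), so it is omitted from
the catalog rather than silently approximated.

**Size restrictions.** Exchanged substituents are limited to modifications
typical within a series: the core must have at least `coreToSubRatio`
(default 2) times as many heavy atoms as the larger exchanged substituent,
each substituent is capped at `maxSubHeavy` (default 13) heavy atoms, and
the two substituents may differ by at most `maxDiffHeavy` (default 8).
The defaults follow the transformation-size conventions customary for
MMP-based analog-series extraction; published threshold choices vary
across implementations, so these are stated as configurable package
defaults (`sizeRestriction()`), not as a reproduction of any one
published table.

**Series.** All compounds are fragmented by all applicable single cuts;
fragmentations are indexed by canonical core; every unordered compound
pair sharing a core with a size-admissible substituent exchange is an
RMMP. The RMMP network (nodes: compounds, edges: pairs) is decomposed into
connected components; each component is one analog series. Compounds in no
RMMP are reported as singletons so that coverage denominators are audited,
not guessed.

**MMSs and scaffold derivation.** A matching molecular series (MMS) is the
set of two or more analogs sharing one core — an AS with a single
substitution site. An AS may consist of several MMSs. Scaffold derivation
proceeds in two generations:

1. *First generation*: if the series has exactly one qualifying core and
   it is produced by a cut of every member, that core (one numbered
   attachment point) is the scaffold.
2. *Second generation*: (a) *redundant-core reduction* — any core equal to
   a smaller core with a conserved fragment inserted at its substitution
   site (`isCoreExtension`) is removed; memberships migrate to the
   retained minimal cores. Extension is a strict partial order (the bigger
   core has strictly more heavy atoms and transitivity holds by
   composition of insertions), so the retained set is exactly the minimal
   elements. (b) *site transfer* — each retained core marks, in every
   analog it matches, the bond between its attachment-image atom and the
   substituent branch; bonds marked by several cores collapse to one site.
   (c) *multi-site extraction* — on an analog carrying the maximal number
   of marked bonds, all marked bonds are cut at once; the remainder,
   with numbered attachment points, is the candidate scaffold. It is
   accepted only if all maximal analogs give the identical candidate and
   every member decomposes as candidate plus one substituent-or-hydrogen
   per site. Failing series are excluded with a reason
   (`ambiguous_mapping` when sites cannot be mapped to a single scaffold,
   `multi_scaffold_required` when no single candidate represents all
   members) — never with a second scaffold, preserving the one-to-one
   correspondence of series and scaffolds.

**R-group tables.** For an accepted scaffold, each member is decomposed
into one substituent or hydrogen per site (`buildRGroupTable`); hydrogen
is a legal R-group value because different MMSs fix different sites.
Reattaching every row reproduces the member set exactly ("regeneration
closure"), which the test suite asserts rather than assumes.

## Numerical and representation choices

* **Canonical structures.** All structure identity decisions are canonical
  SMILES comparisons through one engine (OpenBabel via ChemmineOB). Graph
  surgery (cutting, reattachment, scaffold pruning) happens on an internal
  kekulized graph parsed from the same engine's SDF/MOL2 output and is
  serialized back through it, so equality is never decided by two
  different aromaticity models.
* **Attachment points** are isotope-labeled dummy atoms `[1*]`, `[2*]`,
  ... — the one labeling that survives round trips through the standard
  exchange formats. The atom-map spelling `[*:k]` is accepted on input.
* **Site numbering.** Among all permutations of site labels, the one
  giving the lexicographically smallest canonical SMILES is used
  (`normalizeScaffoldSites`). This makes scaffold strings, R-group column
  order and repeated runs byte-reproducible.
* **Symmetry.** If a core matches an analog at several positions with
  identical substituents (a symmetric molecule), the first bond in
  canonical order is marked; if the branches differ, the series is
  excluded as `ambiguous_mapping` — the conservative reading of
  "sites cannot be unambiguously mapped to a single scaffold".
* **Candidate ties.** When several analogs tie for the maximal number of
  marked sites, candidates are compared starting from the lowest canonical
  member structure, and all must agree.
* **Stereochemistry.** `keepStereo` (default `TRUE`) controls whether
  stereo descriptors are kept in stored structures and hence duplicate
  merging; fragmentation and scaffold identity are constitution-level,
  since cut fragments are exchanged between molecules where the original
  stereo context does not transfer. The alternative (stereo-aware
  fragment comparison) is not offered because no reference behavior exists
  to validate it against.
* **Standardization.** Ingest keeps the largest organic component, strips
  salts/solvents, neutralizes charges where a neutral form exists
  (carboxylates, phenolates, ammonium; zwitterionic groups like nitro are
  untouched), and merges duplicates with id aliasing and target-set union
  — an MMP must be a pair of distinct compounds.
* **Degenerate inputs.** Molecules with no cleavable bond produce no
  records and end in the singleton audit; an empty input yields empty
  artifacts and an all-zero report, not an error.

## The synthetic benchmark

`generateBenchmark()` builds ground-truth series from decorated
heteroaromatic scaffold templates (9–20 heavy atoms) with 1–3 attachment
sites on retrosynthetically cleavable linkages (anilide N-acylation, ester
alkoxy exchange, aryl-ether O-alkyl, aromatic-N alkylation) and
substituent alphabets of 2–5 heavy atoms, so every attachment is
rediscoverable by the rule catalog and every exchange passes the default
size restrictions by construction. Members are a connected star sample of
the substituent cross-product — one base analog plus single-site
variations — never the full cross-product, so multi-site series exercise
site transfer through shared analogs and hydrogen-free R-group rows are
not guaranteed trivially. Decoys carry no cleavable bond at all and must
come out as singletons. The default conditions are 50 series (20 one-site,
20 two-site, 10 three-site), 3–6 substituents per site and 30 decoys,
about 400 compounds — sized so the full recovery experiment runs in well
under two minutes on one CPU.

Aryl-ether sites intentionally produce a redundant core (the cut inside
the O–C bond yields a one-atom core extension), so the benchmark exercises
redundant-core reduction on single-site series too; such series are
labeled generation `"second"` even though they have one site, exactly as
the generation tag is defined (uniqueness of the qualifying core *before*
reduction).

What the generator does not emulate: realistic property distributions,
ring-system diversity beyond the template library, stereochemistry,
measurement noise in activity annotations, or series whose sites cannot be
mapped consistently (those are covered by hand-crafted fixtures in the
test suite instead). Passing the benchmark therefore shows the machinery
is correct on well-posed series; it does not certify behavior on the full
heterogeneity of a curated bioactivity database.

## Limitations

* The rule catalog is a fixed interpretation of the classical
  retrosynthetic bond classes; laboratories differ in the fine print
  (e.g. whether anilines count as cleavable amines). The catalog is
  subsettable per run (`rules =`), which is also how rule-sensitivity can
  be assessed.
* Cores and scaffolds are constitution-level; enantiomeric analogs merge
  only if `keepStereo = FALSE`.
* The multi-site decomposition test searches subsets of a member's
  cleavable bonds; with at most three sites and the handful of cleavable
  bonds typical of drug-sized molecules this is fast, but molecules with
  dozens of cleavable bonds would slow it down.
* Statistics follow the series-level accounting of the method's
  literature: compound coverage is computed against compounds
  participating in series (not all input compounds), and percentages are
  rounded half-up to one decimal. Both choices are visible in the report
  fields, with raw numerators and denominators included.
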