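# ASBScaffolds

Systematic extraction of **analog series** from bioactive compound sets and
derivation of one unique **analog series-based (ASB) scaffold** per series.

Medicinal chemists organize related compounds as analog series — a shared
core with varying substituents, the structure behind every R-group table.
Compound-based scaffolds (Bemis–Murcko: rings plus ring-connecting
linkers) are defined per molecule, so one series may yield several
scaffolds. This package takes the series-first view:

1. Every compound is fragmented by **retrosynthetic single cuts** (RECAP
   bond classes: amide, ester, amine, urea, ether, sulfonamide, ...),
   giving core/substituent decompositions.
2. Two compounds sharing a core and differing by one size-restricted
   substituent exchange form an **RMMP** (retrosynthetic matched molecular
   pair). Default size limits: core ≥ 2 × max(substituent) heavy atoms,
   substituent ≤ 13, exchange difference ≤ 8.
3. The connected components of the RMMP network are the **analog
   series**; the single-site sub-series sharing one core are **matching
   molecular series (MMSs)**.
4. Each series yields at most one scaffold: the unique shared core
   (first generation), or — after **redundant-core reduction** (removing
   cores that are extensions of a smaller core at the same site) and
   **substitution-site transfer** onto shared analogs — a scaffold with
   multiple numbered sites `[1*], [2*], ...` (second generation). Series
   whose sites cannot be mapped to a single scaffold are excluded with a
   stated reason, never split across two scaffolds.
5. Scaffolds inherit the union of member target annotations; R-group
   tables regenerate every member exactly; summary statistics report
   series/compound coverage and single-/multi-target breakdown.

## Worked example

```r
library(ASBScaffolds)

cs <- compoundSet(c("CC(=O)Nc1ccc(C(=O)OC)cc1",
                    "CCC(=O)Nc1ccc(C(=O)OC)cc1",
                    "CC(=O)Nc1ccc(C(=O)OCC)cc1",
                    "c1ccc2ccccc2c1"),
                  c("A", "B", "C", "DEC"))
cuts  <- enumerateCuts(cs)
rmmps <- enumerateRMMPs(cuts)
ss    <- extractSeries(rmmps, cs)
ss
#> AnalogSeriesSet: 1 series (sizes 3-3), 1 singletons

sc <- deriveScaffold(ss[[1]], cs, cuts)
sc
#> ASBScaffold [AS0001] [1*]Nc1ccc(cc1)C(=O)[2*]
#>   sites: 2; generation: second; members: 3
rGroupTable(sc)
#>            R1      R2
#> A  [1*]C(=O)C  [2*]OC
#> B [1*]C(=O)CC  [2*]OC
#> C  [1*]C(=O)C [2*]OCC
```

The three esters form one series with two substitution sites (the acyl
exchange A/B and the alkoxy exchange A/C overlap in the shared analog A);
naphthalene has no retrosynthetic bond and stays a singleton. The scaffold
is the aminobenzoyl core with numbered attachment points, and reattaching
any R-group row reproduces that member's structure exactly
(`attachFragments(scaffoldStructure(sc), c("1" = "[1*]C(=O)C", "2" = "[2*]OC"))`).

`runPipeline()` chains all stages (standardization, fragmentation,
network, scaffolds, statistics) and writes TSV/JSON artifacts; a thin
command-line wrapper with the same stages as subcommands is installed at
`system.file("cli", "asb.R", package = "ASBScaffolds")`
(`simulate`, `fragment`, `series`, `scaffolds`, `stats`, `run`).

`generateBenchmark()` creates ground-truth analog series (scaffold
templates with 1–3 cleavable-linkage sites, decorated ring systems,
decoy singletons) so the whole pipeline is testable without external
data; see the methods vignette for what the generator does and does not
emulate.

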