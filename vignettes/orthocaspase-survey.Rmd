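---
title: "Surveying orthocaspases in cyanobacterial proteomes"
author: "ocascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying orthocaspases in cyanobacterial proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocascan)
```

## The problem

Orthocaspases (OCAs) are prokaryotic caspase homologues found widely in
cyanobacteria. They carry the catalytic p20-like sub-domain of the
caspase/peptidase C14 family but lack the p10 sub-domain. Proteolysis
requires a histidine–cysteine (HC) dyad inside the p20-like sub-domain; a
substantial fraction of cyanobacterial OCAs instead carry substituted dyads
(YS and YN most commonly, plus an assortment of rare two-letter variants)
and are presumed proteolytically inert. These pseudo-variants (δOCAs) are
nonetheless conserved, which raises the questions this package's survey
machinery addresses: how are wild-type and mutated OCAs distributed across
strains, morphotypes and habitats; what accessory domains and membrane
topologies do they combine with; and do the mutated dyad classes form
coherent clades in a p20 phylogeny?

`ocascan` implements the full survey as a tested pipeline over per-strain
proteome FASTA files plus a strain metadata table, and ships a synthetic
proteome generator with a complete ground-truth table so that every stage
can be validated end to end without any external database.

## Detecting the p20-like sub-domain

Domain detection uses a position-specific scoring profile built from a seed
alignment of p20-like sub-domains (`buildProfile()`). Per match column the
score of residue $a$ is the log-odds

$$ s_j(a) = \log_2 \frac{(c_{ja} + \tau\, b_a) / (n_j + \tau)}{b_a}, $$

with $c_{ja}$ the residue count in column $j$, $n_j$ the column total,
$b_a$ a fixed background composition (uniform $1/20$ by default) and
$\tau$ a pseudocount (default 1). Columns with more than 50% gaps are
removed from the match states; removing a catalytic column invalidates the
seed. Ambiguity letters (X/B/Z) score zero, i.e. as background.

Queries are scanned with an affine-gap local aligner over the profile match
columns (Smith–Waterman recurrences; query insertions pay gap penalties but
emit no score; defaults `gapOpen = -11`, `gapExtend = -1`, conventional
BLOSUM-scale values whose absolute scale is absorbed by calibration).
Non-overlapping hits are extracted greedily best-score-first with full
masking of claimed residues, ties resolving to the earlier hit, which makes
scans bit-reproducible. Each hit records a column map from profile match
column to query residue, which later anchors both the catalytic-residue
read-off and the phylogenetic alignment.

The bundled seed alignment is *synthetic*: ten rows derived from a designed
150-residue p20-like template (see below), not from real proteins. It is a
placeholder that makes the package self-contained; a real survey should
substitute a curated alignment via `readSeedAlignment()` (aligned FASTA
plus a two-line sidecar naming the H and C columns).

### Score threshold

Published domain surveys rarely state usable score cut-offs, so the
threshold here is calibrated empirically: `calibrateThreshold()` scans
residue-shuffled copies of the study's own proteins (default 1000,
`makeShuffledBackground()`) and returns the 0.999 quantile of best-hit
scores. A quantile alone still admits roughly one false protein per
thousand, so `runStudy()` additionally floors the threshold at 25% of the
profile self-score — planted or genuine domains score near the self-score
while shuffled backgrounds plateau far below it, so the floor removes the
residual false calls without costing sensitivity. Both knobs
(`thresholdQuantile`, `thresholdFloor`) are exposed and recorded in the
report's run metadata.

## Dyad classification and specificity pockets

The catalytic positions are read off each hit's column map
(`mapCatalyticPositions()`): a dyad column deleted in the query leaves that
side *unresolved*. `classifyDyad()` is total over residue pairs: (H, C) is
wild type, any other resolved pair is mutated, and the two-letter
concatenation is the dyad label.

The specificity pockets are the 5-mers flanking the catalytic residues.
The frames are fixed so that a conserved wild-type site reads `FSGHG`
(catalytic H at unit 4, i.e. offsets −3..+1) and `DTCHS` (catalytic C at
unit 3, offsets −2..+2); positions outside the sequence pad with `-`.
These are the unique 5-mer frames consistent with the degenerate patterns
this kind of survey reports, and `deriveConsensus()` reproduces that
reporting style: per column, residues at frequency ≥ `minFreq` (default
0.05, which retains singleton variants in a ~100-sequence study) survive
into a parenthesised alternative group ordered by descending frequency,
ties alphabetical. `matchConsensus()` provides the exact round-trip check:
at `minFreq ≤ 1/n` every contributing pocket matches the derived pattern.

Unresolved calls are excluded from every percentage denominator and
reported in their own tally, so printed percentages always refer to
classified sub-domains.

## Transmembrane segments and domain architecture

The survey's membrane-topology question only needs a classic single-pass
hydropathy criterion, so `predictTM()` slides a 19-residue window over the
Kyte–Doolittle scale and calls maximal runs of window centres with mean
≥ 1.6, expanded to full window extent and merged; both window and
threshold are configurable. This is deliberately a simple predictor: it
recovers designed hydrophobic stretches essentially perfectly (the test
suite demands ≥ 99% sensitivity and zero calls on hydrophilic-only
sequence) but it is not a topology model — no signal peptides, no
inside/outside orientation.

`buildArchitecture()` merges p20 hits, imported accessory-domain
annotations (simple TSV or hmmscan `--domtblout`; coordinates 1-based
inclusive throughout) and predicted TM segments into an N→C element list.
An accessory annotation overlapping a p20 hit by more than half its own
length is dropped as a database alias of the catalytic domain re-calling
the same residues. Occurrence counting collapses successive repeats first
(`collapseRepeats()`), so a six-bladed WD40 still counts once per protein,
and `classifyTopology()` labels proteins cytoplasmic or membrane-bound
with the first p20's side relative to its nearest TM segment; proteins
with several p20 hits are flagged rather than split.

## Abundance statistics

Abundance is OCAs per 100 proteins, with the strain's *nominal* proteome
size from the metadata as denominator (never the number of records that
happen to be supplied). Group means over morphotypes or habitats are
unweighted across strains, matching how such surveys report per-group
means; strain partitions (both subtypes / wild-type only / mutated only /
none) and carrier-denominator habitat percentages round to integers.
Abundances print to 4 significant figures. No statistical testing of group
differences is performed, deliberately.

## Phylogeny

Each hit's residues are projected onto the profile match columns
(`projectAlignment()`), giving a fixed-width alignment without any
separate MSA step; query insertions are discarded and deleted columns
become gaps. Distances are p-distances over gap-free column pairs, with
pairs sharing fewer than 20 comparable columns set to the maximal distance
1 (with a warning).

`njTree()` is a deterministic Saitou–Nei neighbour-joining implementation:
Q-matrix ties break to the lowest node-index pair and negative branch
lengths clamp to zero, so a given matrix always yields the same tree.
Neighbour joining rather than likelihood is a deliberate choice: the
survey's phylogenetic claims are about clade membership (do YS- and
YN-dyad sub-domains cluster?), which NJ answers exactly on well-separated
groups, at desk scale and with no model-selection machinery. Branch
lengths are therefore not interpretable beyond ordering. Rooting places
the root at the midpoint of a user-supplied outgroup's pendant edge, and
`pureClades()` reports every maximal dyad-pure clade above a size floor in
one post-order pass. A seeded bootstrap is not provided; clade support is
out of scope.

## The synthetic-data generator

`generateStudy()` emulates the survey's study shape with known truth:

* 30 strains in equal morphotype thirds, habitats drawn as 45% freshwater,
  30% terrestrial, 10% symbiotic, 5% marine, 10% other — freshwater- and
  terrestrial-dominant with marine rare, as in the surveyed strain sets;
* nominal proteome sizes uniform on 5000–7500 proteins;
* per-strain planted OCA counts Poisson with morphotype rates 0.066
  (heterocytous), 0.065 (filamentous) and 0.026 (unicellular) OCAs per 100
  proteins, which with the sizes above yields ≈ 98 planted OCAs in
  expectation;
* dyad labels drawn as HC 56%, YS 27%, YN 9% and eight rare dyads (YR, YY,
  YQ, HP, HG, YC, CY, YG) sharing 8%;
* per-label pocket templates whose pooled consensus reproduces the
  `FSG(H/Y)G`-style degenerate patterns;
* accessory motifs at inclusion probabilities 9% (WD40), 6% (AAA_16),
  4% (NACHT), plus DUF domains and pentapeptide repeats at a few percent;
* a transmembrane stretch in 25/98 of OCAs, N-terminal to the p20 in 3/25
  of those.

The planted p20 is a designed 150-residue hydrophilic template (synthetic,
not a real protein) with the catalytic H at position 58 and C at 112;
pocket windows are overwritten per label, the remaining template mutates
i.i.d. at `point_mutation_rate` (default 0), and accessories/TM attach via
short linkers with all coordinates recorded in the truth table. Every
random draw flows from one seed; two runs with the same seed are
byte-identical.

Two scale choices keep simulated studies desk-sized. First, only a capped
subsample of background proteins is emitted per strain (default 120,
lengths 100–400) while the metadata keeps the nominal proteome size — the
backgrounds exist to exercise false-positive behaviour, and scanning
thousands of additional inert proteins per strain would add nothing to any
check. Second, background composition defaults to typical globular-protein
frequencies; a hydrophilic-only composition (with rejection of any
sequence containing a threshold-reaching hydropathy window) is available
where a TM-free guarantee is needed.

What passing on synthetic data does *not* show: real p20 sub-domains are
far more diverse than a mutated template (no indel evolution, no rate
heterogeneity), real annotation tables carry tool errors the generator
does not simulate by default, and the planted TM stretch is idealised. The
generator validates the machinery, not the biology of any particular
proteome set.

## Worked example

```{r example}
rs <- runSyntheticStudy(seed = 1)
r <- rs$report

## dyad tallies and percentages (resolved-call denominator)
r$tallies$dyads
r$partition

## pocket consensus patterns
r$consensus

## morphotype group means (OCAs per 100 proteins)
r$group_means$morphotype

## the three largest dyad-pure clades
head(r$clades[c("label", "size")], 3)
```

`writeStudyResults(r, "out/")` writes the calls and summary TSVs, the
tallies JSON, the architecture and domain-frequency tables and the
dyad-labelled newick tree, byte-stably for a fixed seed.

## Numerical and degenerate-input conventions

* Coordinates in all external files are 1-based inclusive; any internal
  half-open arithmetic is never serialised.
* Score ties in scanning resolve to the earlier hit; Q-matrix ties to the
  lowest node-index pair; consensus-group ties alphabetically — every
  stage is deterministic given its inputs and seed.
* Empty studies are legal end to end: headers-only tables, zeroed tallies
  and no tree file.
* A sequence shorter than the hydropathy window has no TM segments; a
  protein whose dyad column is deleted is unresolved, not mutated.
* Problem sizes used by the test suite and the acceptance script — ~30
  strains, ~3700 proteins, 100-replicate oracle suites — are the package's
  chosen validation scale; they match the survey's study shape while
  keeping a full run in seconds.

## Known limitations

The PSSM scanner has no insert-state emission model and no E-value theory;
the calibration quantile stands in for both. The bundled seed alignment is
synthetic and must be replaced for real surveys. NJ on p-distances will
not resolve deep or rate-heterogeneous splits, and no bootstrap support is
computed. Habitat and morphotype vocabularies are fixed enums; anything
outside them must be mapped (e.g. multi-habitat strains to `other`)
before import.
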