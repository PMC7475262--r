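# ocascan

Orthocaspases (OCAs) are cyanobacterial caspase homologues: proteins that
carry the catalytic p20-like sub-domain of the caspase/peptidase C14 family
but lack the p10 sub-domain. Proteolysis requires the histidine–cysteine
(HC) dyad of the p20-like sub-domain, yet many cyanobacterial OCAs carry a
substituted dyad (YS and YN most often) and are presumed inert
pseudo-variants (δOCAs). `ocascan` is an R package for surveying both kinds
across whole proteomes: it detects p20-like sub-domains, classifies the
catalytic dyad of each hit, characterises specificity pockets, accessory
domains and membrane topology, computes abundance statistics by strain
morphotype and habitat, and builds a dyad-labelled phylogeny with
clade-purity reports. It is aimed at comparative genomicists studying
programmed cell death machinery in prokaryotes.

## What it computes

* **Detection.** A position-specific scoring profile built from a seed
  alignment, with per-column log-odds
  `s_j(a) = log2(((c_ja + τ b_a)/(n_j + τ)) / b_a)`, scanned against each
  protein by affine-gap local alignment (Smith–Waterman over match columns;
  gap open −11, extend −1). The reporting threshold is calibrated as the
  0.999 quantile of best scores on residue-shuffled background proteins.
* **Active sites.** Catalytic positions are read through each hit's
  profile→query column map; `(H, C)` is wild type, any other resolved pair
  a mutated dyad label. Specificity pockets are the 5-mers in the
  `FSGHG`-frame (H at unit 4) and `DTCHS`-frame (C at unit 3), summarised
  as degenerate consensus patterns such as `FSG(H/Y)G`.
* **Architecture.** Kyte–Doolittle sliding-window (19, ≥ 1.6)
  transmembrane segments, imported accessory-domain annotations (TSV or
  hmmscan domtblout), repeat-collapsed occurrence and co-occurrence
  tables, and cytoplasmic vs membrane-bound topology calls.
* **Abundance.** OCAs per 100 proteins per strain, unweighted group means
  by morphotype/habitat, strain partitions by subtype content, habitat
  tables.
* **Phylogeny.** Profile-anchored alignment of all hits, p-distances,
  deterministic neighbour-joining, outgroup rooting, and maximal
  dyad-pure clade reports.
* **Synthetic studies.** A generator that plants OCAs with known dyads,
  pockets, accessory motifs and TM stretches into multi-strain synthetic
  proteomes, emitting a full truth table for end-to-end validation.

## Worked example

```r
library(ocascan)
rs <- runSyntheticStudy(seed = 1)   # ~30 strains, ~98 planted OCAs
r  <- rs$report

r$tallies$dyads
#> HC YS YN HG HP YC YG YQ
#> 48 25 10  2  2  2  1  1

unlist(r$partition)
#>     n_both  n_wt_only n_mut_only     n_none
#>         18          6          5          1

r$consensus
#> $h_pocket
#> [1] "FSG(H/Y)G"
#> $c_pocket
#> [1] "D(T/C/S)(C/S/N)(H/Y/R)(S/N)"

r$group_means$morphotype
#>          group n_strains mean_abundance_wt mean_abundance_mut
#> 1  unicellular        11        0.01384636         0.01464000
#> 2  filamentous         9        0.03192778         0.04127333
#> 3 heterocytous        10        0.03475600         0.01790100

head(r$clades[c("label", "size")], 3)
#>   label size
#> 1    YS   25
#> 2    HC   16
#> 3    HC   16
```

This seed planted 91 OCAs; all 91 are recovered with their dyad labels
(48 wild-type HC, 43 mutated — a 53/47 split for this draw), 18 strains
carry both subtypes, the pooled H-pocket consensus reads `FSG(H/Y)G`, and
all 25 YS-dyad sub-domains fall in a single pure clade of the
neighbour-joining tree. `writeStudyResults(r, "out/")` writes the calls
TSV, strain summaries, tallies JSON and the dyad-labelled newick tree.

For real data, load proteomes and metadata and call the same pipeline:

```r
md  <- readStrainMetadata("metadata.tsv")
prot <- do.call(rbind, lapply(md$strain_id, function(s)
  readProteomeFasta(file.path("proteomes", paste0(s, ".faa")), s)))
ann <- readDomainTable("domains.domtblout")   # optional
r <- runStudy(prot, md, ann, seed = 1)
```

A thin shell wrapper with `simulate` and `all` subcommands is installed at
`inst/scripts/oca-survey.R`.

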