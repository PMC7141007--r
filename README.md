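# coidelim

Species delimitation and barcode-gap analysis for COI reference libraries.

DNA barcode reference libraries pair a standardized ~652 bp fragment of the
mitochondrial COI gene with a morphological species identification for every
voucher specimen. Before such a library can drive automated identification,
two questions must be answered: do the named species form tight,
well-separated sequence clusters (a *barcode gap*), and do molecularly
delimited clusters (OTUs) coincide with the species — or do they reveal
cryptic splits and haplotype-sharing merges? `coidelim` answers both for
taxonomists and molecular ecologists building or auditing such libraries.

## What it computes

* **K2P distances with pairwise deletion.** For each pair, columns with a
  gap or ambiguity in either sequence are dropped; with transition and
  transversion proportions *P* and *Q* over the retained sites,
  *d* = −½ log[(1 − 2*P* − *Q*)·√(1 − 2*Q*)]. Pairs under a minimum overlap
  (default 400 sites) or past saturation raise errors instead of returning
  misleading numbers.
* **Divergence summaries and the barcode gap.** Distance summaries at
  mutually exclusive taxonomic levels (within species / genus / family);
  per species, the maximum intraspecific distance and the distance to the
  nearest heterospecific neighbour, plus the library-wide ratio of their
  means.
* **Four delimiters.** A refined single-linkage clustering (2.2% seed,
  silhouette-validated refinement; "RESL-like"), automatic barcode gap
  discovery over a prior grid with recursive splitting (ABGD-style),
  multi-rate Poisson tree processes on a branch-length tree (mPTP-like),
  and a multi-rate general mixed Yule-coalescent on an ultrametric
  chronogram (mGMYC-like). Desk-scale NJ and strict-clock UPGMA trees are
  built internally (1.2% divergence/My by default); externally built
  trees can be injected as Newick.
* **Consensus and concordance.** A 50% pair-quorum consensus across
  methods, and a per-species report classifying MATCH / SPLIT (cryptic
  lineage candidates) / MERGE / MIXED, with haplotype sharing flagged from
  distance-zero heterospecific pairs.
* **A coalescent simulator.** Yule species tree (with a
  speciation-completion lag), Kingman coalescent within species, K80
  sequences under a strict clock, plus logged cryptic-split and
  introgression scenarios — so the whole pipeline is testable with known
  truth and no downloads.

## Worked example

```r
library(coidelim)

sim <- simulate_barcodes(sim_config(seed = 7, introgression_events = 1))
pp  <- run_pipeline(sim$dataset, seed = 7)
pp
#> <barcode_pipeline: 81 specimens, 20 species, 44 haplotypes>
#>   OTUs: resl=22, abgd=20, mptp=22, mgmyc=9; consensus=20

pp$summaries
#>   level          n_sequences n_taxa n_comparisons   min    mean    max
#> 1 within_species          78     17           162 0     0.00335 0.0662
#> 2 within_genus            78      2          1359 0     0.0697  0.108
#> 3 within_family           81      1          1719 0.106 0.131   0.167

dplyr::filter(tidy(pp$report), status != "MATCH")
#>   species     n n_otus otu_ids shares_otu status haplotype_sharing max_intra
#> 1 Sp12        4      2 12,13   TRUE       MIXED  TRUE                 0.0662
#> 2 Sp19        7      1 13      TRUE       MERGE  TRUE                 0.0156
```

Reading the output: 81 specimens collapse to 44 unique haplotypes; the four
delimiters propose between 9 and 22 OTUs and their 50% consensus lands on
20 OTUs for 20 species. Within-species divergence averages 0.34% against a
within-genus mean of 7.0% — the barcode gap. The simulated introgression
event (a haplotype copied from donor `Sp19` into one `Sp12` specimen)
surfaces exactly as designed: `Sp19` is a MERGE (its OTU 13 also contains
the transferred specimen) and `Sp12` is MIXED (its other specimens form
their own OTU 12), both flagged as haplotype sharing.

For real data, `read_barcode_dataset("barcodes.fasta", "specimens.tsv")`
takes an aligned FASTA plus a tab-separated table with `specimen_id`,
`species`, `genus`, `family` columns, and `run_pipeline()` proceeds
identically; `autoplot(pp$gaps)` draws the classic barcode-gap scatter.

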