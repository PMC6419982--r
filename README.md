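# ampliTax

Profiling microbial communities from **short paired-end 16S rRNA gene
amplicons** (~140 nt of information per read pair) for microbiome
researchers who need results that are driven by biology rather than by
quality-filter and clustering heuristics. ampliTax implements the complete
workflow in R: dual-barcode demultiplexing with exact barcode and IUPAC
primer matching, per-sample OTU picking by a minimum relative-abundance
threshold with one-mismatch rescue, rule-based de novo chimera flagging,
primer-guided trimming of a full-length reference database with consensus
taxonomy at six identity thresholds, relative-abundance profiles with a
weighted-difference divergence — plus a mock-community read simulator with
full ground-truth bookkeeping, so every stage is testable without any
external download.

## The method in brief

* **Demultiplexing.** Both mates carry `barcode + linker + primer`. A pair
  is kept for sample *s* only if both mates match *s*'s barcode exactly and
  its degenerate primer with zero mismatches (linker skipped). Valid
  barcodes in a combination that belongs to no sample indicate molecules
  hybridised after pooling and are rejected as *cross-sample chimeras*.
  Base qualities are never consulted.
* **OTU picking.** An OTU is a unique (5′, 3′) pair of `read_len`-nt
  sub-reads. Pairs with relative abundance ≥ 0.1% (per sample) are
  accepted; discarded reads at Hamming distance 1 from an accepted OTU are
  *rescued* into it, compensating for sequence-specific error. OTU *C* is
  flagged as a chimera when accepted OTUs *A* and *B* match its 5′ and 3′
  reads respectively and both are at least twice as abundant as *C*.
* **Taxonomy.** References are trimmed to the amplified region using the
  primers as a guide; every OTU is scored against every trimmed reference
  (combined identity = mean of the two fragment identities,
  `1 − d_Lev/len`), hits are collected at 100/98/97/95/92/90% identity,
  and a label is accepted at the deepest rank whose modal label is ≥ 50%
  specific and concordant across all lower thresholds.
* **Profiles.** Non-chimeric OTU mass is aggregated per rank (unassigned
  mass kept explicit) and profiles are compared by the weighted difference
  *D(x,y) = Σᵢ (xᵢ−yᵢ)²/((xᵢ+yᵢ)/2)*, which penalises relative as well as
  absolute abundance changes.

See `vignettes/amplicon-workflow.Rmd` for the full account, including
every tunable constant and the reasoning behind the numerical choices.

## Worked example

Simulate an equimolar 17-member mock community with a realistic
substitution error rate, then run every stage:

```r
library(ampliTax)

refs <- synthReferences(17, 17, seed = 42)     # synthetic reference panel
pr   <- standardPrimers()$V4
map  <- SampleMap("S1", "ACGTACGT", "GGTTCCAA", pr[["fwd"]], pr[["rev"]])
design <- mockDesign("mc1", refs$accession, rep(1/17, 17),
                     n_reads = 10000, error_rate = 0.002, seed = 7)
sim  <- simulateReads(design, refs, map[1, , drop = FALSE])

dmx  <- demultiplex(sim$pairs, map)
st   <- stripTechnical(dmx$samples$S1, map[1, , drop = FALSE])
tab  <- buildOTUTable(st$trimmed, "S1", threshold = 0.001)
tab
#> SampleOTUTable 'S1': 17 OTU(s) from 10000 reads (threshold 0.001)
#>   reads in OTUs: 7505 exact + 2157 rescued; chimera-flagged: 0
```

All 10,000 pairs demultiplex cleanly (no technical errors were injected);
at a 0.2% per-base error rate only 75% of reads are exact matches to an
accepted OTU, and one-mismatch rescue recovers another 22% that the
abundance filter alone would have dropped. Classification against the
trimmed references and aggregation to genus:

```r
db  <- trimReferences(refs, pr[["fwd"]], pr[["rev"]], read_len = 70)
asg <- classifyOTUs(tab, db)
head(asg[, c("otu_id", "genus", "assigned_rank", "specificity")], 3)
#>       otu_id    genus assigned_rank specificity
#> 1 S1_OTU0001 Genus_14         genus         100
#> 2 S1_OTU0002 Genus_10         genus         100
#> 3 S1_OTU0003 Genus_06         genus         100

obs <- makeProfile(tab, asg, rank = "genus")
exp <- expectedProfile(design, refs, rank = "genus")
weightedDifference(obs, exp)$total
#> [1] 0.00147915
```

Each of the 17 OTUs maps to its own genus at 100% specificity, and the
observed profile sits at a weighted difference of ≈ 0.0015 from the design
— multinomial sampling noise, since every genus is recovered within a few
tenths of a percentage point of its expected 5.88%.

`runPipeline(pipelineConfig(...))` chains the same stages from FASTQ +
mapping + reference files to per-sample OTU tables, assignments, profiles,
distance matrices and a read-accounting report; `inst/scripts/amplitax`
exposes `simulate`, `demux`, `otu`, `classify`, `profile` and `run`
subcommands for shell use.

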