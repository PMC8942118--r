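# pol3occ

Windowed ChIP-seq occupancy quantification at Pol III-transcribed genes.

## The problem

RNA polymerase III transcribes tRNA genes (tDNAs), 5S rRNA, 7SL and other
short non-coding RNAs. tDNAs are short (~70-90 bp) and carry their promoter
elements — the A-box and B-box — *inside* the transcribed region, so the
peak-calling heuristics tuned for Pol II enhancers work poorly there.
Studies of transcription-factor recruitment to these genes (for example,
estrogen receptor α occupancy at tDNAs in breast cancer cells and tumours)
instead quantify ChIP signal in fixed windows anchored at the gene start
and compare those occupancy scores across gene sets and samples.

`pol3occ` packages that workflow for R/Bioconductor users:

* **Q-values** — for a library of `N` DNA fragments and a region with
  strand-aware 5′ start `s`, the occupancy score is

  `Q = (number of fragments overlapping [s - 500, s + 500)) x 10^6 / N`

  i.e. fragments per million in a ±500 bp window (window, anchor and
  normalization are configurable). Regions are ranked by increasing Q,
  thresholded (`Q > 0.5`) into bound sets, and the top-N taken forward.
* **Signal matrices and metagene profiles** — regions × bins RPM matrices
  around the gene centre (±10 kb default) ordered by Q for ranked
  heatmaps, per-bin column means for average-signal overlays, and
  per-base coverage ("filltrack") exports as bedGraph.
* **Motif interrogation** — position weight matrices built from IUPAC
  consensus strings or count matrices; both-strand scanning with exact
  tail p-values computed by dynamic programming over the discretized
  log-odds score distribution. Bundled motifs: the palindromic full ERE
  (`GGTCAnnnTGACC`), the `GGTCA` half site, and the tRNA A-box
  (`TRGCNNARYNNG`) and B-box (`GTTCGANNC`).
* **Assembly liftover** — UCSC chain-based remapping with a strict rule
  (a region remaps only if every base maps to one contiguous target
  interval), reporting the remap rate.
* **Cross-sample comparison** — Venn overlap of bound sets at a Q
  threshold, proliferation/differentiation category tallies for top-bound
  genes, and pairwise Mann-Whitney tests with Holm correction on Q
  distributions.
* **A synthetic ChIP-seq generator** — seeded genomes with annotated
  tDNA/snoRNA/miRNA loci, planted A/B-box elements, an ERE-bearing
  GREB1-like control locus, and fragment libraries with known per-locus
  enrichment, so the whole pipeline is testable without downloads.

Inputs are the standard formats: BED6/UCSC tables for annotations, SAM/BAM
(paired or single-end) or BED for alignments, FASTA for genomes, UCSC
chain files for liftover.

## Worked example

```r
library(pol3occ)

sim <- makeGenome(simConfig(seed = 1))      # synthetic genome + truth
lib <- simulateChip(sim, "mcf7_like", seed = 1)
lib$fragments
#> FragmentSet with 17171 stored fragments (library size 2e+06) source: simulated:mcf7_like

q <- rankRegions(quantifyRegions(lib$fragments, sim@tdna))
tail(qTable(q)[, c("name", "chrom", "start", "strand", "raw", "Q")], 5)
#>         name chrom   start strand raw   Q
#> 396 tRNA-156  chr4 1772743      +  14 7.0
#> 397 tRNA-355  chr1 4022250      +  15 7.5
#> 398 tRNA-244  chr4 2760931      -  15 7.5
#> 399  tRNA-75  chr2  870225      +  16 8.0
#> 400 tRNA-231  chr4 2610754      -  17 8.5

length(boundSet(q, 0.5))        # tDNAs above the binding threshold
#> [1] 247

top <- topRegions(q, 50)        # all 50 top-ranked genes are truly bound
mean(lib$truth$bound[match(names(top), lib$truth$name)])
#> [1] 1
```

The highest-ranked genes reach Q ≈ 7-8 fragments per million versus a
background around 0.5, and the `Q > 0.5` bound set holds the ~200 planted
bound genes plus the expected Poisson leakage from the background. Motif
interrogation reproduces the designed contrast — internal promoter
elements at every tDNA, no ERE near any tDNA, and the planted ERE 585 bp
upstream of the control locus (reported on both strands because the full
ERE is palindromic):

```r
res <- scanNeighborhood(sim@sequence, sim@control["GREB1like"], flank = 20000)
subset(res$hits, motif == "ERE",
       select = c(region, relStart, strand, score, p.value))
#>      region relStart strand    score      p.value
#> 1 GREB1like     -585      - 13.21928 9.536743e-07
#> 2 GREB1like     -585      + 13.21928 9.536743e-07

colSums(scanNeighborhood(sim@sequence, sim@tdna[1:20], flank = 20000)$found)
#>     ERE halfERE    Abox    Bbox
#>       0       0      20      20
```

`runPipeline()` drives the whole chain (simulate or load → quantify →
matrices/profiles → motif scan of top genes → Venn/classification/
comparison) from one declarative list or YAML config and writes a JSON
manifest with MD5 hashes of every artifact.

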