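---
title: "Windowed occupancy at Pol III genes: models, parameters and design"
author: "pol3occ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed occupancy at Pol III genes: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `pol3occ`, the
parameters that matter, the synthetic-data generator and what passing
tests do and do not demonstrate, and the numerical and design choices
made where the design was genuinely open.

## The occupancy model

ChIP-seq enrichment at Pol III-transcribed genes is quantified without
peak calling. A sequencing library is reduced to DNA fragments: properly
mated read pairs become one fragment spanning the template; single-end
reads are extended to a nominal fragment size (default 200 bp, a typical
ChIP sonication size) in the 3′ direction of their strand; BED intervals
are taken verbatim. For a library of $N$ fragments and a gene with
strand-aware 5′ start $s$, the occupancy score is

$$Q \;=\; \frac{10^6}{N}\,\#\{\text{fragments overlapping } [s - u,\; s + d)\}$$

with $u = d = 500$ bp by default. Overlap means at least one shared base;
there is no minimum-overlap parameter. The anchor is the 5′ gene end
because TFIIIB — the initiation factor adjacent to the transcription
start, and the natural tether for transcription factors at tDNAs — sits
there; the gene centre is available as an alternative anchor and is the
default for heatmaps and metagene profiles, where figure conventions
centre short genes in the window. Optional per-kilobase normalization
divides by window length / 1000 and is off by default, matching the
convention that a ±500 bp window is already a fixed size.

Genes are ranked by increasing $Q$ (ties broken by chromosome and start,
so ranking is deterministic), thresholded into "bound" sets by a strict
$Q > 0.5$, and the top-$N$ (50 by default, 19 for the motif stage of the
pipeline) taken into category and motif analyses.

Distributional comparisons between samples use two-sided unpaired
Mann-Whitney tests on the per-gene $Q$ values over a shared gene
universe, with Holm correction across sample pairs and the conventional
0.05/0.01/0.001/0.0001 significance ladder. The rank test is the
defensible default for heavy-tailed occupancy scores; the choice of an
unpaired test is deliberate and documented — occupancy distributions are
compared as samples, not matched gene by gene.

## Motif scanning with exact p-values

Motifs are position weight matrices over A/C/G/T. From an IUPAC
consensus, each position contributes one count split equally over its
compatible bases; a pseudocount (default 0.25) is added per cell and
columns renormalized, so an `N` column equals the background and
contributes zero bits. Scores are summed per-column $\log_2$ odds against
the background (uniform by default); `N` in the *sequence* also scores
zero bits.

Hit significance uses the exact distribution of the score of a
background-generated sequence of the motif's width, computed by dynamic
programming on a discretized score lattice. The reported granularity is
(score range)/1000; internally the lattice step is that granularity
divided by the motif width, so the accumulated rounding error stays below
one reported bin — the tests verify agreement with exhaustive $k$-mer
enumeration at widths 4-6 within one bin. The tail lookup is monotone
non-increasing by construction.

The default reporting threshold is $p \le 5\times 10^{-4}$. This value is
deliberate: the A-box consensus `TRGCNNARYNNG` has five single-base and
three two-base informative columns, so even its perfect match has a tail
probability of $(1/4)^5 (1/2)^3 \approx 1.22\times 10^{-4}$ — a stricter
threshold such as $10^{-4}$ could never report an A-box at all. At
$5\times 10^{-4}$ the A-box is detectable with a 4x margin while the bare
5-bp half-site `GGTCA` (maximum-score tail $\approx 9.8\times 10^{-4}$)
remains undetectable: a 5-mer simply carries too little information to be
called against a 4-letter background, which is why half-site "absence"
in neighborhood reports reflects the scanner's information-theoretic
floor, not a biological claim.

Both strands are scanned; minus-strand hits are scored on the reverse
complement and reported in forward coordinates. The full ERE is
palindromic, so its plus- and minus-strand scores coincide at every
offset — a property the test suite checks and the worked example shows
(the planted control ERE is reported twice, once per strand, at the same
position).

## Assembly liftover

Chain-based remapping uses a strict rule: a region is "successfully
remapped" only if every base maps through one chain to a single
contiguous target interval on one chromosome and strand. Regions that
straddle block gaps, map partially, or map to multiple pieces are
unmapped. This is the strictest reproducible reading of coordinate
remapping between assemblies; the remap rate is reported as
mapped/(mapped + unmapped).

## The synthetic-data generator

The generator exists so every stage is testable without external
downloads; its defaults are the package's reference study conditions.

**Genome.** Four 4.8 Mb chromosomes carry 400 tDNAs, 100 snoRNA and 100
miRNA loci with at least 25 kb between locus starts (so ±10 kb heatmap
windows are clean), plus a dedicated control chromosome with a bound
GREB1-like gene (a full ERE planted 585 bp upstream of its start) and an
unbound BC200-like gene. Background sequence is i.i.d. uniform. Every
tDNA carries an A-box at +8 and a B-box at +52 from its 5′ start
(classic internal-promoter offsets), instantiated from the consensus and
honouring gene strand. Because i.i.d. sequence contains chance near-EREs
at any practical scanning threshold, the generator scrubs the genome
after planting: it scans for ERE-like sites at the default stringency and
mutates one matching informative base per site (avoiding planted motif
footprints), iterating to convergence, before planting the single control
ERE. The "no ERE near tDNAs" property of the synthetic genome therefore
holds by construction, which is exactly its role: a positive control for
the scanner's negative result, not a model of real sequence composition.

**Libraries.** Fragment midpoints follow a mixture of uniform background
over an *effective genome* and per-bound-locus Gaussians (sd 300 bp,
chosen so a ±500 bp window captures ~90% of peak mass) centred on the
strand-aware locus start. Mixture weights are calibrated so that a bound
locus's expected window count — counted the way `quantifyRegions()`
counts, i.e. over an overlap-effective window of window length plus one
mean fragment length — equals `enrichmentFactor` times the background
expectation. Fragment lengths are Normal(200, 40) truncated at 50 bp.
Everything is seeded; identical configuration and seed reproduce
fragment files byte for byte.

The effective genome (default 2.45 Gb, the uniquely mappable human
genome at 36 bp read length, matching the short-read era of the data the
profiles emulate) is the key scale choice: only the annotated
neighborhoods are instantiated as sequence, but the library is spread
over the full effective genome, with `librarySize` counting all
fragments and only those landing on instantiated chromosomes stored.
This puts Q values on the scale of real human ChIP-seq — background
around 0.4-0.5 and bound loci around 4 — so the conventional
$Q > 0.5$ binding threshold is meaningful. A literal toy genome of a few
tens of Mb would put background Q near 60 and make any fixed threshold
vacuous.

**Profiles.** `mcf7_like` binds the genome's bound tDNA subset (half of
all tDNAs by default, 8-fold window enrichment) plus the control locus
(50-fold — canonical ERE-driven targets tower over tDNA signal).
`met3_like` keeps the same bound set with factors multiplied by 3,
emulating a sample with globally elevated tDNA binding. `mda_like` binds
*only* the control locus: it emulates an exogenous-receptor line whose
ChIP mass concentrates at canonical ERE-driven sites, so 80% of its
library is assigned to virtual off-target peaks outside the simulated
loci and its default depth is 2 × 10⁷ fragments; background occupancy
then concentrates well below the 0.5 threshold and no tDNA reaches it,
while the control locus exceeds the tDNA median by ~50-fold.

**What the simulation does not model:** GC or mappability bias,
duplicate fragments, input/control libraries, non-uniform fragment
placement within peaks, or realistic sequence composition. Passing the
recovery tests shows the counting, ranking, calibration and comparison
machinery is correct under a known model — it does not certify
performance on real libraries with structured background.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open on disk (BED convention), 1-based
  inclusive in `GRanges` as usual; displayed coordinates are 1-based.
* Windows and bins are clipped at chromosome starts; bins fully outside
  bounds score zero and are logged.
* Heatmap bins default to 50 bp (401 bins at ±10 kb), fine enough to
  resolve a ~1 kb peak; minus-strand rows are reversed only for
  start-anchored matrices (centre-anchored figures conventionally ignore
  strand).
* Ties in ranking and top-N selection break on (chromosome, start),
  lowest first; `boundSet` uses a strict inequality so $Q = 0.5$ is
  excluded at the default threshold.
* A `QTable` with RPM off contains integer counts; RPM on requires a
  positive library size.
* Zero-fragment libraries are valid everywhere and produce zero scores
  and tracks; empty region sets are a contract error for quantification.
* Mann-Whitney on identical samples returns $p \approx 1$ ("ns") via the
  tie-corrected normal approximation; small untied samples use the exact
  distribution.
* The per-seed batteries in the test suite use problem sizes of 400
  tDNAs and 2 × 10⁶-fragment libraries (stored fragments ~1.7 × 10⁴),
  with 5-seed batteries for stochastic properties; the counting oracle
  runs 200 random instances up to 10⁴ fragments x 10³ regions.

## Known limitations

* Fragment inference for single-end data is an explicit stand-in: the
  extension length is a parameter, not an estimate from the data.
* The liftover rule is stricter than web remapping services, which may
  accept partial or split mappings; remap rates are therefore
  conservative.
* The motif stage scans known motifs only; it does not discover motifs
  de novo, and reported "absence" is always relative to the stated
  threshold and background model.
* Venn overlap supports two or three sets, matching its role of
  comparing bound sets between a handful of samples.
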