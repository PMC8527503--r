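---
title: "Analysing highly heterozygous chromosome-scale genomes with ctenotools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing highly heterozygous chromosome-scale genomes with ctenotools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctenotools)
```

`ctenotools` implements the bespoke analytics that accompany a
chromosome-scale assembly of a highly heterozygous animal genome: estimating
heterozygosity from read pileups conditioned on the modal mapping depth,
detecting genes nested inside the introns of other genes, chaining
reciprocal-best-hit orthologs into microsynteny blocks, scanning for
trans-spliced leader sequences, and testing whether TAD boundaries sit
closer to genes than chance placement predicts.  Every analysis has a
matching seeded simulator that produces inputs with recorded ground truth,
so the full pipeline is testable without any external data.

All coordinates inside the package are 0-based and half-open.  GFF3
(1-based, inclusive) and BED (0-based, half-open) are converted at the file
boundary and nowhere else; this removes the most common silent-bug class in
interval arithmetic.

## Depth-conditioned heterozygosity

A genome assembled as a single composite sequence from a diploid individual
collapses both haplotypes.  When short reads are mapped back, positions
where both haplotypes are represented attract reads from both alleles, so
the genome-wide depth histogram peaks at a modal depth $D^\*$; regions where
only one haplotype maps sit near $D^\*/2$.  At a true heterozygous site at
$D^\*$, about half the reads carry each allele.  The estimator therefore:

1. builds the depth histogram and takes the modal depth (ties resolved to
   the lowest depth, deterministically);
2. keeps only sites with depth exactly $D^\*$ (a `depth_window` flag widens
   the restriction for sparse data);
3. classifies each kept site by its reference-allele fraction
   $f = \mathrm{ref}/\mathrm{depth}$: heterozygous when
   $\ell \le f \le u$, homozygous-reference when $f \ge u$,
   homozygous-alternate when $f \le 1-u$.  The band defaults to
   $[\ell, u] = [0.30, 0.70]$: "half the reads" cannot be exact at odd
   depths, and the band is wide enough to capture essentially all of a
   Binomial$(D^\*, 1/2)$ allele fraction at $D^\* \approx 178$ while
   excluding sequencing-error fractions at realistic error rates.  The band
   is configurable and recorded in CLI run metadata;
4. reports heterozygosity as heterozygous sites divided by **all** sites at
   $D^\*$ — sites falling between the band and the homozygous cutoffs stay
   in the denominator.

Heterozygous sites subtype as indel-supported when reads supporting an
insertion/deletion allele outnumber substitution-supporting reads, and as
SNPs otherwise (ties to SNP, substitutions being the commoner class).
`stratified_het()` assigns every site one region class with precedence
exonic > intronic > intergenic against the strand-collapsed exon and gene
unions, so a base in one gene's exon and another gene's intron counts as
exonic, and emits estimates per (sequence, region, variant class).

The pileup contract is a 6-column TSV (seqid, 1-based position, depth,
reference-supporting reads, substitution-supporting reads,
indel-supporting reads) rather than a binary alignment file, so tests and
small analyses need no aligner.  A practical converter is
`samtools mpileup` piped through an awk/per-site tally that counts `.`/`,`
as reference support, base characters as substitution support, and `+`/`-`
events as indel support; any per-site caller that can emit these six
numbers works.  Quality filtering is the pileup producer's job — the
package deliberately applies none.

## The diploid pileup simulator

`simulate_diploid_pileup()` draws per-site depth from a Poisson around the
configured mean — the depth peak of real short-read data over a good
assembly is unimodal and near-symmetric, and a negative-binomial switch
(`dispersion`) is available when over-dispersion matters.  Each position is
independently a heterozygous SNP (probability `snp_rate`), a heterozygous
indel (`indel_rate`), or homozygous; at heterozygous sites each read comes
from either haplotype with probability 1/2; sequencing errors flip each
read's support to one of the two wrong categories with probability
`error_rate`.  Indels are planted as pileup signal only (reads supporting
an indel allele), never realized in sequence space, because the estimator
consumes pileups only.  Defaults (`mean_depth = 178`, `snp_rate = 0.02`,
`indel_rate = 0.012`, `error_rate = 0.002`) describe a strongly
heterozygous invertebrate genome sequenced to high short-read depth: 2%
SNP heterozygosity and 3.2% combined, the regime the estimator is designed
for.  What the simulator does **not** model — mapping bias, collapsed
repeats, reference error — is exactly what the depth restriction guards
against in real data, so passing tests demonstrate estimator correctness,
not robustness to mis-mapping.

```{r het-example}
sim <- simulate_diploid_pileup(2e5, mean_depth = 178, snp_rate = 0.02,
                               indel_rate = 0.012, error_rate = 0.002,
                               seed = 1)
dh <- depth_histogram(sim$sites)
dh
estimate_het(sim$sites, dh$modal_depth)
```

## Nested intronic genes

A gene is *nested intronic* (NI) when at least one of its transcripts lies
within the span of a single intron of another gene.  Real annotations make
the definition subtle in three places, each resolved as follows:

* **End overlap.**  Nested transcripts may overhang the host intron into
  the flanking exons.  The allowance is 15% of the nested transcript's
  span, applied independently at the 5' and 3' ends, and the overhang must
  actually lie within the exons of the intron-defining transcript.  The
  denominator (nested transcript length, not host exon length) is a
  declared choice; on a 1000 bp transcript, 150 bp of overlap qualifies
  and 151 bp does not, and the test suite pins that boundary.
* **Leader-induced giant introns.**  Trans-spliced leader exons map far
  upstream of gene bodies and create enormous apparent first introns.  The
  longest 0.5% of introns genome-wide (`ceiling(0.005 * N)`) are excluded
  before detection.  At toy scales this exclusion is disabled explicitly
  (`filter_introns(ann, 0)`), since removing `ceiling(0.005 * 3) = 1` of 3
  introns would delete the host intron itself.
* **Multiplicity.**  Intron sets are per-transcript, deduplicated within a
  gene by coordinates; one qualifying transcript suffices; each NI gene is
  reported once with its minimal-span qualifying intron (ties to the
  leftmost, then the lexicographically smallest host).  A gene nested in
  another NI gene's intron has nesting depth 2; depth is capped at 2 in
  reporting.  Orientation relative to the host (parallel/antiparallel) is
  recorded but never filters.

`summarize_nested()` computes the percent of exonic base pairs inside NI
genes on strand-collapsed exon unions, which makes the figure invariant
under transcript duplication.  `te_flanking()` flags NI genes whose flank
segments — host intron start to gene start, and gene end to intron end —
overlap a transposable-element interval by at least 1 bp; the segment is
bounded by the host intron, not a fixed window, because no window size is
canonical.

The detector is validated against a quadratic brute-force oracle (every
gene x transcript x intron triple tested with scalar interval arithmetic)
on hundreds of random annotations, and on generator output where every
planted relation is known.

## Microsynteny and macrosynteny

`reciprocal_best_hits()` reduces two blast-style tables to one-to-one
ortholog pairs: best hit per query by bitscore, ties by lower e-value then
lexicographic subject; duplicate (query, subject) rows keep the
highest-scoring copy.  `collinear_blocks()` chains pairs into blocks under
the 3/5/30 kb rule: at least `min_block = 3` consecutive genes, at most
`max_intervening = 5` annotated genes (matched or not) between consecutive
members, and at most `max_gap = 30000` bp between consecutive members'
gene starts.  Both constraints are enforced on **both** genomes — the
stricter, order-independent reading — and gene position is the span start,
with ordinals assigned per sequence by sorted starts.  Chains may run in
either direction on genome B (inversions preserve collinearity); the
orientation is fixed by the first two members.  Candidate chains are the
maximal constant-direction runs of the A-ordered pair list; where two
candidates share a pair (an orientation flip point), the longer block
wins, then the earlier-starting one.

One caveat is documented rather than hidden: because chaining scans genome
A in order, an adversarial permutation can interleave a chain that is
contiguous in B order with distant-partner pairs in A order, and the two
scan directions can then disagree.  For segment-structured rearrangements
(inversions, relocations — the biological signal the tool targets) the
directions agree exactly, and the test suite verifies both this symmetry
and equality with an exhaustive $O(n^3)$ interval-enumeration oracle on
random instances.

The ortholog simulator lays genes at 12 kb start-to-start spacing so that
adjacent genes chain (12 kb < 30 kb) while excising three or more genes
breaks a chain (>= 48 kb > 30 kb); relocated spans move to a separate B
sequence and their donor coordinates stay unfilled, which is what makes
the planted truth blocks the unique answer under the chaining rule.
`macrosynteny_summary()` emits the Oxford dot-plot table and, per A
sequence, the B sequence receiving the plurality of its pairs — the
structure used to conclude that two karyotypes share chromosomes without
fusions or fissions.

## Trans-spliced leader scanning

Trans-splicing prepends a short leader RNA to mRNAs; in the genome the
leader appears as a shared "first exon", and on cDNA reads as a common 5'
prefix.  `scan_leader_motif()` aligns the 44-bp leader motif semi-globally
(motif end-to-end, free end gaps on the genome side) against both strands,
keeping candidates with identity >= 0.90 and aligned span within
[35, 48] bp.  Identity is matching columns over all alignment columns, so
gaps count against identity — the stricter convention, configurable.
Candidate windows come from an edit-distance pre-filter
(`Biostrings::matchPattern` with indels) whose radius strictly contains
the identity threshold, so no admissible hit is lost; overlapping
candidates reduce to the highest-identity non-overlapping set, ties to the
leftmost.  At the default threshold the decision is sharp: 4 substitutions
in 44 positions (identity 40/44 = 0.909) pass, 5 (39/44 = 0.886) fail.
When an edge base of a planted copy is mutated, an equal-score alignment
may trim that base and shift a boundary by 1 bp; recovery is therefore
judged by locus overlap, not exact endpoints.

`leader_read_fraction()` counts a read as leader-carrying when some motif
suffix of at least `min_suffix = 15` bases matches the read's 5' end
ungapped with at most 10% mismatches (both read orientations tested).
Fifteen bases keep chance matches rare (a random 15-mer hits ~1 in 10^9
per position even before the identity requirement) while tolerating the
5' shearing common in full-length cDNA preparation — which is also why a
measured read fraction is a lower bound on the true trans-splicing rate.
`shared_first_exon_clusters()` groups genes whose transcript-orientation
first exon matches the motif by the genomic leader locus they share, and
`start_dinucleotide_census()` tallies transcript start dinucleotides over
unambiguous sequences.

The leader simulator plants copies at non-overlapping uniform loci on
random strands in an i.i.d. uniform ACGT background, each mutated at
`ceiling(divergence * 44)` distinct positions.  A uniform background is a
deliberate simplification: the consuming decision is a per-window identity
threshold, and low-complexity or repetitive sequence would only matter for
a motif far shorter or more degenerate than this one.

## TAD boundaries and gene proximity

Each TAD contributes two boundary points (coordinates shared by adjacent
TADs count once).  A boundary inside a gene span — including exactly at a
gene edge — scores distance 0; otherwise the distance to the nearest gene
start or end on that chromosome; chromosomes without genes score the
chromosome length and are flagged.  `tad_permutation_test()` re-places the
observed TADs `n` times, preserving their lengths: a chromosome is chosen
with probability proportional to its length among those the TAD fits, the
start uniformly in `[0, chrom_len - tad_len]`, and placed TADs may overlap
(no exclusion constraint is imposed, because overlap-free packing changes
the null subtly).  The one-sided p-value for "boundaries closer than
expected" uses the add-one correction
$p = (\#\{\text{null} \le \text{observed}\} + 1)/(n + 1)$, so
$p \in [1/(n+1), 1]$ and $p = 0.001$ is the attainable minimum at
$n = 999$.  A distance-to-TSS-only mode is available behind a flag.

The landscape simulator places genes with irregular lengths and gaps
(uniform +/-40% jitter around 2 kb genes and 8 kb gaps, ~20% genic
coverage) precisely so gene edges carry no lattice a random placement
could phase-lock to; boundaries are planted at exact offsets from real
gene ends, and TAD lengths are honored up to the local gene spacing (the
end boundary snaps to the gene end nearest `start + length`).  With the
default 60 kb TADs the emitted length median lands within one mean gene
spacing of 60 kb.  Calibration is part of the test suite: with planted
offset 0 the test attains its minimum p-value; with uniformly placed TADs
the null rejects at 5% no more than its nominal rate.

## Small utilities

`physical_coverage()` is the fold-coverage sum
$\sum_i \text{bases}_i / \text{genome size}$, reported to one decimal and
additive over library sets.  `pairwise_identity()` is an end-to-end global
alignment (match +1, mismatch -1, gap open -2, gap extend -0.5 — declared
defaults, since percent-identity figures in the literature rarely state
their alignment model) with identity counted over all alignment columns.
Both the defaults and the column-counting convention are configurable, and
the implementation is cross-checked against an independent affine-gap
dynamic-programming oracle in the test suite.

## Numerical and design choices, in one place

* Modal depth ties break to the lowest depth; het subtype ties to SNP;
  best-hit ties to lower e-value then subject id; block conflicts to the
  longer then earlier block; overlapping motif hits to higher identity
  then leftmost.  Every tie-break is deterministic.
* Generators draw all randomness from a single seeded stream per
  invocation and restore the caller's RNG state; identical seed and
  configuration give identical output.
* Degenerate inputs: empty pileups, empty TAD sets, and genes without
  exons raise errors or are skipped-and-counted as documented; zero-length
  TE flank segments are "not flanked" rather than errors.
* Test problem sizes are chosen desk-scale — 1 Mb pileups (20 seeds for
  recovery properties), <= 50-gene annotations against quadratic oracles,
  <= 20-gene synteny instances against cubic enumeration, 1 Mb leader
  scans, and permutation tests at n = 999 with 100-seed calibration at
  smaller n.

## Limitations

The simulators validate algorithmic correctness, not robustness to the
failure modes of real data: mis-mapping near indels (which depresses
measurable heterozygosity in noncoding regions of real genomes),
fragmented or haplotype-redundant annotations (which inflate NI and RBH
counts), and assembly gaps (whose treatment in the heterozygosity
denominator is a genuine open question) are all outside the generators'
scope.  Reproducing published genome-wide figures — total NI counts,
genome-wide leader copy numbers, or the identity of two real
mitochondrial genomes — requires the corresponding deposited data as
input; the package computes those quantities but ships no external data.
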