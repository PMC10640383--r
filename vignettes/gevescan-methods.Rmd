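---
title: "Detecting and characterizing giant endogenous viral elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing giant endogenous viral elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gevescan)
```

## The problem

Giant viruses (*Nucleocytoviricota*, dsDNA genomes of 70 kb to 2.5 Mb)
occasionally integrate into eukaryotic chromosomes. Such a giant
endogenous viral element (GEVE) can span more than a megabase, carries
hundreds of viral genes in various states of decay, and differs from its
host chromosome in composition (GC content, repeat density, coding
structure). `gevescan` implements the computational side of a GEVE
study: calling the element from per-ORF homology scores, validating that
it is a chromosomal insertion rather than an assembly artifact or an
episome, and annotating the decay of its genes. Because real chromosomes
and read sets are too large for routine testing, the package includes a
synthetic endogenization generator whose ground truth drives the entire
test suite.

## Region calling model

Each ORF on a chromosome receives a raw score

$$s_i = b^{viral}_i - b^{cellular}_i,$$

the difference between its best viral-database and best
cellular-database HMM bitscores (absent scores count as 0). The track is
smoothed with a centered rolling mean over a window of $w$ ORFs
(default $w = 150$), truncated at chromosome ends so every ORF gets a
value. Maximal runs of ORFs with rolling score strictly greater than a
threshold $s$ (default 0) are reported as viral regions spanning
first-ORF start to last-ORF end.

Choices worth noting:

* The difference-of-best-hits raw score is the simplest faithful
  combination of the two score sources; upstream HMM-scan tools do not
  standardize how the two databases are aggregated, so the formula is a
  declared, replaceable choice.
* Windows are truncated, not NA-padded, so calls can reach chromosome
  ends.
* The threshold is strict (`>`), which makes "all scores equal to the
  threshold" produce no calls, and makes calls invariant under adding a
  constant to both scores and threshold.
* When the two score populations are symmetric (viral ORFs at $+c$,
  cellular at $-c$), the rolling mean crosses 0 within a few ORFs of the
  true boundary, so boundary error is a handful of ORFs rather than
  $w/2$.

Per-region summaries attach GC (windowed profile, default 50 kb windows
to damp repeat effects; N bases are excluded from denominators and an
all-N window is NA, not 0), coding density (union of ORF intervals over
region length) and a marker-gene tally (membership by interval midpoint,
robust to markers straddling a called boundary).

## Insertion validation

Four independent lines of evidence, mirroring how endogenization is
argued for in practice:

* **Junction-spanning reads.** A read witnesses a boundary iff a single
  contiguous alignment covers at least `min_anchor` bp (default 1,000,
  above typical repeat-unit scale) strictly inside and strictly outside
  the region across that boundary. Split-read chaining is deliberately
  out of scope: the evidence class is a single long read across the
  junction.
* **Coverage uniformity.** Per-bin (default 1 kb) mean depth; a
  single-copy chromosomal insertion has a region/complement depth ratio
  near 1, while an unintegrated high-copy element or collapsed repeat
  does not.
* **Contact enrichment.** Given a pre-normalized Hi-C contact matrix
  (consumed, never produced), the mean contact over bin pairs fully
  inside the region (diagonal excluded) is compared with pairs fully
  outside.
* **Cross-strain comparison.** Windows of strain A are declared present
  in strain B iff they share at least `min_shared` distinct amino-acid
  k-mers with B's six-frame index; runs of absent windows are candidate
  strain-specific insertions. Exact k-mer matching replaces tBLASTx to
  stay deterministic and dependency-free. The k-mer length defaults to
  12 because the chance collision expectation per 5-kb window is
  roughly $10^4 \cdot |B| \cdot 0.06^k$: at $k = 6$ this saturates
  against any chromosome-scale index (every window "matches"), while at
  $k = 12$ it stays far below 1 even for a 100-Mb genome, and
  near-identical strain sequence still shares thousands of exact
  12-mers per window.

## Decay annotation

STOP-to-STOP ORFs (maximal inter-stop stretches in all six frames,
stops TAA/TAG/TGA, default minimum 50 aa) recover coding sequence that
ab initio callers miss in decayed regions. Intervals exclude the stop
codons and are trimmed to whole codons so residue counts map exactly
onto interval lengths; codons containing N never count as stops
(conservative). Candidates that overlap a primary gene call by more
than half their length are pruned (strand-agnostic, per-record).

Fragmented ORFs are clustered when they are neighbors on the same
strand (gap at most 5 kb), share the same best-hit subject, and cover
the subject collinearly without nesting. A cluster is classified as an
**intron candidate** iff every junction between adjacent members has
(a) contiguous subject coverage (gap/overlap at most 10 residues) and
(b) a GT..AG splice motif on the coding strand of the inter-member gap;
otherwise it is a **pseudogene**, with each junction labeled frameshift
(coding phase differs), stop gain (same phase, in-frame stop in the
gap) or gap.

One refinement matters in practice: the junction gap is measured
between the *subject-alignment-projected* blocks of the members, not
between the raw ORF intervals. A STOP-to-STOP fragment overruns an
intron boundary until the first in-frame stop inside the intron, so the
raw ORF gap almost never begins at the GT donor; the aligned block ends
at the last residue that matches the subject, which is the exon
boundary up to local-alignment end fuzziness. A ±6 bp slack window
absorbs that fuzziness, and gaps shorter than 4 bp (where GT..AG cannot
fit) are never introns. This projected-gap criterion is the package's
automated surrogate for the manual dot-plot plus exon-model
inspection traditionally used to curate decayed viral genes.

Each STOP-to-STOP ORF is annotated by its *own* reading-frame
translation, not a six-frame search of its window: overlapping ORFs
from other frames or strands would otherwise pick up a real gene's
protein through a cross-frame translation of the same nucleotides, and
every intact gene would masquerade as a fragment cluster (observed as a
precision collapse, 0.56, before this restriction).

Intergenic queries, which have no intrinsic frame, use the full
translated search: six-frame translation,
Smith–Waterman local alignment (BLOSUM62, gap open 11, extend 1) and
Karlin–Altschul E-values $E = K m n e^{-\lambda S}$ with the standard
gapped BLOSUM62 parameters ($\lambda = 0.267$, $K = 0.041$) and $n$ the
total database residues. The module contract aligns every frame against
every protein; an optional exact k-mer seeding prefilter
(`prefilter_k`, off by default) skips pairs sharing no seed, the same
trick production aligners use, and is enabled inside the decay pipeline
for speed. E-value thresholds, not scores, are the contract: the search
is not a bit-for-bit DIAMOND emulation.

Intergenic regions (uncovered stretches of at least 100 bp; a gap of
exactly 100 bp is kept) are searched the same way to count gene traces,
reported as counts and 1-decimal percentages per database and their
intersection. Repeat/TE density decomposes region coverage into coding
and non-coding components that sum to the total exactly (all fractions
share the region length as denominator).

## The synthetic world

The generator emulates the statistical structure of a GEVE-bearing
chromosome: a low-GC host chromosome (default 28% GC, 5 Mb, half
covered by tandem repeat tracts) carrying a single contiguous higher-GC
insert (default 37% GC, 1.5 Mb) whose genes decay in place, uniform
long-read coverage across the junctions, and per-ORF scores elevated
inside the insert.

* **Background sequence** is i.i.d. with $P(G) = P(C) = gc/2$ — GC is
  the only compositional statistic the analysis uses.
* **Genes** are stop-free codon sequences. Rejecting stop codons (which
  are AT-rich) would push realized GC above target, so codons are
  sampled at a corrected base composition solving
  $E[\mathrm{GC} \mid \text{non-stop}] = gc$; realized insert GC lands
  within ±0.005 of target at these scales. Pre-decay gene length
  defaults to 1,050 bp, a typical large-dsDNA-virus gene; gene count
  defaults to a 36% coding target.
* **Decay** applies, in a fixed order for reproducibility (deletions,
  frameshifts, stop gains, intron insertions), per-gene events at
  configurable rates. No decay rates are documented for real GEVEs;
  the defaults (stop gain 0.0015/codon, frameshift 0.08/gene,
  deletion 0.04/gene, intron 0.08/gene, introns 50–400 bp) were chosen
  once to give a heavily decayed but still recognizable element —
  roughly half the genes carry at least one disruption — matching the
  qualitative picture of a region whose non-coding majority derives
  from decayed genes. Every event is recorded in the ground truth, and
  pre-decay protein translations are kept as the homology database.
* **Reads** are sampled uniformly (forward strand by default; strand is
  irrelevant to junction logic) with normal lengths, substitution
  errors only, and their true intervals emitted as PAF. Depth is
  defined as total read bases over genome size. No indel error model:
  read indels would only blur alignment coordinates the package
  consumes as given.
* **Scores** for insert genes draw viral bitscores around a high mean
  and cellular bitscores around a low mean (host ORFs the reverse),
  normal with common sd, floored at 0.

What a green test does *not* establish: real chromosomes are not
i.i.d.; repeats are not clean tandem copies; decay in nature includes
large-scale rearrangement and secondary host-gene insertion; real read
error includes indels; and real HMM bitscores are not Gaussian. The
synthetic world tests the *logic* of detection, validation and decay
annotation against exact ground truth — it cannot certify performance
on real genomes.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally; BED output
  converts to 0-based half-open, PAF keeps its native convention.
* An ORF's residue length is `floor(interval/3)`; intervals are trimmed
  to whole codons so the identity is exact.
* A window of all Ns yields NA GC, never 0. A region covering its whole
  contig has NA complement GC. A zero-coverage complement flags the
  coverage ratio NA rather than dividing by zero.
* Overlap pruning keeps a candidate at exactly the threshold (strictly
  greater removes); intergenic extraction keeps a gap of exactly the
  minimum length; region calling requires strictly positive excess over
  the threshold.
* All generators are deterministic per seed and restore the caller's
  RNG state.

## Known limitations

* Pseudogene recall is bounded by the ≥ 2-fragments-of-≥ 50-aa
  requirement: a disruption within 50 codons of a gene end leaves a
  single detectable fragment and the gene is invisible to clustering.
* Junction evidence ignores split alignments, so a breakpoint inside a
  long repeat (anchors shorter than `min_anchor`) is undetectable by
  design.
* The translated search is exhaustive Smith–Waterman per pair; with the
  seeding prefilter off it scales as queries × database and is meant
  for region-scale, not proteome-scale, databases.
* Cross-strain comparison assumes near-identity between strains; exact
  k-mers at k = 12 will not detect diverged homology the way tBLASTx
  would.
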