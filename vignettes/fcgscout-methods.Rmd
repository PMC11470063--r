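---
title: "Methods: detecting an X-to-Y translocation in FCG mice from synthetic multi-omic data"
author: "fcgscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting an X-to-Y translocation in FCG mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Background and scope

The Four Core Genotypes (FCG) mouse model decouples gonadal sex from sex-chromosome
complement by moving *Sry* off the Y chromosome, yielding XX and XY animals with
either ovaries (O) or testes (T). In the C57BL/6J FCG line, a ~3.2 Mb segment of
the X chromosome adjacent to the pseudoautosomal region (PAR) — spanning nine
annotated genes (*Tmsb4x*, *Tlr8*, *Tlr7*, *Prps2*, *Frmpd4*, *Msl3*, *Arhgap6*,
*Amelx*, *Hccs*) — is duplicated and fused onto the Y^Sry-^ chromosome, near
chrY:90.21 Mb, inside an L1 repeat. The consequence is a doubled dosage of these
genes in every XY FCG animal, confounding sex-chromosome-complement contrasts.

`fcgscout` re-implements, as a tested and reusable pipeline, the inference chain
by which such an event can be discovered and characterised:

1. **Dosage testing** of chrX genes in pseudo-bulked single-cell UMI counts
   (negative-binomial Wald test, XY vs XX within a gonadal group, BH FDR 10%).
2. **Coverage CNV calling** from windowed WGS read depth normalised to the
   autosomal median.
3. **Parental-origin inference** from haplotype-resolved coverage in an
   F1 B6 x CAST cross, where the X is maternal (CAST) and any paternal (B6)
   signal inside the duplicated interval betrays a copy travelling with the
   paternal Y.
4. **Breakpoint localisation** from split long-read alignments clustered into
   consensus junction calls, annotated with overlapping repeats.
5. **sci-RNA-seq3 demultiplexing** (four-barcode hamming-1 whitelist matching
   with 48-nt read rewriting) and **DNA-FISH spot quantification** (X-domain
   counts, Y-to-nearest-X distances).

Everything runs on synthetic data with known ground truth; a small exact-seed
read mapper closes the loop so no external aligner is needed.

## The synthetic genome and what it emulates

The toy genome is a ~1/1000 linear scaling of the real coordinates: chrX is
170 kb with a 1 kb distal PAR, the duplication interval is 3,220 bp
(matching the printed real interval chrX:165.53–168.75 Mb after scaling) and
abuts the PAR; chrY is 91.7 kb with the integration site at position 90,210
(scaling chrY:90.21 Mb); chrA is a 100 kb autosome. Nine genes sit inside the
duplication interval, two more proximally on chrX, and thirty on chrA. Three
identical copies of a 400 bp "L1-like" repeat are interspersed on the three
contigs; the chrY copy is centred on the junction site, so the translocation
boundary falls inside a repeat, as in the real event. The PAR is the same
sequence on chrX and chrY (it recombines and is effectively shared).

Carrier haplotypes insert a copy of the B6 (reference) duplication-interval
sequence into the paternal chrY at the junction site. In the F1 cross the
maternal genome carries CAST alleles at strain SNPs; the SNP rate defaults to
0.007/bp, the approximate genome-wide B6-vs-CAST divergence (~1 SNP per
140 bp). No SNPs are placed in the PAR.

Deliberate simplifications (hence what passing tests do *not* show about real
data): substitution-only sequencing errors (no indels), uniform fragment
sampling (no GC bias or mappability structure beyond the planted repeats), a
single celltype layer with an on/off expression mask (no continuous cell-type
variation, doublets or ambient RNA), and clean Mendelian haplotypes.

## Read simulation and the depth convention

`simulate_wgs_reads(depth = d)` targets d-fold coverage over diploid regions:
each haplotype copy is sampled at d/2, so a male chrX sits at d/2 and
normalises to 0.5 against the autosomal median — the copy-number arithmetic
the CNV caller relies on. Long reads are gamma-distributed in length
(shape 3, mean 3 kb by default, a 1/10 scaling of typical nanopore reads) at
30x. Paired reads are mapped and written as unpaired SAM records; coverage
uses primary-record midpoints, so mate information is never needed
downstream.

## The toy mapper

Unique reference 21-mers anchor reads. Reads whose seed hits form one
collinear group (same contig and diagonal) are accepted as full-length
matches — mismatches are tolerated inside the block, which is how
error-perturbed reads map without an explicit alignment model. Reads with two
seed groups are resolved into primary + supplementary split records by exact
base-level extension from each anchor; because extension is per-base, the
X–Y fusion junction is recovered at single-base resolution even though it
sits inside a repeat (unique seeds beyond the repeat anchor the extension
through it). Reads whose every seed is repeated — drawn wholly from an
L1-like copy or from the PAR — are reported unmapped. One consequence worth
knowing: a short read whose tail crosses an insertion boundary can be
force-aligned full-length to the dominant side, and misaligned tail bases
occasionally mimic the other strain's allele at a SNP; the haplotype module
classifies such reads as `conflicting` (their own category, excluded from
the paternal fraction), so the effect is quarantined.

## Dosage testing

Cells with fewer than 500 UMIs or 500 detected genes are removed at full
scale; the toy gene panel (41 genes) uses scaled thresholds (200 UMIs, 25
genes). Cells whose total UMI count exceeds the outlier rule are flagged; the
default rule is mean + 3 SD, with the literal product form (mean x 3 SD)
available by configuration, because the printed formula is dimensionally odd
and both readings are defensible. Raw counts are summed per mouse
(pseudo-bulk); genes with fewer than 10 reads in *any* sample are removed
(per-sample minimum reading; a total-count mode exists). Size factors are
median-of-ratios: the per-sample median over reference genes (nonzero in all
samples) of the count divided by the gene's geometric mean.

Per gene, a two-group negative-binomial log-link model with size-factor
offsets and fixed dispersion is fitted by iteratively reweighted least
squares; the Wald statistic is log2FC/SE with a two-sided normal p-value.
Only chrX genes are tested and BH-corrected (FDR 10%), mirroring the reduced
multiple-testing burden of the original analysis.

**Dispersion.** The raw estimator is per-gene method-of-moments on
normalised counts, pooled within groups, floored at 1e-8. At three mice per
group this raw estimator is noisy, and when it undershoots it inflates the
Wald statistic: in 200-replicate null simulations the empirical FDR was 0.16
at the 0.10 threshold. The pipeline therefore applies mild information
sharing across genes (`moderate = TRUE`): every gene's dispersion is floored
at the across-gene median raw estimate, in the spirit of the moderated
estimators used by DESeq2 and edgeR. With moderation the null FDR is ~0.07
and fold-change recovery is unaffected (~1.94 for a true 2.0). The
unmoderated estimator remains the default of `estimate_dispersion()` itself.

**Region calling.** chrX genes are ordered by coordinate; the call is the
longest run of significant upregulated genes in which at most `max_skip`
*untested or unexpressed* genes are bridged (default 1 — so a gene silenced
in the analysed cell type, like *Tlr7*/*Tlr8* in hepatocytes, does not split
the cluster), while a tested non-significant gene always breaks the run. In
the integrated report a "dosage event" requires at least two significant
genes in the run: a single significant chrX gene is an expected BH false
positive at FDR 10% over eleven tests and should not flip a control cohort's
verdict.

## Coverage CNV calling

Each mapped primary record adds one count to the window containing its
alignment midpoint (midpoint counting is depth-proportional and
window-exact; a per-base mode is not needed for these tests). Windows of
1 kb are the default, as in the original tracks; every window is divided by
the median count of full autosomal windows, so diploid sequence sits at 1.0
and single-copy male chrX at 0.5. Candidate duplication windows exceed the
midpoint between the contig baseline and one extra copy (baseline + 0.25);
candidate runs are merged across at most one sub-threshold window and
reported when spanning at least three windows. The PAR is excluded from
candidacy (it is diploid in males and, in this toy, unmappable anyway).
Threshold segmentation rather than CBS/HMM is a deliberate simplification:
the event is a single clean duplication; the caller is not meant for
multi-state CNV landscapes.

## Haplotype-resolved origin

Reads are assigned to parental strains by the SNP alleles their aligned
block covers: all informative bases B6 gives paternal, all CAST maternal, a
mixture conflicting, none unassigned; bases matching neither allele are
ignored as sequencing errors. Windows report the bounded paternal fraction
B6/(B6+CAST) where at least `min_informative = 5` strain-informative reads
are present (variance control at toy depths). On the maternally inherited
single-copy X the fraction is ~0; where a paternal B6 copy coexists (the
duplicated interval, in reference coordinates) it is ~0.5. The origin call
compares the mean fraction over windows *fully contained* in the queried
interval (partial edge windows dilute the signal) with the rest of the
contig: paternal-duplication requires inside >= 0.3 and outside <= 0.1.

## Breakpoint clustering

Each read whose primary and supplementary records sit on two contigs yields
one junction-evidence point: the last reference base of the left block and
the first of the right block, in read orientation. The insertion has two
boundaries, so carrier evidence forms two clusters: "XY" orientation at
(duplication end - 1, junction site) and "YX" at (duplication start,
junction site - 1); either localises the fusion. Single-linkage clustering
(Chebyshev radius 50 bp) per orientation, per-side median consensus, minimum
support 3. The Y-side consensus +/- radius is intersected with the repeat
annotation — reproducing the observation that the real boundary lies in an
L1 element.

## Demultiplexing

Barcodes are extracted at fixed R1 offsets (p7 0–10, p5 10–20, ligation
20–29/30, RT next 10, UMI final 8) and matched at hamming distance <= 1;
ambiguous hamming-1 matches are discarded (the conservative choice — the
source protocol does not state this case). 9-nt ligation barcodes are padded
with a G and the whitelist gains the padded aliases. The 9-vs-10 nt width
decision cannot be made from the ligation window alone: for a true 9-nt
read, the 10-nt window (ligation + first RT base) is *always* within
hamming distance 1 of the G-padded alias, so committing to the first
matching width would shift the RT frame for every such read. Frames are
therefore resolved jointly — a frame is accepted only when both its ligation
and its RT window match, trying the 10-nt frame first; both frames matching
different entries is discarded as ambiguous. Assigned reads are rewritten to
the whitelisted barcode sequences plus UMI, always 48 nt; rewritten base
qualities are copied where positions align, with 'I' for the padded G.

## FISH quantification

Input is a spot-centroid table (cell, genotype, domain type, x/y/z in µm);
image segmentation is upstream and out of scope. X-domain counts give exact
histograms and percentages; the two-domain fraction in simulation is
allocated deterministically (floor of fraction x n, randomised order) so
headline percentages reproduce exactly. Distances are 3D Euclidean from the
Y centroid to the nearest X centroid (a 2D projected option exists, since
the original projection is not stated); medians and SDs are reported. The
simulator places the translocated X domain at a near distance
(mean 0.8 µm, SD 0.3 µm) of the Y territory inside a 10 x 10 x 5 µm nucleus
box — values chosen once as a plausible sub-micron colocalisation scale.

## Orchestration, seeds and problem sizes

`run_full()` executes the whole chain and integrates the evidence: the
verdict is "concordant translocation" when the dosage region lies inside the
CNV call (± one window), the XY breakpoint sits at the CNV edge (± one
window), and (on F1 backgrounds) the origin verdict is paternal-duplication;
"no event" when all lines are silent; "discordant evidence" otherwise.
Every stage consumes a sub-seed derived from the root seed and the stage
name, so stages are independently reproducible; reports carry the seeds and
a configuration hash, and contain no timestamps, so identical runs are
byte-identical.

Default study conditions (also used by the test suite and the acceptance
script): 1/1000-scale genome, 3 mice per genotype group and 200 cells per
mouse for dosage (the per-group count is a modelling choice — the original
study does not state it), 20x WGS and 30x long reads for the genomic lines,
10 seeds for fold-change recovery, 200 null simulations for FDR, 50 seeds
for CNV-boundary and breakpoint recovery.

## Known limitations

* Threshold CNV segmentation assumes one clean duplication per contig.
* The mapper is exact-match seeded: highly diverged or indel-containing
  reads are out of scope, and PAR reads are unmappable by construction.
* Dispersion moderation trades a little power for FDR control at n = 3;
  with more replicates the raw per-gene estimator becomes preferable.
* FISH distances ignore voxel anisotropy (centroids are assumed pre-scaled).
* Haplotype inference assumes the cross phase is known (F1 design), not
  estimated from data.
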