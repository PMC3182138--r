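---
title: "Methods: miRNA discovery and digital expression with droughtmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery and digital expression with droughtmiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

droughtmiR implements a complete small RNA sequencing workflow for microRNA
gene discovery and digital differential expression, of the kind used to
compare miRNA expression between plant genotypes under control and drought
conditions. This vignette is the package's account of the underlying models
and of the design choices made where the procedure was genuinely open.

## The discovery model

Plant miRNAs are 20-24 nt RNAs excised by Dicer-like enzymes from precursors
that fold into stem-loop (hairpin) structures. Discovery from deep-sequenced
small RNA libraries rests on two signals: the genomic neighborhood of an
abundantly sequenced read must fold into a qualifying hairpin, and the read
stack at the locus must look like precise Dicer processing rather than random
degradation.

The pipeline proceeds in stages:

1. **Read cleaning.** A raw read is kept only if it contains a clear 3'
   adapter occurrence (exact match of the adapter's first 8 bases,
   configurable); the insert before the adapter must be at least 18 nt.
   Inserts are collapsed to unique reads with per-library counts. All
   internal sequence handling is on the DNA alphabet (U normalized to T at
   ingest); matures are reported as RNA. Reads matching annotated rRNA,
   tRNA, snRNA, snoRNA or repeat sequences on either strand are removed
   (exact matching, mirroring the perfect-match mapping policy; the
   contaminant-matching stringency is exposed for sensitivity analysis).
2. **Anchoring and windows.** Unique reads with at least 10 copies summed
   over all libraries are anchors. Anchors are mapped to each reference set
   with perfect matching, and candidate precursor windows of 100-300 nt
   (20 nt steps) are sampled around each hit with 10 bp of flank beyond the
   read on the anchored side, for both anchorings. Windows clipped by the
   reference edge below 100 nt are dropped. Coordinates are 0-based,
   half-open throughout; minus-strand hits report the plus-strand interval.
3. **Folding.** Each window is folded with the bundled minimum-free-energy
   engine (below), or with ViennaRNA's RNAfold through the pluggable backend
   interface.
4. **Star inference.** The star (miRNA\*) is the region paired opposite the
   mature in the MFE structure, shifted to model the canonical 2-nt 3'
   overhangs on both duplex strands. Candidates whose mature is less than
   60% paired, or pairs with itself (mature in the terminal loop), fail.
5. **Five annotation criteria.** A candidate becomes a gene only if:
   the folding free energy is at most -35 kcal/mol; the mature:star duplex
   has at most 4 mismatches (unpaired mature positions within the paired
   span); the mature-star stem has at most one asymmetric bulge of size at
   most 2; at least 80% of window-mapped reads lie on the hairpin's
   transcribed strand; and at least 75% of sense reads fall within the
   mature or star regions extended by 2 nt (precise processing). Each read
   counts once per window even when it maps the window several times — a
   perfectly complementary duplex otherwise makes the mature read map
   antisense at its own star arm and deterministically halves the strand
   bias of genuine loci.
6. **Best hairpin per region and redundancy removal.** Candidates whose
   mature loci overlap on the same reference strand are alternative hairpins
   for one gene; the winner has the highest mature expression, then the
   lowest free energy, then the shortest window, then the leftmost start (a
   final deterministic tie-break). We group by overlapping *mature loci*
   rather than overlapping windows: 300-nt windows from adjacent but
   independent loci frequently overlap, and window-level grouping collapses
   genuinely distinct genes. Across reference sets — whose coordinates are
   not comparable — genes with identical matures and identical, contained,
   or >= 90%-identical precursors merge, keeping the best-ranked candidate;
   within one set, distinct loci sharing a mature stay distinct genes
   (homologous gene copies).

Thresholds are all configurable through `mirna_criteria()`. Note the -35
kcal/mol threshold is defined with respect to a folding backend; absolute
energies differ between backends, so the backend-agreement contract is
pass/fail concordance at the threshold, not energy equality.

## The bundled folding engine

`fold_rna()` implements a Zuker-style nearest-neighbor dynamic program in
C++: Turner-style stacking energies for Watson-Crick and G:U pairs,
length-dependent hairpin/bulge/internal-loop penalties, an affine multiloop
model, a terminal AU/GU penalty, and no pseudoknots. Internal loops are
capped at 12 unpaired nucleotides total (larger loops are irrelevant to
qualifying hairpins and the cap keeps folding of a 300-nt window well under
0.1 s). The engine returns one MFE structure as dot-bracket plus a pairing
table. On hairpins with stems of 8-45 bp the engine's pass/fail call at
-35 kcal/mol agrees with RNAfold in >= 90% of cases (tested); energies track
within a few kcal/mol on clean stems.

## Family annotation

Matures are clustered by single linkage: two matures join when their
alignment distance is at most 2, where distance counts substitutions plus
indel columns in the optimal unit-cost alignment (the Levenshtein distance;
counting indels as mismatches makes the 2-mismatch rule total over unequal
lengths). Clusters take the family number of the closest reference mature
within 2 mismatches of any member — ties resolved by smallest distance, then
lexicographically first family name, a deterministic rule where common
practice is silent — otherwise they are named as new families
(`vun_cand001`, `vun_cand002`, ... in first-discovery order).

## Target prediction

Candidate sites are found by exhaustive alignment of the mature against
every transcript window: the ungapped configuration and every placement of
one single-nucleotide bulge (on either side). Alignments with two or more
bulged/gapped nucleotides can never be accepted, so this enumeration is a
guaranteed superset of the acceptable duplexes (a heuristic pre-scanner
could drop sites the penalty scheme would accept; exhaustive enumeration
cannot). Scoring divides the duplex into a core region (miRNA positions
2-13 from the 5' end; position 1 is general) and a general region:
mismatches and single-nucleotide bulges or gaps score 1, G:U pairs 0.5, and
scores double in the core. A target-side bulge has no miRNA position and is
classified by the adjacent miRNA position on its 3' side. A site is accepted
when the penalty is at most 4 and the total number of bulges and gaps is
less than 2.

## Digital expression

Counts of each unique mature (the active form; identical matures may derive
from several genes) are normalized to transcripts per ten million:
TPTM = count / library total x 1e7. Differential expression between a
drought library (total N2, count y) and its control (total N1, count x)
uses the Audic-Claverie conditional distribution

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!}\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

which is a negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$ — the package uses that identity only as an independent
cross-check. The two-tailed p-value is $2q$ with
$q = \sum_{y' \le y} p(y'\mid x)$, or $2(1-q)$ when $q > 0.5$. Numerically,
$q$ is a log-space cumulative sum; the $1-q$ branch sums the upper tail
directly, because complementing a cumulative near 1 destroys all relative
precision of small p-values (a naive $2(1-q)$ is wrong by many orders of
magnitude for strongly regulated miRNAs). Above $x+y = 10^4$ the closed
negative-binomial cumulative is used; the two representations agree to
numerical precision and the p-value is continuous across the switch.
Bonferroni adjustment multiplies by the number of matures tested per
comparison (the multiplier is configurable).

A mature is called drought-associated when (1) the adjusted p-value is below
0.01 in at least one genotype comparison, (2) TPTM reaches 100 in at least
one of the four libraries, and (3) the drought/control log2 ratio exceeds 1
in magnitude in at least one genotype. Ratios undefined because of a zero
count are NA: they never satisfy a fold-change check themselves, but the
other genotype can still qualify the mature. The direction of association
comes from the genotype(s) passing criterion (1); records significant in
both genotypes with opposite signs are flagged discordant rather than
resolved. The separate two-fold pattern (`both` / `only_gA` / `only_gB` /
`neither`) uses $|\log_2| \ge 1$ per genotype — "at least two-fold" — which
is deliberately not identical to criterion (3)'s strict inequality.

PCA runs on column-centered $\log_2(\mathrm{TPTM} + 1)$ of matures with at
least 50 combined TPTM, with libraries as observations. The pseudocount of
1 TPTM handles the zeros that genotype-specific miRNAs produce. Because the
rule "miRNAs accounting for 75% of PC1 variance" admits several
loading-cumulation readings, the package reports matures ranked by squared
PC1 loading with cumulative fractions and leaves the cut to the user.

For the SNP re-mapping check (is apparent genotype-specific expression an
artifact of perfect-match mapping?), `quantify_mature()` has a
one-mismatch-to-precursor mode counting reads that map to the precursor's
mature interval (within 2 nt of its boundaries) with at most one
substitution.

## The synthetic study and what it does (not) show

`synthetic_design()` fixes the simulated study: 20 planted miRNA genes on
one synthetic contig, four libraries of 2e5 reads (2 genotypes x 2
conditions), 4 genotype-specific miRNAs (zero designed counts off-genotype,
mirroring observed genotype-restricted rows), 4 drought-upregulated and 3
drought-downregulated miRNAs at a designed |log2 fold change| of 2 applied
in a designated genotype, base abundances log-uniform on 80-2000 expected
counts, 12% imprecise mature reads (ends shifted by 1-2 nt with decaying
probability, so precise processing stays above 75%), 10% contaminant reads
(fragments of synthetic rRNA/tRNA-like sequences), 5% degradation reads and
the classic Illumina small RNA 3' adapter on every read. Library depth and
the problem sizes above were chosen so a full discovery run takes about a
minute on one core while every stage still operates well above its decision
thresholds.

Precursor construction inverts the prediction criteria: the opposite arm is
the reverse complement of the mature with 0-3 planted mismatches, joined by
an unstructured 8-15 nt loop; a complementary extension of 10-22 nt deepens
the stem below the duplex (as in real pre-miRNAs, and keeping the MFE
comfortably past -35 kcal/mol); random flanks with GC 0.45 pad the precursor.
Every construction is folded and re-checked against the structural criteria
at build time, with bounded retries.

Degradation is simulated as dense bidirectional fragment pile-ups over a
dozen non-miRNA source regions, which is both the realistic picture
(degradation products tile their source transcript) and the adversarial
one: any candidate window over such a region carries many scattered
sense/antisense fragments and fails the strand-bias and precise-processing
criteria. Star-strand reads are not simulated, replicate-level structure is
not modeled (libraries are pooled, as sequenced), and there is no per-base
sequencing-error model or genotype SNP simulation — so passing tests
demonstrate correct behavior of the decision rules under clean planted
signal plus structured noise, not performance on the full error spectrum of
real libraries.

## Numerical and degenerate-input choices

* Folding: sequences shorter than 2 nt or without any possible pair return
  energy 0 and an all-dot structure ("non-folding"); non-ACGTU input is an
  error.
* `enumerate_windows()` emits both anchorings even when they coincide after
  clipping; deduplication happens at the fold cache.
* `choose_best_hairpin()` is a total order (final tie-break: leftmost
  start), so permuting candidates never changes the selection.
* Bonferroni caps at 1; p-values are capped into (0, 1].
* `log2_ratio()` returns NA when either TPTM is 0.
* Clustering and naming are order-invariant; new-family labels are stable
  across re-runs on the same input.

## Known limitations

* The bundled energy model is simplified (no dangles, no coaxial stacking,
  no special tetraloops); its absolute energies are not Turner-complete.
  Pass/fail agreement with RNAfold at the -35 kcal/mol threshold is the
  tested contract.
* Exhaustive target scanning is quadratic in transcript length times mature
  length; it is intended for transcript collections, not whole genomes.
* The expression model has no biological replicates and therefore no
  dispersion estimation; the exact test models sampling noise only, as is
  standard for pooled single-library designs.
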