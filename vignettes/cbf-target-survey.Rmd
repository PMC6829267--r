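---
title: "Methods: CBF family identification and the cold-responsive target-gene survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CBF family identification and the cold-responsive target-gene survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfsurvey)
```

This vignette is the package's own account of its methods: what each stage
computes, which tunable parameters matter and why their defaults were
chosen, what the synthetic-data generators emulate, and where the design
was genuinely open.

## The biological procedure

CBF/DREB1 transcription factors are cold-induced AP2/ERF proteins that
bind the CRT/DRE element (G/ACCGAC) in the promoters of cold-responsive
genes. A family survey proceeds from a genome and its gene models to (i)
the family members, (ii) their physicochemical characterization and
phylogeny, (iii) the cis-element content of their promoters, (iv) their
expression across tissues and under cold, and (v) a genome-wide survey of
putative target genes defined by two criteria: a winter/summer expression
change of at least 2-fold, and at least one CRT/DRE in the 1000-bp
promoter.

## Family identification

Candidates are screened by exact Smith–Waterman local alignment against
seed CBF proteins (BLOSUM62, affine gaps with open 11 / extend 1, a gap of
length $L$ costing $11 + L$). The original retrieval step in this kind of
study is a BLAST search followed by domain-database verification; here the
screen is exact local alignment plus explicit signature verification,
which is stricter and fully testable offline. Because no universal score
cutoff exists for arbitrary seeds, the homology threshold is *relative*:
a subject passes at `min_score_frac` (default 0.4) of the seed's
ungapped self-score. The value is a configuration knob, not a claim about
the original search's thresholds, which are not published.

Verification requires both signature sequences in order:
`S1 = P K [KR] P A G R x K F x E T R H P` (two mismatches tolerated at
non-wildcard positions by default, reflecting the natural variation seen
across plant CBFs) and `S2 = DSAWR` (exact by default), with the
separation from the end of S1 to the start of S2 inside 40–120 residues —
the AP2 DNA-binding domain (~60 aa) sits between the signatures, so the
window brackets that length generously on both sides. Wildcard positions
carry no information and never count as mismatches.

## Protein characterization

The property block reproduces the ExPASy-ProtParam definitions exactly:

* **Molecular weight**: sum of *average* residue masses plus one water
  (18.0153 Da), in kDa.
* **pI**: root of the Henderson–Hasselbalch net-charge function under the
  Bjellqvist pKa set, including residue-specific N- and C-terminal pKa
  values. The charge is monotone decreasing in pH, so bisection on
  $[0, 14]$ to $|Q| < 10^{-4}$ finds the unique root.
* **GRAVY**: mean Kyte–Doolittle hydropathy; order-free by construction.
* **Instability index**: $(10/L)\sum_i \mathrm{DIWV}(x_i, x_{i+1})$ over
  the Guruprasad dipeptide weights; values below 40 predict an
  in-vitro-stable protein. Unlike GRAVY this statistic is order-sensitive.
* **Aliphatic index**: $X_A + 2.9\,X_V + 3.9\,(X_I + X_L)$ in mole
  percent.

The Bjellqvist set (rather than, say, the EMBOSS or Lehninger pKa tables)
was chosen because published CBF characterization tables are produced with
ProtParam and only reproduce under this set. Computation runs at full
precision; presentation tables round *half away from zero* to two
decimals (R's `round()` rounds half to even, which would disagree with
published tables on boundary values). Ambiguous residues (B, Z, X) are
rejected with the offending position named.

## Phylogeny

Distances are p-distances from pairwise global (Needleman–Wunsch)
alignments: mismatched positions divided by aligned non-gap columns. This
differs from an MSA-based pipeline (e.g. MEGA's): pairwise p-distances
avoid committing to a multiple alignment but are not guaranteed identical
to MSA-column distances; the choice is flagged, not asserted as
equivalent to any particular published tree. A Poisson correction
$-\log(1-p)$ is available behind a flag.

Neighbor joining follows Saitou–Nei with the Studier–Keppler criterion
$Q(i,j) = (n-2)\,d(i,j) - r_i - r_j$. Two numerical decisions make the
output deterministic and well-formed:

* ties in the $Q$ minimization are broken by the lowest $(i, j)$ index
  pair;
* negative branch-length estimates are clamped to zero with the deficit
  moved to the sibling branch (preserving the pair's total length), and
  the number of clamped branches is recorded on the tree object.

On additive input the algorithm provably returns the generating tree;
the test suite asserts exact recovery (topology and lengths to $10^{-9}$)
on random additive matrices, with `ape::nj` and `phangorn::RF.dist`
serving as independent cross-checks, never as the implementation.

Bootstrap support resamples alignment columns with replacement and
rebuilds the tree per replicate; support is the percentage of replicates
containing each internal bipartition of the full-data tree. With
pairwise alignments there is no single column set, so one *master
coordinate vector* $u \sim U(0,1)^L$ is drawn per replicate and mapped
into each pair's own columns ($\lceil u\,L_{ij}\rceil$), resampling all
pairs jointly. The seed is mandatory (default 20191017) and fixed seeds
give bit-identical supports.

## Promoters and motif scanning

"Upstream 1000 bp of the start codon" is measured from the CDS start, not
the transcript start — transcription start sites are generally unavailable
for non-model genomes, and the original procedure is phrased against the
start codon. Coordinates are 1-based inclusive on disk (GFF3) and
converted once at the reader/writer boundary; promoter windows carry
0-based half-open genome coordinates. Minus-strand promoters are
reverse-complemented so every reported promoter reads 5'→3' toward the
start codon. Windows are clipped at contig edges (`truncated = TRUE`);
zero-length windows are excluded from scans with a warning.

Motif matching is IUPAC-consensus matching (no PWM scores — the CRT/DRE
consensus itself is degenerate, `RCCGAC`): a pattern position matches the
set its code denotes, `N` in the *scanned sequence* matches nothing, all
overlapping windows are reported, and by default both strands are scanned
(minus-strand hits are windows matching the reverse-complemented
pattern), matching how motif-presence tools treat promoters. The survey
criterion only needs presence (≥ 1 hit), so multiplicity is
informational. The shipped cis-element catalogue contains canonical
consensus patterns for the commonly reported plant elements (G-box, ABRE,
CGTCA-motif, MBS, LTR, ERE, TGA-element, TATC-box, GARE-motif, …); it is
a convenience default, not a snapshot of any external database, and can
be replaced wholesale.

## Expression

FPKM is $c \cdot 10^9 / (N L)$ with $L$ the *exonic* length (effective
length correction is out of scope) and $N$ the per-library total mapped
fragments, supplied explicitly rather than recomputed from the table —
column sums understate library totals when the table is a gene subset.

Fold changes guard against zeros with a ratio floor (default 0.1 FPKM)
rather than a pseudocount, so printed FPKM values are unmodified and only
ratios are affected. "At least 2-fold" is boundary-inclusive: `up` iff
$fc \ge 2$, `down` iff $fc \le 0.5$. Winter and summer are single
libraries in this design, so the fold-change criterion carries no
p-value — it is threshold-only by construction.

For qPCR, $\Delta Ct = Ct_{target} - Ct_{ref}$ per biological replicate,
$\Delta\Delta Ct$ subtracts the calibrator's mean $\Delta Ct$, and
$RQ = 2^{-\Delta\Delta Ct}$. The summary RQ is $2^{-\overline{\Delta\Delta Ct}}$
(the geometric mean of replicate RQs), which makes the calibrator's own
RQ identically 1 for any replicate count; the per-replicate RQs and their
standard error are reported alongside. Significance is a two-sided Welch
t-test on the replicate $\Delta Ct$ values against the calibrator's (not
on RQ, whose distribution is log-skewed) at $p < 0.05$; zero-variance
degenerate inputs are resolved by comparing means.

## The target survey

The survey is a set intersection: genes with $|\log_2 fc| \ge 1$ *and*
$\ge 1$ CRT/DRE promoter hit, each record carrying its direction and hit
count, with the totals block (total/up/down) conserving `up + down =
total` by construction. Classification is case-insensitive substring
matching of free-text annotations against an eleven-category keyword map
(carbohydrate metabolism, lipid metabolism, cell wall modification,
circadian rhythm, calcium signaling, transcription factor, hormone
signaling, kinase, chloroplast, transporter, other); multi-category
assignments are kept in map order and unmatched annotations fall into
"other". Enrichment is the upper-tail hypergeometric probability
$P(X \ge k)$ with parameters (background annotated $M$, term size $K$,
survey annotated $n$), with Benjamini–Hochberg adjustment reported next
to the raw p — the conventional $p < 0.05$ call is made on raw p, with
the BH column available for stricter reading. The enrichment background
defaults to all genes with both a promoter and an expression value; term
maps are user-supplied tables, since database annotations are
version-dependent.

## Synthetic data: what it emulates, and what it does not

The generators produce the study's substrate at desk scale with recorded
ground truth:

* `make_genome()` — uniform-base contigs carrying stranded single-CDS
  genes with 1000-bp promoters and a controlled number of planted CRT/DRE
  copies per promoter at recorded offsets. The expected *chance* rate of
  `RCCGAC` is $\approx 2 \cdot (1/4)^6$ per strand per position — about
  one hit per kilobase over both strands — so by default chance hits in
  promoters are scrubbed (a base inside each unplanned hit is mutated),
  making "planted = total" exact for recovery tests. The default study
  fixture is 200 genes on 4 contigs, 110 of them with one planted copy.
* `make_counts()` — a per-gene baseline FPKM drawn log-normally (sd 0.1
  log2 units around 20 FPKM) and *shared by both conditions*; the planted
  effect (default $2^3$) multiplies the winter mean, decoys drift by a
  factor drawn strictly inside (0.6, 1.7), and counts are
  Poisson-sampled around the FPKM-implied means (libraries of $2\times
  10^7$ fragments). The shared baseline mirrors the single-library
  winter/summer design: the only between-condition noise is Poisson
  counting noise, which at these depths perturbs $\log_2 fc$ by well
  under 0.1, so decoys keep a safe margin from the 2-fold boundary and
  planted calls are deterministic. Independent per-condition biological
  noise would make the boundary probabilistic; that regime can be
  explored by widening `noise_sd`, but it is not the fixture's default
  condition.
* `make_family()` — members are point-mutated copies (8% per site outside
  the signatures) of a signature-bearing ancestor, so they are genuinely
  homologous under alignment; backgrounds are uniform-random proteins
  rejection-sampled to carry neither signature at the patterns' own
  mismatch tolerances, guaranteeing zero false positives by construction.
* `evolve_sequences()` — independent-site substitution along a tree: each
  site on a branch of length $t$ is hit with probability
  $1 - e^{-rt}$ and redrawn uniformly from the four bases, so the
  observable per-branch difference saturates at $3/4$ — a Jukes–Cantor
  style process adequate for testing distance-based tree recovery.

Passing on this substrate shows the *computational* chain is correct:
extraction arithmetic, degenerate matching, the selection logic,
NJ/bootstrap, and the statistics. It does not show robustness to what
real data adds — biased base composition, multi-exon gene models with
mis-annotated starts, biological replicate noise, alignment ambiguity in
diverged families, or database-dependent annotations. Those caveats are
inherent to the original procedure as well.

Every generator is a pure function of its seed; all randomness in the
pipeline flows from one configured master seed.

## Problem sizes

The test suite and the acceptance script run at desk scale by design: the
survey study uses 200 genes (30 up, 80 down, 90 decoys), oracle
comparisons use 200 random survey fixtures and 11 motif patterns × 1000
random 1-kb promoters, tree checks use 100 random additive matrices (4–8
taxa) and 100 six-taxon simulations of 1000 sites, and the congruent-
column bootstrap runs the full 1000 replicates. These sizes make every
property exactly checkable while keeping a complete run in minutes.

## Known limitations

* Homology screening is alignment-score based, not an E-value model; the
  relative threshold is a design parameter without a significance
  interpretation.
* Pairwise p-distances are not MSA distances; published trees built with
  MSA pipelines may differ in branch lengths and, for marginal splits,
  topology.
* The pI bisection reproduces ProtParam to ~0.01 pH units; other pKa
  tables give systematically different values.
* Promoter definition ignores transcription start sites and UTRs.
* Keyword classification is a transparent but crude stand-in for curated
  functional annotation; categories are only as good as the keyword map.
* The five published tea CsCBF reference rows can only be checked when
  their sequences (supplementary data of the source study) are supplied
  locally; they are not redistributed with the package.
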